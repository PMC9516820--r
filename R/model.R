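# Model configuration and the two-subnetwork architecture.
#
# Subnetwork1 is one shared hierarchical graph encoder applied to every
# pathway graph: n_blocks of (graph convolution -> SAGPool), a readout after
# each block, graph normalisation between blocks.  The concatenated readouts
# H pass through a two-layer tanh MLP to a scalar pathway score
# S_i = tanh(W2 tanh(W1 H + b1) + c) in (-1, 1).  Subnetwork2 concatenates the
# pathway-score vector with clinical covariates and classifies long-term vs
# non-long-term survival through a 128/32 ReLU MLP with 40% dropout.

#' Configuration of one graph-encoder block
#'
#' @param conv_variant graph convolution: `"sage"` (GraphSAGE with mean
#'   aggregation), `"gat"` (single-head attention) or `"gcn"`.
#' @param hidden_dim node embedding width.
#' @param pool_ratio SAGPool keep fraction in (0, 1].
#' @param readout `"set2set"`, `"add"` or `"mean"`.
#' @param set2set_steps attention rounds of the Set2Set readout.
#' @return a `block_config` list.
#' @export
block_config <- function(conv_variant = c("sage", "gat", "gcn"), hidden_dim = 32L,
                         pool_ratio = 0.5, readout = c("set2set", "add", "mean"),
                         set2set_steps = 2L) {
  conv_variant <- match.arg(conv_variant)
  readout <- match.arg(readout)
  assert_that(hidden_dim >= 1, "hidden_dim must be positive")
  assert_that(pool_ratio > 0 && pool_ratio <= 1, "pool_ratio must be in (0, 1]")
  assert_that(set2set_steps >= 1, "set2set_steps must be positive")
  structure(list(conv_variant = conv_variant, hidden_dim = as.integer(hidden_dim),
                 pool_ratio = pool_ratio, readout = readout,
                 set2set_steps = as.integer(set2set_steps)),
            class = "block_config")
}

#' Full model configuration
#'
#' @param n_pathways number of retained pathways (length of the score vector).
#' @param n_clinical number of clinical covariates entering Subnetwork2.
#' @param n_blocks number of encoder blocks (1, 3 and 5 are the studied
#'   settings; any positive integer is accepted).
#' @param block a [block_config()].
#' @param subnet2_hidden hidden widths of the outcome classifier.
#' @param dropout dropout rate applied before the output layer in training.
#' @param score_hidden hidden width of the per-pathway scoring MLP head.
#' @param graphnorm_after_last also normalise after the final block
#'   (default: between blocks only).
#' @param seed RNG seed for weight initialisation.
#' @return a `model_config` list.
#' @export
model_config <- function(n_pathways, n_clinical = 0L, n_blocks = 3L,
                         block = block_config(), subnet2_hidden = c(128L, 32L),
                         dropout = 0.4, score_hidden = 16L,
                         graphnorm_after_last = FALSE, seed = 2022L) {
  assert_that(n_pathways >= 1, "n_pathways must be positive")
  assert_that(n_blocks >= 1, "n_blocks must be positive")
  assert_that(all(subnet2_hidden >= 1) && length(subnet2_hidden) == 2L,
              "subnet2_hidden must be two positive widths")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  structure(list(n_pathways = as.integer(n_pathways),
                 n_clinical = as.integer(n_clinical),
                 n_blocks = as.integer(n_blocks), block = block,
                 subnet2_hidden = as.integer(subnet2_hidden), dropout = dropout,
                 score_hidden = as.integer(score_hidden),
                 graphnorm_after_last = isTRUE(graphnorm_after_last),
                 seed = as.integer(seed)),
            class = "model_config")
}

readout_dim <- function(block) {
  if (block$readout == "set2set") 2L * block$hidden_dim else block$hidden_dim
}

#' Initialise all model parameters
#'
#' Glorot-uniform weights, zero biases; one shared encoder for all pathways.
#'
#' @param config a [model_config()].
#' @return named list of parameter matrices.
#' @export
init_model_params <- function(config) {
  blk <- config$block
  h <- blk$hidden_dim
  with_seed(config$seed, {
    P <- list()
    for (b in seq_len(config$n_blocks)) {
      din <- if (b == 1L) 1L else h
      pre <- paste0("enc.b", b)
      cp <- conv_param_init(din, h, blk$conv_variant)
      for (nm in names(cp)) P[[paste0(pre, ".conv.", nm)]] <- cp[[nm]]
      P[[paste0(pre, ".pool.Wscore")]] <- glorot(h, 1L)
      P[[paste0(pre, ".pool.bscore")]] <- zeros(1L, 1L)
      if (blk$readout == "set2set") {
        sp <- set2set_param_init(h)
        for (nm in names(sp)) P[[paste0(pre, ".r.", nm)]] <- sp[[nm]]
      }
      if (b < config$n_blocks || config$graphnorm_after_last) {
        P[[paste0(pre, ".gn.gamma")]] <- matrix(1, 1L, h)
        P[[paste0(pre, ".gn.beta")]] <- zeros(1L, h)
        P[[paste0(pre, ".gn.alpha")]] <- matrix(1, 1L, h)
      }
    }
    hdim <- config$n_blocks * readout_dim(blk)
    P[["head.W1"]] <- glorot(hdim, config$score_hidden)
    P[["head.b1"]] <- zeros(1L, config$score_hidden)
    P[["head.W2"]] <- glorot(config$score_hidden, 1L)
    P[["head.c"]] <- zeros(1L, 1L)
    din <- config$n_pathways + config$n_clinical
    w <- config$subnet2_hidden
    P[["clf.W1"]] <- glorot(din, w[1L]); P[["clf.b1"]] <- zeros(1L, w[1L])
    P[["clf.W2"]] <- glorot(w[1L], w[2L]); P[["clf.b2"]] <- zeros(1L, w[2L])
    P[["clf.W3"]] <- glorot(w[2L], 2L); P[["clf.b3"]] <- zeros(1L, 2L)
    P
  })
}

# encoder forward for one pathway graph batch; returns per-block readouts and S
encoder_forward <- function(Pn, gb, X0, config) {
  blk <- config$block
  X <- X0
  reads <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    pre <- paste0("enc.b", b)
    X <- ad_relu(gnn_conv(X, gb, Pn, paste0(pre, ".conv"), blk$conv_variant))
    pl <- gnn_sagpool(X, gb, Pn, paste0(pre, ".pool"), blk$pool_ratio)
    X <- pl$X
    gb <- pl$gb
    if (gb$N == 0L) stop("pooling emptied the graph")
    reads[[b]] <- gnn_readout(X, gb, Pn, paste0(pre, ".r"), blk$readout,
                              blk$set2set_steps)
    if (b < config$n_blocks || config$graphnorm_after_last) {
      X <- gnn_graphnorm(X, gb, Pn, paste0(pre, ".gn"))
    }
  }
  H <- if (config$n_blocks == 1L) reads[[1L]] else ad_concat_cols(reads)
  hid <- ad_tanh(ad_add_rowvec(ad_matmul(H, Pn[["head.W1"]]), Pn[["head.b1"]]))
  S <- ad_tanh(ad_add_rowvec(ad_matmul(hid, Pn[["head.W2"]]), Pn[["head.c"]]))
  list(readouts = reads, S = S)
}

# Subnetwork2 forward: input (B x (P + n_clinical)) -> logits (B x 2)
classifier_forward <- function(Pn, input, config, train_mode = FALSE,
                               dropout_mask = NULL) {
  h1 <- ad_relu(ad_add_rowvec(ad_matmul(input, Pn[["clf.W1"]]), Pn[["clf.b1"]]))
  h2 <- ad_relu(ad_add_rowvec(ad_matmul(h1, Pn[["clf.W2"]]), Pn[["clf.b2"]]))
  if (train_mode && config$dropout > 0) {
    if (is.null(dropout_mask)) {
      keep <- 1 - config$dropout
      dropout_mask <- matrix(stats::rbinom(length(h2$val), 1L, keep) / keep,
                             nrow(h2$val), ncol(h2$val))
    }
    h2 <- ad_mul(h2, dropout_mask)
  }
  ad_add_rowvec(ad_matmul(h2, Pn[["clf.W3"]]), Pn[["clf.b3"]])
}

wrap_all_params <- function(tp, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ad_leaf(tp, params[[nm]])
  out
}

collect_grads <- function(Pn) {
  lapply(Pn, function(nd) if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad)
}

#' Encode a pathway graph to its score
#'
#' Runs the shared Subnetwork1 encoder on one pathway graph for one or more
#' samples: `n_blocks` of (graph convolution -> SAGPool), a readout after each
#' block, graph normalisation between blocks, then the two-layer tanh head
#' mapping the concatenated readouts to the scalar pathway score in (-1, 1).
#'
#' @param features numeric matrix, nodes x samples (one column per sample).
#' @param edges two-column integer matrix of undirected edges.
#' @param params parameter list from [init_model_params()].
#' @param config a [model_config()].
#' @return list with `S` (numeric vector of per-sample scores) and `readouts`
#'   (list of per-block readout matrices, samples x readout width).
#' @export
encode_pathway <- function(features, edges, params, config) {
  features <- as.matrix(features)
  n <- nrow(features)
  B <- ncol(features)
  assert_that(n >= 1L, "pathway graph must have at least one node")
  tp <- ad_tape()
  Pn <- wrap_all_params(tp, params)
  gb <- make_graph_batch(n, as_edge_matrix(edges), B)
  X0 <- ad_leaf(tp, matrix(as.vector(features), ncol = 1L))
  res <- encoder_forward(Pn, gb, X0, config)
  list(S = as.vector(res$S$val),
       readouts = lapply(res$readouts, function(r) r$val))
}

#' Classify samples from pathway scores and clinical features
#'
#' Subnetwork2: the pathway-score vector concatenated with clinical
#' covariates passes through a 128/32 ReLU MLP with dropout (training mode
#' only) and a softmax output.
#'
#' @param S numeric matrix, samples x pathways, of pathway scores.
#' @param clinical numeric matrix, samples x clinical covariates (may have
#'   zero columns).
#' @param params parameter list from [init_model_params()].
#' @param config a [model_config()].
#' @param train_mode logical; enables dropout.
#' @return matrix of class probabilities with columns `nonLTS`, `LTS`.
#' @export
classify <- function(S, clinical = NULL, params, config, train_mode = FALSE) {
  S <- as.matrix(S)
  assert_that(all(is.finite(S)), "NaN or non-finite pathway scores")
  if (is.null(clinical)) clinical <- matrix(0, nrow(S), 0L)
  clinical <- as.matrix(clinical)
  assert_that(all(is.finite(clinical)), "NaN or non-finite clinical features")
  input <- cbind(S, clinical)
  assert_that(ncol(input) == config$n_pathways + config$n_clinical,
              "input width does not match the model configuration")
  tp <- ad_tape()
  Pn <- wrap_all_params(tp, params)
  logits <- classifier_forward(Pn, ad_leaf(tp, input), config, train_mode)
  pr <- softmax_probs(logits$val)
  colnames(pr) <- c("nonLTS", "LTS")
  pr
}

#' Save a trained model checkpoint
#'
#' Writes the model configuration and all parameter matrices to a single JSON
#' file; [load_model()] validates shapes against the embedded configuration.
#'
#' @param model a `pathgnn_model` (or a bare `list(params, config)`).
#' @param path output file.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    block = unclass(model$config$block),
    params = lapply(model$params, function(m) list(dim = dim(m), data = as.vector(m))),
    pathway_ids = model$pathway_ids,
    clinical_features = model$clinical_features,
    preproc = model$preproc,
    version = pathgnn_version()
  )
  obj$config$block <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path JSON checkpoint written by [save_model()].
#' @return a `pathgnn_model` list.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blk <- do.call(block_config, obj$block[c("conv_variant", "hidden_dim",
                                           "pool_ratio", "readout", "set2set_steps")])
  cfgargs <- obj$config[c("n_pathways", "n_clinical", "n_blocks", "subnet2_hidden",
                          "dropout", "score_hidden", "graphnorm_after_last", "seed")]
  cfg <- do.call(model_config, c(cfgargs, list(block = blk)))
  params <- lapply(obj$params, function(p) matrix(p$data, p$dim[1L], p$dim[2L]))
  ref <- init_model_params(cfg)
  assert_that(setequal(names(params), names(ref)),
              "checkpoint parameters do not match the embedded configuration")
  for (nm in names(ref)) {
    assert_that(identical(dim(params[[nm]]), dim(ref[[nm]])),
                paste0("shape mismatch for parameter ", nm))
  }
  structure(list(params = params[names(ref)], config = cfg,
                 pathway_ids = obj$pathway_ids,
                 clinical_features = obj$clinical_features,
                 preproc = obj$preproc),
            class = "pathgnn_model")
}

#' @export
print.pathgnn_model <- function(x, ...) {
  cfg <- x$config
  cat("PathGNN model:", cfg$n_pathways, "pathways,", cfg$n_clinical,
      "clinical features\n")
  cat("  encoder:", cfg$n_blocks, "x (", cfg$block$conv_variant,
      "-> SAGPool(", cfg$block$pool_ratio, ") ->", cfg$block$readout, ")\n")
  cat("  classifier: ", paste(cfg$subnet2_hidden, collapse = "/"),
      " hidden, dropout ", cfg$dropout, "\n", sep = "")
  invisible(x)
}
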