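# Cross-validated training: Adam with the two-phase learning-rate schedule,
# minibatch cross-entropy, AUC evaluation, fold handling and the ablation
# grid runner.

#' Training configuration
#'
#' Defaults follow the reference protocol: 250 epochs, batch size 60, Adam
#' with learning rate 0.001 for the first 150 epochs and 0.0005 afterwards,
#' fivefold cross-validation.
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr_phase1,lr_phase2 learning rates before/after `lr_milestone`.
#' @param lr_milestone last epoch trained at `lr_phase1`.
#' @param folds cross-validation folds.
#' @param seed RNG seed for shuffling, dropout and fold assignment.
#' @param restarts maximum number of fresh re-initialisations when a fit
#'   fails to move off its starting loss (final epoch loss above 95% of the
#'   first epoch's); selection uses the training loss only.  Default 0
#'   (single fit).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 250L, batch_size = 60L, lr_phase1 = 0.001,
                         lr_phase2 = 0.0005, lr_milestone = 150L, folds = 5L,
                         seed = 2022L, restarts = 0L) {
  assert_that(epochs >= 0, "epochs must be nonnegative")
  assert_that(epochs == 0L || lr_milestone < epochs,
              "lr_milestone (end of the first learning-rate phase) must be below epochs")
  assert_that(lr_phase1 > 0 && lr_phase2 > 0, "learning rates must be positive")
  assert_that(batch_size >= 1 && folds >= 2, "invalid batch size or fold count")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 lr_milestone = as.integer(lr_milestone), folds = as.integer(folds),
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "train_config")
}

lr_at_epoch <- function(tc, epoch) {
  if (epoch <= tc$lr_milestone) tc$lr_phase1 else tc$lr_phase2
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals samples round-robin, so folds
#' are disjoint, cover all samples, and per-class counts differ by at most
#' one from proportionality.
#'
#' @param labels class labels (any type with at least `folds` members per
#'   class).
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..folds.
#' @export
stratified_kfold <- function(labels, folds = 5L, seed = 2022L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  assert_that(length(labels) >= folds && all(counts >= 1L),
              "need at least `folds` samples and a non-empty class structure")
  assign <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      # rotate the starting fold across classes so fold sizes balance
      assign[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  assign
}

#' Area under the ROC curve
#'
#' Pairwise-concordance AUC: the probability that a positive sample scores
#' above a negative one, counting ties as one half.  Equals the trapezoidal
#' ROC area.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  assert_that(npos > 0L && nneg > 0L, "AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + state$eps)
  }
  list(state = state, params = params)
}

# ---- model data preparation ------------------------------------------------

#' Prepare model-ready data for a sample subset
#'
#' Extracts per-pathway node-feature matrices, the clinical design matrix and
#' labels for the requested samples, applying the given preprocessing
#' statistics.  When preparing validation data, `preproc` must be fitted on
#' the training samples only, so normalisation statistics never leak across
#' folds; when `preproc` is `NULL` it is fitted on the requested samples.
#'
#' @param dataset a `pathgnn_dataset` from [build_dataset()].
#' @param idx integer indices into the usable (labelled) samples; default all.
#' @param preproc a `pathgnn_preproc` from [fit_preprocess()], or `NULL`.
#' @return a `pathgnn_model_data` list consumed by [train_model()],
#'   [predict_pathgnn()] and [pathway_scores()].
#' @export
prepare_model_data <- function(dataset, idx = NULL, preproc = NULL) {
  ids <- dataset$cohort_used$sample_id
  if (is.null(idx)) idx <- seq_along(ids)
  pp <- preproc %||% fit_preprocess(dataset$expression, dataset$preprocess,
                                    sample_ids = ids[idx])
  X <- apply_preprocess(dataset$expression[, ids[idx], drop = FALSE], pp)
  paths <- dataset$collection$pathways
  feats <- lapply(paths, function(p) {
    r <- match(p$genes, rownames(X))
    m <- matrix(0, length(r), ncol(X))
    ok <- !is.na(r)
    m[ok, ] <- X[r[ok], , drop = FALSE]
    m
  })
  structure(list(
    pathways = lapply(paths, function(p) list(n = length(p$genes),
                                              edges = pathway_edge_index(p))),
    feats = feats,
    clinical = dataset$clinical[idx, , drop = FALSE],
    y = dataset$y[idx],
    sample_ids = ids[idx],
    preproc = pp,
    gb_cache = new.env(parent = emptyenv())
  ), class = "pathgnn_model_data")
}

# One disconnected graph batch holding every pathway graph of every sample in
# the minibatch (graph id = pathway-major, sample-minor), so the shared
# encoder runs once per minibatch.  The structural skeleton depends only on
# the batch size and is cached.
get_multibatch <- function(data, B) {
  key <- paste0("mb.", B)
  mb <- data$gb_cache[[key]]
  if (is.null(mb)) {
    P <- length(data$pathways)
    ns <- vapply(data$pathways, `[[`, integer(1), "n")
    node_offset <- c(0L, cumsum(ns * B))[seq_len(P)]
    groups <- integer(sum(ns) * B)
    src <- vector("list", P)
    dst <- vector("list", P)
    for (p in seq_len(P)) {
      n <- ns[p]
      rows <- node_offset[p] + seq_len(n * B)
      groups[rows] <- (p - 1L) * B + rep(seq_len(B), each = n)
      e <- data$pathways[[p]]$edges
      if (nrow(e)) {
        s0 <- c(e[, 1L], e[, 2L])
        d0 <- c(e[, 2L], e[, 1L])
        off <- node_offset[p] + rep((seq_len(B) - 1L) * n, each = length(s0))
        src[[p]] <- rep(s0, times = B) + off
        dst[[p]] <- rep(d0, times = B) + off
      }
    }
    gb <- graph_batch_from(groups, P * B, unlist(src), unlist(dst),
                           rep(ns, each = B))
    mb <- list(gb = gb, P = P, B = B)
    data$gb_cache[[key]] <- mb
  }
  mb
}

# full forward over one minibatch; returns logits node and score node
pathgnn_batch_forward <- function(Pn, data, batch, config, train_mode) {
  B <- length(batch)
  tp <- Pn[[1L]]$tape
  mb <- get_multibatch(data, B)
  X0 <- ad_leaf(tp, matrix(
    unlist(lapply(data$feats, function(f) f[, batch, drop = FALSE]),
           use.names = FALSE), ncol = 1L))
  enc <- encoder_forward(Pn, mb$gb, X0, config)
  S <- ad_reshape(enc$S, B, mb$P)   # graph order is pathway-major
  input <- if (config$n_clinical > 0L) {
    ad_concat_cols(list(S, data$clinical[batch, , drop = FALSE]))
  } else S
  logits <- classifier_forward(Pn, input, config, train_mode)
  list(logits = logits, S = S)
}

#' Train a PathGNN model
#'
#' Minimises mean cross-entropy with Adam under the two-phase learning-rate
#' schedule; records per-epoch loss and learning rate.  A fixed seed makes
#' the history reproducible.
#'
#' @param data a `pathgnn_model_data` from [prepare_model_data()].
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param params optional initial parameters (default: fresh initialisation
#'   from `config$seed`).
#' @return list with trained `params`, `history` (epoch, loss, lr), `config`
#'   and `tc`.
#' @export
train_model <- function(data, config, tc = train_config(), params = NULL) {
  given_params <- params
  max_restarts <- if (is.null(params)) max(tc$restarts %||% 0L, 0L) else 0L
  for (attempt in 0:max_restarts) {
    if (attempt > 0L) {
      cfg2 <- config
      cfg2$seed <- derive_seed(config$seed, 7000L + attempt)
      tc$seed <- derive_seed(tc$seed, 9000L + attempt)
      params <- init_model_params(cfg2)
    } else {
      params <- given_params
    }
    fit <- train_model_once(data, config, tc, params)
    h <- fit$history
    moved <- nrow(h) == 0L || h$loss[nrow(h)] <= 0.95 * h$loss[1L]
    if (moved || attempt == max_restarts) {
      fit$attempts <- attempt + 1L
      return(fit)
    }
  }
}

train_model_once <- function(data, config, tc, params = NULL) {
  n <- length(data$y)
  assert_that(n > 0L, "empty training data")
  if (tc$epochs > 0L) {
    assert_that(length(unique(data$y)) == 2L,
                "training data must contain both classes")
  }
  params <- params %||% init_model_params(config)
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  if (tc$epochs == 0L) {
    return(list(params = params, history = history, config = config, tc = tc))
  }
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      lr <- lr_at_epoch(tc, epoch)
      perm <- sample(n)
      nb <- ceiling(n / tc$batch_size)
      ep_loss <- 0
      for (bi in seq_len(nb)) {
        batch <- perm[((bi - 1L) * tc$batch_size + 1L):min(bi * tc$batch_size, n)]
        tp <- ad_tape()
        Pn <- wrap_all_params(tp, params)
        fwd <- pathgnn_batch_forward(Pn, data, batch, config, train_mode = TRUE)
        loss <- ad_softmax_crossentropy(fwd$logits, data$y[batch] + 1L)
        if (!is.finite(loss$val)) {
          stop("training loss became non-finite at epoch ", epoch)
        }
        ad_backward(loss)
        st <- adam_step(opt, params, collect_grads(Pn), lr)
        opt <- st$state
        params <- st$params
        ep_loss <- ep_loss + loss$val * length(batch)
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n, lr = lr))
    }
  })
  list(params = params, history = history, config = config, tc = tc)
}

#' Predict class probabilities with a trained model
#'
#' Evaluation mode (dropout disabled); deterministic for fixed inputs.
#'
#' @param fit result of [train_model()] (or a list with `params`, `config`).
#' @param data a `pathgnn_model_data`.
#' @param idx sample indices to score (default all).
#' @param batch_size forward batch size.
#' @return matrix of probabilities with columns `nonLTS`, `LTS`.
#' @export
predict_pathgnn <- function(fit, data, idx = NULL, batch_size = 200L) {
  if (is.null(idx)) idx <- seq_along(data$y)
  out <- matrix(NA_real_, length(idx), 2L, dimnames = list(NULL, c("nonLTS", "LTS")))
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    tp <- ad_tape()
    Pn <- wrap_all_params(tp, fit$params)
    fwd <- pathgnn_batch_forward(Pn, data, sel, fit$config, train_mode = FALSE)
    out[start:(start + length(sel) - 1L), ] <- softmax_probs(fwd$logits$val)
  }
  out
}

#' Pathway-score matrix of a trained model
#'
#' Runs the shared encoder in evaluation mode and returns the Subnetwork1 to
#' Subnetwork2 interface: one score in (-1, 1) per sample and pathway.
#'
#' @inheritParams predict_pathgnn
#' @return numeric matrix, samples x pathways.
#' @export
pathway_scores <- function(fit, data, idx = NULL, batch_size = 200L) {
  if (is.null(idx)) idx <- seq_along(data$y)
  P <- length(data$feats)
  out <- matrix(NA_real_, length(idx), P,
                dimnames = list(data$sample_ids[idx], names(data$feats)))
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    tp <- ad_tape()
    Pn <- wrap_all_params(tp, fit$params)
    fwd <- pathgnn_batch_forward(Pn, data, sel, fit$config, train_mode = FALSE)
    out[start:(start + length(sel) - 1L), ] <- fwd$S$val
  }
  out
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Cross-validated training and evaluation
#'
#' For each fold, preprocessing statistics are refitted on the training
#' portion only, the model is trained on it, and the held-out fold is scored.
#'
#' @param dataset a `pathgnn_dataset`.
#' @param config a [model_config()] **without** `n_pathways`/`n_clinical`
#'   fixed, or `NULL` to use defaults; widths are inferred from the dataset.
#' @param tc a [train_config()].
#' @param config_args named list of [model_config()] arguments used when
#'   `config` is `NULL`.
#' @return a `cv_result`: per-fold AUCs, mean, population sd, fold
#'   assignment, per-fold histories and preprocessing statistics.
#' @export
run_cv <- function(dataset, config = NULL, tc = train_config(),
                   config_args = list()) {
  y <- dataset$y
  folds <- stratified_kfold(y, tc$folds, tc$seed)
  if (is.null(config)) {
    config <- do.call(model_config, c(list(
      n_pathways = length(dataset$collection$pathways),
      n_clinical = ncol(dataset$clinical)), config_args))
  }
  aucs <- numeric(tc$folds)
  histories <- vector("list", tc$folds)
  preprocs <- vector("list", tc$folds)
  for (f in seq_len(tc$folds)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    pp <- fit_preprocess(dataset$expression, dataset$preprocess,
                         sample_ids = dataset$cohort_used$sample_id[tr])
    dtr <- prepare_model_data(dataset, tr, pp)
    dva <- prepare_model_data(dataset, va, pp)
    fit <- train_model(dtr, config, tc)
    pr <- predict_pathgnn(fit, dva)
    aucs[f] <- evaluate_auc(pr[, "LTS"], y[va])
    histories[[f]] <- fit$history
    preprocs[[f]] <- pp
  }
  structure(list(fold_auc = aucs, mean_auc = mean(aucs),
                 sd_auc = population_sd(aucs), folds = folds,
                 histories = histories, preprocs = preprocs,
                 config = config, tc = tc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV AUC: %.3f +/- %.3f  (folds: %s)\n", x$mean_auc, x$sd_auc,
              paste(sprintf("%.3f", x$fold_auc), collapse = ", ")))
  invisible(x)
}

#' Ablation grid runner
#'
#' Runs cross-validation for every configuration in the grid (convolution
#' variant x block count x readout) and tabulates the results.
#'
#' @param dataset a `pathgnn_dataset`.
#' @param grid data frame with columns among `conv_variant`, `n_blocks`,
#'   `readout` (missing columns take the defaults).
#' @param tc a [train_config()].
#' @param config_args extra [model_config()] arguments shared by all rows.
#' @return data frame with one row per grid point: the grid columns, per-fold
#'   AUCs (comma separated), mean and sd.
#' @export
run_ablation <- function(dataset, grid, tc = train_config(), config_args = list()) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- config_args
    blk_args <- list()
    if (!is.null(grid$conv_variant)) blk_args$conv_variant <- as.character(grid$conv_variant[i])
    if (!is.null(grid$readout)) blk_args$readout <- as.character(grid$readout[i])
    if (!is.null(grid$hidden_dim)) blk_args$hidden_dim <- grid$hidden_dim[i]
    base_blk <- args$block %||% block_config()
    for (nm in names(blk_args)) base_blk[[nm]] <- blk_args[[nm]]
    args$block <- do.call(block_config, unclass(base_blk))
    if (!is.null(grid$n_blocks)) args$n_blocks <- grid$n_blocks[i]
    cv <- run_cv(dataset, tc = tc, config_args = args)
    rows[[i]] <- data.frame(
      conv_variant = args$block$conv_variant,
      n_blocks = args$n_blocks %||% 3L,
      readout = args$block$readout,
      fold_auc = paste(sprintf("%.4f", cv$fold_auc), collapse = ","),
      mean_auc = cv$mean_auc, sd_auc = cv$sd_auc,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
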