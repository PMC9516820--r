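# Benchmark models sharing the cross-validation harness: a dense network
# (DNN), the pathway-masked sparse network (PGDNN) whose first layer connects
# each pathway unit only to its member genes, random forest and L2 logistic
# regression.  RF and LR are thin adapters over randomForest and glmnet; the
# neural baselines run on the package's autodiff engine with the same Adam
# protocol as the graph model.

#' Binary gene-by-pathway membership mask
#'
#' @param collection a `pathway_collection`.
#' @param genes gene universe (row order of the mask); default: all genes in
#'   the collection.
#' @return binary matrix, genes x pathways; entry 1 iff the gene belongs to
#'   the pathway.
#' @export
pathway_mask <- function(collection, genes = NULL) {
  genes <- genes %||% unique(unlist(lapply(collection$pathways, `[[`, "genes")))
  M <- matrix(0, length(genes), length(collection$pathways),
              dimnames = list(genes, names(collection$pathways)))
  for (j in seq_along(collection$pathways)) {
    M[intersect(collection$pathways[[j]]$genes, genes), j] <- 1
  }
  M
}

#' Build the dense network baseline
#'
#' Fully connected `n_genes -> 855 -> 128 -> 64 -> 16 -> 2` with ReLU between
#' layers and a softmax output.  Clinical covariates, when present, are
#' concatenated after the first hidden layer.
#'
#' @param n_genes input width.
#' @param n_clinical number of clinical covariates.
#' @param widths hidden-layer widths.
#' @param seed RNG seed for initialisation.
#' @return an `mlp_model` list with `params`, `widths`, `type = "dnn"`.
#' @export
build_dnn <- function(n_genes, n_clinical = 0L, widths = c(855L, 128L, 64L, 16L),
                      seed = 2022L) {
  with_seed(seed, {
    dims <- c(n_genes, widths, 2L)
    params <- list()
    for (l in seq_len(length(dims) - 1L)) {
      din <- dims[l] + if (l == 2L) n_clinical else 0L
      params[[paste0("W", l)]] <- glorot(din, dims[l + 1L])
      params[[paste0("b", l)]] <- zeros(1L, dims[l + 1L])
    }
    structure(list(type = "dnn", params = params, widths = widths,
                   n_genes = n_genes, n_clinical = as.integer(n_clinical),
                   mask = NULL),
              class = "mlp_model")
  })
}

#' Build the pathway-masked sparse network baseline (PGDNN)
#'
#' Same architecture as the dense baseline, but the first hidden layer is the
#' pathway layer: its weight matrix is elementwise-multiplied by the binary
#' gene-by-pathway mask at every forward pass, so pathway unit j receives
#' only its member genes and masked gradients are identically zero.
#'
#' @param mask binary genes x pathways matrix from [pathway_mask()]; every
#'   pathway column must contain at least one 1.
#' @param n_clinical number of clinical covariates (concatenated after the
#'   pathway layer).
#' @param widths widths of the layers after the pathway layer.
#' @param seed RNG seed.
#' @return an `mlp_model` with `type = "pgdnn"`.
#' @export
build_pgdnn <- function(mask, n_clinical = 0L, widths = c(128L, 64L, 16L),
                        seed = 2022L) {
  mask <- as.matrix(mask)
  assert_that(all(colSums(mask != 0) >= 1L),
              "every pathway column of the mask needs at least one member gene")
  m <- build_dnn(nrow(mask), n_clinical, widths = c(ncol(mask), widths), seed = seed)
  m$type <- "pgdnn"
  m$mask <- (mask != 0) * 1
  m$params$W1 <- m$params$W1 * m$mask
  m
}

mlp_forward <- function(model, Pn, X, clinical, config_dropout = 0,
                        train_mode = FALSE) {
  nlayer <- length(model$widths) + 1L
  W1 <- if (!is.null(model$mask)) ad_mul(Pn$W1, model$mask) else Pn$W1
  h <- ad_relu(ad_add_rowvec(ad_matmul(X, W1), Pn$b1))
  if (model$n_clinical > 0L) h <- ad_concat_cols(list(h, clinical))
  for (l in 2L:(nlayer - 1L)) {
    h <- ad_relu(ad_add_rowvec(ad_matmul(h, Pn[[paste0("W", l)]]),
                               Pn[[paste0("b", l)]]))
  }
  if (train_mode && config_dropout > 0) {
    keep <- 1 - config_dropout
    mask <- matrix(stats::rbinom(length(h$val), 1L, keep) / keep,
                   nrow(h$val), ncol(h$val))
    h <- ad_mul(h, mask)
  }
  ad_add_rowvec(ad_matmul(h, Pn[[paste0("W", nlayer)]]), Pn[[paste0("b", nlayer)]])
}

#' Predict class probabilities with a neural baseline
#'
#' @param model a trained `mlp_model`.
#' @param X samples x genes feature matrix.
#' @param clinical samples x covariates matrix (or `NULL`).
#' @return matrix of probabilities, columns `nonLTS`, `LTS`.
#' @export
predict_mlp <- function(model, X, clinical = NULL) {
  tp <- ad_tape()
  Pn <- wrap_all_params(tp, model$params)
  cl <- if (model$n_clinical > 0L) ad_leaf(tp, as.matrix(clinical)) else NULL
  logits <- mlp_forward(model, Pn, ad_leaf(tp, as.matrix(X)), cl)
  pr <- softmax_probs(logits$val)
  colnames(pr) <- c("nonLTS", "LTS")
  pr
}

#' Train a neural baseline with the shared Adam protocol
#'
#' @param model an `mlp_model` from [build_dnn()] or [build_pgdnn()].
#' @param X samples x genes training features.
#' @param y binary labels (1 = LTS).
#' @param clinical optional covariate matrix.
#' @param tc a [train_config()].
#' @param dropout dropout rate before the output layer.
#' @return the model with trained parameters and a `history` element.
#' @export
train_mlp <- function(model, X, y, clinical = NULL, tc = train_config(),
                      dropout = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  params <- model$params
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
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
        cl <- if (model$n_clinical > 0L) {
          ad_leaf(tp, as.matrix(clinical)[batch, , drop = FALSE])
        } else NULL
        logits <- mlp_forward(model, Pn, ad_leaf(tp, X[batch, , drop = FALSE]),
                              cl, dropout, TRUE)
        loss <- ad_softmax_crossentropy(logits, y[batch] + 1L)
        if (!is.finite(loss$val)) stop("baseline loss became non-finite")
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
  model$params <- params
  model$history <- history
  model
}

# samples x genes feature matrix (preprocessed expression of pathway genes)
gene_feature_matrix <- function(dataset, idx, preproc) {
  ids <- dataset$cohort_used$sample_id[idx]
  X <- apply_preprocess(dataset$expression[, ids, drop = FALSE], preproc)
  genes <- unique(unlist(lapply(dataset$collection$pathways, `[[`, "genes")))
  genes <- intersect(genes, rownames(X))
  t(X[genes, , drop = FALSE])
}

#' Run all benchmark methods under shared cross-validation folds
#'
#' Evaluates PathGNN, PGDNN, DNN, random forest and logistic regression with
#' identical fold assignments and per-fold preprocessing.  RF and LR consume
#' the flattened gene-expression table plus clinical covariates; the neural
#' baselines consume genes with clinical covariates concatenated after the
#' first hidden layer.
#'
#' @param dataset a `pathgnn_dataset`.
#' @param methods subset of `c("pathgnn", "pgdnn", "dnn", "rf", "lr")`.
#' @param tc a [train_config()] (shared protocol; also fixes the folds).
#' @param config_args [model_config()] arguments for the PathGNN rows.
#' @param dnn_widths hidden widths of the dense baseline.
#' @param rf_trees random-forest size.
#' @param include_clinical give the neural baselines the clinical covariates.
#' @return data frame: method, per-fold AUCs, mean, sd; the shared fold
#'   assignment is attached as attribute `folds`.
#' @export
run_benchmarks <- function(dataset,
                           methods = c("pathgnn", "pgdnn", "dnn", "rf", "lr"),
                           tc = train_config(), config_args = list(),
                           dnn_widths = c(855L, 128L, 64L, 16L),
                           rf_trees = 500L, include_clinical = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  y <- dataset$y
  folds <- stratified_kfold(y, tc$folds, tc$seed)
  ncl <- if (include_clinical) ncol(dataset$clinical) else 0L
  genes <- unique(unlist(lapply(dataset$collection$pathways, `[[`, "genes")))
  genes <- intersect(genes, rownames(dataset$expression))
  mask <- pathway_mask(dataset$collection, genes)
  res <- list()
  for (m in methods) res[[m]] <- numeric(tc$folds)
  for (f in seq_len(tc$folds)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    pp <- fit_preprocess(dataset$expression, dataset$preprocess,
                         sample_ids = dataset$cohort_used$sample_id[tr])
    Xtr <- gene_feature_matrix(dataset, tr, pp)
    Xva <- gene_feature_matrix(dataset, va, pp)
    ctr <- dataset$clinical[tr, , drop = FALSE]
    cva <- dataset$clinical[va, , drop = FALSE]
    for (m in methods) {
      sc <- switch(m,
        pathgnn = {
          cfg <- do.call(model_config, c(list(
            n_pathways = length(dataset$collection$pathways),
            n_clinical = ncol(dataset$clinical)), config_args))
          fit <- train_model(prepare_model_data(dataset, tr, pp), cfg, tc)
          predict_pathgnn(fit, prepare_model_data(dataset, va, pp))[, "LTS"]
        },
        pgdnn = {
          mdl <- build_pgdnn(mask, n_clinical = ncl, seed = tc$seed)
          mdl <- train_mlp(mdl, Xtr, y[tr],
                           if (ncl > 0L) ctr else NULL, tc, dropout = 0.4)
          predict_mlp(mdl, Xva, if (ncl > 0L) cva else NULL)[, "LTS"]
        },
        dnn = {
          mdl <- build_dnn(ncol(Xtr), n_clinical = ncl, widths = dnn_widths,
                           seed = tc$seed)
          mdl <- train_mlp(mdl, Xtr, y[tr],
                           if (ncl > 0L) ctr else NULL, tc, dropout = 0.4)
          predict_mlp(mdl, Xva, if (ncl > 0L) cva else NULL)[, "LTS"]
        },
        rf = {
          with_seed(tc$seed, {
            rf <- randomForest::randomForest(cbind(Xtr, ctr), factor(y[tr]),
                                             ntree = rf_trees)
            stats::predict(rf, cbind(Xva, cva), type = "prob")[, "1"]
          })
        },
        lr = {
          with_seed(tc$seed, {
            fitlr <- glmnet::cv.glmnet(cbind(Xtr, ctr), y[tr],
                                       family = "binomial", alpha = 0,
                                       nfolds = 3L)
            as.vector(stats::predict(fitlr, cbind(Xva, cva),
                                     s = "lambda.min", type = "response"))
          })
        }
      )
      res[[m]][f] <- evaluate_auc(sc, y[va])
    }
  }
  out <- data.frame(
    method = methods,
    t(vapply(methods, function(m) res[[m]], numeric(tc$folds))),
    mean_auc = vapply(methods, function(m) mean(res[[m]]), numeric(1)),
    sd_auc = vapply(methods, function(m) population_sd(res[[m]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(out)[2:(1 + tc$folds)] <- paste0("fold", seq_len(tc$folds))
  attr(out, "folds") <- folds
  out
}
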