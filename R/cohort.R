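# Cohort handling: expression and clinical IO, survival labelling, clinical
# feature selection, expression preprocessing, and per-patient graph assembly.

#' Read a gene-expression matrix
#'
#' TSV with gene symbols in the first column and one column per sample;
#' values are nonnegative FPKM.
#'
#' @param path TSV file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  assert_that(file.exists(path), paste("cannot read", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- as.character(df[[1L]])
  assert_that(!anyDuplicated(genes), "duplicate gene symbols in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  assert_that(!anyDuplicated(colnames(m)), "duplicate sample ids in expression matrix")
  assert_that(all(is.finite(m)) && all(m >= 0),
              "expression values must be finite and nonnegative")
  m
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `time_years`, `event`, `age`, `stage`
#' (additional covariate columns are carried along).
#'
#' @param path TSV file.
#' @return data frame, one row per sample.
#' @export
read_clinical <- function(path) {
  assert_that(file.exists(path), paste("cannot read", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time_years", "event")
  assert_that(all(need %in% names(df)),
              "clinical table needs sample_id, time_years, event columns")
  df$event <- as.logical(df$event)
  df
}

#' Assign long-term-survival labels
#'
#' A sample is `LTS` when it survived more than `k_years` after diagnosis
#' (alive or deceased), `nonLTS` when it died within `k_years`, and
#' `excluded` when it was censored alive at or before `k_years` (follow-up
#' too short to determine the outcome) or when a required field is missing.
#'
#' @param cohort data frame with `time_years` and `event` columns.
#' @param k_years survival threshold in years (default 3).
#' @return the cohort with a `label` factor column
#'   (`LTS` / `nonLTS` / `excluded`).
#' @export
assign_survival_labels <- function(cohort, k_years = 3) {
  assert_that(k_years > 0, "k_years must be positive")
  t <- cohort$time_years
  ev <- cohort$event
  assert_that(all(is.na(t) | t >= 0), "negative survival time")
  label <- rep("excluded", nrow(cohort))
  ok <- !is.na(t) & !is.na(ev)
  label[ok & t > k_years] <- "LTS"
  label[ok & t <= k_years & ev] <- "nonLTS"
  cohort$label <- factor(label, levels = c("nonLTS", "LTS", "excluded"))
  cohort
}

#' Select clinical features by univariate tests
#'
#' Continuous covariates are compared between the LTS and nonLTS groups by a
#' two-sample t-test, categorical covariates by a chi-square test of the
#' feature-by-label contingency table (no continuity correction).  Features
#' with p < `alpha` are retained; constant features are skipped with a
#' warning.
#'
#' @param cohort labelled cohort from [assign_survival_labels()].
#' @param features candidate column names (default: all columns except the
#'   identifier/survival/label bookkeeping columns).
#' @param alpha significance threshold.
#' @return data frame with `feature`, `type`, `p_value`, `selected`.
#' @export
select_clinical_features <- function(cohort, features = NULL, alpha = 0.05) {
  lab <- cohort$label
  keep <- lab %in% c("LTS", "nonLTS")
  assert_that(sum(lab[keep] == "LTS") > 0L && sum(lab[keep] == "nonLTS") > 0L,
              "need both LTS and nonLTS samples for feature selection")
  if (is.null(features)) {
    features <- setdiff(names(cohort), c("sample_id", "time_years", "event", "label"))
  }
  rows <- list()
  for (f in features) {
    x <- cohort[[f]][keep]
    g <- droplevels(factor(lab[keep]))
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("clinical feature '", f, "' is constant; skipped")
      next
    }
    if (is.numeric(x)) {
      p <- stats::t.test(x ~ g)$p.value
      type <- "continuous"
    } else {
      tab <- table(factor(x), g)
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      type <- "categorical"
    }
    rows[[f]] <- data.frame(feature = f, type = type, p_value = p,
                            selected = p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- expression preprocessing ---------------------------------------------

#' Fit expression preprocessing statistics
#'
#' `none` passes FPKM through; `log2p1` applies log2(FPKM + 1);
#' `log2p1_zscore` additionally standardises each gene over the (training)
#' samples the statistics are fitted on.  Genes with zero variance get unit
#' scale so they map to 0 after centring.
#'
#' @param expression genes x samples FPKM matrix.
#' @param method preprocessing mode.
#' @param sample_ids samples to fit the statistics on (default: all); in
#'   cross-validation these are the training-fold samples only.
#' @return a `pathgnn_preproc` list.
#' @export
fit_preprocess <- function(expression, method = c("log2p1_zscore", "log2p1", "none"),
                           sample_ids = NULL) {
  method <- match.arg(method)
  st <- list(method = method)
  if (method == "log2p1_zscore") {
    sub <- if (is.null(sample_ids)) expression else expression[, sample_ids, drop = FALSE]
    lg <- log2(sub + 1)
    mu <- rowMeans(lg)
    sdv <- apply(lg, 1L, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    st$center <- stats::setNames(mu, rownames(expression))
    st$scale <- stats::setNames(sdv, rownames(expression))
  }
  structure(st, class = "pathgnn_preproc")
}

#' Apply fitted preprocessing to an expression matrix
#'
#' @param expression genes x samples FPKM matrix.
#' @param preproc statistics from [fit_preprocess()].
#' @return transformed matrix of the same shape.
#' @export
apply_preprocess <- function(expression, preproc) {
  switch(preproc$method,
    none = expression,
    log2p1 = log2(expression + 1),
    log2p1_zscore = {
      lg <- log2(expression + 1)
      (lg - preproc$center[rownames(expression)]) /
        preproc$scale[rownames(expression)]
    }
  )
}

#' Build per-patient pathway graph sets
#'
#' For every non-excluded sample, attaches the preprocessed expression of each
#' pathway's genes (in the pathway's fixed gene order) as node features.
#' Genes absent from the expression matrix receive the fill value 0
#' (post-preprocessing); cohort samples missing from the expression matrix are
#' excluded with a warning.
#'
#' @param collection a filtered `pathway_collection`.
#' @param expression genes x samples FPKM matrix.
#' @param cohort labelled cohort from [assign_survival_labels()].
#' @param preprocess preprocessing mode, or a fitted `pathgnn_preproc`.
#' @return list of `patient_graph_set` objects (one per retained sample),
#'   each with `sample_id` and `features` (named list of per-pathway node
#'   feature vectors); the shared pathway order and per-pathway edge indices
#'   are in attributes `pathway_ids` and `edge_index`.
#' @export
build_patient_graphs <- function(collection, expression, cohort,
                                 preprocess = "log2p1_zscore") {
  keep <- cohort$label %in% c("LTS", "nonLTS")
  ids <- cohort$sample_id[keep]
  missing <- setdiff(ids, colnames(expression))
  if (length(missing)) {
    warning(length(missing), " sample(s) missing from the expression matrix were excluded")
    ids <- setdiff(ids, missing)
  }
  pp <- if (inherits(preprocess, "pathgnn_preproc")) preprocess else {
    fit_preprocess(expression, preprocess, sample_ids = ids)
  }
  X <- apply_preprocess(expression[, ids, drop = FALSE], pp)
  pids <- names(collection$pathways)
  gene_rows <- lapply(collection$pathways, function(p) match(p$genes, rownames(X)))
  n_missing_genes <- sum(vapply(gene_rows, function(r) sum(is.na(r)), integer(1)))
  if (n_missing_genes > 0L) {
    warning(n_missing_genes,
            " pathway gene slot(s) absent from the expression matrix; filled with 0")
  }
  out <- lapply(ids, function(s) {
    fl <- lapply(seq_along(pids), function(i) {
      r <- gene_rows[[i]]
      v <- numeric(length(r))
      ok <- !is.na(r)
      v[ok] <- X[r[ok], s]
      v
    })
    names(fl) <- pids
    structure(list(sample_id = s, features = fl), class = "patient_graph_set")
  })
  attr(out, "pathway_ids") <- pids
  attr(out, "edge_index") <- lapply(collection$pathways, pathway_edge_index)
  attr(out, "preproc") <- pp
  out
}

# ---- assembled modelling dataset ------------------------------------------

#' Assemble a modelling dataset from pathway, expression and clinical inputs
#'
#' Applies the size filter and survival labelling, and packages everything the
#' training, baseline and interpretation code consumes.  Expression is kept
#' raw (FPKM); preprocessing statistics are fitted per training fold inside
#' the cross-validation harness.
#'
#' @param collection a `pathway_collection` (filtered or not).
#' @param expression genes x samples FPKM matrix.
#' @param clinical clinical data frame (see [read_clinical()]).
#' @param k_years survival threshold for labelling.
#' @param min_genes,max_genes pathway size filter bounds.
#' @param preprocess default preprocessing mode for model fitting.
#' @param clinical_features character vector of clinical covariates to use,
#'   or `NULL` to run [select_clinical_features()].
#' @param alpha significance threshold for clinical feature selection.
#' @return a `pathgnn_dataset`.
#' @export
build_dataset <- function(collection, expression, clinical, k_years = 3,
                          min_genes = 15L, max_genes = 400L,
                          preprocess = "log2p1_zscore",
                          clinical_features = NULL, alpha = 0.05) {
  if (is.null(collection$provenance$filters)) {
    collection <- filter_pathways(collection, min_genes, max_genes)
  }
  assert_that(length(collection$pathways) > 0L,
              "no pathways remain after filtering")
  cohort <- assign_survival_labels(clinical, k_years)
  keep <- cohort$label %in% c("LTS", "nonLTS") &
    cohort$sample_id %in% colnames(expression)
  n_missing <- sum(cohort$label %in% c("LTS", "nonLTS")) - sum(keep)
  if (n_missing > 0L) {
    warning(n_missing, " labelled sample(s) missing from the expression matrix were excluded")
  }
  cohort_used <- cohort[keep, , drop = FALSE]
  assert_that(nrow(cohort_used) > 0L, "no usable samples after labelling")
  if (is.null(clinical_features)) {
    sel <- tryCatch(select_clinical_features(cohort_used, alpha = alpha),
                    error = function(e) NULL)
    clinical_features <- if (is.null(sel)) character(0) else sel$feature[sel$selected]
  }
  clin_mat <- clinical_design_matrix(cohort_used, clinical_features)
  y <- as.integer(cohort_used$label == "LTS")   # 1 = LTS, 0 = nonLTS
  structure(list(
    collection = collection,
    expression = expression[, cohort_used$sample_id, drop = FALSE],
    cohort = cohort,
    cohort_used = cohort_used,
    y = y,
    clinical_features = clinical_features,
    clinical = clin_mat,
    preprocess = preprocess,
    k_years = k_years
  ), class = "pathgnn_dataset")
}

# numeric design matrix for the selected clinical covariates (categoricals
# dummy-coded; continuous covariates standardised)
clinical_design_matrix <- function(cohort, features) {
  if (length(features) == 0L) {
    return(matrix(0, nrow(cohort), 0L, dimnames = list(cohort$sample_id, NULL)))
  }
  cols <- list()
  for (f in features) {
    x <- cohort[[f]]
    if (is.numeric(x)) {
      s <- stats::sd(x)
      cols[[f]] <- (x - mean(x)) / (if (is.finite(s) && s > 0) s else 1)
    } else {
      x <- factor(x)
      for (lv in levels(x)[-1L]) {
        cols[[paste0(f, "=", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- cohort$sample_id
  m
}

#' @export
print.pathgnn_dataset <- function(x, ...) {
  cat("PathGNN dataset:", length(x$collection$pathways), "pathways,",
      nrow(x$cohort_used), "samples (",
      sum(x$y == 1L), "LTS /", sum(x$y == 0L), "nonLTS ),",
      sum(x$cohort$label == "excluded"), "excluded\n")
  cat("  clinical features:",
      if (length(x$clinical_features)) paste(x$clinical_features, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Serialise a built dataset to a directory with a manifest
#'
#' Writes the standard external dialects (GMT, edge TSV, expression TSV,
#' clinical TSV) plus `manifest.json` recording filter parameters, pathway
#' order and the preprocessing mode.
#'
#' @param dataset a `pathgnn_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pathways(dataset$collection, file.path(dir, "pathways.gmt"),
                 file.path(dir, "edges.tsv"))
  write_expression(dataset$expression, file.path(dir, "expression.tsv"))
  utils::write.table(dataset$cohort, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    filters = dataset$collection$provenance$filters,
    pathway_order = names(dataset$collection$pathways),
    preprocess = dataset$preprocess,
    k_years = dataset$k_years,
    clinical_features = dataset$clinical_features,
    n_samples = nrow(dataset$cohort_used),
    version = pathgnn_version()
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
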