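# Synthetic pathway universes and cohorts with controllable, topology-
# dependent class signal.
#
# The headline mode ("topological") draws causal-pathway expression from a
# Gaussian copula whose correlation sits on the pathway's TRUE edge set for
# short-survival samples and on a degree-preserving REWIRING of that edge set
# for long-survival samples.  Per-gene marginal means and variances are
# identical between classes, so the class signal is invisible to bag-of-genes
# models and reachable only through edge-aware ones.

#' Simulation configuration
#'
#' @param n_pathways number of pathways in the universe.
#' @param n_samples cohort size.
#' @param gene_count_meanlog,gene_count_sdlog log-normal parameters of the
#'   per-pathway gene count (clipped to `[min_genes, max_genes]`; defaults
#'   target a median of about 50 genes).
#' @param min_genes,max_genes clip bounds of the size distribution.
#' @param sharing_rate fraction of each pathway's genes drawn from a shared
#'   pool (controls membership overlap between pathways).
#' @param shared_pool_size size of the shared gene pool.
#' @param graph_model `"erdos_renyi"` or `"barabasi_albert"`.
#' @param er_degree expected node degree of Erdos-Renyi pathway graphs.
#' @param ba_m edges added per node for Barabasi-Albert graphs.
#' @param n_causal number of causal pathways (the first `n_causal` generated).
#' @param effect_mode `"topological"`, `"meanshift"` or `"none"`.
#' @param effect_size edge correlation (topological) or mean shift in
#'   within-gene standard deviations (meanshift); must be nonnegative.
#' @param censoring_rate target fraction of censored survival times.
#' @param class_balance probability of the long-survival latent class.
#' @param k_years survival threshold the cohort is built around.
#' @param clinical_signal age shift (years) of the short-survival class; 0
#'   makes the clinical covariates uninformative.
#' @param expr_meanlog,expr_sdlog,expr_sigma log-scale location spread and
#'   within-gene noise of the FPKM-like expression model
#'   `FPKM = exp(mu_g + sigma * z)`.
#' @param seed RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_pathways = 20L, n_samples = 300L,
                              gene_count_meanlog = log(50), gene_count_sdlog = 0.45,
                              min_genes = 15L, max_genes = 400L,
                              sharing_rate = 0.15, shared_pool_size = 200L,
                              graph_model = c("erdos_renyi", "barabasi_albert"),
                              er_degree = 3, ba_m = 2L,
                              n_causal = 2L,
                              effect_mode = c("topological", "meanshift", "none"),
                              effect_size = 0.8, censoring_rate = 0.3,
                              class_balance = 0.5, k_years = 3,
                              clinical_signal = 0,
                              expr_meanlog = 1.5, expr_sdlog = 0.7,
                              expr_sigma = 0.8, seed = 2022L) {
  graph_model <- match.arg(graph_model)
  effect_mode <- match.arg(effect_mode)
  assert_that(n_pathways >= 1 && n_samples >= 2, "counts must be positive")
  assert_that(effect_size >= 0, "effect size must be nonnegative")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "censoring_rate must be in [0, 1)")
  assert_that(n_causal <= n_pathways, "more causal pathways than pathways")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a pathway universe
#'
#' Pathways with log-normal size distribution, overlapping membership via a
#' shared gene pool, and random interaction graphs.
#'
#' @param config a [simulation_config()].
#' @return a `pathway_collection` in the exact shape [load_pathways()]
#'   produces; causal pathway ids are in `provenance$causal_ids`.
#' @export
simulate_pathway_universe <- function(config) {
  with_seed(config$seed, {
    shared_pool <- sprintf("SG%04d", seq_len(config$shared_pool_size))
    next_private <- 1L
    pw <- list()
    for (i in seq_len(config$n_pathways)) {
      n <- round(stats::rlnorm(1, config$gene_count_meanlog, config$gene_count_sdlog))
      n <- as.integer(min(max(n, config$min_genes), config$max_genes))
      n_shared <- as.integer(round(config$sharing_rate * n))
      assert_that(n_shared <= config$shared_pool_size,
                  "sharing rate infeasible for the shared pool size")
      genes_shared <- if (n_shared > 0L) sample(shared_pool, n_shared) else character(0)
      n_priv <- n - n_shared
      genes_priv <- sprintf("G%05d", seq.int(next_private, length.out = n_priv))
      next_private <- next_private + n_priv
      genes <- sample(c(genes_shared, genes_priv))
      g <- if (config$graph_model == "erdos_renyi") {
        igraph::sample_gnp(n, min(1, config$er_degree / max(n - 1L, 1L)))
      } else {
        igraph::sample_pa(n, m = config$ba_m, directed = FALSE)
      }
      el <- igraph::as_edgelist(g, names = FALSE)
      el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
      edges_sym <- if (nrow(el)) {
        e <- cbind(genes[pmin(el[, 1L], el[, 2L])], genes[pmax(el[, 1L], el[, 2L])])
        e <- unique(t(apply(e, 1L, sort)))
        dimnames(e) <- NULL
        e
      } else matrix(character(0), 0L, 2L)
      id <- sprintf("PW%03d", i)
      pw[[id]] <- new_pathway(id, paste("simulated pathway", i), genes, edges_sym)
    }
    structure(list(
      pathways = pw,
      provenance = list(source = "simulate_pathway_universe",
                        causal_ids = names(pw)[seq_len(config$n_causal)],
                        config_seed = config$seed, filters = NULL)
    ), class = "pathway_collection")
  })
}

# largest rho keeping I + rho*A positive definite, with a small safety margin
shrink_rho <- function(rho, A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(ev)
  if (lmin >= 0) return(rho)
  rho_max <- 0.97 / abs(lmin)
  if (rho > rho_max) {
    warning(sprintf("edge correlation %.2f is not positive definite for this graph; shrunk to %.3f",
                    rho, rho_max))
    rho <- rho_max
  }
  rho
}

adjacency_from_edges <- function(n, edge_idx) {
  A <- matrix(0, n, n)
  if (nrow(edge_idx)) {
    A[edge_idx] <- 1
    A[edge_idx[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

# degree-preserving rewiring by repeated double-edge swaps
rewire_edges <- function(n, edge_idx, seed) {
  if (nrow(edge_idx) < 2L) return(edge_idx)
  with_seed(seed, {
    g <- igraph::graph_from_edgelist(edge_idx, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 100L * nrow(edge_idx)))
    el <- igraph::as_edgelist(g2, names = FALSE)
    el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
    storage.mode(el) <- "integer"
    el
  })
}

#' Simulate a cohort for a pathway universe
#'
#' Generates an FPKM-like expression matrix and a clinical table with
#' censored survival.  A latent class (long vs short survival) drives the
#' expression signal of the causal pathways according to `effect_mode` and
#' class-conditional survival times; labels recovered later by
#' [assign_survival_labels()] agree with the latent class for every
#' non-excluded sample.
#'
#' @param collection a collection from [simulate_pathway_universe()].
#' @param config the same [simulation_config()].
#' @return list with `expression` (genes x samples FPKM matrix), `clinical`
#'   (data frame: sample_id, time_years, event, age, stage) and `truth`
#'   (latent classes, causal ids, rewired edge sets, effective correlations).
#' @export
simulate_cohort <- function(collection, config) {
  with_seed(derive_seed(config$seed, 1L), {
    genes <- unique(unlist(lapply(collection$pathways, `[[`, "genes")))
    ng <- length(genes)
    ns <- config$n_samples
    cls <- stats::rbinom(ns, 1L, config$class_balance)  # 1 = long survival
    Z <- matrix(stats::rnorm(ng * ns), ng, ns, dimnames = list(genes, NULL))
    causal <- collection$provenance$causal_ids %||% character(0)
    if (config$effect_mode == "none") causal <- character(0)
    truth_edges <- list()
    eff_rho <- list()
    for (pid in causal) {
      p <- collection$pathways[[pid]]
      rows <- match(p$genes, genes)
      eidx <- pathway_edge_index(p)
      if (config$effect_mode == "meanshift") {
        Z[rows, cls == 0L] <- Z[rows, cls == 0L] + config$effect_size
        next
      }
      n <- length(p$genes)
      A_true <- adjacency_from_edges(n, eidx)
      eidx_rew <- rewire_edges(n, eidx, derive_seed(config$seed, 100L + match(pid, causal)))
      A_rew <- adjacency_from_edges(n, eidx_rew)
      rho_t <- shrink_rho(config$effect_size, A_true)
      rho_r <- shrink_rho(config$effect_size, A_rew)
      L_true <- t(chol(diag(n) + rho_t * A_true))
      L_rew <- t(chol(diag(n) + rho_r * A_rew))
      # normalise rows so marginal variances stay exactly 1
      L_true <- L_true / sqrt(rowSums(L_true^2))
      L_rew <- L_rew / sqrt(rowSums(L_rew^2))
      raw <- matrix(stats::rnorm(n * ns), n, ns)
      Z[rows, cls == 0L] <- L_true %*% raw[, cls == 0L, drop = FALSE]
      Z[rows, cls == 1L] <- L_rew %*% raw[, cls == 1L, drop = FALSE]
      truth_edges[[pid]] <- eidx_rew
      eff_rho[[pid]] <- c(true = rho_t, rewired = rho_r)
    }
    mu <- stats::rnorm(ng, config$expr_meanlog, config$expr_sdlog)
    expr <- exp(mu + config$expr_sigma * Z)
    sample_ids <- sprintf("S%04d", seq_len(ns))
    colnames(expr) <- sample_ids

    # class-conditional survival: short-survival deaths within k years
    # (truncated exponential), long survivors beyond k years
    k <- config$k_years
    lam0 <- 0.7
    u <- stats::runif(ns)
    death <- numeric(ns)
    short <- cls == 0L
    death[short] <- stats::qexp(u[short] * stats::pexp(k, lam0), lam0)
    death[!short] <- k + stats::rexp(sum(!short), rate = 1 / 2.5)
    death <- pmax(death, 0.05)
    if (config$censoring_rate > 0) {
      f <- function(lc) mean(1 - exp(-lc * death)) - config$censoring_rate
      lam_c <- stats::uniroot(f, c(1e-6, 100))$root
      cens <- stats::rexp(ns, lam_c)
    } else {
      cens <- rep(Inf, ns)
    }
    time <- pmin(death, cens)
    event <- death <= cens
    age <- stats::rnorm(ns, 65, 8) + ifelse(short, config$clinical_signal, 0)
    stage_probs <- if (config$clinical_signal > 0) {
      list(long = c(0.4, 0.3, 0.2, 0.1), short = c(0.15, 0.25, 0.3, 0.3))
    } else {
      list(long = c(0.3, 0.3, 0.25, 0.15), short = c(0.3, 0.3, 0.25, 0.15))
    }
    stage <- vapply(cls, function(ci) {
      sample(c("I", "II", "III", "IV"), 1L,
             prob = if (ci == 1L) stage_probs$long else stage_probs$short)
    }, character(1))
    clinical <- data.frame(sample_id = sample_ids,
                           time_years = round(time, 4),
                           event = event, age = round(age, 1), stage = stage,
                           stringsAsFactors = FALSE)
    list(expression = expr, clinical = clinical,
         truth = list(latent_class = cls, causal_ids = causal,
                      effect_mode = config$effect_mode,
                      effect_size = config$effect_size,
                      effective_rho = eff_rho,
                      rewired_edges = truth_edges,
                      censoring_rate = config$censoring_rate,
                      k_years = k, seed = config$seed))
  })
}

#' Named simulation presets
#'
#' `tiny` (8 pathways, 120 samples, topological signal) for fast end-to-end
#' smoke runs; `null` (20 pathways, 200 samples, no signal) for calibration;
#' `topological` (20 pathways, 2 causal, 300 samples, edge correlation 0.8)
#' for signal recovery; `meanshift` (same sizes, mean-shift signal).
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @return a [simulation_config()].
#' @export
preset_config <- function(preset = c("tiny", "null", "topological", "meanshift"),
                          seed = 2022L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = simulation_config(n_pathways = 8L, n_samples = 120L,
                             gene_count_meanlog = log(25), gene_count_sdlog = 0.35,
                             n_causal = 2L, effect_mode = "topological",
                             effect_size = 0.8, clinical_signal = 6, seed = seed),
    null = simulation_config(n_pathways = 20L, n_samples = 200L,
                             gene_count_meanlog = log(40), gene_count_sdlog = 0.4,
                             n_causal = 0L, effect_mode = "none", seed = seed),
    topological = simulation_config(n_pathways = 20L, n_samples = 300L,
                                    gene_count_meanlog = log(40), gene_count_sdlog = 0.4,
                                    n_causal = 2L, effect_mode = "topological",
                                    effect_size = 0.8, seed = seed),
    meanshift = simulation_config(n_pathways = 20L, n_samples = 300L,
                                  gene_count_meanlog = log(40), gene_count_sdlog = 0.4,
                                  n_causal = 2L, effect_mode = "meanshift",
                                  effect_size = 0.8, clinical_signal = 6, seed = seed)
  )
}

#' Write a complete fixture bundle to a directory
#'
#' Simulates a pathway universe and cohort for a named preset and writes the
#' standard external dialects: `pathways.gmt`, `edges.tsv`, `expression.tsv`,
#' `clinical.tsv`, plus `truth.json` (causal pathway ids and generator
#' parameters) and `manifest.json` with file checksums.
#'
#' @param out_dir output directory (created if needed).
#' @param preset preset name, see [preset_config()].
#' @param seed RNG seed.
#' @param config optional explicit [simulation_config()] overriding the
#'   preset.
#' @return the manifest list, invisibly.
#' @export
write_fixture_bundle <- function(out_dir, preset = "tiny", seed = 2022L,
                                 config = NULL) {
  cfg <- config %||% preset_config(preset, seed)
  collection <- simulate_pathway_universe(cfg)
  sim <- simulate_cohort(collection, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pathways(collection, file.path(out_dir, "pathways.gmt"),
                 file.path(out_dir, "edges.tsv"))
  write_expression(round(sim$expression, 4), file.path(out_dir, "expression.tsv"))
  utils::write.table(sim$clinical, file.path(out_dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$latent_class <- as.integer(truth$latent_class)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("pathways.gmt", "edges.tsv", "expression.tsv", "clinical.tsv",
             "truth.json")
  manifest <- list(preset = preset, seed = seed,
                   n_pathways = cfg$n_pathways, n_samples = cfg$n_samples,
                   effect_mode = cfg$effect_mode, effect_size = cfg$effect_size,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a fixture bundle directory into a modelling dataset
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @param ... passed to [build_dataset()].
#' @return a `pathgnn_dataset`.
#' @export
load_fixture_bundle <- function(dir, ...) {
  collection <- load_pathways(file.path(dir, "pathways.gmt"),
                              file.path(dir, "edges.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  build_dataset(collection, expr, clin, ...)
}
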