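# Shared fixtures, built in code and cached across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# write a minimal GMT + edge file pair and return the paths
write_micro_pathway_files <- function(dir = withr_like_tempdir()) {
  gmt <- file.path(dir, "sets.gmt")
  edg <- file.path(dir, "edges.tsv")
  writeLines(c(
    "P1\tfirst pathway\tgA\tgB\tgC",
    "P2\tsecond pathway\tgB\tgD"
  ), gmt)
  writeLines(c(
    "pathway_id\tgene_a\tgene_b",
    "P1\tgA\tgB",
    "P1\tgB\tgC",
    "P2\tgB\tgD"
  ), edg)
  list(gmt = gmt, edges = edg)
}

withr_like_tempdir <- function() {
  d <- tempfile("pathgnnfix")
  dir.create(d)
  d
}

# training protocol scaled to desk size: same two-phase shape, higher rate
demo_tc <- function(epochs, seed = 1L, folds = 5L, batch = 60L, restarts = 0L) {
  train_config(epochs = epochs, batch_size = batch, lr_phase1 = 0.01,
               lr_phase2 = 0.005, lr_milestone = max(1L, round(0.6 * epochs)),
               folds = folds, seed = seed, restarts = restarts)
}

demo_config_args <- function(seed = 1L) {
  list(n_blocks = 1L, block = block_config("sage", hidden_dim = 8L), seed = seed)
}

# small cohort with a strong mean-shift signal: linearly separable by design
micro_dataset <- function(seed = 5L) {
  cached(paste0("micro", seed), {
    cfg <- simulation_config(n_pathways = 3L, n_samples = 80L,
                             gene_count_meanlog = log(18), gene_count_sdlog = 0.1,
                             sharing_rate = 0, n_causal = 1L,
                             effect_mode = "meanshift", effect_size = 2,
                             censoring_rate = 0.15, clinical_signal = 6,
                             seed = seed)
    coll <- simulate_pathway_universe(cfg)
    sim <- simulate_cohort(coll, cfg)
    build_dataset(coll, sim$expression, sim$clinical)
  })
}

topo_dataset <- function(seed = 11L) {
  cached(paste0("topo", seed), {
    cfg <- preset_config("topological", seed = seed)
    coll <- simulate_pathway_universe(cfg)
    sim <- suppressWarnings(simulate_cohort(coll, cfg))
    ds <- build_dataset(coll, sim$expression, sim$clinical)
    attr(ds, "truth") <- sim$truth
    ds
  })
}

null_dataset <- function(seed = 7L) {
  cached(paste0("null", seed), {
    cfg <- preset_config("null", seed = seed)
    coll <- simulate_pathway_universe(cfg)
    sim <- simulate_cohort(coll, cfg)
    ds <- build_dataset(coll, sim$expression, sim$clinical)
    attr(ds, "truth") <- sim$truth
    ds
  })
}

# a small tanh MLP trained by Adam on a nonlinear regression, exposing the
# scalar value and gradient functions integrated-gradients tests need
trained_tanh_toy <- function(d_in = 4L, hidden = 6L, seed = 7L) {
  set.seed(seed)
  params <- list(W1 = pathgnn:::glorot(d_in, hidden),
                 b1 = pathgnn:::zeros(1L, hidden),
                 W2 = pathgnn:::glorot(hidden, 1L),
                 b2 = pathgnn:::zeros(1L, 1L))
  X <- matrix(rnorm(60 * d_in), 60, d_in)
  y <- matrix(tanh(X[, 1] * X[, 2]) + 0.5 * X[, 3], ncol = 1)
  fwd <- function(Pn, Xn) {
    h <- pathgnn:::ad_tanh(pathgnn:::ad_add_rowvec(
      pathgnn:::ad_matmul(Xn, Pn$W1), Pn$b1))
    pathgnn:::ad_add_rowvec(pathgnn:::ad_matmul(h, Pn$W2), Pn$b2)
  }
  opt <- pathgnn:::adam_init(params)
  for (step in 1:200) {
    tp <- pathgnn:::ad_tape()
    Pn <- pathgnn:::wrap_all_params(tp, params)
    out <- fwd(Pn, pathgnn:::ad_leaf(tp, X))
    resid <- pathgnn:::ad_sub(out, y)
    loss <- pathgnn:::ad_mean(pathgnn:::ad_mul(resid, resid))
    pathgnn:::ad_backward(loss)
    st <- pathgnn:::adam_step(opt, params, pathgnn:::collect_grads(Pn), 0.02)
    opt <- st$state; params <- st$params
  }
  f <- function(S) {
    tp <- pathgnn:::ad_tape()
    Pn <- pathgnn:::wrap_all_params(tp, params)
    as.vector(fwd(Pn, pathgnn:::ad_leaf(tp, as.matrix(S)))$val)
  }
  grad <- function(S) {
    tp <- pathgnn:::ad_tape()
    Pn <- pathgnn:::wrap_all_params(tp, params)
    leaf <- pathgnn:::ad_leaf(tp, as.matrix(S))
    out <- fwd(Pn, leaf)
    pathgnn:::ad_backward(out, matrix(1, nrow(out$val), 1L))
    leaf$grad
  }
  list(f = f, grad = grad, params = params,
       S = matrix(rnorm(20 * d_in, sd = 0.8), 20, d_in))
}

# random small graph for model-layer tests
random_graph <- function(n, p = 0.3, seed = 1L) {
  set.seed(seed)
  e <- which(upper.tri(matrix(0, n, n)) & matrix(runif(n * n) < p, n, n),
             arr.ind = TRUE)
  unname(cbind(e[, 1], e[, 2]))
}

expect_no_warning <- function(expr) {
  expect_warning(expr, regexp = NA)
}
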