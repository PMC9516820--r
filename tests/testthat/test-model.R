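test_that("GraphSAGE convolution follows the self + mean-neighbour update", {
  # 2-node path, x_A = 1, x_B = 3, unit weights, no bias
  params <- list(Wself = matrix(1), Wnbr = matrix(1), b = matrix(0))
  out <- graph_conv(matrix(c(1, 3), 2, 1), matrix(c(1, 2), 1, 2), params, "sage")
  expect_equal(as.vector(out), c(4, 4))
  # isolated node: aggregated term is the zero vector
  out2 <- graph_conv(matrix(c(1, 3), 2, 1), NULL, params, "sage")
  expect_equal(as.vector(out2), c(1, 3))
  # with W_nbr = 0 the layer degenerates to a per-node linear map
  set.seed(4)
  X <- matrix(rnorm(12), 6, 2)
  W <- matrix(rnorm(6), 2, 3)
  p3 <- list(Wself = W, Wnbr = W * 0, b = matrix(0, 1, 3))
  expect_equal(graph_conv(X, random_graph(6), p3, "sage"), X %*% W)
})

test_that("graph convolutions are permutation equivariant", {
  set.seed(8)
  n <- 7
  X <- matrix(rnorm(n * 3), n, 3)
  edges <- random_graph(n, 0.4, seed = 2)
  perm <- sample(n)
  ip <- integer(n); ip[perm] <- seq_len(n)   # new label of old node i
  pedges <- matrix(ip[edges], ncol = 2)
  for (variant in c("sage", "gcn", "gat")) {
    params <- pathgnn:::with_seed(3, pathgnn:::conv_param_init(3L, 4L, variant))
    names(params) <- names(params)
    out <- graph_conv(X, edges, params, variant)
    pout <- graph_conv(X[perm, ], pedges, params, variant)
    expect_equal(pout, out[perm, ], tolerance = 1e-12)
  }
})

test_that("SAGPool keeps ceiling(ratio * n) nodes with index tie-breaks", {
  sp <- list(Wscore = matrix(1), bscore = matrix(0))
  # count contract on random graphs
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(1:50, 1)
    ratio <- runif(1, 0.05, 1)
    X <- matrix(rnorm(n), n, 1)
    res <- sag_pool(X, random_graph(n, 0.2, seed = rep), ratio, sp)
    expect_equal(nrow(res$X), ceiling(ratio * n))
  }
  # all scores equal: kept = lowest original indices
  res <- sag_pool(matrix(1, 5, 1), NULL, 0.5, sp)
  expect_equal(res$kept, c(1L, 2L, 3L))
  # score equals the node feature (isolated nodes, identity scorer):
  # keep the single top node, gated by tanh
  res2 <- sag_pool(matrix(c(0.1, 0.9, 0.5), 3, 1), NULL, 1 / 3, sp)
  expect_equal(res2$kept, 2L)
  expect_equal(res2$X[1, 1], 0.9 * tanh(0.9), tolerance = 1e-12)
  # induced subgraph on kept nodes
  X4 <- matrix(c(4, 3, 2, 1), 4, 1)
  e4 <- matrix(c(1, 2, 2, 3, 3, 4), ncol = 2, byrow = TRUE)
  res3 <- sag_pool(X4, e4, 0.5, sp)
  expect_equal(res3$kept, c(1L, 2L))
  expect_equal(res3$edges, matrix(c(1L, 2L), 1, 2), ignore_attr = TRUE)
  expect_error(sag_pool(matrix(0, 0, 1), NULL, 0.5, sp), "zero nodes")
})

test_that("readouts compute add, mean and Set2Set with the 2d width contract", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(as.vector(readout(X, method = "add")), c(4, 6))
  expect_equal(as.vector(readout(X, method = "mean")), c(2, 3))
  # Set2Set output width is twice the feature width, for any graph
  set.seed(5)
  X2 <- matrix(rnorm(12), 4, 3)
  s2s <- init_set2set_params(3L, seed = 6)
  out <- readout(X2, method = "set2set", params = s2s)
  expect_equal(dim(out), c(1L, 6L))
  # single-node graph: attention weight 1, attended half equals the node
  x1 <- matrix(c(0.3, -0.7, 0.2), 1, 3)
  out1 <- readout(x1, method = "set2set", params = s2s)
  expect_equal(out1[, 4:6, drop = FALSE], x1, ignore_attr = TRUE)
  # two disjoint graphs in one batch equal per-graph readouts stacked
  ga <- c(1L, 1L, 2L, 2L)
  both <- readout(X2, ga, method = "set2set", params = s2s)
  single1 <- readout(X2[1:2, ], method = "set2set", params = s2s)
  single2 <- readout(X2[3:4, ], method = "set2set", params = s2s)
  expect_equal(both, rbind(single1, single2), tolerance = 1e-12)
})

test_that("graph normalisation standardises within graphs independently", {
  set.seed(9)
  X <- matrix(rnorm(20, mean = 3), 10, 2)
  out <- graph_norm(X)
  expect_equal(colMeans(out), c(0, 0), tolerance = 1e-6)
  # constant column collapses to ~0 under the epsilon guard
  Xc <- cbind(rnorm(5), rep(2, 5))
  expect_true(all(abs(graph_norm(Xc)[, 2]) < 1e-6))
  # batch independence
  ga <- rep(1:2, each = 5)
  X2 <- matrix(rnorm(20), 10, 2)
  joint <- graph_norm(X2, ga)
  expect_equal(joint, rbind(graph_norm(X2[1:5, ]), graph_norm(X2[6:10, ])),
               tolerance = 1e-12)
  # scale and shift apply after standardisation
  out2 <- graph_norm(X, scale = c(2, 2), shift = c(1, 1))
  expect_equal(colMeans(out2), c(1, 1), tolerance = 1e-6)
})

test_that("pathway scores live in (-1, 1) and are permutation invariant", {
  set.seed(12)
  cfg <- model_config(n_pathways = 1L, n_clinical = 0L, n_blocks = 2L,
                      block = block_config("sage", hidden_dim = 6L), seed = 3L)
  params <- init_model_params(cfg)
  n <- 12
  edges <- random_graph(n, 0.3, seed = 13)
  feats <- matrix(rnorm(n * 4), n, 4)
  enc <- encode_pathway(feats, edges, params, cfg)
  expect_true(all(abs(enc$S) < 1))
  expect_equal(length(enc$S), 4L)

  # relabelled copy of the same graph gives identical scores (no score ties)
  perm <- sample(n)
  ip <- integer(n); ip[perm] <- seq_len(n)
  enc2 <- encode_pathway(feats[perm, ], matrix(ip[edges], ncol = 2), params, cfg)
  expect_equal(enc2$S, enc$S, tolerance = 1e-9)

  # constant network: zero head weights force S = tanh(c) everywhere
  params0 <- params
  params0$head.W1[] <- 0
  params0$head.W2[] <- 0
  params0$head.c[] <- 0.3
  enc3 <- encode_pathway(feats, edges, params0, cfg)
  expect_equal(enc3$S, rep(tanh(0.3), 4), tolerance = 1e-12)
})

test_that("batched encoding equals singleton encoding", {
  set.seed(30)
  cfg <- model_config(n_pathways = 1L, n_clinical = 0L, n_blocks = 3L,
                      block = block_config("sage", hidden_dim = 5L), seed = 4L)
  params <- init_model_params(cfg)
  n <- 9
  edges <- random_graph(n, 0.35, seed = 31)
  feats <- matrix(rnorm(n * 6), n, 6)
  batch <- encode_pathway(feats, edges, params, cfg)
  singles <- vapply(1:6, function(j) {
    encode_pathway(feats[, j, drop = FALSE], edges, params, cfg)$S
  }, numeric(1))
  expect_equal(batch$S, singles, tolerance = 1e-5)
})

test_that("classifier outputs valid, deterministic probabilities", {
  cfg <- model_config(n_pathways = 4L, n_clinical = 2L, seed = 5L)
  params <- init_model_params(cfg)
  S <- matrix(runif(12, -0.9, 0.9), 3, 4)
  clin <- matrix(rnorm(6), 3, 2)
  p1 <- classify(S, clin, params, cfg)
  expect_equal(rowSums(p1), rep(1, 3), tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  # eval mode is deterministic
  expect_identical(p1, classify(S, clin, params, cfg))
  # zero weights and biases give (0.5, 0.5)
  p0 <- lapply(params, function(m) m * 0)
  expect_equal(unname(classify(S, clin, p0, cfg)),
               matrix(0.5, 3, 2), tolerance = 1e-12)
  expect_error(classify(S * NA, clin, params, cfg), "finite")
})

test_that("checkpoints round-trip parameters and validate shapes", {
  cfg <- model_config(n_pathways = 3L, n_clinical = 1L, n_blocks = 1L,
                      block = block_config("gcn", hidden_dim = 4L), seed = 9L)
  model <- structure(list(params = init_model_params(cfg), config = cfg,
                          pathway_ids = c("A", "B", "C"),
                          clinical_features = "age", preproc = NULL),
                     class = "pathgnn_model")
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  loaded <- load_model(path)
  expect_equal(loaded$params, model$params, tolerance = 1e-12)
  expect_equal(loaded$config$block$conv_variant, "gcn")
  expect_equal(loaded$pathway_ids, model$pathway_ids)
  # corrupt a shape: loading must fail
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$params$head.W1$dim <- c(1L, 1L)
  obj$params$head.W1$data <- 0
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, digits = NA, auto_unbox = TRUE)
  expect_error(load_model(bad), "shape mismatch")
})

test_that("repeated eval-mode forwards are bit-stable", {
  ds <- micro_dataset()
  d <- prepare_model_data(ds)
  cfg <- model_config(n_pathways = length(d$feats), n_clinical = ncol(d$clinical),
                      n_blocks = 1L, block = block_config("sage", hidden_dim = 4L),
                      seed = 2L)
  fit <- list(params = init_model_params(cfg), config = cfg)
  p1 <- predict_pathgnn(fit, d)
  p2 <- predict_pathgnn(fit, d)
  expect_identical(p1, p2)
})
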