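# Batched graph operations.
#
# A "graph batch" replicates one pathway graph across the samples of a
# minibatch: node rows are stacked sample-block by sample-block, `groups`
# maps each row to its sample, and edges are stored as directed index pairs
# (both directions of every undirected interaction).  All per-sample graphs in
# a batch have the same node count, which SAGPool preserves (it keeps
# ceiling(ratio * n) nodes in every sample), so the structure stays uniform
# through the block stack.

make_graph_batch <- function(n_nodes, edges, n_graphs = 1L) {
  assert_that(n_nodes >= 1L, "graph must have at least one node")
  groups <- structure(rep(seq_len(n_graphs), each = n_nodes),
                      uniform_n = as.integer(n_nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    src <- integer(0); dst <- integer(0)
  } else {
    s0 <- c(edges[, 1L], edges[, 2L])
    d0 <- c(edges[, 2L], edges[, 1L])
    off <- rep((seq_len(n_graphs) - 1L) * n_nodes, each = length(s0))
    src <- rep(s0, times = n_graphs) + off
    dst <- rep(d0, times = n_graphs) + off
  }
  graph_batch_from(groups, n_graphs, src, dst,
                   rep(as.integer(n_nodes), n_graphs))
}

# graph batch from an explicit row->graph map and directed edge lists.
# Rows of each graph must be contiguous and in ascending graph order.
graph_batch_from <- function(groups, n_graphs, src, dst, group_sizes) {
  gb <- new.env(parent = emptyenv())
  gb$B <- as.integer(n_graphs)
  gb$group_sizes <- as.integer(group_sizes)
  gb$N <- length(groups)
  if (is.null(attr(groups, "uniform_n")) && length(unique(group_sizes)) == 1L &&
      length(groups) == group_sizes[1L] * n_graphs && !is.unsorted(groups)) {
    attr(groups, "uniform_n") <- as.integer(group_sizes[1L])
  }
  gb$groups <- groups
  gb$src <- src
  gb$dst <- dst
  gb
}

# mean-neighbourhood aggregation operator (rows with no neighbours stay zero)
gb_ahat <- function(gb) {
  if (is.null(gb$Ahat)) {
    deg <- tabulate(gb$dst, nbins = gb$N)
    gb$Ahat <- Matrix::sparseMatrix(
      i = gb$dst, j = gb$src, x = 1 / deg[gb$dst],
      dims = c(gb$N, gb$N)
    )
  }
  gb$Ahat
}

# symmetric-normalised adjacency with self-loops (GCN propagation operator)
gb_shat <- function(gb) {
  if (is.null(gb$Shat)) {
    deg <- tabulate(gb$dst, nbins = gb$N) + 1
    i <- c(gb$dst, seq_len(gb$N))
    j <- c(gb$src, seq_len(gb$N))
    gb$Shat <- Matrix::sparseMatrix(
      i = i, j = j, x = 1 / sqrt(deg[i] * deg[j]),
      dims = c(gb$N, gb$N)
    )
  }
  gb$Shat
}

# ---- differentiable layers (internal, ad-node in / ad-node out) ------------

# Graph convolution.  sage: h' = X W_self + mean_nbr(X) W_nbr + b
# gcn: h' = Shat X W + b;  gat: single-head attention over self-looped edges.
gnn_conv <- function(X, gb, P, prefix, variant) {
  if (variant == "sage") {
    agg <- ad_matmul(gb_ahat(gb), X)
    ad_add_rowvec(
      ad_add(ad_matmul(X, P[[paste0(prefix, ".Wself")]]),
             ad_matmul(agg, P[[paste0(prefix, ".Wnbr")]])),
      P[[paste0(prefix, ".b")]]
    )
  } else if (variant == "gcn") {
    ad_add_rowvec(ad_matmul(ad_matmul(gb_shat(gb), X), P[[paste0(prefix, ".W")]]),
                  P[[paste0(prefix, ".b")]])
  } else if (variant == "gat") {
    Wh <- ad_matmul(X, P[[paste0(prefix, ".W")]])
    es <- ad_matmul(Wh, P[[paste0(prefix, ".asrc")]])  # N x 1
    ed <- ad_matmul(Wh, P[[paste0(prefix, ".adst")]])
    src <- c(gb$src, seq_len(gb$N))
    dst <- c(gb$dst, seq_len(gb$N))
    e <- ad_leakyrelu(ad_add(ad_gather(es, src), ad_gather(ed, dst)), 0.2)
    alpha <- ad_segment_softmax(e, dst, gb$N)
    out <- ad_segment_sum(ad_mul_colvec(ad_gather(Wh, src), alpha), dst, gb$N)
    ad_add_rowvec(out, P[[paste0(prefix, ".b")]])
  } else {
    stop("unknown conv variant: ", variant)
  }
}

conv_param_init <- function(din, dout, variant) {
  if (variant == "sage") {
    list(Wself = glorot(din, dout), Wnbr = glorot(din, dout), b = zeros(1L, dout))
  } else if (variant == "gcn") {
    list(W = glorot(din, dout), b = zeros(1L, dout))
  } else if (variant == "gat") {
    list(W = glorot(din, dout), asrc = glorot(dout, 1L), adst = glorot(dout, 1L),
         b = zeros(1L, dout))
  } else stop("unknown conv variant: ", variant)
}

# Self-attention graph pooling.  Scores nodes with a GCN layer mapping to a
# scalar, keeps the ceiling(ratio*n) top-scoring nodes per graph (ties broken
# by lower original index), gates kept features by tanh(score), and induces
# the subgraph on the kept nodes.
gnn_sagpool <- function(X, gb, P, prefix, ratio) {
  z <- ad_add_rowvec(ad_matmul(ad_matmul(gb_shat(gb), X), P[[paste0(prefix, ".Wscore")]]),
                     P[[paste0(prefix, ".bscore")]])
  B <- gb$B
  sizes <- gb$group_sizes
  k <- as.integer(ceiling(ratio * sizes))
  # one radix sort over (graph, -score): stable, so ties keep the lower
  # original index; rows of each graph are contiguous blocks
  ord <- order(gb$groups, -as.vector(z$val), method = "radix")
  starts <- c(0L, cumsum(sizes)[-B])
  topk <- ord[sequence(k) + rep(starts, k)]
  kept <- sort(topk)
  Xk <- ad_mul_colvec(ad_gather(X, kept), ad_tanh(ad_gather(z, kept)))
  pos <- integer(gb$N)
  pos[kept] <- seq_along(kept)
  keep_e <- pos[gb$src] > 0L & pos[gb$dst] > 0L
  gb2 <- graph_batch_from(rep(seq_len(B), k), B,
                          pos[gb$src[keep_e]], pos[gb$dst[keep_e]], k)
  list(X = Xk, gb = gb2, kept = kept, score = z)
}

# Set2Set readout: T rounds of LSTM query update + content-based attention.
# Output per graph is [q_T, r_T], twice the node-feature width.
gnn_set2set <- function(X, gb, P, prefix, steps) {
  d <- ncol(X$val)
  B <- gb$B
  q <- matrix(0, B, d)
  cstate <- matrix(0, B, d)
  qstar <- matrix(0, B, 2L * d)
  r <- NULL
  for (t in seq_len(steps)) {
    gate <- function(tag) {
      ad_add_rowvec(
        ad_add(ad_matmul(qstar, P[[paste0(prefix, ".Wx", tag)]]),
               ad_matmul(q, P[[paste0(prefix, ".Wh", tag)]])),
        P[[paste0(prefix, ".b", tag)]]
      )
    }
    i <- ad_sigmoid(gate("i"))
    f <- ad_sigmoid(gate("f"))
    o <- ad_sigmoid(gate("o"))
    g <- ad_tanh(gate("g"))
    cstate <- ad_add(ad_mul(f, cstate), ad_mul(i, g))
    q <- ad_mul(o, ad_tanh(cstate))
    e <- ad_rowsum(ad_mul(X, ad_gather(q, gb$groups)))
    a <- ad_segment_softmax(e, gb$groups, B)
    r <- ad_segment_sum(ad_mul_colvec(X, a), gb$groups, B)
    qstar <- ad_concat_cols(list(q, r))
  }
  qstar
}

set2set_param_init <- function(d) {
  out <- list()
  for (tag in c("i", "f", "o", "g")) {
    out[[paste0("Wx", tag)]] <- glorot(2L * d, d)
    out[[paste0("Wh", tag)]] <- glorot(d, d)
    out[[paste0("b", tag)]] <- zeros(1L, d)
  }
  out
}

gnn_readout <- function(X, gb, P, prefix, method, steps = 2L) {
  assert_that(gb$N >= 1L, "readout on an empty graph batch")
  switch(method,
    add = ad_segment_sum(X, gb$groups, gb$B),
    mean = ad_segment_mean(X, gb$groups, gb$B),
    set2set = gnn_set2set(X, gb, P, prefix, steps),
    stop("unknown readout method: ", method)
  )
}

# Graph normalisation: per graph and feature dimension, subtract the learnably
# weighted within-graph mean, divide by the within-graph sd (+eps), then apply
# scale and shift.
gnn_graphnorm <- function(X, gb, P, prefix, eps = 1e-5) {
  m <- ad_segment_mean(X, gb$groups, gb$B)
  mr <- ad_gather(m, gb$groups)
  xc <- ad_sub(X, ad_mul_rowvec(mr, P[[paste0(prefix, ".alpha")]]))
  v <- ad_segment_mean(ad_mul(xc, xc), gb$groups, gb$B)
  inv <- ad_pow(ad_add_const(ad_gather(v, gb$groups), eps), -0.5)
  ad_add_rowvec(ad_mul_rowvec(ad_mul(xc, inv), P[[paste0(prefix, ".gamma")]]),
                P[[paste0(prefix, ".beta")]])
}

# ---- user-facing single-graph wrappers -------------------------------------

wrap_params <- function(tp, params, prefix) {
  P <- list()
  for (nm in names(params)) P[[paste0(prefix, ".", nm)]] <- ad_leaf(tp, params[[nm]])
  P
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) return(matrix(integer(0), 0L, 2L))
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  edges
}

#' Graph convolution on a single graph
#'
#' Applies one graph-convolution layer (`sage`, `gcn` or `gat`) to a node
#' feature matrix.  For `sage` the update is
#' `h'_v = X W_self + mean_{u in N(v)} x_u W_nbr + b`; nodes without
#' neighbours receive a zero aggregated term.
#'
#' @param X numeric matrix, nodes x features.
#' @param edges two-column integer matrix of undirected edges (node indices).
#' @param params named list of weight matrices as produced by the variant's
#'   initialiser: `sage` needs `Wself`, `Wnbr`, `b`; `gcn` needs `W`, `b`;
#'   `gat` needs `W`, `asrc`, `adst`, `b`.
#' @param variant one of `"sage"`, `"gcn"`, `"gat"`.
#' @return numeric matrix of convolved node features.
#' @export
graph_conv <- function(X, edges, params, variant = c("sage", "gcn", "gat")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  tp <- ad_tape()
  P <- wrap_params(tp, params, "c")
  gb <- make_graph_batch(nrow(X), as_edge_matrix(edges), 1L)
  gnn_conv(ad_leaf(tp, X), gb, P, "c", variant)$val
}

#' Self-attention graph pooling (SAGPool) on a single graph
#'
#' Scores nodes with a one-layer graph convolution mapping to a scalar, keeps
#' the `ceiling(pool_ratio * n)` highest-scoring nodes (ties broken by lower
#' original index), gates the kept rows by `tanh(score)`, and returns the
#' induced subgraph.
#'
#' @param X numeric node-feature matrix.
#' @param edges two-column integer matrix of undirected edges.
#' @param pool_ratio fraction of nodes to keep, in (0, 1].
#' @param score_params named list with `Wscore` (d x 1) and `bscore` (1 x 1).
#' @return list with `X` (gated kept features), `edges` (re-indexed induced
#'   undirected edges), `kept` (original indices of kept nodes) and `score`
#'   (raw attention scores of all nodes).
#' @export
sag_pool <- function(X, edges, pool_ratio, score_params) {
  assert_that(pool_ratio > 0 && pool_ratio <= 1, "pool_ratio must be in (0, 1]")
  X <- as.matrix(X)
  assert_that(nrow(X) >= 1L, "cannot pool a graph with zero nodes")
  tp <- ad_tape()
  P <- wrap_params(tp, score_params, "p")
  gb <- make_graph_batch(nrow(X), as_edge_matrix(edges), 1L)
  res <- gnn_sagpool(ad_leaf(tp, X), gb, P, "p", pool_ratio)
  e2 <- cbind(res$gb$src, res$gb$dst)
  e2 <- e2[e2[, 1L] < e2[, 2L], , drop = FALSE]  # one row per undirected edge
  list(X = res$X$val, edges = e2, kept = res$kept, score = as.vector(res$score$val))
}

#' Graph readout on a batch of graphs
#'
#' Aggregates node features into one vector per graph by global add pooling,
#' global average pooling, or the Set2Set iterative-attention readout (output
#' width `2 * ncol(X)`).
#'
#' @param X numeric node-feature matrix.
#' @param graph_assignment integer vector mapping each row to its graph id
#'   (1..G); defaults to a single graph.
#' @param method `"set2set"`, `"add"` or `"mean"`.
#' @param params for `set2set`, LSTM parameters from [init_set2set_params()].
#' @param steps number of Set2Set attention rounds.
#' @return numeric matrix, one row per graph.
#' @export
readout <- function(X, graph_assignment = NULL, method = c("set2set", "add", "mean"),
                    params = NULL, steps = 2L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  assert_that(nrow(X) >= 1L, "readout on an empty graph")
  if (is.null(graph_assignment)) graph_assignment <- rep(1L, nrow(X))
  B <- max(graph_assignment)
  assert_that(all(tabulate(graph_assignment, B) > 0L),
              "every graph in the batch must have at least one node")
  gb <- graph_batch_from(as.integer(graph_assignment), B, integer(0), integer(0),
                         tabulate(graph_assignment, B))
  tp <- ad_tape()
  P <- if (method == "set2set") {
    if (is.null(params)) params <- init_set2set_params(ncol(X))
    wrap_params(tp, params, "r")
  } else list()
  gnn_readout(ad_leaf(tp, X), gb, P, "r", method, steps)$val
}

#' Initialise Set2Set LSTM parameters
#'
#' @param d node-feature width the readout will operate on.
#' @param seed optional RNG seed for reproducible initialisation.
#' @return named list of LSTM gate weights.
#' @export
init_set2set_params <- function(d, seed = NULL) {
  with_seed(seed, set2set_param_init(d))
}

#' Graph normalisation
#'
#' Per graph and per feature dimension, subtracts the learnably weighted
#' within-graph mean and divides by the within-graph standard deviation
#' (guarded by `eps`), then applies `scale` and `shift`.
#'
#' @param X numeric node-feature matrix.
#' @param graph_assignment integer row-to-graph map (defaults to one graph).
#' @param scale,shift numeric vectors of length `ncol(X)`.
#' @param alpha mean weight (length `ncol(X)`; default 1 = full centering).
#' @param eps variance guard.
#' @return normalised node-feature matrix.
#' @export
graph_norm <- function(X, graph_assignment = NULL, scale = NULL, shift = NULL,
                       alpha = NULL, eps = 1e-5) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (is.null(graph_assignment)) graph_assignment <- rep(1L, nrow(X))
  params <- list(
    gamma = matrix(scale %||% rep(1, d), 1L),
    beta = matrix(shift %||% rep(0, d), 1L),
    alpha = matrix(alpha %||% rep(1, d), 1L)
  )
  B <- max(graph_assignment)
  gb <- graph_batch_from(as.integer(graph_assignment), B, integer(0), integer(0),
                         tabulate(graph_assignment, B))
  tp <- ad_tape()
  P <- wrap_params(tp, params, "n")
  gnn_graphnorm(ad_leaf(tp, X), gb, P, "n", eps)$val
}
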