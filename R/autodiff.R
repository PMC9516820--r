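# Reverse-mode automatic differentiation on dense matrices.
#
# Every neural component in the package (graph convolutions, pooling, Set2Set,
# the classifier heads) is expressed with the `ad_*` operations below, so one
# backward pass over the recorded tape yields exact gradients for Adam and for
# integrated-gradients attribution.  Values are base R matrices; sparse
# `Matrix` objects may appear as constant left operands of `ad_matmul` (the
# neighbourhood-aggregation operators), never as differentiated nodes.

#' @keywords internal
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

is_adnode <- function(x) is.environment(x)

ad_val <- function(x) if (is_adnode(x)) x$val else x

ad_node <- function(tape, val, bw = NULL) {
  id <- tape$n + 1L
  tape$n <- id
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$id <- id
  nd$tape <- tape
  class(nd) <- "adnode"
  if (id > length(tape$nodes)) {
    nodes <- tape$nodes
    length(nodes) <- 2L * id
    tape$nodes <- nodes
  }
  tape$nodes[[id]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  if (!is_adnode(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ad_leaf <- function(tape, val) ad_node(tape, val)

tape_of <- function(...) {
  for (x in list(...)) if (is_adnode(x)) return(x$tape)
  stop("at least one argument must be an ad node")
}

# ---- elementary operations -------------------------------------------------

ad_matmul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  val <- as.matrix(av %*% bv)
  ad_node(tp, val, bw = function(g) {
    if (is_adnode(a)) ad_accum(a, as.matrix(g %*% t(bv)))
    if (is_adnode(b)) ad_accum(b, as.matrix(Matrix::crossprod(av, g)))
  })
}

ad_add <- function(a, b) {
  tp <- tape_of(a, b)
  val <- ad_val(a) + ad_val(b)
  ad_node(tp, val, bw = function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

ad_sub <- function(a, b) {
  tp <- tape_of(a, b)
  val <- ad_val(a) - ad_val(b)
  ad_node(tp, val, bw = function(g) {
    ad_accum(a, g)
    if (is_adnode(b)) ad_accum(b, -g)
  })
}

# X (n x d) + row vector b (length d), broadcast over rows
ad_add_rowvec <- function(x, b) {
  tp <- tape_of(x, b)
  xv <- ad_val(x); bv <- as.vector(ad_val(b))
  n <- nrow(xv)
  val <- xv + rep(bv, each = n)
  ad_node(tp, val, bw = function(g) {
    ad_accum(x, g)
    if (is_adnode(b)) ad_accum(b, matrix(colSums(g), 1L))
  })
}

ad_mul <- function(a, b) {
  tp <- tape_of(a, b)
  av <- ad_val(a); bv <- ad_val(b)
  ad_node(tp, av * bv, bw = function(g) {
    if (is_adnode(a)) ad_accum(a, g * bv)
    if (is_adnode(b)) ad_accum(b, g * av)
  })
}

# X (n x d) * column vector v (n x 1), broadcast across columns
ad_mul_colvec <- function(x, v) {
  tp <- tape_of(x, v)
  xv <- ad_val(x); vv <- as.vector(ad_val(v))
  ad_node(tp, xv * vv, bw = function(g) {
    if (is_adnode(x)) ad_accum(x, g * vv)
    if (is_adnode(v)) ad_accum(v, matrix(rowSums(g * xv), ncol = 1L))
  })
}

# X (n x d) * row vector v (length d), broadcast down rows
ad_mul_rowvec <- function(x, v) {
  tp <- tape_of(x, v)
  xv <- ad_val(x); vv <- as.vector(ad_val(v))
  n <- nrow(xv)
  vrep <- rep(vv, each = n)
  ad_node(tp, xv * vrep, bw = function(g) {
    if (is_adnode(x)) ad_accum(x, g * vrep)
    if (is_adnode(v)) ad_accum(v, matrix(colSums(g * xv), 1L))
  })
}

ad_scale <- function(a, s) {
  ad_node(tape_of(a), ad_val(a) * s, bw = function(g) ad_accum(a, g * s))
}

ad_add_const <- function(a, c) {
  ad_node(tape_of(a), ad_val(a) + c, bw = function(g) ad_accum(a, g))
}

ad_pow <- function(a, p) {
  av <- ad_val(a)
  ad_node(tape_of(a), av^p, bw = function(g) ad_accum(a, g * p * av^(p - 1)))
}

ad_tanh <- function(a) {
  v <- tanh(ad_val(a))
  ad_node(tape_of(a), v, bw = function(g) ad_accum(a, g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-ad_val(a)))
  ad_node(tape_of(a), v, bw = function(g) ad_accum(a, g * v * (1 - v)))
}

ad_relu <- function(a) {
  av <- ad_val(a)
  v <- pmax(av, 0)
  ad_node(tape_of(a), v, bw = function(g) ad_accum(a, g * (av > 0)))
}

ad_leakyrelu <- function(a, slope = 0.2) {
  av <- ad_val(a)
  pos <- av > 0
  v <- ifelse(pos, av, slope * av)
  dim(v) <- dim(av)
  ad_node(tape_of(a), v, bw = function(g) ad_accum(a, g * ifelse(pos, 1, slope)))
}

ad_exp <- function(a) {
  v <- exp(ad_val(a))
  ad_node(tape_of(a), v, bw = function(g) ad_accum(a, g * v))
}

ad_sum <- function(a) {
  av <- ad_val(a)
  ad_node(tape_of(a), matrix(sum(av), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

ad_mean <- function(a) {
  av <- ad_val(a)
  n <- length(av)
  ad_node(tape_of(a), matrix(mean(av), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(as.numeric(g) / n, nrow(av), ncol(av)))
  })
}

# row sums: (n x d) -> (n x 1)
ad_rowsum <- function(a) {
  av <- ad_val(a)
  d <- ncol(av)
  ad_node(tape_of(a), matrix(rowSums(av), ncol = 1L), bw = function(g) {
    ad_accum(a, matrix(rep(as.vector(g), d), nrow(av), d))
  })
}

# gather rows by index (with repetitions allowed)
ad_gather <- function(x, idx) {
  xv <- ad_val(x)
  idx <- as.integer(idx)
  ad_node(tape_of(x), xv[idx, , drop = FALSE], bw = function(g) {
    gr <- rowsum(g, group = idx)
    full <- matrix(0, nrow(xv), ncol(xv))
    full[as.integer(rownames(gr)), ] <- gr
    ad_accum(x, full)
  })
}

# per-group row sums: (n x d, groups in 1..G) -> (G x d).  When the groups
# are contiguous equal-size blocks (attribute "uniform_n" set), the sum is a
# cheap reshaped colSums.
ad_segment_sum <- function(x, groups, ngroups) {
  xv <- ad_val(x)
  un <- attr(groups, "uniform_n")
  if (!is.null(un)) {
    d <- ncol(xv)
    val <- colSums(array(xv, c(un, ngroups, d)), dims = 1L)
    if (d == 1L) val <- matrix(val, ncol = 1L)
  } else {
    groups <- as.integer(groups)
    val <- matrix(0, ngroups, ncol(xv))
    gr <- rowsum(xv, group = groups)
    val[as.integer(rownames(gr)), ] <- gr
  }
  ad_node(tape_of(x), val, bw = function(g) {
    ad_accum(x, g[groups, , drop = FALSE])
  })
}

ad_segment_mean <- function(x, groups, ngroups) {
  counts <- tabulate(as.integer(groups), nbins = ngroups)
  s <- ad_segment_sum(x, groups, ngroups)
  ad_mul_colvec(s, matrix(1 / pmax(counts, 1L), ncol = 1L))
}

# softmax of a column vector within groups (all groups 1..G non-empty)
ad_segment_softmax <- function(x, groups, ngroups) {
  xv <- as.vector(ad_val(x))
  un <- attr(groups, "uniform_n")
  if (!is.null(un)) {
    zm <- matrix(xv, un, ngroups)
    mx <- zm[1L, ]
    if (un > 1L) for (r in 2L:un) mx <- pmax(mx, zm[r, ])
    e <- exp(xv - rep(mx, each = un))
    tot <- colSums(matrix(e, un, ngroups))
    a <- e / rep(tot, each = un)
  } else {
    groups <- as.integer(groups)
    mx <- vapply(split(xv, groups), max, numeric(1))
    e <- exp(xv - mx[groups])
    tot <- rowsum(e, groups)[, 1L]
    a <- e / tot[groups]
  }
  ad_node(tape_of(x), matrix(a, ncol = 1L), bw = function(g) {
    gv <- as.vector(g)
    if (!is.null(un)) {
      dot <- colSums(matrix(a * gv, un, ngroups))
      ad_accum(x, matrix(a * (gv - rep(dot, each = un)), ncol = 1L))
    } else {
      dot <- rowsum(a * gv, groups)[, 1L]
      ad_accum(x, matrix(a * (gv - dot[groups]), ncol = 1L))
    }
  })
}

ad_reshape <- function(a, nrow, ncol) {
  av <- ad_val(a)
  ad_node(tape_of(a), matrix(as.vector(av), nrow, ncol), bw = function(g) {
    ad_accum(a, matrix(as.vector(g), dim(av)[1L], dim(av)[2L]))
  })
}

ad_concat_cols <- function(parts) {
  tp <- NULL
  for (p in parts) if (is_adnode(p)) { tp <- p$tape; break }
  vals <- lapply(parts, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  val <- do.call(cbind, vals)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tp, val, bw = function(g) {
    for (i in seq_along(parts)) {
      if (is_adnode(parts[[i]])) {
        ad_accum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
      }
    }
  })
}

# mean softmax cross-entropy with integer labels in 1..K; fused for stability
ad_softmax_crossentropy <- function(logits, y) {
  lv <- ad_val(logits)
  n <- nrow(lv)
  y <- as.integer(y)
  m <- apply(lv, 1L, max)
  ex <- exp(lv - m)
  p <- ex / rowSums(ex)
  picked <- p[cbind(seq_len(n), y)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  ad_node(tape_of(logits), matrix(loss, 1L, 1L), bw = function(g) {
    oh <- matrix(0, n, ncol(lv))
    oh[cbind(seq_len(n), y)] <- 1
    ad_accum(logits, as.numeric(g) * (p - oh) / n)
  })
}

#' @keywords internal
ad_backward <- function(root, grad = NULL) {
  tp <- root$tape
  root$grad <- if (is.null(grad)) matrix(1, nrow(root$val), ncol(root$val)) else grad
  for (i in root$id:1L) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd) && !is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# softmax probabilities (plain numeric, no tape) for evaluation paths
softmax_probs <- function(logits) {
  m <- apply(logits, 1L, max)
  ex <- exp(logits - m)
  ex / rowSums(ex)
}
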