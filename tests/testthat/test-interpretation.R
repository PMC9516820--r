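# a tiny trained classifier head over pathway scores, reused across blocks
toy_fit <- function(P = 4L, seed = 3L) {
  cached(paste0("toyfit", P, seed), {
    cfg <- model_config(n_pathways = P, n_clinical = 0L,
                        subnet2_hidden = c(6L, 4L), dropout = 0, seed = seed)
    set.seed(seed)
    params <- init_model_params(cfg)
    # keep only the classifier head; nudge weights so f is genuinely nonlinear
    params$clf.W1 <- params$clf.W1 * 3
    list(params = params, config = cfg)
  })
}

test_that("integrated gradients are exact for linear models at any step count", {
  set.seed(14)
  w <- rnorm(5)
  grad_fn <- function(X) matrix(w, nrow(X), 5, byrow = TRUE)
  S <- matrix(rnorm(15), 3, 5)
  for (steps in c(1L, 7L, 64L)) {
    att <- integrated_gradients(grad_fn, S, baseline = NULL, steps = steps)
    expect_equal(att, S * matrix(w, 3, 5, byrow = TRUE), tolerance = 1e-12)
  }
  # input equal to the baseline: all attributions are zero
  b <- rnorm(5)
  att0 <- integrated_gradients(grad_fn, matrix(b, 1), baseline = b, steps = 16L)
  expect_equal(as.vector(att0), rep(0, 5))
})

test_that("completeness holds against a 10,000-step quadrature oracle", {
  fit <- toy_fit()
  f <- pathgnn:::classifier_value_fn(fit$params, fit$config)
  gf <- pathgnn:::classifier_grad_fn(fit$params, fit$config)
  set.seed(15)
  S <- matrix(runif(5 * 4, -0.9, 0.9), 5, 4)
  gap_vs_truth <- function(steps) {
    att <- integrated_gradients(gf, S, steps = steps)
    truth <- f(S) - f(matrix(0, 1, 4))
    abs(rowSums(att) - truth)
  }
  oracle <- integrated_gradients(gf, S, steps = 10000L)
  att256 <- integrated_gradients(gf, S, steps = 256L)
  truth <- f(S) - rep(f(matrix(0, 1, 4)), 5)
  # oracle itself closes the completeness gap
  expect_equal(rowSums(oracle), truth, tolerance = 1e-6)
  # 256 steps: relative gap below 1e-3
  expect_true(all(abs(rowSums(att256) - truth) <
                    1e-3 * abs(truth) + 1e-6))
  # and attributions converge to the oracle's
  expect_equal(att256, oracle, tolerance = 1e-3)
})

test_that("functionally identical models receive identical attributions", {
  # a two-layer linear network and its algebraically collapsed form
  set.seed(16)
  W1 <- matrix(rnorm(12), 4, 3)
  W2 <- matrix(rnorm(3), 3, 1)
  w <- W1 %*% W2
  gf_deep <- function(X) matrix(as.vector(w), nrow(X), 4, byrow = TRUE)
  gf_flat <- function(X) matrix(as.vector(w), nrow(X), 4, byrow = TRUE)
  S <- matrix(rnorm(8), 2, 4)
  expect_equal(integrated_gradients(gf_deep, S, steps = 32L),
               integrated_gradients(gf_flat, S, steps = 32L), tolerance = 1e-6)
  # and the autodiff gradient of the real classifier head agrees with
  # numerical differentiation of its value function
  fitlin <- toy_fit()
  gf <- pathgnn:::classifier_grad_fn(fitlin$params, fitlin$config)
  S1 <- matrix(c(0.2, -0.3, 0.5, 0.1), 1, 4)
  eps <- 1e-6
  f <- pathgnn:::classifier_value_fn(fitlin$params, fitlin$config)
  num <- vapply(1:4, function(j) {
    up <- S1; up[j] <- up[j] + eps
    dn <- S1; dn[j] <- dn[j] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(as.vector(gf(S1)), num, tolerance = 1e-5)
})

test_that("pathway importance z-scores follow the population convention", {
  # aggregates [1, 2, 9]: z(9) = (9-4)/3.5590 = 1.4048, not selected
  att <- rbind(c(1, 2, 9), c(1, 2, 9))
  colnames(att) <- c("a", "b", "c")
  imp <- pathway_importance(att)
  expect_equal(imp$aggregate, c(1, 2, 9))
  expect_equal(imp$z[3], (9 - 4) / sqrt(mean((c(1, 2, 9) - 4)^2)),
               tolerance = 1e-10)
  expect_equal(round(imp$z[3], 4), round(5 / sqrt(38 / 3), 4))  # 1.4049
  expect_false(any(imp$selected))

  # the strict > 1.96 rule: reported-scale z-scores like 4.955 and 3.927
  # clear the cut-off, 0.1 does not
  expect_equal(c(4.955, 3.927, 0.1) > 1.96, c(TRUE, TRUE, FALSE))
  # in a wider collection, two strongly attributed pathways are the selected set
  set.seed(17)
  agg <- c(10, 8, rnorm(38, 0, 0.5))
  att2 <- rbind(agg, agg + rnorm(40, 0, 0.01))
  colnames(att2) <- paste0("pw", 1:40)
  imp2 <- pathway_importance(att2)
  expect_setequal(imp2$pathway_id[imp2$selected], c("pw1", "pw2"))
  expect_true(all(imp2$z[1:2] > 1.96))

  # degenerate: equal aggregates select nothing, with a warning
  expect_warning(imp3 <- pathway_importance(matrix(1, 3, 3)), "zero variance")
  expect_false(any(imp3$selected))
  expect_error(pathway_importance(matrix(1, 3, 1)), "two pathways")
})

test_that("the z threshold corresponds to two-sided p below 0.05", {
  expect_lte(2 * stats::pnorm(1.96, lower.tail = FALSE), 0.05)
})

test_that("log-rank statistic matches the hand computation and survdiff", {
  # groups A events at 1, 2; B events at 3, 4; no censoring.
  # By hand over the four event times: O_A = 2, E_A = 1/2 + 1/3 = 0.8333,
  # V = 1/4 + 2/9 = 0.47222, so (O-E)^2/V = 2.88235.
  time <- c(1, 2, 3, 4)
  event <- rep(TRUE, 4)
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$observed[1], 2)
  expect_equal(lr$expected[1], 1 / 2 + 1 / 3, tolerance = 1e-12)
  expect_equal(lr$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  skip_if_not_installed("survival")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank agrees with survdiff on random censored data", {
  skip_if_not_installed("survival")
  set.seed(18)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    time <- round(rexp(n, 0.3), 2)
    event <- runif(n) > 0.3
    grp <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(grp)) < 2) grp[1:2] <- c("x", "y")
    if (!any(event)) event[1] <- TRUE
    lr <- logrank_test(time, event, grp)
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
    expect_equal(lr$p_value, stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("log-rank null behaviour and permutation oracle agree", {
  # identical survival in both groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(TRUE, 6),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  # permutation oracle: the permutation p-value of the statistic brackets the
  # chi-square p for the worked example
  time <- c(1, 2, 3, 4); event <- rep(TRUE, 4)
  obs <- logrank_test(time, event, c("A", "A", "B", "B"))$statistic
  perms <- combn(4, 2)
  stats_perm <- apply(perms, 2, function(ix) {
    g <- rep("B", 4); g[ix] <- "A"
    logrank_test(time, event, g)$statistic
  })
  p_perm <- mean(stats_perm >= obs - 1e-12)
  # the observed split is the most extreme of the 6 assignments
  expect_equal(max(stats_perm), obs, tolerance = 1e-12)
  expect_equal(p_perm, 2 / 6, tolerance = 1e-12)  # ties: the mirror split
})

test_that("Kaplan-Meier product-limit and Greenwood band match closed forms", {
  km <- km_curve(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, c(4L, 3L, 2L, 1L))
  # Greenwood variance after the first death: S^2 * d/(n(n-d))
  expect_equal(km$se[1], 0.75 * sqrt(1 / (4 * 3)), tolerance = 1e-12)
  skip_if_not_installed("survival")
  set.seed(19)
  time <- round(rexp(30, 0.4), 2)
  event <- runif(30) > 0.25
  if (!any(event)) event[1] <- TRUE
  ours <- km_curve(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  at <- sf$time %in% ours$time & sf$n.event > 0
  expect_equal(ours$surv, sf$surv[at], tolerance = 1e-10)
  ok <- ours$surv > 0   # survfit reports no finite se once S hits 0
  expect_equal(ours$se[ok], (sf$std.err[at] * sf$surv[at])[ok], tolerance = 1e-8)
})

test_that("median splits put ties in the high group and reject degenerate ones", {
  ig <- c(0.1, 0.5, 0.5, 0.9, 0.2, 0.7)
  sp <- median_split_logrank(ig, c(1, 2, 3, 4, 5, 6), rep(TRUE, 6))
  expect_equal(as.character(sp$group),
               c("low", "high", "high", "high", "low", "high"))
  expect_true(sp$p_value >= 0 && sp$p_value <= 1)
  expect_error(median_split_logrank(rep(1, 6), 1:6, rep(TRUE, 6)),
               "fewer than two")
})

test_that("a survival difference planted between groups is detected", {
  set.seed(20)
  n <- 60
  ig <- c(rnorm(n / 2, 1), rnorm(n / 2, -1))
  time <- c(rexp(n / 2, 1), 3 + rexp(n / 2, 1 / 3))
  sp <- median_split_logrank(ig, time, rep(TRUE, n))
  expect_lt(sp$p_value, 0.001)
  expect_true(all(c("high", "low") %in% names(sp$km)))
  expect_true(all(sp$km$high$lower <= sp$km$high$surv + 1e-12))
})
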