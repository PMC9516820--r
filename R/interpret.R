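# Model interpretation: integrated-gradients attribution over the pathway
# score vector, z-score selection of aberrant pathways, and median-split
# Kaplan-Meier / log-rank follow-up.

#' Integrated gradients along a straight-line path
#'
#' Midpoint-Riemann approximation of
#' `(x - x') * integral_0^1 grad f(x' + a (x - x')) da`, per feature.
#' Satisfies completeness (attributions sum to `f(x) - f(x')` as the step
#' count grows) and implementation invariance.
#'
#' @param grad_fn function taking a numeric matrix (rows = inputs) and
#'   returning the gradient of the scalar model output at each row, same
#'   shape.
#' @param X inputs to attribute, samples x features.
#' @param baseline baseline vector `x'` (default all zeros).
#' @param steps number of integration steps (>= 1).
#' @return attribution matrix, same shape as `X`.
#' @export
integrated_gradients <- function(grad_fn, X, baseline = NULL, steps = 256L) {
  X <- as.matrix(X)
  assert_that(steps >= 1L, "steps must be at least 1")
  n <- nrow(X); d <- ncol(X)
  baseline <- if (is.null(baseline)) rep(0, d) else as.numeric(baseline)
  assert_that(length(baseline) == d, "baseline length must match feature count")
  diff <- X - matrix(baseline, n, d, byrow = TRUE)
  alphas <- (seq_len(steps) - 0.5) / steps
  # evaluate all (step, sample) points in one call
  big <- matrix(baseline, n * steps, d, byrow = TRUE) +
    diff[rep(seq_len(n), times = steps), , drop = FALSE] *
    rep(alphas, each = n)
  G <- grad_fn(big)
  assert_that(all(is.finite(G)), "non-finite gradient during path integration")
  avg <- matrix(0, n, d)
  for (s in seq_len(steps)) {
    avg <- avg + G[((s - 1L) * n + 1L):(s * n), , drop = FALSE]
  }
  dimnames(diff) <- dimnames(X)
  diff * (avg / steps)
}

# gradient of the chosen classifier output w.r.t. the pathway-score inputs,
# with clinical covariates held at the baseline (removed for interpretation)
classifier_grad_fn <- function(params, config, target = c("logit_nonLTS",
                                                          "logit_LTS",
                                                          "prob_nonLTS")) {
  target <- match.arg(target)
  sel <- switch(target,
    logit_nonLTS = matrix(c(1, 0), 2L, 1L),
    logit_LTS = matrix(c(0, 1), 2L, 1L),
    prob_nonLTS = NULL
  )
  function(S) {
    S <- as.matrix(S)
    tp <- ad_tape()
    Pn <- wrap_all_params(tp, params)
    inp <- ad_leaf(tp, S)
    full <- if (config$n_clinical > 0L) {
      ad_concat_cols(list(inp, matrix(0, nrow(S), config$n_clinical)))
    } else inp
    logits <- classifier_forward(Pn, full, config, train_mode = FALSE)
    out <- if (is.null(sel)) {
      # two-class softmax probability: sigmoid of the logit difference
      ad_sigmoid(ad_matmul(logits, matrix(c(1, -1), 2L, 1L)))
    } else {
      ad_matmul(logits, sel)
    }
    ad_backward(out, matrix(1, nrow(S), 1L))
    inp$grad
  }
}

# scalar model value matching classifier_grad_fn (for completeness checks)
classifier_value_fn <- function(params, config, target = "logit_nonLTS") {
  function(S) {
    S <- as.matrix(S)
    tp <- ad_tape()
    Pn <- wrap_all_params(tp, params)
    full <- if (config$n_clinical > 0L) {
      cbind(S, matrix(0, nrow(S), config$n_clinical))
    } else S
    logits <- classifier_forward(Pn, ad_leaf(tp, full), config, FALSE)$val
    switch(target,
      logit_nonLTS = logits[, 1L],
      logit_LTS = logits[, 2L],
      prob_nonLTS = softmax_probs(logits)[, 1L]
    )
  }
}

#' Attribute predictions to pathways with integrated gradients
#'
#' Computes per-sample, per-pathway integrated-gradients attributions of the
#' short-survival (nonLTS) logit with respect to the pathway-score vector,
#' with clinical covariates held at the baseline (they are removed for
#' interpretation runs) and an all-zero pathway-score baseline.
#'
#' @param fit trained model (list with `params`, `config`).
#' @param S pathway-score matrix from [pathway_scores()].
#' @param baseline score baseline (default all zeros, the centre of the tanh
#'   range).
#' @param steps integration steps.
#' @param target scalar output to attribute: the nonLTS logit (default,
#'   avoids softmax saturation), the LTS logit, or the nonLTS probability.
#' @return attribution matrix, samples x pathways.
#' @export
attribute_pathways <- function(fit, S, baseline = NULL, steps = 256L,
                               target = "logit_nonLTS") {
  gf <- classifier_grad_fn(fit$params, fit$config, target)
  integrated_gradients(gf, S, baseline, steps)
}

#' Aggregate attributions into pathway importance and select aberrant pathways
#'
#' Per-pathway aggregate attribution, z-transformed over pathways
#' (population sd); pathways with z > `z_threshold` (strict) are flagged as
#' candidate aberrant pathways.
#'
#' The default aggregate is the signed mean attribution over the
#' **risk-class samples** (`risk`, normally the nonLTS group).  Averaging
#' over the whole cohort cancels: attributions of a discriminative pathway
#' carry opposite signs in the two outcome classes (the product of score and
#' gradient is invariant to the arbitrary sign the encoder learns for the
#' score, and flips with the class), so with balanced classes the cohort
#' mean sits near zero regardless of how important the pathway is.
#' Restricting the mean to the risk class yields a statistic that is
#' strictly positive for risk-predictive pathways, symmetric around zero
#' under the null (so the z > 1.96 rule keeps its nominal ~2.5% false
#' selection rate), and invariant to the score's sign.  When `risk` is
#' `NULL` the mean is taken over all samples; `"mean_abs"` aggregates
#' magnitudes instead.
#'
#' @param attributions samples x pathways attribution matrix (>= 2 pathways).
#' @param aggregate `"mean_risk"` (default), `"mean_abs"`, or `"mean"`.
#' @param risk logical or integer index of the risk-class (nonLTS) rows,
#'   used by `"mean_risk"`; `NULL` means all rows.
#' @param z_threshold selection cut-off (default 1.96, two-sided p < 0.05).
#' @return data frame: `pathway_id`, `aggregate`, `z`, `selected`.
#' @export
pathway_importance <- function(attributions,
                               aggregate = c("mean_risk", "mean_abs", "mean"),
                               risk = NULL, z_threshold = 1.96) {
  aggregate <- match.arg(aggregate)
  attributions <- as.matrix(attributions)
  assert_that(ncol(attributions) >= 2L, "z-scores need at least two pathways")
  agg <- switch(aggregate,
    mean = colMeans(attributions),
    mean_abs = colMeans(abs(attributions)),
    mean_risk = {
      sub <- if (is.null(risk)) attributions else attributions[risk, , drop = FALSE]
      assert_that(nrow(sub) >= 1L, "no risk-class samples to aggregate over")
      colMeans(sub)
    })
  sdv <- population_sd(agg)
  if (sdv < 1e-12) {
    warning("pathway aggregates have zero variance; no pathway selected")
    z <- rep(0, length(agg))
  } else {
    z <- (agg - mean(agg)) / sdv
  }
  data.frame(pathway_id = colnames(attributions) %||% paste0("P", seq_along(agg)),
             aggregate = unname(agg), z = unname(z),
             selected = unname(z > z_threshold),
             stringsAsFactors = FALSE)
}

# ---- survival statistics ---------------------------------------------------

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed vs expected events in group 1 summed
#' over the pooled event times (censoring respected), chi-square p-value on
#' one degree of freedom.
#'
#' @param time follow-up times.
#' @param event event indicator (TRUE/1 = event observed).
#' @param group two-level group membership.
#' @return list with `statistic`, `p_value`, `observed`, `expected` (group
#'   order = factor level order).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) == 2L, "log-rank test needs two groups")
  g1 <- group == levels(group)[1L]
  event <- as.logical(event)
  times <- sort(unique(time[event]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
    }
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = c(O1, sum(event) - O1),
       expected = c(E1, sum(event) - E1))
}

#' Kaplan-Meier product-limit curve with Greenwood confidence band
#'
#' @param time follow-up times.
#' @param event event indicator.
#' @param conf_level confidence level of the Greenwood band.
#' @return data frame with one row per distinct event time: `time`, `n_risk`,
#'   `n_event`, `surv`, `se`, `lower`, `upper`.
#' @export
km_curve <- function(time, event, conf_level = 0.95) {
  event <- as.logical(event)
  times <- sort(unique(time[event]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  surv <- 1
  gw <- 0
  rows <- lapply(times, function(t) {
    n <- sum(time >= t)
    d <- sum(event & time == t)
    surv <<- surv * (1 - d / n)
    if (n > d) gw <<- gw + d / (n * (n - d))
    se <- surv * sqrt(gw)
    data.frame(time = t, n_risk = n, n_event = d, surv = surv, se = se,
               lower = max(surv - zq * se, 0), upper = min(surv + zq * se, 1))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                      surv = numeric(0), se = numeric(0), lower = numeric(0),
                      upper = numeric(0))
  }
  out
}

#' Median-split survival comparison for one pathway
#'
#' Dichotomizes samples at the median of their per-sample attribution (ties
#' to the high group), compares the two groups with the log-rank test, and
#' returns Kaplan-Meier coordinates with 95% Greenwood bands.
#'
#' @param per_sample_ig per-sample attribution values for one pathway.
#' @param survival_times follow-up times (same order).
#' @param events event indicators.
#' @return list with `group` (factor high/low), `statistic`, `p_value`, and
#'   `km` (named list of per-group Kaplan-Meier curves).
#' @export
median_split_logrank <- function(per_sample_ig, survival_times, events) {
  med <- stats::median(per_sample_ig)
  grp <- factor(ifelse(per_sample_ig >= med, "high", "low"),
                levels = c("high", "low"))
  assert_that(min(table(grp)) >= 2L,
              "median split left fewer than two samples in a group")
  lr <- logrank_test(survival_times, events, grp)
  list(group = grp, statistic = lr$statistic, p_value = lr$p_value,
       km = list(high = km_curve(survival_times[grp == "high"], events[grp == "high"]),
                 low = km_curve(survival_times[grp == "low"], events[grp == "low"])))
}

#' Full interpretation pass over a trained model
#'
#' Computes pathway scores, integrated-gradients attributions, pathway
#' importance with z-score selection, and the median-split log-rank test for
#' every selected pathway (skipping, with a message, pathways whose split is
#' degenerate).
#'
#' @param fit trained model from [train_model()].
#' @param data `pathgnn_model_data` for the samples to interpret.
#' @param survival data frame with `time_years` and `event` columns aligned
#'   to `data$sample_ids`.
#' @param steps integration steps.
#' @param z_threshold selection cut-off.
#' @param all_pathways also run the survival split for unselected pathways.
#' @return list with `S`, `attributions`, `importance` (with a `logrank_p`
#'   column for tested pathways) and `splits`.
#' @export
interpret_model <- function(fit, data, survival, steps = 256L,
                            z_threshold = 1.96, all_pathways = FALSE) {
  S <- pathway_scores(fit, data)
  att <- attribute_pathways(fit, S, steps = steps)
  imp <- pathway_importance(att, risk = data$y == 0L, z_threshold = z_threshold)
  imp$logrank_p <- NA_real_
  splits <- list()
  test_idx <- if (all_pathways) seq_len(nrow(imp)) else which(imp$selected)
  for (i in test_idx) {
    pid <- imp$pathway_id[i]
    sp <- tryCatch(
      median_split_logrank(att[, pid], survival$time_years, survival$event),
      error = function(e) {
        message("survival split skipped for ", pid, ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(sp)) {
      imp$logrank_p[i] <- sp$p_value
      splits[[pid]] <- sp
    }
  }
  list(S = S, attributions = att, importance = imp, splits = splits)
}
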