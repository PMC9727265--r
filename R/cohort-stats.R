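# Statistics computable from printed group summaries (n, mean, SD) or raw
# vectors: one-way ANOVA, LSD post-hoc, two-sample t, chi-square/Fisher,
# ROC with Youden cutoff, logistic risk models.

#' Build a group summary table
#'
#' @param label Group labels.
#' @param n Group sizes.
#' @param mean,sd Group means and standard deviations (units of the
#'   underlying variable).
#' @return A tibble usable by the `*_from_summary()` tests.
#' @export
group_summary <- function(label, n, mean, sd) {
  out <- tibble::tibble(label = as.character(label), n = as.integer(n),
                        mean = as.numeric(mean), sd = as.numeric(sd))
  if (any(out$n < 1) || any(out$sd < 0) || any(out$n < 2 & out$sd > 0)) {
    abort("invalid group summary: need n >= 1, sd >= 0, and n >= 2 when sd > 0",
          class = "cytomesf_input_error")
  }
  out
}

#' One-way ANOVA from group summary statistics
#'
#' Between-group and within-group sums of squares are recovered exactly from
#' (n, mean, SD): `SSB = sum n_i (m_i - grand mean)^2`,
#' `SSW = sum (n_i - 1) s_i^2`, `F = (SSB/(k-1)) / (SSW/(N-k))`. This
#' reproduces the F-test that would be computed from the raw data, so
#' printed cohort tables can be re-tested directly.
#'
#' @param groups Tibble with `n`, `mean`, `sd` (one row per group), e.g.
#'   from [group_summary()].
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_oneway_from_summary <- function(groups) {
  assert_cols(groups, c("n", "mean", "sd"), "group summaries")
  k <- nrow(groups)
  if (k < 2) {
    abort("at least two groups are required", class = "cytomesf_input_error")
  }
  if (all(groups$n == 1)) {
    abort("cannot test with every group of size 1",
          class = "cytomesf_input_error")
  }
  N <- sum(groups$n)
  gm <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - gm)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  if (ssw == 0) {
    if (ssb == 0) {
      return(tibble::tibble(statistic = 0, df1 = k - 1, df2 = N - k,
                            p_value = 1))
    }
    warn("zero within-group variance with unequal means; p reported as 0")
    return(tibble::tibble(statistic = Inf, df1 = k - 1, df2 = N - k,
                          p_value = 0))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(statistic = f, df1 = k - 1, df2 = N - k,
                 p_value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' LSD (least significant difference) pairwise test from group summaries
#'
#' Fisher's LSD post-hoc comparison of groups `i` and `j`, pooling the
#' within-group mean square over all supplied groups:
#' `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))` on `N - k` degrees of
#' freedom, two-sided, with no multiplicity adjustment. The pooling set is
#' whatever `groups` contains, so pass exactly the groups of the parent
#' ANOVA.
#'
#' @param groups Tibble with `label`, `n`, `mean`, `sd`.
#' @param i,j Group labels (or row indices) to compare.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`.
#' @export
lsd_pairwise_from_summary <- function(groups, i, j) {
  assert_cols(groups, c("n", "mean", "sd"), "group summaries")
  idx <- function(g) {
    if (is.character(g)) {
      m <- match(g, groups$label)
      if (is.na(m)) abort(paste0("unknown group '", g, "'"),
                          class = "cytomesf_input_error")
      m
    } else {
      if (g < 1 || g > nrow(groups)) {
        abort("group index out of range", class = "cytomesf_input_error")
      }
      g
    }
  }
  i <- idx(i)
  j <- idx(j)
  N <- sum(groups$n)
  k <- nrow(groups)
  msw <- sum((groups$n - 1) * groups$sd^2) / (N - k)
  if (msw == 0) {
    abort("zero pooled within-group variance",
          class = "cytomesf_input_error")
  }
  t <- (groups$mean[i] - groups$mean[j]) /
    sqrt(msw * (1 / groups$n[i] + 1 / groups$n[j]))
  tibble::tibble(statistic = t, df = N - k,
                 p_value = 2 * pt(-abs(t), N - k))
}

#' Two-sample t-test from group summaries
#'
#' Classical pooled-variance Student's t (df `n1 + n2 - 2`) or Welch's t
#' with Satterthwaite degrees of freedom, two-sided.
#'
#' @param g1,g2 One-row tibbles (or named lists) with `n`, `mean`, `sd`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `variant`.
#' @export
t_test_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  g1 <- as.list(g1)
  g2 <- as.list(g2)
  n1 <- g1$n; n2 <- g2$n
  if (n1 < 2 || n2 < 2) {
    abort("both groups need n >= 2", class = "cytomesf_input_error")
  }
  if (g1$sd == 0 && g2$sd == 0) {
    if (g1$mean == g2$mean) {
      return(tibble::tibble(statistic = 0, df = n1 + n2 - 2, p_value = 1,
                            variant = variant))
    }
    abort("zero variance in both groups with unequal means",
          class = "cytomesf_input_error")
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / (n1 + n2 - 2)
    t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- g1$sd^2 / n1
    v2 <- g2$sd^2 / n2
    t <- (g1$mean - g2$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
                 variant = variant)
}

#' Chi-square or Fisher's exact test on a contingency table
#'
#' Pearson's chi-square without continuity correction by default (the form
#' that matches printed cohort-table p-values); Fisher's exact test by
#' hypergeometric enumeration for small tables.
#'
#' @param table A counts matrix (2 x k) or data frame coercible to one.
#' @param method `"pearson"` or `"fisher"`.
#' @return A one-row tibble: `statistic` (chi-square; `NA` for Fisher),
#'   `df`, `p_value`, `method`.
#' @export
chi_square_test <- function(table, method = c("pearson", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("contingency table must contain non-negative integer counts",
          class = "cytomesf_input_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero margin",
          class = "cytomesf_input_error")
  }
  if (method == "pearson") {
    res <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(res$statistic),
                   df = unname(res$parameter),
                   p_value = res$p.value, method = method)
  } else {
    res <- fisher.test(tab)
    tibble::tibble(statistic = NA_real_, df = NA_real_,
                   p_value = res$p.value, method = method)
  }
}

#' ROC analysis with Youden-index cutoff
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation with midrank
#' tie handling; its p-value against AUC = 0.5 uses the normal approximation
#' to the Mann-Whitney statistic with tie correction. The operating cutoff
#' maximizes the Youden index (sensitivity + specificity - 1) over the
#' observed score values, breaking ties toward the lower threshold; a case
#' is called positive when its score exceeds the cutoff (direction `">"`,
#' the default) or falls below it (`"<"`).
#'
#' @param scores Numeric marker values.
#' @param labels Binary outcome (logical, 0/1, or two-level factor).
#' @param direction `">"` if positives score higher, `"<"` if lower.
#' @return A `roc_result`: `auc`, `p_value`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `direction`, `n_pos`, `n_neg`, and the full
#'   `curve` tibble (threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(scores, labels, direction = c(">", "<")) {
  direction <- match.arg(direction)
  labels <- as.logical(
    if (is.factor(labels)) as.integer(labels) - 1L else labels
  )
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (length(unique(labels)) < 2) {
    abort("both outcome classes must be present",
          class = "cytomesf_input_error")
  }
  s <- if (direction == ">") scores else -scores
  n1 <- as.numeric(sum(labels))
  n0 <- as.numeric(sum(!labels))
  r <- rank(s)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # Mann-Whitney normal approximation with tie correction
  N <- n1 + n0
  ties <- as.numeric(table(s))
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n0 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  u <- auc * n1 * n0
  p <- if (var_u == 0) 1 else 2 * pnorm(-abs(u - n1 * n0 / 2) / sqrt(var_u))

  thresholds <- sort(unique(s))
  idx <- match(s, thresholds)
  pos_at <- tabulate(idx[labels], nbins = length(thresholds))
  neg_at <- tabulate(idx[!labels], nbins = length(thresholds))
  sens <- (n1 - cumsum(pos_at)) / n1  # P(score > t | positive)
  spec <- cumsum(neg_at) / n0         # P(score <= t | negative)
  jj <- sens + spec - 1
  best <- which.max(jj) # which.max takes the first (lowest threshold) on ties
  cutoff <- thresholds[best]
  curve <- tibble::tibble(
    threshold = if (direction == ">") thresholds else -thresholds,
    sensitivity = sens, specificity = spec
  )
  structure(
    list(auc = auc, p_value = p,
         cutoff = if (direction == ">") cutoff else -cutoff,
         sensitivity = sens[best], specificity = spec[best],
         youden = jj[best], direction = direction,
         n_pos = n1, n_neg = n0, curve = curve),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC =", signif(x$auc, 4), "(p =", signif(x$p_value, 3),
      "vs 0.5)\n  Youden cutoff", signif(x$cutoff, 6),
      "(direction", x$direction, "): sens", signif(x$sensitivity, 4),
      ", spec", signif(x$specificity, 4), "\n")
  invisible(x)
}

#' Univariate and multivariate logistic risk models
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) with Wald z p-values and 95% Wald confidence
#' intervals on the odds-ratio scale, `exp(b +/- 1.96 SE)`. Univariate mode
#' fits each covariate alone; multivariate mode fits them jointly, by
#' default entering the covariates whose univariate p-value falls below
#' `entry_p`. Non-convergence or separation is flagged, with estimates
#' still reported under a warning.
#'
#' @param data Data frame of covariates and outcome.
#' @param outcome Name of the binary outcome column.
#' @param covariates Character vector of covariate names; default all other
#'   columns (univariate) or the univariate-significant set (multivariate).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param entry_p Univariate entry threshold for the multivariate model.
#' @param ci_z Wald multiplier for the 95% interval (default 1.96).
#' @return A `logistic_fit`: tibble `terms` (term, estimate, std_error, or,
#'   ci_lower, ci_upper, p_value), `mode`, `converged`.
#' @export
logistic_fit <- function(data, outcome, covariates = NULL,
                         mode = c("univariate", "multivariate"),
                         entry_p = 0.05, ci_z = 1.96) {
  mode <- match.arg(mode)
  assert_cols(data, outcome, "model data")
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    abort("outcome must have both classes", class = "cytomesf_input_error")
  }
  all_covs <- covariates %||% setdiff(names(data), outcome)
  if (length(all_covs) < 1) {
    abort("at least one covariate is required",
          class = "cytomesf_input_error")
  }
  assert_cols(data, all_covs, "model data")

  fit_one <- function(covs) {
    fml <- stats::reformulate(covs, response = outcome)
    fit <- suppressWarnings(glm(fml, family = binomial(), data = data))
    sm <- summary(fit)$coefficients
    est <- sm[-1, 1, drop = TRUE]
    se <- sm[-1, 2, drop = TRUE]
    separated <- any(abs(est) > 15 | se > 100)
    list(
      terms = tibble::tibble(
        term = rownames(sm)[-1], estimate = unname(est),
        std_error = unname(se), or = exp(unname(est)),
        ci_lower = exp(unname(est) - ci_z * unname(se)),
        ci_upper = exp(unname(est) + ci_z * unname(se)),
        p_value = unname(sm[-1, 4])
      ),
      converged = fit$converged && !separated
    )
  }

  if (mode == "univariate") {
    fits <- lapply(all_covs, fit_one)
    terms <- purrr::map_dfr(fits, "terms")
    converged <- all(vapply(fits, function(f) f$converged, logical(1)))
  } else {
    if (is.null(covariates)) {
      uni <- logistic_fit(data, outcome, all_covs, mode = "univariate",
                          entry_p = entry_p, ci_z = ci_z)
      sel <- unique(uni$terms$term[uni$terms$p_value < entry_p])
      # map factor-expanded terms back to source columns
      sel <- all_covs[vapply(all_covs, function(cv) {
        any(startsWith(sel, cv)) }, logical(1))]
      if (length(sel) == 0) {
        abort("no covariate passes the univariate entry threshold",
              class = "cytomesf_input_error")
      }
      all_covs <- sel
    }
    f <- fit_one(all_covs)
    terms <- f$terms
    converged <- f$converged
  }
  if (!converged) {
    warn("logistic fit did not converge cleanly (possible separation); estimates reported")
  }
  structure(list(terms = terms, mode = mode, outcome = outcome,
                 covariates = all_covs, converged = converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic model (", x$mode, ") for ", x$outcome,
      if (!x$converged) "  [convergence flagged]", "\n", sep = "")
  print(x$terms)
  invisible(x)
}
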