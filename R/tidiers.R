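# broom-style tidiers for fitted objects.

#' @exportS3Method generics::tidy
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, intercept = x$intercept,
                 slope = x$slope, r_squared = x$r_squared,
                 n_levels = x$n_levels)
}

#' @exportS3Method generics::glance
glance.icc_result <- function(x, ...) {
  tibble::tibble(icc = x$icc, model = x$model, n_subjects = x$n_subjects,
                 n_protocols = x$n_protocols)
}

#' @exportS3Method generics::tidy
tidy.bland_altman_result <- function(x, ...) {
  x$data
}

#' @exportS3Method generics::glance
glance.bland_altman_result <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 n_outliers = length(x$outliers))
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_value = x$p_value, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 youden = x$youden, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method generics::tidy
tidy.logistic_fit <- function(x, ...) {
  x$terms
}

#' @exportS3Method generics::glance
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, outcome = x$outcome,
                 n_terms = nrow(x$terms), converged = x$converged)
}
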