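# Multi-protocol harmonization: reliability (ICC), agreement (Bland-Altman
# against the per-sample mean), 3-SD outlier exclusion, consensus averaging.

# Long tibble (subject_id, protocol, <value>) -> complete wide matrix.
measurement_matrix <- function(data, value = "mesf") {
  assert_cols(data, c("subject_id", "protocol", value), "measurement set")
  wide <- data |>
    dplyr::select("subject_id", "protocol", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "protocol",
                       values_from = dplyr::all_of(value))
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$subject_id
  mat
}

#' Intraclass correlation of a subjects-by-protocols measurement set
#'
#' ICC(2,1): two-way random effects, absolute agreement, single measurement,
#' computed from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. This form is the
#' one that speaks to MESF standardization: the same samples measured under
#' fixed instrument settings, judged on absolute agreement. Rows with any
#' missing cell are dropped listwise.
#'
#' @param data Long tibble with `subject_id`, `protocol` and a value column.
#' @param value Name of the value column (default `"mesf"`).
#' @return An `icc_result`: `icc`, `model`, `n_subjects`, `n_protocols`,
#'   and the mean squares `msr`, `msc`, `mse`.
#' @export
icc <- function(data, value = "mesf") {
  mat <- measurement_matrix(data, value)
  mat <- mat[complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) {
    abort("ICC requires at least 2 subjects and 2 protocols",
          class = "cytomesf_input_error")
  }
  gm <- mean(mat)
  if (sum((mat - gm)^2) == 0) {
    abort("zero total variance; ICC undefined",
          class = "cytomesf_input_error")
  }
  rm <- rowMeans(mat)
  cm <- colMeans(mat)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((mat - outer(rm, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(
    list(icc = est,
         model = "ICC(2,1) two-way random, absolute agreement, single measurement",
         n_subjects = n, n_protocols = k, msr = msr, msc = msc, mse = mse),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC =", signif(x$icc, 4), "(", x$model, ")\n",
      x$n_subjects, "subjects x", x$n_protocols, "protocols\n")
  invisible(x)
}

#' Bland-Altman agreement of one protocol against the per-sample mean
#'
#' Pairs each subject's value under `protocol` with that subject's mean
#' across all protocols. Differences are protocol value minus per-subject
#' mean; limits of agreement are bias +/- `loa_multiplier` * SD of the
#' differences, and subjects whose difference lies more than
#' `outlier_sd` * SD from the bias are flagged as outliers.
#'
#' @param data Long tibble with `subject_id`, `protocol` and a value column.
#' @param protocol Protocol to compare against the per-subject mean.
#' @param value Name of the value column.
#' @param loa_multiplier Limits-of-agreement multiplier (default 1.96).
#' @param outlier_sd Outlier threshold in difference-SD units (default 3).
#' @return A `bland_altman_result`: `protocol`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `outliers`, and a `data` tibble of
#'   per-subject (mean, difference, outlier flag).
#' @export
bland_altman <- function(data, protocol, value = "mesf",
                         loa_multiplier = 1.96, outlier_sd = 3) {
  mat <- measurement_matrix(data, value)
  if (!protocol %in% colnames(mat)) {
    abort(paste0("protocol '", protocol, "' not present"),
          class = "cytomesf_input_error")
  }
  mat <- mat[complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 3) {
    abort("Bland-Altman needs at least 3 complete subjects",
          class = "cytomesf_input_error")
  }
  subj_mean <- rowMeans(mat)
  diffs <- mat[, protocol] - subj_mean
  bias <- mean(diffs)
  sd_diff <- sd(diffs)
  out <- abs(diffs - bias) > outlier_sd * sd_diff
  structure(
    list(protocol = protocol, bias = bias, sd_diff = sd_diff,
         loa_lower = bias - loa_multiplier * sd_diff,
         loa_upper = bias + loa_multiplier * sd_diff,
         loa_multiplier = loa_multiplier, outlier_sd = outlier_sd,
         outliers = rownames(mat)[out],
         data = tibble::tibble(subject_id = rownames(mat),
                               mean = unname(subj_mean),
                               diff = unname(diffs),
                               outlier = unname(out))),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat("Bland-Altman [", x$protocol, " vs per-sample mean]\n",
      "  bias ", signif(x$bias, 4), ", LoA [", signif(x$loa_lower, 4), ", ",
      signif(x$loa_upper, 4), "], ", length(x$outliers), " outlier(s)\n",
      sep = "")
  invisible(x)
}

#' Consensus MESF per subject after outlier exclusion
#'
#' The consensus is the arithmetic mean over the protocol values not
#' excluded as outliers. A subject with every protocol excluded falls back
#' to the unfiltered mean with a warning (a consensus is always emitted).
#'
#' @param data Long tibble with `subject_id`, `protocol` and a value column.
#' @param exclusions Tibble of (`subject_id`, `protocol`) cells to exclude,
#'   typically from [harmonize()]'s Bland-Altman pass; `NULL` excludes
#'   nothing.
#' @param value Name of the value column.
#' @return A tibble: `subject_id`, `consensus`, `n_included`, `excluded`
#'   (comma-separated protocol ids, `""` if none).
#' @export
consensus_mesf <- function(data, exclusions = NULL, value = "mesf") {
  assert_cols(data, c("subject_id", "protocol", value), "measurement set")
  data$.value <- data[[value]]
  data$.excluded <- FALSE
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    assert_cols(exclusions, c("subject_id", "protocol"), "exclusions")
    key <- paste(data$subject_id, data$protocol)
    data$.excluded <- key %in% paste(exclusions$subject_id,
                                     exclusions$protocol)
  }
  out <- data |>
    dplyr::filter(!is.na(.data$.value)) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      consensus = if (all(.data$.excluded)) {
        mean(.data$.value)
      } else {
        mean(.data$.value[!.data$.excluded])
      },
      n_included = if (all(.data$.excluded)) dplyr::n() else
        sum(!.data$.excluded),
      excluded = if (all(.data$.excluded)) "" else
        paste(.data$protocol[.data$.excluded], collapse = ","),
      all_excluded = all(.data$.excluded),
      .groups = "drop"
    )
  if (any(out$all_excluded)) {
    warn(paste0("all protocols excluded for subject(s) ",
                paste(out$subject_id[out$all_excluded], collapse = ", "),
                "; falling back to unfiltered mean"))
  }
  dplyr::select(out, -"all_excluded")
}

#' Full harmonization pass over a multi-protocol measurement set
#'
#' Runs the reliability and agreement workflow end to end: ICC(2,1) of the
#' set, a Bland-Altman comparison of every protocol against the per-sample
#' mean, collection of the >`outlier_sd`-SD outlier cells, a single
#' exclude-and-average consensus pass, and a second agreement pass of the
#' retained values against the consensus. The maximum standardized absolute
#' difference before and after exclusion summarizes the consistency gain.
#'
#' @inheritParams bland_altman
#' @return A `harmonization_report`: `icc`, `bland_altman` (named list per
#'   protocol), `outliers` (subject x protocol tibble), `consensus` tibble,
#'   `max_std_diff_before`, `max_std_diff_after`.
#' @export
harmonize <- function(data, value = "mesf", loa_multiplier = 1.96,
                      outlier_sd = 3) {
  protocols <- unique(data$protocol)
  icc_res <- icc(data, value)
  ba <- lapply(protocols, function(p) {
    bland_altman(data, p, value, loa_multiplier, outlier_sd)
  })
  names(ba) <- protocols
  outliers <- purrr::map_dfr(ba, function(b) {
    tibble::tibble(subject_id = b$outliers, protocol = b$protocol)
  })
  max_before <- max(vapply(ba, function(b) {
    max(abs(b$data$diff - b$bias)) / b$sd_diff
  }, numeric(1)))
  cons <- consensus_mesf(data, outliers, value)

  # second pass: retained values vs the consensus value
  kept <- data |>
    dplyr::anti_join(outliers, by = c("subject_id", "protocol")) |>
    dplyr::left_join(cons[, c("subject_id", "consensus")], by = "subject_id")
  kept$.diff <- kept[[value]] - kept$consensus
  max_after <- max(vapply(split(kept, kept$protocol), function(d) {
    if (nrow(d) < 3) return(0)
    b <- mean(d$.diff)
    s <- sd(d$.diff)
    if (s == 0) 0 else max(abs(d$.diff - b)) / s
  }, numeric(1)))

  structure(
    list(icc = icc_res, bland_altman = ba, outliers = outliers,
         consensus = cons, max_std_diff_before = max_before,
         max_std_diff_after = max_after),
    class = "harmonization_report"
  )
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("Harmonization report:", x$icc$n_subjects, "subjects x",
      x$icc$n_protocols, "protocols\n  ICC =", signif(x$icc$icc, 4),
      "\n  outlier cells:", nrow(x$outliers),
      "\n  max standardized |diff|:", signif(x$max_std_diff_before, 4),
      "->", signif(x$max_std_diff_after, 4), "\n")
  invisible(x)
}
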