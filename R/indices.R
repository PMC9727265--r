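#' CD64 index
#'
#' `(nCD64 / lymCD64) / (mCD64 / nCD64)`, algebraically
#' `nCD64^2 / (lymCD64 * mCD64)`: a dimensionless composite that contrasts
#' inducible neutrophil CD64 against the constitutive lymphocyte and
#' monocyte levels. All inputs are MESF values and must be positive; the
#' index is unchanged when all three are scaled by a common factor.
#'
#' @param ncd64,lymcd64,mcd64 Positive MESF values (vectorized).
#' @return The dimensionless index.
#' @export
cd64_index <- function(ncd64, lymcd64, mcd64) {
  if (any(!is.finite(ncd64) | ncd64 <= 0) ||
      any(!is.finite(lymcd64) | lymcd64 <= 0) ||
      any(!is.finite(mcd64) | mcd64 <= 0)) {
    abort("CD64 index inputs must all be positive",
          class = "cytomesf_input_error")
  }
  (ncd64 / lymcd64) / (mcd64 / ncd64)
}

#' Sepsis Index
#'
#' `SI = 100 * nCD64 / mHLA-DR`, combining the pro-inflammatory (nCD64 up)
#' and immunosuppressive (mHLA-DR down) axes in one dimensionless number.
#'
#' @param ncd64,mhladr Positive MESF values (vectorized).
#' @return The Sepsis Index.
#' @export
sepsis_index <- function(ncd64, mhladr) {
  if (any(!is.finite(mhladr) | mhladr <= 0) ||
      any(!is.finite(ncd64) | ncd64 <= 0)) {
    abort("Sepsis Index inputs must be positive",
          class = "cytomesf_input_error")
  }
  100 * ncd64 / mhladr
}

#' Add composite indices to a subject record table
#'
#' Computes `cd64_index` and `si` columns where all inputs are present and
#' positive; rows with missing or non-positive inputs get `NA` rather than
#' an error.
#'
#' @param records Tibble with `ncd64`, `lymcd64`, `mcd64`, `mhladr` columns.
#' @return `records` with `cd64_index` and `si` columns added.
#' @export
add_indices <- function(records) {
  assert_cols(records, c("ncd64", "lymcd64", "mcd64", "mhladr"), "records")
  ok_idx <- with(records, is.finite(ncd64) & ncd64 > 0 &
                   is.finite(lymcd64) & lymcd64 > 0 &
                   is.finite(mcd64) & mcd64 > 0)
  ok_si <- with(records, is.finite(ncd64) & ncd64 > 0 &
                  is.finite(mhladr) & mhladr > 0)
  records$cd64_index <- ifelse(
    ok_idx, (records$ncd64 / records$lymcd64) /
      (records$mcd64 / records$ncd64), NA_real_)
  records$si <- ifelse(ok_si, 100 * records$ncd64 / records$mhladr, NA_real_)
  records
}

#' Longitudinal change between two tests of the same subject
#'
#' Deltas are second test minus first test for each marker and index, plus
#' the SOFA change; a positive SOFA change defines exacerbation.
#'
#' @param first,second One-row subject records (tibbles or named lists) with
#'   the same `subject_id`; each may carry `ncd64`, `mhladr`, `si`,
#'   `cd64_index`, `sofa`. Missing values at either timepoint yield `NA`
#'   deltas.
#' @return A one-row tibble: `subject_id`, `d_ncd64`, `d_mhladr`, `d_si`,
#'   `d_cd64_index`, `d_sofa`, `exacerbation`.
#' @export
longitudinal_delta <- function(first, second) {
  first <- as.list(first)
  second <- as.list(second)
  if (!identical(first$subject_id, second$subject_id)) {
    abort("records belong to different subjects",
          class = "cytomesf_input_error")
  }
  if (!is.null(first$timepoint) && !is.null(second$timepoint) &&
      first$timepoint >= second$timepoint) {
    abort("first timepoint must precede the second",
          class = "cytomesf_input_error")
  }
  d <- function(field) {
    a <- first[[field]]
    b <- second[[field]]
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) NA_real_ else b - a
  }
  d_sofa <- d("sofa")
  tibble::tibble(
    subject_id = first$subject_id,
    d_ncd64 = d("ncd64"), d_mhladr = d("mhladr"), d_si = d("si"),
    d_cd64_index = d("cd64_index"), d_sofa = d_sofa,
    exacerbation = if (is.na(d_sofa)) NA else d_sofa > 0
  )
}

#' Longitudinal deltas for every retested subject in a record table
#'
#' @param records Subject-timepoint tibble with a `timepoint` column; only
#'   subjects with both timepoints 1 and 2 contribute.
#' @return One row per retested subject, as [longitudinal_delta()].
#' @export
longitudinal_deltas <- function(records) {
  assert_cols(records, c("subject_id", "timepoint"), "records")
  ids <- records |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$subject_id)
  purrr::map_dfr(ids, function(id) {
    rows <- records[records$subject_id == id, ]
    longitudinal_delta(rows[which.min(rows$timepoint), ],
                       rows[which.max(rows$timepoint), ])
  })
}

#' Renal SOFA adjustment for transplant recipients
#'
#' Kidney-transplant recipients often run chronically elevated creatinine,
#' so scoring renal SOFA from the raw creatinine overstates infection
#' severity. The renal component is retained only when creatinine is at or
#' above `abs_threshold` umol/L, or has risen by at least `ratio` times the
#' subject's baseline; otherwise it is zeroed. With no baseline available
#' the relative rule is skipped with a warning and the absolute rule alone
#' decides.
#'
#' @param creatinine Current creatinine, umol/L (vectorized).
#' @param baseline Baseline creatinine, umol/L (may be `NA`).
#' @param renal_sofa Raw renal SOFA component, points.
#' @param abs_threshold Absolute creatinine threshold (default 171 umol/L).
#' @param ratio Relative-increase threshold (default 1.5).
#' @return Adjusted renal SOFA points.
#' @export
adjust_renal_sofa <- function(creatinine, baseline = NA_real_, renal_sofa,
                              abs_threshold = 171, ratio = 1.5) {
  if (any(!is.finite(creatinine) | creatinine <= 0)) {
    abort("creatinine must be positive", class = "cytomesf_input_error")
  }
  n <- length(creatinine)
  baseline <- rep_len(baseline, n)
  renal_sofa <- rep_len(renal_sofa, n)
  need_rel <- creatinine < abs_threshold & is.na(baseline)
  if (any(need_rel)) {
    warn("baseline creatinine missing; applying the absolute rule only")
  }
  retained <- creatinine >= abs_threshold |
    (!is.na(baseline) & creatinine >= ratio * baseline)
  ifelse(retained, renal_sofa, 0)
}

#' Dichotomize a marker at its diagnostic cutoff
#'
#' Strict greater-than comparison at the configured cutoff (defaults: nCD64
#' MESF > 3089, mHLA-DR MESF > 2433, the Youden-derived cutoffs used for
#' infection risk modelling).
#'
#' @param value MESF value(s).
#' @param marker `"ncd64"` or `"mhladr"` (or any name present in `cutoffs`).
#' @param cutoffs Named cutoff vector.
#' @return Logical flag(s).
#' @export
binarize_marker <- function(value, marker,
                            cutoffs = c(ncd64 = 3089, mhladr = 2433)) {
  if (!marker %in% names(cutoffs)) {
    abort(paste0("unknown marker '", marker, "'"),
          class = "cytomesf_input_error")
  }
  value > cutoffs[[marker]]
}
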