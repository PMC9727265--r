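#' Fit the per-protocol bead calibration curve
#'
#' Ordinary least squares of log10(peak MFI) on log10(lot MESF):
#' `log10(MFI) = a + b * log10(MESF)`. The fitted line links the
#' instrument-relative fluorescence scale to absolute PE-molecule
#' equivalents for one acquisition protocol.
#'
#' @param peaks A [find_bead_peaks()] result (or any tibble with `mfi` per
#'   level, ascending).
#' @param lot The [bead_lot()], supplying the known MESF per level.
#' @param r2_floor Fits with R-squared below this carry a calibration
#'   quality warning.
#' @return A `calibration_curve` object: `protocol`, `intercept` (a),
#'   `slope` (b), `r_squared`, `n_levels`.
#' @export
fit_calibration_curve <- function(peaks, lot, r2_floor = 0.98) {
  stopifnot(inherits(lot, "bead_lot"))
  assert_cols(peaks, "mfi", "bead peaks")
  if (nrow(peaks) != length(lot$mesf)) {
    abort("peak count must equal the lot level count",
          class = "cytomesf_calibration_error")
  }
  if (nrow(peaks) < 2) {
    abort("at least two bead levels are required",
          class = "cytomesf_calibration_error")
  }
  if (any(peaks$mfi <= 0) || any(lot$mesf <= 0)) {
    abort("bead peak MFIs and lot MESFs must be positive",
          class = "cytomesf_calibration_error")
  }
  x <- log10(lot$mesf)
  y <- log10(peaks$mfi)
  if (var(x) == 0) {
    abort("zero variance in log10 MESF predictor",
          class = "cytomesf_calibration_error")
  }
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  slope <- unname(coef(fit)[2])
  if (slope <= 0) {
    warn("fitted calibration slope is not positive; conversion will fail")
  }
  if (r2 < r2_floor) {
    warn(paste0("calibration R-squared ", signif(r2, 4), " below floor ",
                r2_floor))
  }
  structure(
    list(protocol = attr(peaks, "protocol") %||% NA_character_,
         intercept = unname(coef(fit)[1]), slope = slope,
         r_squared = r2, n_levels = nrow(peaks)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Calibration curve", if (!is.na(x$protocol)) paste0("[", x$protocol, "]"),
      "\n  log10(MFI) =", signif(x$intercept, 6), "+",
      signif(x$slope, 6), "* log10(MESF)   R^2 =", signif(x$r_squared, 6),
      "\n")
  invisible(x)
}

#' Convert an MFI to MESF with a fitted calibration curve
#'
#' Inverts the fitted line: `MESF = 10^((log10(MFI) - a) / b)`. The forward
#' regression is of log MFI on log MESF, so conversion is the algebraic
#' inverse rather than a refitted reverse regression; it is strictly
#' increasing in MFI since the slope is positive.
#'
#' @param mfi Positive fluorescence value(s).
#' @param curve A [fit_calibration_curve()] result.
#' @return MESF value(s), PE-molecule equivalents.
#' @export
mfi_to_mesf <- function(mfi, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) {
    abort("calibration slope must be positive to invert",
          class = "cytomesf_calibration_error")
  }
  if (any(!is.finite(mfi)) || any(mfi <= 0)) {
    abort("MFI must be positive to convert to MESF",
          class = "cytomesf_calibration_error")
  }
  10^((log10(mfi) - curve$intercept) / curve$slope)
}

#' Calibrate a table of MFI measurements to MESF
#'
#' Applies each measurement's protocol-specific calibration curve, keeping
#' both scales and the protocol provenance.
#'
#' @param mfis Tibble with at least `protocol` and `mfi` columns (e.g. rows
#'   from [extract_mfi()] or [generate_protocol_measurements()]).
#' @param curves Named list of [fit_calibration_curve()] results (names =
#'   protocol ids), or an unnamed list whose elements carry protocol ids.
#' @return `mfis` with an added `mesf` column.
#' @export
calibrate_measurements <- function(mfis, curves) {
  if (nrow(mfis) == 0) {
    return(dplyr::mutate(mfis, mesf = numeric(0)))
  }
  assert_cols(mfis, c("protocol", "mfi"), "measurements")
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- vapply(curves, function(cc) cc$protocol, character(1))
  }
  missing <- setdiff(unique(mfis$protocol), names(curves))
  if (length(missing) > 0) {
    abort(paste0("no calibration curve for protocol(s): ",
                 paste(missing, collapse = ", ")),
          class = "cytomesf_calibration_error")
  }
  mfis$mesf <- vapply(seq_len(nrow(mfis)), function(i) {
    mfi_to_mesf(mfis$mfi[i], curves[[mfis$protocol[i]]])
  }, numeric(1))
  mfis
}
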