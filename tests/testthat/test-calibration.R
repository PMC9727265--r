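peaks_from <- function(mfi, protocol = NA_character_) {
  p <- tibble::tibble(level = seq_along(mfi), mfi = mfi,
                      n_events = rep(100L, length(mfi)))
  attr(p, "protocol") <- protocol
  class(p) <- c("bead_peaks", class(p))
  p
}

test_that("identity bead points fit slope 1, intercept 0, R^2 1", {
  lot <- bead_lot(mesf = c(500, 5000, 25000, 60000))
  cv <- fit_calibration_curve(peaks_from(lot$mesf), lot)
  expect_equal(cv$slope, 1, tolerance = 1e-12)
  expect_equal(cv$intercept, 0, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
})

test_that("constructed power-law points recover their exact coefficients", {
  lot <- bead_lot(mesf = c(100, 1000, 10000, 100000))
  mfi <- 10^0.5 * lot$mesf^0.9
  cv <- fit_calibration_curve(peaks_from(mfi), lot)
  expect_equal(cv$slope, 0.9, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.5, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate bead inputs are rejected", {
  expect_error(fit_calibration_curve(peaks_from(500),
                                     bead_lot(mesf = c(500, 5000))),
               class = "cytomesf_calibration_error")
  expect_error(bead_lot(mesf = 500), class =
                 "cytomesf_parameterization_error")
  lot <- bead_lot(mesf = c(500, 5000))
  expect_error(fit_calibration_curve(peaks_from(c(-1, 10)), lot),
               class = "cytomesf_calibration_error")
})

test_that("MFI-to-MESF inverts the fitted line and rejects bad input", {
  ident <- fit_calibration_curve(
    peaks_from(c(500, 5000, 25000, 60000)), bead_lot())
  expect_equal(mfi_to_mesf(3089, ident), 3089, tolerance = 1e-12)

  lot <- bead_lot(mesf = c(100, 1000, 10000, 100000))
  cv <- fit_calibration_curve(peaks_from(10^0.5 * lot$mesf^0.9), lot)
  expect_equal(mfi_to_mesf(10^3.2, cv), 1000, tolerance = 1e-9)
  expect_error(mfi_to_mesf(0, cv), class = "cytomesf_calibration_error")
  expect_error(mfi_to_mesf(-5, cv), class = "cytomesf_calibration_error")
})

test_that("bead round trip is exact for perfectly linear peaks", {
  lot <- bead_lot(mesf = c(500, 5000, 25000, 60000))
  mfi <- 10^(0.3 + 1.05 * log10(lot$mesf))
  cv <- fit_calibration_curve(peaks_from(mfi), lot)
  expect_equal(mfi_to_mesf(mfi, cv), lot$mesf, tolerance = 1e-9)
})

test_that("a common gain on all MFIs leaves recovered MESF unchanged", {
  lot <- bead_lot(mesf = c(500, 5000, 25000, 60000))
  base_mfi <- 10^(0.2 + 0.97 * log10(lot$mesf))
  for (c0 in c(0.5, 3, 100)) {
    cv <- fit_calibration_curve(peaks_from(base_mfi * c0), lot)
    expect_equal(mfi_to_mesf(1234 * c0, cv),
                 mfi_to_mesf(
                   1234, fit_calibration_curve(peaks_from(base_mfi), lot)),
                 tolerance = 1e-9)
  }
})

test_that("noise-free protocols round-trip fitted gain/offset and MESF exactly", {
  protocols <- default_protocols(cv = 0)
  lot <- bead_lot(cv = 0)
  for (i in seq_len(nrow(protocols))) {
    run <- generate_bead_run(protocols[i, ], lot, seed = 1)
    cv <- fit_calibration_curve(find_bead_peaks(run, lot), lot)
    expect_equal(cv$slope, protocols$gain[i], tolerance = 1e-9)
    expect_equal(cv$intercept, protocols$offset[i], tolerance = 1e-9)
  }

  co <- generate_cohort(seed = 6)[1:20, ]
  meas <- generate_protocol_measurements(co, protocols, seed = 2)
  curves <- lapply(seq_len(nrow(protocols)), function(i) {
    run <- generate_bead_run(protocols[i, ], lot, seed = 1)
    fit_calibration_curve(find_bead_peaks(run, lot), lot)
  })
  names(curves) <- protocols$protocol
  cal <- calibrate_measurements(meas, curves)
  expect_equal(cal$mesf, cal$true_mesf, tolerance = 1e-9)
})

test_that("5% protocol noise keeps cross-protocol MESF CV within 10%", {
  st <- mesf_recovery_study(n_subjects = 100, cv = 0.05, seed = 8)
  cvs <- st$measurements |>
    dplyr::group_by(.data$subject_id, .data$marker) |>
    dplyr::summarise(cv = sd(mesf) / mean(mesf), .groups = "drop")
  expect_lte(stats::median(cvs$cv), 0.10)
  expect_lte(mean(cvs$cv > 0.10), 0.05)
})

test_that("calibration errors name missing protocols; empty input passes through", {
  curves <- list(p1 = fit_calibration_curve(
    peaks_from(c(500, 5000, 25000, 60000), "p1"), bead_lot()))
  mfis <- tibble::tibble(protocol = c("p1", "p9"), mfi = c(100, 100))
  expect_error(calibrate_measurements(mfis, curves), "p9",
               class = "cytomesf_calibration_error")
  expect_equal(nrow(calibrate_measurements(mfis[0, ], curves)), 0)
})
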