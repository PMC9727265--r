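test_that("empty spec yields an empty cohort with the full schema", {
  spec <- cohort_spec(group_sizes = c(HC = 0, stable = 0, sepsis = 0,
                                      non_sepsis = 0),
                      pathogen_counts = c(bacterial = 0, viral = 0,
                                          fungal = 0),
                      n_second = c(sepsis = 0, non_sepsis = 0),
                      n_exacerbation = 0)
  co <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(co), 0)
  expect_true(all(c("subject_id", "group", "ncd64", "mhladr", "sofa",
                    "timepoint") %in% names(co)))
})

test_that("marker draws are moment-matched to the stratum targets", {
  spec <- cohort_spec(group_sizes = c(HC = 0, stable = 5000, sepsis = 0,
                                      non_sepsis = 0),
                      pathogen_counts = c(bacterial = 0, viral = 0,
                                          fungal = 0),
                      n_second = c(sepsis = 0, non_sepsis = 0),
                      n_exacerbation = 0)
  co <- generate_cohort(spec, seed = 42)
  expect_equal(mean(co$ncd64), 1697.89, tolerance = 0.02)
  expect_equal(sd(co$ncd64), 1056.32, tolerance = 0.05)
  expect_equal(mean(co$mhladr), 2728.62, tolerance = 0.02)
  expect_equal(sd(co$mhladr), 854.87, tolerance = 0.05)
})

test_that("default cohort has the study's group structure", {
  co <- generate_cohort(seed = 5)
  t1 <- co[co$timepoint == 1, ]
  expect_equal(nrow(t1), 141)
  expect_equal(sum(t1$group == "HC"), 26)
  expect_equal(sum(t1$group == "stable"), 65)
  expect_equal(sum(t1$group == "infection"), 50)
  expect_equal(sum(t1$sepsis, na.rm = TRUE), 19)
  expect_equal(sort(as.integer(table(t1$pathogen))), sort(c(26, 13, 11)))
  expect_equal(sum(co$timepoint == 2), 21)
  expect_true(all(t1$ncd64 > 0 & t1$mhladr > 0 & t1$lymcd64 > 0))
  expect_true(all(t1$sofa[which(t1$sepsis)] >= 2))
})

test_that("cohort generation is deterministic under a fixed seed", {
  expect_identical(generate_cohort(seed = 9), generate_cohort(seed = 9))
  expect_false(identical(generate_cohort(seed = 9)$ncd64,
                         generate_cohort(seed = 10)$ncd64))
})

test_that("non-positive targets are a parameterization error", {
  bad <- default_marker_params()
  bad$sd[1] <- 0
  expect_error(cohort_spec(markers = bad), class =
                 "cytomesf_parameterization_error")
})

test_that("identity protocol reproduces the truth; offsets act as exact factors", {
  co <- generate_cohort(seed = 2)[1:10, ]
  ident <- protocol_spec("p1", gain = 1, offset = 0, cv = 0)
  m <- generate_protocol_measurements(co, ident, seed = 1)
  truth <- co |>
    tidyr::pivot_longer(c("ncd64", "mcd64", "lymcd64", "mhladr"),
                        names_to = "marker", values_to = "true") |>
    dplyr::select(subject_id, timepoint, marker, true)
  joined <- dplyr::inner_join(m, truth, by = c("subject_id", "timepoint",
                                               "marker"))
  expect_equal(joined$mfi, joined$true, tolerance = 1e-12)

  offs <- c(0, 0.3, 0.6, -0.2)
  four <- protocol_spec(paste0("p", 1:4), gain = 1, offset = offs, cv = 0)
  m4 <- generate_protocol_measurements(co, four, seed = 1)
  wide <- tidyr::pivot_wider(m4, id_cols = c("subject_id", "timepoint",
                                             "marker"),
                             names_from = "protocol", values_from = "mfi")
  expect_equal(wide$p2 / wide$p1, rep(10^0.3, nrow(wide)), tolerance = 1e-12)
  expect_equal(wide$p4 / wide$p1, rep(10^-0.2, nrow(wide)),
               tolerance = 1e-12)
})

test_that("empty cohort gives an empty measurement set, not an error", {
  m <- generate_protocol_measurements(generate_cohort(cohort_spec(
    group_sizes = c(HC = 0, stable = 0, sepsis = 0, non_sepsis = 0),
    pathogen_counts = c(bacterial = 0, viral = 0, fungal = 0),
    n_second = c(sepsis = 0, non_sepsis = 0), n_exacerbation = 0)),
    default_protocols(), seed = 1)
  expect_equal(nrow(m), 0)
})

test_that("bead runs cluster at the gain-transformed lot values", {
  lot0 <- bead_lot(mesf = c(100, 1000, 10000, 100000), cv = 0)
  run <- generate_bead_run(protocol_spec("id", 1, 0, 0), lot0, seed = 1)
  expect_equal(sort(unique(run$pe)), c(100, 1000, 10000, 100000))
  expect_equal(length(unique(run$level)), 4)

  pr <- protocol_spec("g", gain = 0.95, offset = 0.4, cv = 0)
  lot2 <- bead_lot(cv = 0.02, events_per_level = 2000)
  run2 <- generate_bead_run(pr, lot2, seed = 3)
  centers <- 10^(0.4 + 0.95 * log10(lot2$mesf))
  means <- as.numeric(tapply(run2$pe, run2$level, mean))
  expect_equal(means, centers, tolerance = 0.01)
})

test_that("event generator hits the protocol-transformed truth and labels populations", {
  co <- generate_cohort(seed = 4)
  pr <- protocol_spec("p", gain = 1.05, offset = 0.2, cv = 0)
  ev <- generate_events(co[3, ], "ncd64", pr, seed = 1, n_events = 400,
                        pe_cv = 0)
  for (pop in c("neutrophil", "monocyte", "lymphocyte")) {
    marker <- c(neutrophil = "ncd64", monocyte = "mcd64",
                lymphocyte = "lymcd64")[[pop]]
    expect_equal(unique(ev$pe[ev$population == pop]),
                 10^(0.2 + 1.05 * log10(co[[marker]][3])),
                 tolerance = 1e-12)
  }
  expect_equal(sort(unique(ev$population)),
               c("lymphocyte", "monocyte", "neutrophil"))
})

test_that("near-zero marker truth is clamped to the floor with a warning", {
  co <- generate_cohort(seed = 4)[1, ]
  co$lymcd64 <- 1e-6
  expect_warning(
    ev <- generate_events(co, "ncd64", protocol_spec("p", 1, 0, 0),
                          seed = 1, n_events = 50, pe_cv = 0, floor = 1),
    "clamped"
  )
  expect_equal(unique(ev$pe[ev$population == "lymphocyte"]), 1)
})

test_that("unknown panel id is rejected", {
  co <- generate_cohort(seed = 4)[1, ]
  expect_error(generate_events(co, "tbnk", protocol_spec("p", 1, 0, 0)),
               class = "cytomesf_input_error")
})

test_that("calibrated MESF agrees across protocols far better than raw MFI", {
  st <- mesf_recovery_study(n_subjects = 100, cv = 0.05, seed = 21)
  for (m in c("ncd64", "mhladr")) {
    d <- st$measurements[st$measurements$marker == m, ]
    d$subject_id <- paste0(d$subject_id, ":", d$timepoint)
    icc_mesf <- icc(d, value = "mesf")$icc
    icc_mfi <- icc(d, value = "mfi")$icc
    expect_gte(icc_mesf, 0.95)
    expect_gt(icc_mesf, icc_mfi)
  }
})
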