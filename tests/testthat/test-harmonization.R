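test_that("ICC(2,1) matches hand-computed variance components", {
  perfect <- matrix(rep(c(1, 2, 3), each = 4), ncol = 4, byrow = TRUE)
  expect_equal(icc(mat_to_long(perfect))$icc, 1)

  ident2 <- matrix(c(1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  expect_equal(icc(mat_to_long(ident2))$icc, 1)

  # anticorrelated columns: MSR = 0, MSE = 2 -> exactly -3
  anti <- matrix(c(1, 3, 2, 2, 3, 1), ncol = 2, byrow = TRUE)
  res <- icc(mat_to_long(anti))
  expect_equal(res$icc, -3)
  expect_lt(res$icc, 0)

  rand <- withr::with_seed(11, matrix(rnorm(60, 10, 3), ncol = 4) +
                             rnorm(15, 0, 5))
  expect_equal(icc(mat_to_long(rand))$icc, icc21_matrix(rand))
})

test_that("ICC approaches the variance-ratio truth on simulated data", {
  mat <- withr::with_seed(5, {
    subj <- rnorm(200, 100, 10)   # between-subject SD 10
    sweep(matrix(rnorm(200 * 4, 0, 1), ncol = 4), 1, subj, "+")
  })
  expect_gte(icc(mat_to_long(mat))$icc, 0.97)
})

test_that("ICC is invariant to common scaling and degenerate sets error", {
  mat <- withr::with_seed(2, matrix(rlnorm(80, 7, 1), ncol = 4))
  base <- icc(mat_to_long(mat))$icc
  expect_equal(icc(mat_to_long(mat * 3.7))$icc, base)
  expect_error(icc(mat_to_long(mat[1, , drop = FALSE])),
               class = "cytomesf_input_error")
  expect_error(icc(mat_to_long(matrix(5, 4, 3))),
               class = "cytomesf_input_error")
})

test_that("Bland-Altman reproduces closed-form bias, limits and outliers", {
  # protocol equal to the mean for every subject
  mat <- matrix(c(1, 1, 2, 2, 3, 3, 4, 4), ncol = 2, byrow = TRUE)
  ba <- bland_altman(mat_to_long(mat), "p1")
  expect_equal(ba$bias, 0)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0, 0))
  expect_equal(ba$outliers, character(0))

  # alternating +/-1 differences from the per-subject mean
  n <- 20
  base <- seq(100, by = 10, length.out = n)
  dev <- rep(c(1, -1), n / 2)
  mat2 <- cbind(p1 = base + dev, p2 = base - dev)
  rownames(mat2) <- paste0("s", 1:n)
  ba2 <- bland_altman(mat_to_long(mat2), "p1")
  sd_expected <- sd(dev) # differences are exactly dev
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_upper, 1.96 * sd_expected)
  expect_equal(ba2$loa_lower, -1.96 * sd_expected)

  expect_error(bland_altman(mat_to_long(mat2[1:2, ]), "p1"),
               class = "cytomesf_input_error")
})

test_that("a gross single-protocol error is flagged by the 3-SD rule", {
  mat <- withr::with_seed(3, matrix(rnorm(4 * 50, 1000, 5), ncol = 4))
  rownames(mat) <- sprintf("s%02d", 1:50)
  colnames(mat) <- paste0("p", 1:4)
  mat["s07", "p2"] <- mat["s07", "p2"] + 500
  ba <- bland_altman(mat_to_long(mat), "p2")
  expect_equal(ba$outliers, "s07")
})

test_that("limits of agreement contain about 95% of normal differences", {
  mat <- withr::with_seed(17, {
    subj <- rnorm(1000, 5000, 800)
    sweep(matrix(rnorm(4000, 0, 50), ncol = 4), 1, subj, "+")
  })
  ba <- bland_altman(mat_to_long(mat), "p1", outlier_sd = Inf)
  inside <- mean(ba$data$diff >= ba$loa_lower & ba$data$diff <= ba$loa_upper)
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
})

test_that("consensus averages the retained protocols and always emits", {
  mat <- matrix(c(100, 102, 98, 1000), nrow = 1)
  colnames(mat) <- paste0("p", 1:4)
  rownames(mat) <- "s1"
  long <- mat_to_long(mat)
  cons <- consensus_mesf(long, exclusions = tibble::tibble(
    subject_id = "s1", protocol = "p4"))
  expect_equal(cons$consensus, 100)
  expect_equal(cons$n_included, 3)
  expect_equal(cons$excluded, "p4")

  plain <- consensus_mesf(long)
  expect_equal(plain$consensus, mean(c(100, 102, 98, 1000)))

  expect_warning(
    all_out <- consensus_mesf(long, exclusions = tibble::tibble(
      subject_id = "s1", protocol = paste0("p", 1:4))),
    "unfiltered"
  )
  expect_equal(all_out$consensus, mean(c(100, 102, 98, 1000)))
})

test_that("outlier exclusion strictly improves worst-case consistency", {
  mat <- withr::with_seed(23, {
    subj <- rlnorm(100, 8, 0.8)
    sweep(matrix(rlnorm(400, 0, 0.05), ncol = 4), 1, subj, "*")
  })
  rownames(mat) <- sprintf("s%03d", 1:100)
  colnames(mat) <- paste0("p", 1:4)
  mat["s050", "p3"] <- mat["s050", "p3"] * 10
  rep <- suppressWarnings(harmonize(mat_to_long(mat)))
  expect_gt(nrow(rep$outliers), 0)
  expect_lt(rep$max_std_diff_after, rep$max_std_diff_before)
})
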