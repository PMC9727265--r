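#' Default per-stratum marker parameters
#'
#' Target arithmetic mean and SD (MESF units, PE-molecule equivalents) of the
#' four CD64/HLA-DR markers for each generating stratum of the synthetic
#' cohort. nCD64 and mHLA-DR parameters follow the group summaries of a
#' published kidney-transplant immune-monitoring cohort (healthy controls,
#' stable recipients, and infected recipients split by sepsis status);
#' lymphocyte and monocyte CD64 parameters are not published at group level
#' and are package defaults chosen so that the implied CD64 index magnitudes
#' are realistic (see the methods vignette).
#'
#' @return A tibble with columns `stratum`, `marker`, `mean`, `sd`.
#' @export
default_marker_params <- function() {
  tibble::tribble(
    ~stratum,     ~marker,   ~mean,    ~sd,
    "HC",         "ncd64",   1192.58,  537.61,
    "HC",         "mhladr",  2341.27,  781.75,
    "HC",         "mcd64",   3000,     900,
    "HC",         "lymcd64", 41,       15,
    "stable",     "ncd64",   1697.89,  1056.32,
    "stable",     "mhladr",  2728.62,  854.87,
    "stable",     "mcd64",   3200,     1000,
    "stable",     "lymcd64", 51,       20,
    "sepsis",     "ncd64",   10265.47, 8293.09,
    "sepsis",     "mhladr",  1803.47,  1192.66,
    "sepsis",     "mcd64",   8000,     2500,
    "sepsis",     "lymcd64", 130,      50,
    "non_sepsis", "ncd64",   8908.39,  8837.41,
    "non_sepsis", "mhladr",  3021.52,  1260.32,
    "non_sepsis", "mcd64",   7500,     2500,
    "non_sepsis", "lymcd64", 131,      50
  )
}

#' Default per-stratum TBNK lymphocyte-subset count parameters
#'
#' Absolute counts (cells/uL). Stable and infection parameters follow the
#' published group summaries; sepsis and non-sepsis share the infection-group
#' parameters (no finer split is published). Healthy-control parameters are
#' package defaults in the adult reference range.
#'
#' @return A tibble with columns `stratum`, `subset`, `mean`, `sd`.
#' @export
default_tbnk_params <- function() {
  infection <- tibble::tribble(
    ~subset, ~mean,  ~sd,
    "cd3",   628.52, 469.07,
    "cd8",   284.68, 243.10,
    "cd4",   301.36, 228.33,
    "nk",    123.40, 104.91,
    "b",     67.17,  66.67
  )
  dplyr::bind_rows(
    tibble::tribble(
      ~subset, ~mean,   ~sd,
      "cd3",   1400,    450,
      "cd8",   520,     230,
      "cd4",   750,     280,
      "nk",    260,     160,
      "b",     210,     120
    ) |> dplyr::mutate(stratum = "HC"),
    tibble::tribble(
      ~subset, ~mean,    ~sd,
      "cd3",   1141.11,  537.85,
      "cd8",   471.15,   242.78,
      "cd4",   598.42,   322.91,
      "nk",    223.26,   204.71,
      "b",     162.00,   113.84
    ) |> dplyr::mutate(stratum = "stable"),
    infection |> dplyr::mutate(stratum = "sepsis"),
    infection |> dplyr::mutate(stratum = "non_sepsis")
  ) |>
    dplyr::select("stratum", "subset", "mean", "sd")
}

#' Specification of a synthetic study cohort
#'
#' Bundles every parameter the cohort generator needs: stratum sizes, marker
#' and TBNK lognormal targets, creatinine and SOFA models, and the
#' longitudinal (second-timepoint) model. Defaults emulate a cohort of 26
#' healthy controls, 65 stable kidney-transplant recipients and 50 infected
#' recipients (19 sepsis / 31 non-sepsis; pathogen classes 26 bacterial /
#' 13 viral / 11 fungal), with 21 infected patients retested about one week
#' later, 3 of whom deteriorate (SOFA increase).
#'
#' @param group_sizes Named integer vector with elements `HC`, `stable`,
#'   `sepsis`, `non_sepsis`.
#' @param pathogen_counts Named integer vector (`bacterial`, `viral`,
#'   `fungal`) summing to the infection size.
#' @param markers Tibble of per-stratum marker targets, as
#'   [default_marker_params()].
#' @param tbnk Tibble of per-stratum TBNK count targets, as
#'   [default_tbnk_params()].
#' @param creatinine Tibble with columns `stratum`, `mean`, `sd` (umol/L).
#' @param n_second Named integer vector: how many `sepsis` / `non_sepsis`
#'   subjects receive a second timepoint.
#' @param n_exacerbation Number of retested subjects with a SOFA increase.
#' @param longitudinal List with per-marker log-scale drift for the
#'   exacerbation (`exac`) and non-exacerbation (`nonexac`) courses and a
#'   common log-scale noise SD `sigma`.
#' @param marker_floor Positive floor applied to generated marker values.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(group_sizes = c(HC = 26, stable = 65,
                                        sepsis = 19, non_sepsis = 31),
                        pathogen_counts = c(bacterial = 26, viral = 13,
                                            fungal = 11),
                        markers = default_marker_params(),
                        tbnk = default_tbnk_params(),
                        creatinine = tibble::tribble(
                          ~stratum,     ~mean,  ~sd,
                          "HC",         70,     12,
                          "stable",     121.91, 54.94,
                          "sepsis",     172.10, 113.10,
                          "non_sepsis", 172.10, 113.10
                        ),
                        n_second = c(sepsis = 14, non_sepsis = 7),
                        n_exacerbation = 3,
                        longitudinal = list(
                          exac = c(ncd64 = 0.05, mhladr = -0.7,
                                   mcd64 = 0.05, lymcd64 = 0),
                          nonexac = c(ncd64 = -1.0, mhladr = 0.3,
                                      mcd64 = -0.5, lymcd64 = 0),
                          sigma = 0.25
                        ),
                        marker_floor = 1) {
  strata <- c("HC", "stable", "sepsis", "non_sepsis")
  if (!setequal(names(group_sizes), strata) || any(group_sizes < 0)) {
    abort("group_sizes must name HC/stable/sepsis/non_sepsis with sizes >= 0",
          class = "cytomesf_parameterization_error")
  }
  assert_cols(markers, c("stratum", "marker", "mean", "sd"), "markers")
  assert_cols(tbnk, c("stratum", "subset", "mean", "sd"), "tbnk")
  if (any(markers$mean <= 0) || any(markers$sd <= 0) ||
      any(tbnk$mean <= 0) || any(tbnk$sd <= 0)) {
    abort("all target means and SDs must be strictly positive",
          class = "cytomesf_parameterization_error")
  }
  n_inf <- sum(group_sizes[c("sepsis", "non_sepsis")])
  if (n_inf > 0 && sum(pathogen_counts) != n_inf) {
    abort("pathogen_counts must sum to the infection group size",
          class = "cytomesf_parameterization_error")
  }
  if (sum(n_second) > n_inf || n_exacerbation > sum(n_second)) {
    abort("second-timepoint counts exceed available subjects",
          class = "cytomesf_parameterization_error")
  }
  if (marker_floor <= 0) {
    abort("marker_floor must be > 0",
          class = "cytomesf_parameterization_error")
  }
  structure(
    list(group_sizes = group_sizes, pathogen_counts = pathogen_counts,
         markers = markers, tbnk = tbnk, creatinine = creatinine,
         n_second = n_second, n_exacerbation = n_exacerbation,
         longitudinal = longitudinal, marker_floor = marker_floor),
    class = "cohort_spec"
  )
}

#' Specification of the measurement protocols (instrument settings)
#'
#' Each protocol models one acquisition setting as a log-domain linear
#' response: `MFI = 10^(offset + gain * log10(MESF))` times multiplicative
#' lognormal noise with the given CV. Defaults model four settings: three
#' PE-channel voltages on one cytometer plus a second instrument, all with
#' 5% measurement CV.
#'
#' @param protocol Character protocol ids.
#' @param gain Log-domain slopes (> 0, dimensionless).
#' @param offset Log-domain intercepts (log10 fluorescence units).
#' @param cv Multiplicative noise coefficients of variation (>= 0).
#' @return A tibble with one row per protocol.
#' @export
protocol_spec <- function(protocol, gain = 1, offset = 0, cv = 0) {
  out <- tibble::tibble(protocol = as.character(protocol),
                        gain = gain, offset = offset, cv = cv)
  if (any(out$gain <= 0)) {
    abort("protocol gain must be > 0",
          class = "cytomesf_parameterization_error")
  }
  if (any(out$cv < 0)) {
    abort("protocol noise CV must be >= 0",
          class = "cytomesf_parameterization_error")
  }
  if (anyDuplicated(out$protocol)) {
    abort("protocol ids must be unique",
          class = "cytomesf_parameterization_error")
  }
  out
}

#' @rdname protocol_spec
#' @export
default_protocols <- function(cv = 0.05) {
  protocol_spec(
    protocol = c("canto_high", "canto_medium", "canto_low", "dxflex"),
    gain = c(1.00, 1.05, 0.95, 1.02),
    offset = c(0, 0.3, -0.2, 0.6),
    cv = cv
  )
}

#' Calibration bead lot
#'
#' A bead set with several calibrated PE-molecule levels (MESF units) used to
#' fit the MFI-to-MESF regression. No lot values are published for the study
#' this package emulates; the defaults are arbitrary placeholders spanning
#' the physiological MESF range and are fully configurable.
#'
#' @param mesf Strictly increasing, strictly positive PE molecules per bead.
#' @param events_per_level Bead events simulated per level.
#' @param cv Within-level multiplicative spread (CV) of bead fluorescence.
#' @return A `bead_lot` object.
#' @export
bead_lot <- function(mesf = c(500, 5000, 25000, 60000),
                     events_per_level = 500, cv = 0.02) {
  if (length(mesf) < 2 || any(mesf <= 0) ||
      is.unsorted(mesf, strictly = TRUE)) {
    abort(paste("bead lot needs at least two strictly increasing,",
                "positive MESF levels"),
          class = "cytomesf_parameterization_error")
  }
  if (events_per_level < 1 || cv < 0) {
    abort("invalid bead lot event count or CV",
          class = "cytomesf_parameterization_error")
  }
  structure(list(mesf = mesf, events_per_level = events_per_level, cv = cv),
            class = "bead_lot")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject true receptor quantities from moment-matched lognormal
#' distributions (arithmetic mean and SD equal the spec targets), assigns
#' group labels, TBNK counts, creatinine and SOFA scores, and simulates a
#' second timepoint for a configurable subset of infected subjects whose
#' marker drift direction is tied to the SOFA change (deterioration raises
#' nCD64 and depresses mHLA-DR; recovery does the reverse).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same spec and seed give identical cohorts.
#' @return A tibble with one row per subject-timepoint: identifiers and group
#'   labels, true marker MESFs (`ncd64`, `mcd64`, `lymcd64`, `mhladr`), TBNK
#'   counts and percentages, `creatinine`, `baseline_creatinine`, `sofa`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  sizes <- spec$group_sizes
  n_total <- sum(sizes)
  if (n_total == 0) return(empty_cohort())

  stratum <- rep(names(sizes), times = sizes)
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    stratum = stratum,
    group = dplyr::case_when(
      stratum == "HC" ~ "HC",
      stratum == "stable" ~ "stable",
      TRUE ~ "infection"
    ),
    sepsis = dplyr::case_when(
      stratum == "sepsis" ~ TRUE,
      stratum == "non_sepsis" ~ FALSE,
      TRUE ~ NA
    )
  )

  # pathogen classes within the infection group, fixed counts, random order
  inf_idx <- which(subjects$group == "infection")
  subjects$pathogen <- NA_character_
  if (length(inf_idx) > 0) {
    labels <- rep(names(spec$pathogen_counts), times = spec$pathogen_counts)
    subjects$pathogen[inf_idx] <- sample(labels)
  }

  # true marker MESFs, lognormal moment-matched per stratum
  draw_marker <- function(marker) {
    vals <- numeric(n_total)
    for (st in unique(subjects$stratum)) {
      par <- spec$markers[spec$markers$stratum == st &
                            spec$markers$marker == marker, ]
      if (nrow(par) != 1) {
        abort(paste0("missing marker parameters for ", st, "/", marker),
              class = "cytomesf_parameterization_error")
      }
      idx <- which(subjects$stratum == st)
      lp <- lnorm_params(par$mean, par$sd)
      vals[idx] <- rlnorm(length(idx), lp$meanlog, lp$sdlog)
    }
    pmax(vals, spec$marker_floor)
  }
  for (m in c("ncd64", "mcd64", "lymcd64", "mhladr")) {
    subjects[[m]] <- draw_marker(m)
  }

  # TBNK counts (truncated at zero via lognormal positivity) and percentages
  for (s in unique(spec$tbnk$subset)) {
    vals <- numeric(n_total)
    for (st in unique(subjects$stratum)) {
      par <- spec$tbnk[spec$tbnk$stratum == st & spec$tbnk$subset == s, ]
      idx <- which(subjects$stratum == st)
      lp <- lnorm_params(par$mean, par$sd)
      vals[idx] <- rlnorm(length(idx), lp$meanlog, lp$sdlog)
    }
    subjects[[paste0(s, "_count")]] <- vals
  }
  lym_total <- subjects$cd3_count + subjects$b_count + subjects$nk_count
  for (s in c("cd3", "cd4", "cd8", "nk", "b")) {
    subjects[[paste0(s, "_pct")]] <-
      100 * subjects[[paste0(s, "_count")]] / lym_total
  }

  # creatinine and SOFA
  subjects$baseline_creatinine <- NA_real_
  subjects$creatinine <- NA_real_
  for (st in unique(subjects$stratum)) {
    par <- spec$creatinine[spec$creatinine$stratum == st, ]
    idx <- which(subjects$stratum == st)
    lp <- lnorm_params(par$mean, par$sd)
    subjects$creatinine[idx] <- rlnorm(length(idx), lp$meanlog, lp$sdlog)
  }
  ktr <- subjects$group != "HC"
  subjects$baseline_creatinine[ktr] <-
    rlnorm(sum(ktr), lnorm_params(110, 30)$meanlog, lnorm_params(110, 30)$sdlog)
  subjects$baseline_creatinine[!ktr] <- subjects$creatinine[!ktr]

  subjects$sofa <- 0L
  subjects$sofa[subjects$stratum == "sepsis"] <-
    2L + rpois(sizes[["sepsis"]], 2)
  subjects$sofa[subjects$stratum == "non_sepsis"] <-
    rbinom(sizes[["non_sepsis"]], 1, 0.5)

  subjects$timepoint <- 1L

  # second timepoint for a subset of infected subjects
  second <- character(0)
  for (st in names(spec$n_second)) {
    pool <- subjects$subject_id[subjects$stratum == st]
    k <- min(spec$n_second[[st]], length(pool))
    if (k > 0) second <- c(second, sample(pool, k))
  }
  if (length(second) > 0) {
    exac_ids <- sample(second, min(spec$n_exacerbation, length(second)))
    t2 <- subjects[subjects$subject_id %in% second, ]
    t2$timepoint <- 2L
    exac <- t2$subject_id %in% exac_ids
    dsofa <- integer(nrow(t2))
    dsofa[exac] <- sample(1:3, sum(exac), replace = TRUE)
    dsofa[!exac] <- -sample(0:3, sum(!exac), replace = TRUE)
    t2$sofa <- pmax(t2$sofa + dsofa, 0L)
    lg <- spec$longitudinal
    for (m in c("ncd64", "mcd64", "lymcd64", "mhladr")) {
      drift <- ifelse(exac, lg$exac[[m]], lg$nonexac[[m]])
      t2[[m]] <- pmax(
        t2[[m]] * exp(drift + rnorm(nrow(t2), 0, lg$sigma)),
        spec$marker_floor
      )
    }
    t2$creatinine <- t2$creatinine * exp(ifelse(exac, 0.2, -0.1) +
                                           rnorm(nrow(t2), 0, 0.05))
    subjects <- dplyr::bind_rows(subjects, t2)
  }

  subjects |>
    dplyr::select(-"stratum") |>
    dplyr::arrange(.data$subject_id, .data$timepoint)
}

empty_cohort <- function() {
  tibble::tibble(
    subject_id = character(0), group = character(0), sepsis = logical(0),
    pathogen = character(0),
    ncd64 = numeric(0), mcd64 = numeric(0), lymcd64 = numeric(0),
    mhladr = numeric(0),
    cd3_count = numeric(0), cd8_count = numeric(0), cd4_count = numeric(0),
    nk_count = numeric(0), b_count = numeric(0),
    cd3_pct = numeric(0), cd4_pct = numeric(0), cd8_pct = numeric(0),
    nk_pct = numeric(0), b_pct = numeric(0),
    baseline_creatinine = numeric(0), creatinine = numeric(0),
    sofa = integer(0), timepoint = integer(0)
  )
}

#' Simulate per-protocol MFI measurements of true marker quantities
#'
#' Applies each protocol's log-domain gain/offset response and multiplicative
#' lognormal noise to every subject-timepoint marker truth, yielding the raw
#' MFIs an instrument would report under that setting.
#'
#' @param truths Cohort tibble from [generate_cohort()].
#' @param protocols Protocol tibble from [protocol_spec()].
#' @param seed Integer seed.
#' @param markers Marker columns of `truths` to measure.
#' @return A long tibble: `subject_id`, `timepoint`, `marker`, `protocol`,
#'   `true_mesf`, `mfi`.
#' @export
generate_protocol_measurements <- function(truths,
                                           protocols = default_protocols(),
                                           seed = 1L,
                                           markers = c("ncd64", "mcd64",
                                                       "lymcd64", "mhladr")) {
  if (nrow(protocols) < 1) {
    abort("at least one protocol is required",
          class = "cytomesf_parameterization_error")
  }
  assert_cols(protocols, c("protocol", "gain", "offset", "cv"), "protocols")
  if (nrow(truths) == 0) {
    return(tibble::tibble(subject_id = character(0), timepoint = integer(0),
                          marker = character(0), protocol = character(0),
                          true_mesf = numeric(0), mfi = numeric(0)))
  }
  assert_cols(truths, c("subject_id", "timepoint", markers), "truths")
  long <- truths |>
    dplyr::select("subject_id", "timepoint", dplyr::all_of(markers)) |>
    tidyr::pivot_longer(dplyr::all_of(markers), names_to = "marker",
                        values_to = "true_mesf") |>
    tidyr::crossing(protocols) |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$marker,
                   .data$protocol)
  withr::with_seed(seed, {
    sdlog <- sqrt(log1p(long$cv^2))
    noise <- rlnorm(nrow(long), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    long |>
      dplyr::mutate(
        mfi = protocol_transform(.data$true_mesf, .data$gain, .data$offset) *
          noise
      ) |>
      dplyr::select("subject_id", "timepoint", "marker", "protocol",
                    "true_mesf", "mfi")
  })
}
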