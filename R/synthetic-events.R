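#' Default event-level channel model for synthetic samples
#'
#' Location and spread (linear fluorescence units) of the gating channels for
#' each leukocyte population. CD45/side-scatter separate neutrophils,
#' monocytes and lymphocytes in the CD64 panel; CD14 isolates monocytes in
#' the HLA-DR panel. Published gating figures for the emulated study are not
#' available, so these are declared conventions with wide separation, not
#' inferred values.
#'
#' @return A tibble with columns `population`, `channel`, `mean`, `sd`.
#' @export
default_channel_params <- function() {
  tibble::tribble(
    ~population,  ~channel, ~mean, ~sd,
    "neutrophil", "cd45",   300,   40,
    "neutrophil", "ssc",    900,   70,
    "neutrophil", "cd14",   150,   50,
    "monocyte",   "cd45",   600,   50,
    "monocyte",   "ssc",    500,   60,
    "monocyte",   "cd14",   800,   100,
    "lymphocyte", "cd45",   1000,  60,
    "lymphocyte", "ssc",    200,   40,
    "lymphocyte", "cd14",   100,   40
  )
}

# marker measured on the PE channel per population, by panel
panel_pe_marker <- function(panel) {
  switch(panel,
    ncd64 = c(neutrophil = "ncd64", monocyte = "mcd64",
              lymphocyte = "lymcd64"),
    mhladr = c(neutrophil = NA_character_, monocyte = "mhladr",
               lymphocyte = NA_character_),
    abort(paste0("unknown panel id: ", panel),
          class = "cytomesf_input_error")
  )
}

#' Simulate an event-level cytometry sample for one subject-timepoint
#'
#' Emits neutrophil, monocyte and lymphocyte events with separable gating
#' channels (`cd45`, `ssc`, `cd14`) and a PE channel whose per-population
#' arithmetic mean equals the protocol-transformed true marker value. In the
#' CD64 panel the PE channel carries CD64 on all three populations; in the
#' HLA-DR panel it carries HLA-DR on monocytes and a low background
#' elsewhere. The generating population label is retained per event.
#'
#' @param subject One row of a [generate_cohort()] tibble.
#' @param panel `"ncd64"` or `"mhladr"`.
#' @param protocol One row of a [protocol_spec()] tibble.
#' @param seed Integer seed.
#' @param n_events Events per population.
#' @param pe_cv Within-population multiplicative spread (CV) of the PE
#'   channel around the transformed truth.
#' @param channel_params Gating-channel model, as [default_channel_params()].
#' @param background_pe Linear PE background for populations not carrying
#'   the panel marker.
#' @param floor Positive floor for near-zero true marker values; values below
#'   it are clamped with a warning.
#' @return An event tibble: `sample_id`, `timepoint`, `panel`, `protocol`,
#'   `event_id`, `cd45`, `ssc`, `cd14`, `pe`, `population` (ground truth).
#' @export
generate_events <- function(subject, panel, protocol, seed = 1L,
                            n_events = 1000, pe_cv = 0.3,
                            channel_params = default_channel_params(),
                            background_pe = 30, floor = 1) {
  markers <- panel_pe_marker(panel)
  stopifnot(nrow(subject) == 1, nrow(protocol) == 1)
  withr::with_seed(seed, {
    pops <- names(markers)
    out <- purrr::map_dfr(pops, function(pop) {
      m <- markers[[pop]]
      truth <- if (is.na(m)) background_pe else subject[[m]]
      if (!is.na(m) && truth < floor) {
        warn(paste0("true ", m, " below positive floor for ",
                    subject$subject_id, "; clamped to ", floor))
        truth <- floor
      }
      center <- protocol_transform(truth, protocol$gain, protocol$offset)
      cp <- channel_params[channel_params$population == pop, ]
      ch <- function(name) {
        p <- cp[cp$channel == name, ]
        pmax(rnorm(n_events, p$mean, p$sd), 0)
      }
      tibble::tibble(
        cd45 = ch("cd45"), ssc = ch("ssc"), cd14 = ch("cd14"),
        pe = center * mult_noise(n_events, pe_cv),
        population = pop
      )
    })
    out |>
      dplyr::mutate(
        sample_id = subject$subject_id,
        timepoint = subject$timepoint %||% 1L,
        panel = panel,
        protocol = protocol$protocol,
        event_id = dplyr::row_number(),
        .before = 1
      )
  })
}

#' Simulate a calibration bead run under one protocol
#'
#' One event cluster per bead level, centred on the protocol-transformed lot
#' MESF (the same gain law as cell measurements) with the lot's
#' within-level multiplicative spread.
#'
#' @param protocol One row of a [protocol_spec()] tibble.
#' @param lot A [bead_lot()].
#' @param seed Integer seed.
#' @return An event tibble: `protocol`, `event_id`, `pe`, `level` (ground
#'   truth level index).
#' @export
generate_bead_run <- function(protocol, lot = bead_lot(), seed = 1L) {
  stopifnot(inherits(lot, "bead_lot"), nrow(protocol) == 1)
  withr::with_seed(seed, {
    centers <- protocol_transform(lot$mesf, protocol$gain, protocol$offset)
    purrr::map_dfr(seq_along(centers), function(i) {
      tibble::tibble(
        level = i,
        pe = centers[i] * mult_noise(lot$events_per_level, lot$cv)
      )
    }) |>
      dplyr::mutate(protocol = protocol$protocol,
                    event_id = dplyr::row_number(), .before = 1)
  })
}
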