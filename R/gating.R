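#' Gating thresholds
#'
#' Rectangular CD45/side-scatter gates for the CD64 panel and a CD14
#' threshold for the HLA-DR panel, matched by default to
#' [default_channel_params()]. All thresholds are configurable; the gating
#' convention is declared by this package (see the methods vignette).
#'
#' @param cd45_bright Lymphocytes: CD45 above this.
#' @param cd45_dim Neutrophils: CD45 below this.
#' @param ssc_high Neutrophils: side scatter above this.
#' @param ssc_low Lymphocytes: side scatter below this.
#' @param cd14_threshold Monocytes (HLA-DR panel): CD14 above this.
#' @param min_events Populations below this count carry a quality flag.
#' @return A named list of gating parameters.
#' @export
gating_params <- function(cd45_bright = 800, cd45_dim = 450, ssc_high = 700,
                          ssc_low = 350, cd14_threshold = 400,
                          min_events = 100) {
  as.list(environment())
}

required_channels <- function(panel) {
  switch(panel,
    ncd64 = c("cd45", "ssc", "pe"),
    mhladr = c("cd14", "ssc", "pe"),
    abort(paste0("unknown panel id: ", panel),
          class = "cytomesf_input_error")
  )
}

#' Identify leukocyte populations in an event table
#'
#' CD64 panel: neutrophils are CD45-dim with high side scatter, lymphocytes
#' CD45-bright with low side scatter, monocytes intermediate on both.
#' HLA-DR panel: monocytes are CD14-positive, everything else is pooled as
#' `other`. Populations are disjoint by construction; events matching no
#' gate stay unassigned. Populations that are empty or below `min_events`
#' are flagged, never silently dropped.
#'
#' @param events Event tibble (see [generate_events()] for the canonical
#'   columns); any table with the panel's required channels works.
#' @param panel `"ncd64"` or `"mhladr"`.
#' @param params A [gating_params()] list.
#' @return A `gated_populations` object: `assignment` (tibble of `event_id`,
#'   `population`), `counts`, `flags`, `panel`, `params`.
#' @export
gate_populations <- function(events, panel, params = gating_params()) {
  if (nrow(events) == 0) {
    abort("no events to gate", class = "cytomesf_input_error")
  }
  assert_cols(events, required_channels(panel), "event table")
  if (!all(is.finite(events$pe)) || any(events$pe < 0)) {
    abort("PE channel must be finite and non-negative",
          class = "cytomesf_input_error")
  }
  pop <- if (panel == "ncd64") {
    dplyr::case_when(
      events$cd45 < params$cd45_dim & events$ssc > params$ssc_high ~
        "neutrophil",
      events$cd45 > params$cd45_bright & events$ssc < params$ssc_low ~
        "lymphocyte",
      events$cd45 >= params$cd45_dim & events$cd45 <= params$cd45_bright &
        events$ssc >= params$ssc_low & events$ssc <= params$ssc_high ~
        "monocyte",
      TRUE ~ NA_character_
    )
  } else {
    ifelse(events$cd14 > params$cd14_threshold, "monocyte", "other")
  }
  expected <- if (panel == "ncd64") {
    c("neutrophil", "monocyte", "lymphocyte")
  } else {
    c("monocyte", "other")
  }
  event_id <- if ("event_id" %in% names(events)) events$event_id else
    seq_len(nrow(events))
  assignment <- tibble::tibble(event_id = event_id, population = pop)
  counts <- tibble::tibble(population = expected) |>
    dplyr::left_join(
      assignment |> dplyr::count(.data$population, name = "n_events"),
      by = "population"
    ) |>
    tidyr::replace_na(list(n_events = 0L))
  flags <- character(0)
  for (i in seq_len(nrow(counts))) {
    if (counts$n_events[i] == 0) {
      flags <- c(flags, paste0(counts$population[i], ": empty"))
    } else if (counts$n_events[i] < params$min_events) {
      flags <- c(flags, paste0(counts$population[i], ": below ",
                               params$min_events, " events"))
    }
  }
  structure(list(assignment = assignment, counts = counts, flags = flags,
                 panel = panel, params = params),
            class = "gated_populations")
}

#' @export
print.gated_populations <- function(x, ...) {
  cat("Gated populations (", x$panel, " panel)\n", sep = "")
  print(x$counts)
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Extract a population MFI from gated events
#'
#' The MFI is the arithmetic mean of the marker channel over the
#' population's events by default; a geometric mean is available and the
#' averaging rule used is recorded in the result.
#'
#' @param events The event tibble that was gated.
#' @param gated The matching [gate_populations()] result.
#' @param population Population name.
#' @param channel Marker channel, default `"pe"`.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @param min_events Counts below this attach a `low_count` flag with a
#'   warning.
#' @return A one-row tibble: `sample_id`, `timepoint`, `protocol`,
#'   `population`, `channel`, `mfi`, `n_events`, `method`, `low_count`.
#' @export
extract_mfi <- function(events, gated, population, channel = "pe",
                        method = c("arithmetic", "geometric"),
                        min_events = gated$params$min_events) {
  method <- match.arg(method)
  stopifnot(inherits(gated, "gated_populations"))
  assert_cols(events, channel, "event table")
  event_id <- if ("event_id" %in% names(events)) events$event_id else
    seq_len(nrow(events))
  keep <- event_id %in%
    gated$assignment$event_id[!is.na(gated$assignment$population) &
                                gated$assignment$population == population]
  x <- events[[channel]][keep]
  if (length(x) == 0) {
    abort(paste0("population '", population, "' is empty"),
          class = "cytomesf_input_error")
  }
  mfi <- if (method == "arithmetic") mean(x) else exp(mean(log(x)))
  low <- length(x) < min_events
  if (low) {
    warn(paste0("population '", population, "' has ", length(x),
                " events (minimum ", min_events, ")"))
  }
  meta <- function(col, default) {
    if (col %in% names(events)) events[[col]][1] else default
  }
  tibble::tibble(
    sample_id = meta("sample_id", NA_character_),
    timepoint = meta("timepoint", NA_integer_),
    protocol = meta("protocol", NA_character_),
    population = population, channel = channel,
    mfi = mfi, n_events = length(x), method = method, low_count = low
  )
}

#' Locate bead-level clusters in a calibration bead run
#'
#' Partitions bead events into as many clusters as the lot has levels by
#' one-dimensional k-means on log10 PE intensity with quantile
#' initialization (deterministic and invariant to event order), then reports
#' the arithmetic-mean MFI per cluster in ascending order. Collapsed levels
#' (fewer resolvable clusters than lot levels) are an error naming the
#' merged levels.
#'
#' @param events Bead event tibble with a `pe` column.
#' @param lot The [bead_lot()] the run used.
#' @param min_log_gap Minimum log10 separation between adjacent cluster
#'   centers before levels are declared merged.
#' @return A `bead_peaks` tibble: `level`, `mfi`, `n_events`, with the
#'   protocol id as an attribute when present.
#' @export
find_bead_peaks <- function(events, lot = bead_lot(), min_log_gap = 0.05) {
  stopifnot(inherits(lot, "bead_lot"))
  if (nrow(events) == 0) {
    abort("no bead events", class = "cytomesf_input_error")
  }
  assert_cols(events, "pe", "bead run")
  k <- length(lot$mesf)
  x <- log10(events$pe)
  centers <- as.numeric(quantile(x, probs = (seq_len(k) - 0.5) / k))
  for (iter in seq_len(200)) {
    assign <- apply(abs(outer(x, centers, "-")), 1, which.min)
    sizes <- tabulate(assign, nbins = k)
    if (any(sizes == 0)) {
      merged <- which(sizes == 0)
      abort(paste0("bead levels appear merged; no events resolved for ",
                   "level(s) ", paste(merged, collapse = ", ")),
            class = "cytomesf_bead_error")
    }
    new_centers <- vapply(seq_len(k), function(j) mean(x[assign == j]),
                          numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  ord <- order(centers)
  gaps <- diff(centers[ord])
  if (any(gaps < min_log_gap)) {
    merged <- which(gaps < min_log_gap)[1]
    abort(paste0("bead levels ", merged, " and ", merged + 1,
                 " are merged (log10 gap ", signif(gaps[merged], 3),
                 " < ", min_log_gap, ")"),
          class = "cytomesf_bead_error")
  }
  peaks <- tibble::tibble(
    level = seq_len(k),
    mfi = vapply(ord, function(j) mean(events$pe[assign == j]), numeric(1)),
    n_events = sizes[ord]
  )
  attr(peaks, "protocol") <- if ("protocol" %in% names(events))
    events$protocol[1] else NA_character_
  class(peaks) <- c("bead_peaks", class(peaks))
  peaks
}
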