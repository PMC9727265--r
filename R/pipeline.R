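#' Pipeline configuration
#'
#' Central configuration for the simulate/analyse pipeline. Unknown keys are
#' rejected so config files fail loudly. All defaults mirror the package's
#' analysis conventions: 1.96-SD limits of agreement, 3-SD outlier
#' exclusion, diagnostic cutoffs nCD64 > 3089 and mHLA-DR > 2433 MESF, and
#' the renal SOFA rule (creatinine >= 171 umol/L or >= 1.5x baseline).
#'
#' @param ... Overrides of the default entries (nested lists merge by key).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    mode = "measurements",
    paths = list(output_dir = NULL, summary_tables = NULL,
                 contingency_tables = NULL),
    simulate = list(write_events = FALSE, events_per_population = 300,
                    pe_cv = 0.3),
    protocols = default_protocols(),
    lot = bead_lot(),
    gating = gating_params(),
    calibration = list(r2_floor = 0.98),
    harmonization = list(loa_multiplier = 1.96, outlier_sd = 3),
    indices = list(cutoffs = c(ncd64 = 3089, mhladr = 2433),
                   renal_abs = 171, renal_ratio = 1.5),
    stats = list(entry_p = 0.05),
    cohort = NULL
  )
  overrides <- list(...)
  config <- merge_config(defaults, overrides, path = "config")
  if (!config$mode %in% c("events", "measurements", "summary")) {
    abort("mode must be one of events/measurements/summary",
          class = "cytomesf_config_error")
  }
  if (config$harmonization$loa_multiplier <= 0 ||
      config$harmonization$outlier_sd <= 0 ||
      any(config$indices$cutoffs <= 0) || config$indices$renal_abs <= 0 ||
      config$indices$renal_ratio <= 0) {
    abort("multipliers and cutoffs must be positive",
          class = "cytomesf_config_error")
  }
  structure(config, class = "pipeline_config")
}

merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown ", path, " key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "cytomesf_config_error")
  }
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && !is.data.frame(defaults[[key]]) &&
        !inherits(defaults[[key]], c("bead_lot", "cohort_spec")) &&
        is.list(overrides[[key]]) && !is.data.frame(overrides[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      paste0(path, "$", key))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys follow [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$protocols)) {
    raw$protocols <- do.call(protocol_spec, raw$protocols)
  }
  if (!is.null(raw$lot)) raw$lot <- do.call(bead_lot, raw$lot)
  if (!is.null(raw$indices$cutoffs)) {
    raw$indices$cutoffs <- unlist(raw$indices$cutoffs)
  }
  do.call(pipeline_config, raw)
}

#' Simulate a complete synthetic study bundle on disk
#'
#' Writes the cohort truth table, per-protocol marker measurements, bead
#' runs, the lot sheet, and (optionally) event-level samples as plain CSV,
#' plus a JSON echo of the generating parameters. Re-running with the same
#' config and seed reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (defaults to `config$paths$output_dir`).
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(config, dir = config$paths$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dir)) {
    abort("an output directory is required", class = "cytomesf_config_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(paste0("cannot create output directory ", dir),
          class = "cytomesf_config_error")
  }
  spec <- config$cohort %||% cohort_spec()
  seed <- config$seed
  cohort <- generate_cohort(spec, child_seed(seed, 1))
  meas <- generate_protocol_measurements(cohort, config$protocols,
                                         child_seed(seed, 2))
  beads <- purrr::map_dfr(seq_len(nrow(config$protocols)), function(i) {
    generate_bead_run(config$protocols[i, ], config$lot,
                      child_seed(seed, 100 + i))
  })
  files <- c(
    cohort = file.path(dir, "cohort.csv"),
    measurements = file.path(dir, "measurements.csv"),
    beads = file.path(dir, "beads.csv"),
    lot = file.path(dir, "lot.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(cohort, files[["cohort"]])
  readr::write_csv(meas, files[["measurements"]])
  readr::write_csv(beads, files[["beads"]])
  readr::write_csv(tibble::tibble(level = seq_along(config$lot$mesf),
                                  mesf = config$lot$mesf), files[["lot"]])
  jsonlite::write_json(
    list(seed = seed, group_sizes = as.list(spec$group_sizes),
         protocols = config$protocols,
         lot = list(mesf = config$lot$mesf,
                    events_per_level = config$lot$events_per_level,
                    cv = config$lot$cv)),
    files[["truth"]], auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$simulate$write_events)) {
    for (panel in c("ncd64", "mhladr")) {
      ev <- purrr::map_dfr(seq_len(nrow(cohort)), function(r) {
        purrr::map_dfr(seq_len(nrow(config$protocols)), function(i) {
          generate_events(
            cohort[r, ], panel, config$protocols[i, ],
            seed = child_seed(seed, 1000 + r * 10 + i +
                                ifelse(panel == "ncd64", 0, 5e5)),
            n_events = config$simulate$events_per_population,
            pe_cv = config$simulate$pe_cv)
        })
      })
      f <- file.path(dir, paste0("events_", panel, ".csv"))
      readr::write_csv(ev, f)
      files[[paste0("events_", panel)]] <- f
    }
  }
  invisible(files)
}

# population -> marker mapping used when rebuilding measurements from events
population_marker <- function(panel, population) {
  if (panel == "ncd64") {
    c(neutrophil = "ncd64", monocyte = "mcd64",
      lymphocyte = "lymcd64")[[population]]
  } else {
    c(monocyte = "mhladr")[[population]]
  }
}

#' Run the full analysis pipeline on a simulated (or compatible) bundle
#'
#' Executes bead-peak finding, calibration-curve fitting, MFI-to-MESF
#' conversion, per-marker multi-protocol harmonization (ICC, Bland-Altman,
#' 3-SD outlier exclusion, consensus), index computation, longitudinal
#' deltas, and the cohort statistics layer (group ANOVAs and LSD contrasts,
#' ROC analyses for infection and sepsis, univariate and multivariate
#' logistic models). In `"events"` mode per-population MFIs are first
#' recovered by gating the event tables; in `"measurements"` mode the MFI
#' table is used directly; in `"summary"` mode only the statistics layer
#' runs, on typed-in group summary tables, producing an identically
#' structured report.
#'
#' @param config A [pipeline_config()].
#' @param dir Bundle directory written by [run_simulate()] (ignored in
#'   summary mode).
#' @return A `pipeline_report` list: `mode`, `reliability`, `records`,
#'   `group_comparisons`, `roc`, `logistic`, `longitudinal`.
#' @export
run_full_pipeline <- function(config, dir = config$paths$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$mode == "summary") {
    return(summary_mode_report(config))
  }
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
                            show_col_types = FALSE)
  lot_df <- readr::read_csv(file.path(dir, "lot.csv"),
                            show_col_types = FALSE)
  lot <- bead_lot(mesf = lot_df$mesf,
                  events_per_level = config$lot$events_per_level,
                  cv = config$lot$cv)
  beads <- readr::read_csv(file.path(dir, "beads.csv"),
                           show_col_types = FALSE)

  curves <- lapply(split(beads, beads$protocol), function(b) {
    peaks <- find_bead_peaks(b, lot)
    fit_calibration_curve(peaks, lot, config$calibration$r2_floor)
  })

  mfis <- if (config$mode == "events") {
    purrr::map_dfr(c("ncd64", "mhladr"), function(panel) {
      path <- file.path(dir, paste0("events_", panel, ".csv"))
      if (!file.exists(path)) {
        abort(paste0("gating stage: missing event table ", path),
              class = "cytomesf_pipeline_error")
      }
      ev <- readr::read_csv(path, show_col_types = FALSE)
      purrr::map_dfr(
        split(ev, list(ev$sample_id, ev$timepoint, ev$protocol),
              drop = TRUE),
        function(e) {
          gated <- gate_populations(e, panel, config$gating)
          pops <- if (panel == "ncd64") {
            c("neutrophil", "monocyte", "lymphocyte")
          } else "monocyte"
          purrr::map_dfr(pops, function(p) {
            extract_mfi(e, gated, p) |>
              dplyr::mutate(marker = population_marker(panel, p))
          })
        })
    }) |>
      dplyr::rename(subject_id = "sample_id")
  } else {
    readr::read_csv(file.path(dir, "measurements.csv"),
                    show_col_types = FALSE)
  }

  calibrated <- calibrate_measurements(mfis, curves)
  calibrated$uid <- paste0(calibrated$subject_id, ":", calibrated$timepoint)

  markers <- intersect(c("ncd64", "mcd64", "lymcd64", "mhladr"),
                       unique(calibrated$marker))
  reliability <- lapply(setNames(markers, markers), function(m) {
    d <- calibrated |>
      dplyr::filter(.data$marker == m) |>
      dplyr::transmute(subject_id = .data$uid, .data$protocol, .data$mesf)
    harmonize(d, loa_multiplier = config$harmonization$loa_multiplier,
              outlier_sd = config$harmonization$outlier_sd)
  })

  consensus <- purrr::map_dfr(markers, function(m) {
    reliability[[m]]$consensus |>
      dplyr::mutate(marker = m)
  }) |>
    tidyr::separate("subject_id", into = c("subject_id", "timepoint"),
                    sep = ":", convert = TRUE) |>
    dplyr::select("subject_id", "timepoint", "marker", "consensus") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "consensus")

  records <- cohort |>
    dplyr::select(-dplyr::any_of(c("ncd64", "mcd64", "lymcd64", "mhladr"))) |>
    dplyr::inner_join(consensus, by = c("subject_id", "timepoint")) |>
    add_indices()

  report_from_records(records, reliability, config)
}

report_from_records <- function(records, reliability, config) {
  first <- records[records$timepoint == 1, ]

  summarize_groups <- function(data, var, group_col) {
    data |>
      dplyr::filter(!is.na(.data[[var]]), !is.na(.data[[group_col]])) |>
      dplyr::group_by(label = .data[[group_col]]) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data[[var]]),
                       sd = sd(.data[[var]]), .groups = "drop") |>
      dplyr::filter(.data$n >= 2) # SD undefined below two observations
  }
  na_row <- tibble::tibble(statistic = NA_real_, p_value = NA_real_)
  safe <- function(expr) tryCatch(expr, error = function(e) na_row)

  params <- c("ncd64", "mhladr", "cd64_index", "si")
  comparisons <- purrr::map_dfr(params, function(v) {
    sg <- first |>
      dplyr::mutate(sg = dplyr::case_when(
        .data$group == "stable" ~ "stable",
        .data$group == "infection" & .data$sepsis ~ "sepsis",
        .data$group == "infection" & !.data$sepsis ~ "non_sepsis",
        TRUE ~ NA_character_)) |>
      summarize_groups(v, "sg")
    dplyr::bind_rows(
      safe(anova_oneway_from_summary(summarize_groups(first, v, "group"))) |>
        dplyr::mutate(block = "cohort_group", parameter = v,
                      method = "anova"),
      safe(anova_oneway_from_summary(sg)) |>
        dplyr::mutate(block = "sepsis_group", parameter = v,
                      method = "anova"),
      safe(lsd_pairwise_from_summary(sg, "sepsis", "non_sepsis")) |>
        dplyr::mutate(block = "sepsis_group", parameter = v,
                      method = "lsd_sepsis_vs_non_sepsis"),
      safe(anova_oneway_from_summary(
        summarize_groups(first[first$group == "infection", ], v,
                         "pathogen"))) |>
        dplyr::mutate(block = "pathogen", parameter = v, method = "anova")
    )
  }) |>
    dplyr::select("block", "parameter", "method", "statistic",
                  dplyr::everything())

  ktr <- first[first$group != "HC", ]
  roc <- purrr::map_dfr(params, function(v) {
    dplyr::bind_rows(
      glance(roc_analysis(ktr[[v]], ktr$group == "infection")) |>
        dplyr::mutate(outcome = "infection", parameter = v),
      {
        inf <- ktr[ktr$group == "infection", ]
        glance(roc_analysis(inf[[v]], inf$sepsis,
                            direction = if (v == "mhladr") "<" else ">")) |>
          dplyr::mutate(outcome = "sepsis", parameter = v)
      }
    )
  }) |>
    dplyr::select("outcome", "parameter", dplyr::everything())

  model_data <- ktr |>
    dplyr::transmute(
      infection = .data$group == "infection",
      ncd64_high = binarize_marker(.data$ncd64, "ncd64",
                                   config$indices$cutoffs),
      mhladr_high = binarize_marker(.data$mhladr, "mhladr",
                                    config$indices$cutoffs),
      cd3 = .data$cd3_count, cd4 = .data$cd4_count, cd8 = .data$cd8_count,
      nk = .data$nk_count, b = .data$b_count
    )
  logistic <- list(
    univariate = tidy(logistic_fit(model_data, "infection",
                                   mode = "univariate")),
    multivariate = tidy(tryCatch(
      logistic_fit(model_data, "infection", mode = "multivariate",
                   entry_p = config$stats$entry_p),
      error = function(e) structure(list(terms = tibble::tibble()),
                                    class = "logistic_fit")))
  )

  deltas <- longitudinal_deltas(records)
  longitudinal <- if (nrow(deltas) >= 4 &&
                      length(unique(deltas$exacerbation)) == 2) {
    purrr::map_dfr(c("d_ncd64", "d_mhladr", "d_si", "d_cd64_index"),
                   function(v) {
      g <- deltas |>
        dplyr::filter(!is.na(.data[[v]])) |>
        dplyr::group_by(label = ifelse(.data$exacerbation, "exacerbation",
                                       "non_exacerbation")) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data[[v]]),
                         sd = sd(.data[[v]]), .groups = "drop")
      if (nrow(g) < 2 || any(g$n < 2)) {
        return(tibble::tibble(parameter = v, statistic = NA_real_,
                              df = NA_real_, p_value = NA_real_))
      }
      t_test_from_summary(g[g$label == "exacerbation", ],
                          g[g$label == "non_exacerbation", ]) |>
        dplyr::mutate(parameter = v) |>
        dplyr::select("parameter", dplyr::everything())
    })
  } else {
    tibble::tibble()
  }

  structure(
    list(
      mode = config$mode,
      reliability = lapply(reliability, function(h) {
        list(icc = glance(h$icc),
             bland_altman = purrr::map_dfr(h$bland_altman, glance),
             n_outlier_cells = nrow(h$outliers),
             max_std_diff_before = h$max_std_diff_before,
             max_std_diff_after = h$max_std_diff_after)
      }),
      records = records,
      group_comparisons = comparisons,
      roc = roc,
      logistic = logistic,
      longitudinal = longitudinal
    ),
    class = "pipeline_report"
  )
}

#' Statistics on typed-in group summary tables
#'
#' Runs the summary-statistic tests a printed cohort table supports: one-way
#' ANOVA over each parameter's groups, pooled or Welch two-group t-tests,
#' LSD pairwise contrasts, and Pearson/Fisher tests on count tables.
#'
#' @param summaries Tibble with columns `block`, `parameter`, `label`, `n`,
#'   `mean`, `sd`, `test` (`anova`, `t_pooled`, `t_welch`, or `lsd`), and
#'   `compare` (`"a|b"`, the two labels contrasted by `t_*`/`lsd` rows).
#' @param contingency Optional tibble with columns `block`, `row_label`,
#'   `col_label`, `count`, `test` (`pearson` or `fisher`).
#' @return A tibble: `block`, `parameter`, `method`, `statistic`, `p_value`.
#' @export
run_summary_stats <- function(summaries, contingency = NULL) {
  assert_cols(summaries, c("block", "parameter", "label", "n", "mean", "sd",
                           "test"), "summary tables")
  res <- purrr::map_dfr(
    split(summaries,
          list(summaries$block, summaries$parameter), drop = TRUE),
    function(d) {
      test <- d$test[1]
      groups <- group_summary(d$label, d$n, d$mean, d$sd)
      out <- if (test == "anova") {
        a <- anova_oneway_from_summary(groups)
        tibble::tibble(p_value = a$p_value, statistic = a$statistic)
      } else if (test %in% c("t_pooled", "t_welch")) {
        pair <- strsplit(d$compare[1], "|", fixed = TRUE)[[1]]
        tt <- t_test_from_summary(
          groups[groups$label == pair[1], ],
          groups[groups$label == pair[2], ],
          variant = sub("t_", "", test))
        tibble::tibble(p_value = tt$p_value, statistic = tt$statistic)
      } else if (test == "lsd") {
        pair <- strsplit(d$compare[1], "|", fixed = TRUE)[[1]]
        ll <- lsd_pairwise_from_summary(groups, pair[1], pair[2])
        tibble::tibble(p_value = ll$p_value, statistic = ll$statistic)
      } else {
        abort(paste0("unknown summary test '", test, "'"),
              class = "cytomesf_input_error")
      }
      dplyr::mutate(out, block = d$block[1], parameter = d$parameter[1],
                    method = test)
    })
  if (!is.null(contingency)) {
    assert_cols(contingency, c("block", "row_label", "col_label", "count",
                               "test"), "contingency tables")
    res <- dplyr::bind_rows(res, purrr::map_dfr(
      split(contingency, contingency$block),
      function(d) {
        tab <- tidyr::pivot_wider(d[, c("row_label", "col_label", "count")],
                                  names_from = "col_label",
                                  values_from = "count")
        m <- as.matrix(tab[-1])
        rownames(m) <- tab$row_label
        ct <- chi_square_test(m, method = d$test[1])
        tibble::tibble(block = d$block[1], parameter = "counts",
                       method = d$test[1], statistic = ct$statistic,
                       p_value = ct$p_value)
      }))
  }
  dplyr::select(res, "block", "parameter", "method", "statistic", "p_value")
}

summary_mode_report <- function(config) {
  path <- config$paths$summary_tables
  if (is.null(path)) {
    abort("summary mode requires paths$summary_tables",
          class = "cytomesf_config_error")
  }
  summaries <- readr::read_csv(path, show_col_types = FALSE)
  contingency <- if (!is.null(config$paths$contingency_tables)) {
    readr::read_csv(config$paths$contingency_tables, show_col_types = FALSE)
  }
  structure(
    list(mode = "summary", reliability = list(),
         records = tibble::tibble(),
         group_comparisons = run_summary_stats(summaries, contingency),
         roc = tibble::tibble(), logistic = list(),
         longitudinal = tibble::tibble()),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report (", x$mode, " mode)\n", sep = "")
  if (length(x$reliability) > 0) {
    for (m in names(x$reliability)) {
      cat("  ICC[", m, "] = ",
          signif(x$reliability[[m]]$icc$icc, 4), "\n", sep = "")
    }
  }
  cat("  group comparisons:", nrow(x$group_comparisons), "tests\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_report <- function(report, path) {
  out <- report
  out$records <- NULL # bulky; CSV-ready via readr on the records tibble
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' The default synthetic measurement study
#'
#' The canonical end-to-end recovery setting used for reliability
#' properties: `n_subjects` drawn proportionally from the default cohort
#' strata (single timepoint), measured for nCD64 and mHLA-DR under the four
#' default protocols at the given CV, with a bead run per protocol,
#' calibration-curve fits, and MFI-to-MESF conversion.
#'
#' @param n_subjects Cohort size (default 100).
#' @param cv Protocol measurement CV (default 0.05).
#' @param protocols Protocol table; default the four standard settings at
#'   `cv`.
#' @param lot Calibration [bead_lot()].
#' @param seed Integer seed driving every stage.
#' @return List: `truths`, `measurements` (with `mfi` and `mesf`), `curves`,
#'   `protocols`, `lot`.
#' @export
mesf_recovery_study <- function(n_subjects = 100, cv = 0.05,
                                protocols = default_protocols(cv),
                                lot = bead_lot(), seed = 1L) {
  base <- c(HC = 26, stable = 65, sepsis = 19, non_sepsis = 31)
  sizes <- round(base / sum(base) * n_subjects)
  sizes[1] <- n_subjects - sum(sizes[-1])
  n_inf <- sizes[["sepsis"]] + sizes[["non_sepsis"]]
  pc <- round(c(bacterial = 26, viral = 13, fungal = 11) / 50 * n_inf)
  pc[1] <- n_inf - sum(pc[-1])
  spec <- cohort_spec(group_sizes = sizes, pathogen_counts = pc,
                      n_second = c(sepsis = 0, non_sepsis = 0),
                      n_exacerbation = 0)
  truths <- generate_cohort(spec, child_seed(seed, 1))
  meas <- generate_protocol_measurements(truths, protocols,
                                         child_seed(seed, 2),
                                         markers = c("ncd64", "mhladr"))
  curves <- lapply(seq_len(nrow(protocols)), function(i) {
    run <- generate_bead_run(protocols[i, ], lot, child_seed(seed, 100 + i))
    fit_calibration_curve(find_bead_peaks(run, lot), lot)
  })
  names(curves) <- protocols$protocol
  list(truths = truths, measurements = calibrate_measurements(meas, curves),
       curves = curves, protocols = protocols, lot = lot)
}
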