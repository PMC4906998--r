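# Tidy organ-bath table schema: one row per measurement.
BATH_COLUMNS <- c("subject_id", "tissue", "precontraction", "drug_labels",
                  "mode", "concentration_molar", "time_min", "response_raw",
                  "papaverine_reference", "pretreatment_efs_reference")

BATH_MODES <- c("crc", "efs", "combination_crc", "time_control")

bath_col_types <- readr::cols(
  subject_id = readr::col_character(),
  tissue = readr::col_character(),
  precontraction = readr::col_character(),
  drug_labels = readr::col_character(),
  mode = readr::col_character(),
  concentration_molar = readr::col_double(),
  time_min = readr::col_double(),
  response_raw = readr::col_double(),
  papaverine_reference = readr::col_double(),
  pretreatment_efs_reference = readr::col_double()
)

#' Read and validate a tidy organ-bath measurement table
#'
#' The CSV schema holds one measurement per row: `subject_id`, `tissue`
#' (`bronchus`/`pcls`), `precontraction`, `drug_labels` (";"-joined for
#' combinations), `mode` (`crc`, `combination_crc`, `efs`, `time_control`),
#' `concentration_molar` (CRC rows), `time_min` (EFS rows), `response_raw`,
#' `papaverine_reference` (CRC rows) and `pretreatment_efs_reference` (EFS
#' rows). Columns are matched by header name, so column order is free.
#' Row-level violations are reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble with the schema columns.
#' @export
read_bath_table <- function(path) {
  if (!file.exists(path)) {
    stop_airwaysyn(paste0("file not found: ", path), "io")
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(BATH_COLUMNS, header)
  if (length(missing) > 0) {
    stop_airwaysyn(
      paste0("schema error: missing column(s) ", paste(missing, collapse = ", ")),
      "schema"
    )
  }
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = bath_col_types, show_col_types = FALSE)
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop_airwaysyn(
      paste0("row error(s): non-numeric or malformed values at row(s) ",
             paste(unique(probs$row), collapse = ", ")),
      "row"
    )
  }
  tbl <- tbl[, BATH_COLUMNS]
  validate_bath_table(tbl)
  tbl
}

validate_bath_table <- function(tbl) {
  errs <- character(0)
  bad_mode <- which(!tbl$mode %in% BATH_MODES)
  if (length(bad_mode) > 0) {
    errs <- c(errs, paste0("unknown mode at row(s) ",
                           paste(head(bad_mode, 5), collapse = ", ")))
  }
  conc_rows <- tbl$mode %in% c("crc", "combination_crc")
  time_rows <- tbl$mode %in% c("efs", "time_control")
  both <- which(!is.na(tbl$concentration_molar) & !is.na(tbl$time_min))
  neither <- which(is.na(tbl$concentration_molar) & is.na(tbl$time_min))
  if (length(both) > 0) {
    errs <- c(errs, paste0("both concentration_molar and time_min set at row(s) ",
                           paste(head(both, 5), collapse = ", ")))
  }
  if (length(neither) > 0) {
    errs <- c(errs, paste0("neither concentration_molar nor time_min set at row(s) ",
                           paste(head(neither, 5), collapse = ", ")))
  }
  miss_pap <- which(conc_rows & is.na(tbl$papaverine_reference))
  if (length(miss_pap) > 0) {
    errs <- c(errs, paste0("schema error: papaverine_reference missing on crc row(s) ",
                           paste(head(miss_pap, 5), collapse = ", ")))
  }
  miss_efs <- which(time_rows & is.na(tbl$pretreatment_efs_reference))
  if (length(miss_efs) > 0) {
    errs <- c(errs, paste0("pretreatment_efs_reference missing on efs row(s) ",
                           paste(head(miss_efs, 5), collapse = ", ")))
  }
  if (length(errs) > 0) {
    stop_airwaysyn(paste(errs, collapse = "; "), "schema")
  }
  invisible(tbl)
}

#' Write a tidy organ-bath table to CSV
#'
#' @param tbl A bath table (see [read_bath_table()] for the schema).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bath_table <- function(tbl, path) {
  stopifnot(all(BATH_COLUMNS %in% names(tbl)))
  readr::write_csv(tbl[, BATH_COLUMNS], path)
  invisible(path)
}

#' Render simulated (normalized) data as a raw organ-bath table
#'
#' Maps normalized response fractions back onto a raw measurement scale so
#' that generator output exercises the full read-normalize-analyze path:
#' CRC rows use a precontraction plateau of `plateau` and papaverine level
#' `papaverine` (raw = plateau - response * (plateau - papaverine)); EFS rows
#' use a pre-treatment contraction amplitude of `efs_reference`
#' (raw = reference * (1 - response)).
#'
#' @param data Tibble from [simulate_crc()] (needs `conc_molar`) or
#'   [simulate_efs_timecourse()] (needs `time_min`).
#' @param mode `"crc"`, `"combination_crc"` or `"efs"`.
#' @param tissue,precontraction Metadata columns.
#' @param plateau,papaverine,efs_reference Raw-scale anchors.
#' @return A schema-conforming bath table tibble.
#' @export
as_bath_table <- function(data, mode = c("crc", "efs"),
                          tissue = "bronchus", precontraction = "acetylcholine",
                          plateau = 2, papaverine = 0.5, efs_reference = 1) {
  mode <- match.arg(mode)
  if (mode == "crc") {
    stopifnot(all(c("subject_id", "drug", "conc_molar", "response") %in% names(data)))
    tibble::tibble(
      subject_id = data$subject_id, tissue = tissue,
      precontraction = precontraction, drug_labels = data$drug, mode = "crc",
      concentration_molar = data$conc_molar, time_min = NA_real_,
      response_raw = plateau - data$response * (plateau - papaverine),
      papaverine_reference = papaverine,
      pretreatment_efs_reference = NA_real_
    )
  } else {
    stopifnot(all(c("subject_id", "treatment", "time_min", "response") %in% names(data)))
    tibble::tibble(
      subject_id = data$subject_id, tissue = tissue, precontraction = "EFS",
      drug_labels = gsub("\\+", ";", data$treatment),
      mode = ifelse(data$treatment == "time_control", "time_control", "efs"),
      concentration_molar = NA_real_, time_min = data$time_min,
      response_raw = efs_reference * (1 - data$response),
      papaverine_reference = NA_real_,
      pretreatment_efs_reference = efs_reference
    )
  }
}

#' Analysis run configuration
#'
#' @param mode `"all"`, `"crc"` or `"efs"`.
#' @param alpha Significance level in (0, 1).
#' @param ec_levels Isoeffective effect levels (percent) for the combination
#'   CRC design.
#' @param intervals AUC intervals in hours (list of `c(start, end)`).
#' @param pairing Expected-effect uncertainty scheme (see
#'   [expected_with_uncertainty()]).
#' @param per_drug_effect Single-agent EFS plateau effect fraction (EC level
#'   of the time-course design).
#' @param seed Integer seed for the synthetic stages.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @param synthetic A [synthetic_config()] for the generator stages.
#' @return Object of class `run_config`; serializable with
#'   [jsonlite::toJSON()] via `unclass()`.
#' @export
run_config <- function(mode = c("all", "crc", "efs"), alpha = 0.05,
                       ec_levels = seq(10, 90, by = 10),
                       intervals = list(c(0, 1), c(0, 3), c(0, 6), c(0, 9),
                                        c(0, 12)),
                       pairing = c("by_subject", "delta_method"),
                       per_drug_effect = 0.2,
                       seed = 1L, out_dir = NULL,
                       synthetic = synthetic_config(seed = seed)) {
  mode <- match.arg(mode)
  pairing <- match.arg(pairing)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_airwaysyn("alpha must lie in (0, 1)", "invalid_input")
  }
  structure(
    list(mode = mode, alpha = alpha, ec_levels = ec_levels,
         intervals = parse_intervals(intervals), pairing = pairing,
         per_drug_effect = per_drug_effect, seed = as.integer(seed),
         out_dir = out_dir, synthetic = synthetic),
    class = "run_config"
  )
}

config_hash <- function(config) rlang::hash(unclass(config))

strip_classes <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, strip_classes) else x
}

#' Serialize a run or generator configuration to JSON
#'
#' @param config A [run_config()] or [synthetic_config()].
#' @return A JSON string (class `json`).
#' @export
config_json <- function(config) {
  jsonlite::toJSON(strip_classes(config), auto_unbox = TRUE, null = "null",
                   digits = NA)
}

#' Run the full interaction-analysis pipeline
#'
#' Orchestrates the study designs end to end on synthetic data (or on traces
#' supplied by the caller): simulates per-drug CRCs and fits the 4PL model
#' per subject; simulates the isoeffective combination design and classifies
#' the interaction at every attainable effect level; simulates the 12-h EFS
#' time course, computes the synergism curve, onset t1/2, plateau, interval
#' AUCs and duration of synergism. Deterministic given the config seed. When
#' `config$out_dir` is set, writes `fits_summary.csv`, `crc_assessments.csv`,
#' `efs_synergism.csv`, `metrics.json` and `run_log.txt` (with the config
#' hash).
#'
#' @param config A [run_config()].
#' @param truths Named list of 2 `drug_truth` objects (default
#'   [reference_truths()]).
#' @param efs_data Optional EFS trace table replacing the simulated one.
#' @return List with `crc` (fit summaries and per-level assessments), `efs`
#'   (synergism curve, metrics, AUCs, duration), `config_hash`.
#' @export
run_pipeline <- function(config = run_config(), truths = reference_truths(),
                         efs_data = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config$synthetic
  hash <- config_hash(config)
  result <- list(config_hash = hash)

  if (config$mode %in% c("all", "crc")) {
    fits_sum <- list()
    for (i in seq_along(truths)) {
      crc <- simulate_crc(truths[[i]], cfg, seed = cfg$seed + i)
      fits <- fit_crc_replicates(crc)
      fits_sum[[names(truths)[i]]] <-
        dplyr::mutate(summarize_crc_fits(fits), drug = names(truths)[i],
                      .before = 1)
    }
    fits_summary <- dplyr::bind_rows(fits_sum)

    combo <- simulate_combination_crc(truths[[1]], truths[[2]], cfg = cfg,
                                      levels = config$ec_levels,
                                      seed = cfg$seed + 101L)
    resp <- combo$responses[combo$responses$attainable, ]
    assessments <- lapply(unique(resp$level_pct), function(lv) {
      d <- resp[resp$level_pct == lv, ]
      singles <- lapply(combo$drug_labels, function(l) {
        d$response[d$treatment == l][order(d$subject_id[d$treatment == l])]
      })
      names(singles) <- combo$drug_labels
      expd <- expected_with_uncertainty(singles, pairing = config$pairing)
      obs <- d$response[d$treatment == combo$combination_label]
      assess_interaction(obs, expd, alpha = config$alpha, condition = lv)
    })
    assessments <- dplyr::bind_rows(assessments)
    result$crc <- list(fits_summary = fits_summary,
                       assessments = assessments,
                       concentrations = combo$concentrations)
  }

  if (config$mode %in% c("all", "efs")) {
    efs <- efs_data %||%
      simulate_efs_timecourse(truths, per_drug_effect = config$per_drug_effect,
                              cfg = cfg, seed = cfg$seed + 202L)
    sc <- synergism_curve(efs, alpha = config$alpha)

    comb_mean <- dplyr::summarise(
      dplyr::group_by(efs[efs$treatment == "combination", ], .data$time_min),
      response = mean(.data$response), .groups = "drop"
    )
    trend <- fit_trend(comb_mean$time_min, comb_mean$response)
    onset_trend <- fit_trend(comb_mean$time_min, comb_mean$response,
                             window = c(0, cfg$wash_time))
    metrics <- compute_metrics(trend, onset_trend = onset_trend)

    aucs <- auc_intervals(sc, intervals = config$intervals)
    duration <- duration_of_synergism(sc, alpha = config$alpha)

    result$efs <- list(synergism = sc, metrics = metrics, auc = aucs,
                       duration_h = duration,
                       max_delta_pp = max(sc$delta_pp),
                       anova_p_group = attr(sc, "anova_p_group"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(result$crc)) {
      readr::write_csv(result$crc$fits_summary,
                       file.path(config$out_dir, "fits_summary.csv"))
      readr::write_csv(result$crc$assessments,
                       file.path(config$out_dir, "crc_assessments.csv"))
    }
    if (!is.null(result$efs)) {
      readr::write_csv(tibble::as_tibble(result$efs$synergism),
                       file.path(config$out_dir, "efs_synergism.csv"))
      jsonlite::write_json(
        list(e_max_relaxation = result$efs$metrics$e_max_relaxation,
             t_half_min = result$efs$metrics$t_half_min,
             e_max_plateau = result$efs$metrics$e_max_plateau,
             duration_h = result$efs$duration_h,
             auc = setNames(as.list(result$efs$auc$auc_pct_h),
                            result$efs$auc$interval)),
        file.path(config$out_dir, "metrics.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    writeLines(
      c(paste0("airwaysyn run, config hash ", hash),
        paste0("mode: ", config$mode, "; seed: ", config$seed)),
      file.path(config$out_dir, "run_log.txt")
    )
  }
  result
}
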