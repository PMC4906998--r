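#' Ground-truth drug parameters for simulation
#'
#' A `drug_truth` holds the generating 4PL parameters for one drug on the
#' normalized relaxation scale (fractions of the papaverine maximal effect).
#'
#' @param label Drug label.
#' @param bottom,top Lower/upper asymptotes (fractions; `top > bottom`,
#'   top may slightly exceed 1 as seen in luminal-area data).
#' @param log_ec50 log10 of the half-maximal molar concentration.
#' @param hill_slope Hill slope (> 0).
#' @return Object of class `drug_truth`.
#' @export
#' @examples
#' drug_truth("glycopyrronium", top = 0.9968, log_ec50 = -8.44)
drug_truth <- function(label, bottom = 0, top = 1, log_ec50, hill_slope = 1) {
  stopifnot(is.character(label), length(label) == 1,
            is_scalar_number(bottom), is_scalar_number(top),
            is_scalar_number(log_ec50), is_scalar_number(hill_slope))
  if (top <= bottom) stop_airwaysyn("top must exceed bottom", "invalid_input")
  if (hill_slope <= 0) stop_airwaysyn("hill_slope must be > 0", "invalid_input")
  if (bottom < 0 - 1e-9 && bottom < -0.05) {
    stop_airwaysyn("bottom must be >= -0.05 on the normalized scale", "invalid_input")
  }
  if (top > 1.05) stop_airwaysyn("top must be <= 1.05", "invalid_input")
  structure(list(label = label, bottom = bottom, top = top,
                 log_ec50 = log_ec50, hill_slope = hill_slope),
            class = "drug_truth")
}

#' Reference generating truths for the glycopyrronium/indacaterol pair
#'
#' Default simulation truths matching published potency and efficacy estimates
#' in human isolated bronchi precontracted with acetylcholine: pEC50 8.44 and
#' E_max 99.68 % for glycopyrronium, pEC50 7.39 and E_max 92.28 % for
#' indacaterol, Hill slope 1.
#'
#' @return Named list of two `drug_truth` objects.
#' @export
reference_truths <- function() {
  list(
    glycopyrronium = drug_truth("glycopyrronium", bottom = 0, top = 0.9968,
                                log_ec50 = -8.44, hill_slope = 1),
    indacaterol = drug_truth("indacaterol", bottom = 0, top = 0.9228,
                             log_ec50 = -7.39, hill_slope = 1)
  )
}

#' Configuration of the synthetic organ-bath generator
#'
#' Bundles every tunable of the generator so that a seed plus a config fully
#' determines the simulated tables. Defaults emulate the study conditions the
#' analysis assumes: n = 3 subject replicates, additive Gaussian noise of SD
#' 0.05 on the fraction-of-maximum scale (SEM-scale noise for n = 3), a
#' 12-hour EFS time course sampled every 5 min with a wash at 60 min, an
#' injected synergy of +0.30 effect fraction over the first 9 h, a smooth
#' synergy onset with half-time 18.3 min and a fast offset (half-time 2 min)
#' after the window so the window edge defines the ground-truth duration.
#'
#' @param n_subjects Number of subject replicates (>= 2).
#' @param noise_sd Gaussian noise SD on the normalized effect scale (>= 0).
#' @param synergy_delta Ground-truth deviation of the combination from the
#'   Bliss surface, as an effect fraction in \[-1, 1\].
#' @param synergy_window Time window `[t_start, t_end]` (min) over which the
#'   synergy applies in EFS mode.
#' @param concentration_grid Optional log10 molar grid for CRCs; default is
#'   `log_ec50 + seq(-3, 3, length.out = 9)` per drug.
#' @param efs_grid Time grid in minutes (strictly increasing, 0-720).
#' @param wash_time Wash-out time (min); must be before the end of `efs_grid`.
#' @param include_time_control Also simulate an untreated time-control trace?
#' @param onset_half_time Half-time (min) of the saturating-exponential onset
#'   of drug effects and of the injected synergy.
#' @param decay_half_time Half-time (min) of the synergy offset after the
#'   window closes.
#' @param subject_sd SD of an optional subject-level random offset shared
#'   across a curve (default 0 = off).
#' @param seed Integer seed; fully determines the generator output.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_subjects = 3, noise_sd = 0.05,
                             synergy_delta = 0.30,
                             synergy_window = c(0, 540),
                             concentration_grid = NULL,
                             efs_grid = seq(0, 720, by = 5),
                             wash_time = 60,
                             include_time_control = TRUE,
                             onset_half_time = 18.3,
                             decay_half_time = 2,
                             subject_sd = 0,
                             seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    stop_airwaysyn("n_subjects must be >= 2", "invalid_input")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    stop_airwaysyn("noise_sd must be >= 0", "invalid_input")
  }
  if (!is_scalar_number(synergy_delta) || abs(synergy_delta) > 1) {
    stop_airwaysyn("synergy_delta must lie in [-1, 1]", "invalid_input")
  }
  if (length(efs_grid) < 2 || any(diff(efs_grid) <= 0)) {
    stop_airwaysyn("efs_grid must be strictly increasing", "invalid_input")
  }
  if (length(synergy_window) != 2 || synergy_window[1] > synergy_window[2] ||
      synergy_window[1] < 0 || synergy_window[2] > max(efs_grid)) {
    stop_airwaysyn("synergy_window must lie within [0, max(efs_grid)]",
                   "invalid_input")
  }
  if (!is_scalar_number(wash_time) || wash_time >= max(efs_grid)) {
    stop_airwaysyn("wash_time must be before the end of the EFS grid",
                   "invalid_input")
  }
  if (!is_scalar_number(seed)) stop_airwaysyn("seed must be an integer", "invalid_input")
  structure(
    list(n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
         synergy_delta = synergy_delta, synergy_window = synergy_window,
         concentration_grid = concentration_grid, efs_grid = efs_grid,
         wash_time = wash_time, include_time_control = include_time_control,
         onset_half_time = onset_half_time, decay_half_time = decay_half_time,
         subject_sd = subject_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

subject_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate per-subject concentration-response curves for one drug
#'
#' Each response is the generating 4PL value plus (optionally) a shared
#' subject offset and i.i.d. Gaussian noise, truncated to the plausible
#' normalized band \[-0.05, 1.10\]. The output is byte-identical for a given
#' config and seed.
#'
#' @param truth A `drug_truth`.
#' @param cfg A `synthetic_config`.
#' @param seed Seed for this call (default `cfg$seed`); pass distinct seeds
#'   when simulating several drugs from one config.
#' @return Tibble with columns `subject_id`, `drug`, `log10_conc`,
#'   `conc_molar`, `response`.
#' @export
simulate_crc <- function(truth, cfg, seed = cfg$seed) {
  stopifnot(inherits(truth, "drug_truth"), inherits(cfg, "synthetic_config"))
  grid <- cfg$concentration_grid %||% (truth$log_ec50 + seq(-3, 3, length.out = 9))
  if (length(grid) == 0) {
    stop_airwaysyn("concentration grid is empty", "invalid_input")
  }
  mu <- fourpl_response(grid, truth$bottom, truth$top, truth$log_ec50,
                        truth$hill_slope)
  withr::with_seed(seed, {
    out <- lapply(seq_len(cfg$n_subjects), function(s) {
      offset <- if (cfg$subject_sd > 0) rnorm(1, 0, cfg$subject_sd) else 0
      resp <- truncate_response(mu + offset + rnorm(length(grid), 0, cfg$noise_sd))
      tibble::tibble(subject_id = subject_ids(cfg$n_subjects)[s],
                     drug = truth$label, log10_conc = grid,
                     conc_molar = 10^grid, response = resp)
    })
    dplyr::bind_rows(out)
  })
}

synergy_at_level <- function(level_pct, synergy_delta, synergy_levels) {
  if (is.null(synergy_levels)) return(synergy_delta)
  ifelse(level_pct >= synergy_levels[1] & level_pct <= synergy_levels[2],
         synergy_delta, 0)
}

#' Simulate a combination experiment at isoeffective concentrations
#'
#' Emulates the isoeffective combination design: at each requested effect
#' level f, every drug is applied at its EC_f (so each single agent produces
#' the fraction f), and the combination response is the Bliss expectation of
#' those single-agent effects plus the injected ground-truth synergy, clipped
#' to \[0, 1\], plus noise. Levels unattainable by any drug (outside its
#' bottom-top range) are flagged and carry no responses.
#'
#' @param truth_a,truth_b,truth_c `drug_truth` objects (`truth_c` optional).
#' @param cfg A `synthetic_config`.
#' @param levels Effect levels in percent of maximal effect.
#' @param synergy_delta Injected deviation from the Bliss surface (effect
#'   fraction); defaults to `cfg$synergy_delta`.
#' @param synergy_levels Optional `[lo, hi]` percent window outside which the
#'   injected synergy is 0 (default: applies at all levels).
#' @param seed Seed for this call.
#' @return List of class `combo_crc_sim` with elements `responses` (tibble:
#'   `level_pct`, `subject_id`, `treatment`, `response`, `attainable`),
#'   `concentrations` (tibble: `level_pct`, `drug`, `conc_molar`,
#'   `attainable`), and `truth` (tibble: `level_pct`, `expected`,
#'   `injected_delta`).
#' @export
simulate_combination_crc <- function(truth_a, truth_b, truth_c = NULL, cfg,
                                     levels = seq(10, 90, by = 10),
                                     synergy_delta = cfg$synergy_delta,
                                     synergy_levels = NULL,
                                     seed = cfg$seed) {
  truths <- Filter(Negate(is.null), list(truth_a, truth_b, truth_c))
  stopifnot(all(vapply(truths, inherits, logical(1), "drug_truth")),
            inherits(cfg, "synthetic_config"))
  if (abs(synergy_delta) > 1) {
    stop_airwaysyn("synergy_delta must lie in [-1, 1]", "invalid_input")
  }
  labels <- vapply(truths, `[[`, character(1), "label")
  combo_label <- paste(labels, collapse = "+")

  conc <- tidyr::expand_grid(level_pct = levels, drug = labels)
  conc$conc_molar <- NA_real_
  conc$attainable <- FALSE
  for (i in seq_len(nrow(conc))) {
    tr <- truths[[match(conc$drug[i], labels)]]
    frac <- (conc$level_pct[i] / 100 - tr$bottom) / (tr$top - tr$bottom)
    if (frac > 0 && frac < 1) {
      conc$conc_molar[i] <- ec_n(tr, conc$level_pct[i])
      conc$attainable[i] <- TRUE
    }
  }
  level_ok <- tapply(conc$attainable, conc$level_pct, all)
  k <- length(truths)

  truth_tbl <- tibble::tibble(
    level_pct = levels,
    expected = 1 - (1 - levels / 100)^k,
    injected_delta = synergy_at_level(levels, synergy_delta, synergy_levels)
  )
  truth_tbl$expected[!level_ok[as.character(levels)]] <- NA_real_

  ids <- subject_ids(cfg$n_subjects)
  withr::with_seed(seed, {
    rows <- list()
    for (lv in levels) {
      ok <- level_ok[[as.character(lv)]]
      f <- lv / 100
      e_comb <- clip01(1 - (1 - f)^k +
                         synergy_at_level(lv, synergy_delta, synergy_levels))
      for (s in ids) {
        for (lab in labels) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            level_pct = lv, subject_id = s, treatment = lab,
            response = if (ok) truncate_response(f + rnorm(1, 0, cfg$noise_sd)) else NA_real_,
            attainable = ok
          )
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          level_pct = lv, subject_id = s, treatment = combo_label,
          response = if (ok) truncate_response(e_comb + rnorm(1, 0, cfg$noise_sd)) else NA_real_,
          attainable = ok
        )
      }
    }
    structure(
      list(responses = dplyr::bind_rows(rows), concentrations = conc,
           truth = truth_tbl, drug_labels = labels,
           combination_label = combo_label),
      class = "combo_crc_sim"
    )
  })
}

synergy_shape <- function(t, window, onset_half_time, decay_half_time) {
  t0 <- window[1]
  t1 <- window[2]
  shape <- numeric(length(t))
  on <- t >= t0 & t <= t1
  shape[on] <- 1 - 2^(-(t[on] - t0) / onset_half_time)
  after <- t > t1
  shape_end <- 1 - 2^(-(t1 - t0) / onset_half_time)
  shape[after] <- shape_end * 2^(-(t[after] - t1) / decay_half_time)
  shape
}

#' Simulate EFS time-course traces for single agents and their combination
#'
#' Emulates the 12-h electrical-field-stimulation design: each single agent
#' (given at an isoeffective low concentration, e.g. EC20) relaxes the
#' EFS-evoked contraction towards `per_drug_effect` with a saturating
#' exponential onset and, being long-acting, holds the plateau; the
#' combination follows the Bliss expectation of the single-agent effects plus
#' the injected synergy profile (smooth onset inside `cfg$synergy_window`,
#' rapid decay after it); the time control fluctuates around 0 relaxation.
#' Gaussian noise is added pointwise and responses truncated to
#' \[-0.05, 1.10\].
#'
#' @param truths List of 1-3 `drug_truth` objects (labels are used for the
#'   treatment column).
#' @param per_drug_effect Plateau single-agent effect fraction in (0, 1)
#'   (default 0.2, the EC20 design).
#' @param cfg A `synthetic_config`.
#' @param synergy_delta Injected synergy (effect fraction), default from `cfg`.
#' @param seed Seed for this call.
#' @return Tibble with columns `subject_id`, `treatment` (drug labels,
#'   `"combination"`, `"time_control"`), `time_min`, `response` (fraction of
#'   the pre-treatment EFS contraction). The generating noiseless curves are
#'   attached as the `"truth"` attribute.
#' @export
simulate_efs_timecourse <- function(truths, per_drug_effect = 0.2, cfg,
                                    synergy_delta = cfg$synergy_delta,
                                    seed = cfg$seed) {
  if (inherits(truths, "drug_truth")) truths <- list(truths)
  stopifnot(all(vapply(truths, inherits, logical(1), "drug_truth")),
            inherits(cfg, "synthetic_config"))
  if (!is_scalar_number(per_drug_effect) || per_drug_effect <= 0 ||
      per_drug_effect >= 1) {
    stop_airwaysyn("per_drug_effect must lie in (0, 1)", "invalid_input")
  }
  t <- cfg$efs_grid
  labels <- unname(vapply(truths, `[[`, character(1), "label"))

  onset <- 1 - 2^(-t / cfg$onset_half_time)
  single <- per_drug_effect * onset
  bi <- 1 - (1 - single)^length(truths)
  delta_t <- synergy_delta *
    synergy_shape(t, cfg$synergy_window, cfg$onset_half_time, cfg$decay_half_time)
  comb <- clip01(bi + delta_t)

  truth_curves <- dplyr::bind_rows(
    lapply(labels, function(l) tibble::tibble(treatment = l, time_min = t,
                                              true_response = single)),
    tibble::tibble(treatment = "combination", time_min = t, true_response = comb),
    if (cfg$include_time_control) {
      tibble::tibble(treatment = "time_control", time_min = t, true_response = 0)
    }
  )

  ids <- subject_ids(cfg$n_subjects)
  withr::with_seed(seed, {
    out <- lapply(ids, function(s) {
      d <- truth_curves
      d$subject_id <- s
      d$response <- truncate_response(
        d$true_response + rnorm(nrow(d), 0, cfg$noise_sd)
      )
      d$true_response <- NULL
      d
    })
    out <- dplyr::bind_rows(out)[, c("subject_id", "treatment", "time_min",
                                     "response")]
    attr(out, "truth") <- truth_curves
    attr(out, "drug_labels") <- labels
    out
  })
}
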