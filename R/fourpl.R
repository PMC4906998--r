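#' Variable-slope sigmoid (four-parameter logistic) response
#'
#' Evaluates `Y = Bottom + (Top - Bottom) / (1 + 10^((LogEC50 - X) * HillSlope))`,
#' the standard variable-slope concentration-response model, at log10 molar
#' concentration `x`.
#'
#' @param x Numeric vector of log10 concentrations (log10 mol/L).
#' @param bottom,top Lower/upper asymptotes, as fractions of the papaverine
#'   maximal relaxation.
#' @param log_ec50 log10 of the half-maximal concentration (mol/L).
#' @param hill_slope Hill slope (dimensionless, > 0 for a relaxant effect that
#'   increases with concentration).
#' @return Numeric vector of responses (fractions).
#' @export
#' @examples
#' fourpl_response(-8.44, bottom = 0, top = 1, log_ec50 = -8.44, hill_slope = 1)
fourpl_response <- function(x, bottom, top, log_ec50, hill_slope) {
  bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill_slope))
}

#' Normalize raw organ-bath responses to the papaverine maximal relaxation
#'
#' Maps raw tension (g) or luminal area readings onto the fraction-of-maximal
#' relaxation scale: the precontraction plateau maps to 0 and the papaverine
#' (100 uM) reference level to 1, linearly in between and beyond. Works for
#' either measurement direction (tension decreasing or luminal area increasing
#' on relaxation).
#'
#' @param raw Numeric vector of raw responses.
#' @param papaverine_reference Raw response at the papaverine (100 uM) maximal
#'   relaxation. Recycled to the length of `raw`.
#' @param precontraction_plateau Raw response at the precontraction (e.g.
#'   acetylcholine EC70) plateau, before any relaxant is added. Recycled.
#' @return Numeric vector of response fractions (0 = plateau, 1 = papaverine).
#' @export
#' @examples
#' normalize_responses(c(2, 1.25, 0.5), papaverine_reference = 0.5,
#'                     precontraction_plateau = 2)
normalize_responses <- function(raw, papaverine_reference, precontraction_plateau) {
  stopifnot(is.numeric(raw), is.numeric(papaverine_reference),
            is.numeric(precontraction_plateau))
  span <- precontraction_plateau - papaverine_reference
  if (any(span == 0)) {
    stop_airwaysyn(
      "degenerate normalization: papaverine reference equals the precontraction plateau",
      "degenerate_normalization"
    )
  }
  (precontraction_plateau - raw) / span
}

default_4pl_bounds <- function() {
  list(
    lower = c(bottom = -0.05, top = 0.5, log_ec50 = -Inf, hill_slope = 1e-3),
    upper = c(bottom = 0.20, top = 1.1, log_ec50 = Inf, hill_slope = 5)
  )
}

#' Fit the variable-slope sigmoid model to a concentration-response curve
#'
#' Least-squares fit of the four-parameter logistic (4PL) model to normalized
#' responses via bounded Levenberg-Marquardt. Starting values are
#' deterministic (bottom = min response, top = max response, log EC50 = grid
#' point nearest the half-range response, Hill slope = 1), so the fit is
#' reproducible given the data.
#'
#' By default parameters are constrained to physiologically sensible ranges on
#' the normalized scale (bottom in \[-0.05, 0.2\], top in \[0.5, 1.1\], Hill
#' slope in (0, 5\]); use `constrained = FALSE` for an unconstrained fit.
#'
#' @param log10_conc Numeric vector of log10 molar concentrations, or a
#'   data frame with columns `log10_conc` and `response`.
#' @param response Numeric vector of responses (fractions of the papaverine
#'   maximal relaxation); ignored when `log10_conc` is a data frame.
#' @param constrained Apply the default parameter bounds?
#' @param lower,upper Named bound vectors (`bottom`, `top`, `log_ec50`,
#'   `hill_slope`) overriding the defaults.
#' @return An object of class `fourpl_fit`: a list with elements `bottom`,
#'   `top`, `log_ec50`, `hill_slope`, `pec50` (= -log_ec50), `e_max` (fitted
#'   top), `standard_errors`, `rss`, `n_points`, `df_residual`, `converged`
#'   and the fitted data.
#' @export
#' @examples
#' x <- seq(-11, -6, length.out = 8)
#' y <- fourpl_response(x, 0, 1, -8.44, 1)
#' fit <- fit_4pl(x, y)
#' fit$pec50
fit_4pl <- function(log10_conc, response = NULL, constrained = TRUE,
                    lower = NULL, upper = NULL) {
  if (is.data.frame(log10_conc)) {
    df <- log10_conc
    stopifnot(all(c("log10_conc", "response") %in% names(df)))
    x <- df$log10_conc
    y <- df$response
  } else {
    x <- log10_conc
    y <- response
  }
  if (length(x) != length(y) || anyNA(x) || anyNA(y) || !all(is.finite(y))) {
    stop_airwaysyn("concentrations and responses must be finite and of equal length",
                   "invalid_input")
  }
  if (length(unique(x)) < 5) {
    stop_airwaysyn("at least 5 distinct concentrations are required for a 4PL fit",
                   "invalid_input")
  }
  if (diff(range(y)) < 0.02) {
    stop_airwaysyn(
      "no fit: response range is below 2 % of the normalized maximum (flat data)",
      "no_fit"
    )
  }

  bounds <- default_4pl_bounds()
  if (!constrained) {
    bounds$lower[] <- -Inf
    bounds$upper[] <- Inf
    bounds$lower["hill_slope"] <- 1e-6  # relaxant direction; keeps model identifiable
  }
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper

  clamp <- function(v, nm) min(max(v, bounds$lower[nm]), bounds$upper[nm])
  b0 <- clamp(min(y), "bottom")
  t0 <- clamp(max(y), "top")
  half <- (min(y) + max(y)) / 2
  e0 <- x[which.min(abs(y - half))]
  start <- list(bottom = b0, top = t0, log_ec50 = e0, hill_slope = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^((log_ec50 - x) * hill_slope)),
      start = start,
      lower = bounds$lower[c("bottom", "top", "log_ec50", "hill_slope")],
      upper = bounds$upper[c("bottom", "top", "log_ec50", "hill_slope")],
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop_airwaysyn(
        paste0("4PL fit did not converge: ", conditionMessage(e)),
        "convergence"
      )
    }
  )

  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  res <- y - fourpl_response(x, cf["bottom"], cf["top"], cf["log_ec50"], cf["hill_slope"])

  structure(
    list(
      bottom = unname(cf["bottom"]),
      top = unname(cf["top"]),
      log_ec50 = unname(cf["log_ec50"]),
      hill_slope = unname(cf["hill_slope"]),
      pec50 = unname(-cf["log_ec50"]),
      e_max = unname(cf["top"]),
      standard_errors = se,
      rss = sum(res^2),
      n_points = length(y),
      df_residual = length(y) - 4L,
      converged = isTRUE(fit$convInfo$isConv),
      constrained = constrained,
      data = tibble::tibble(log10_conc = x, response = y)
    ),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Four-parameter logistic fit (", x$n_points, " points)\n", sep = "")
  cat(sprintf("  pEC50      %.4f\n", x$pec50))
  cat(sprintf("  E_max (top) %.4f   bottom %.4f   Hill slope %.4f\n",
              x$top, x$bottom, x$hill_slope))
  cat(sprintf("  RSS %.3e   converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' @export
predict.fourpl_fit <- function(object, log10_conc = NULL, ...) {
  x <- log10_conc %||% object$data$log10_conc
  fourpl_response(x, object$bottom, object$top, object$log_ec50, object$hill_slope)
}

#' Effective concentration for a given percent of maximal effect
#'
#' Inverts the fitted 4PL model: `EC_n = EC50 * (f / (1 - f))^(1 / HillSlope)`
#' with `f = (n/100 - bottom) / (top - bottom)`. The round trip
#' `predict(fit, log10(ec_n(fit, n)))` returns `n/100` to numerical precision.
#'
#' @param fit A `fourpl_fit` object (or any list with `bottom`, `top`,
#'   `log_ec50`, `hill_slope`).
#' @param n_percent Numeric vector of target effect levels in percent of
#'   maximal effect (each must lie strictly between `100 * bottom` and
#'   `100 * top`).
#' @return Concentrations in mol/L.
#' @export
#' @examples
#' fit <- list(bottom = 0, top = 1, log_ec50 = -8, hill_slope = 1)
#' ec_n(fit, 50)   # 1e-8
#' ec_n(fit, 70)   # (7/3) * 1e-8
ec_n <- function(fit, n_percent) {
  stopifnot(is.numeric(n_percent))
  f <- (n_percent / 100 - fit$bottom) / (fit$top - fit$bottom)
  if (any(f <= 0 | f >= 1)) {
    stop_airwaysyn(
      sprintf(
        "effect level(s) %s %% outside the fitted response range (%.1f %%, %.1f %%)",
        paste(n_percent[f <= 0 | f >= 1], collapse = ", "),
        100 * fit$bottom, 100 * fit$top
      ),
      "out_of_range"
    )
  }
  10^fit$log_ec50 * (f / (1 - f))^(1 / fit$hill_slope)
}

#' Isoeffective concentration design for a drug combination
#'
#' For each requested effect level, returns the concentration of every drug
#' that alone produces that level (its EC_n), i.e. the isoeffective pairing
#' used to combine drugs in interaction experiments. Levels not attainable by
#' a drug (outside its fitted bottom-top range) are flagged, not dropped.
#'
#' @param fits Named list of 2 or 3 `fourpl_fit` objects (names are drug labels).
#' @param levels Effect levels in percent of maximal effect.
#' @return A tibble with columns `level_pct`, `drug`, `conc_molar` (NA when
#'   the level is unattainable for that drug), `attainable` (per drug) and
#'   `attainable_level` (all drugs attain the level).
#' @export
isoeffective_grid <- function(fits, levels = seq(10, 90, by = 10)) {
  stopifnot(is.list(fits), length(fits) >= 2, length(fits) <= 3)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    stop_airwaysyn("`fits` must be a named list (names are drug labels)",
                   "invalid_input")
  }
  grid <- tidyr::expand_grid(level_pct = levels, drug = names(fits))
  grid$conc_molar <- NA_real_
  grid$attainable <- FALSE
  for (i in seq_len(nrow(grid))) {
    f <- fits[[grid$drug[i]]]
    frac <- (grid$level_pct[i] / 100 - f$bottom) / (f$top - f$bottom)
    if (frac > 0 && frac < 1) {
      grid$conc_molar[i] <- ec_n(f, grid$level_pct[i])
      grid$attainable[i] <- TRUE
    }
  }
  grid <- dplyr::group_by(grid, .data$level_pct)
  grid <- dplyr::mutate(grid, attainable_level = all(.data$attainable))
  grid <- dplyr::ungroup(grid)
  if (!any(grid$attainable_level)) {
    stop_airwaysyn("no requested effect level is attainable by every drug",
                   "empty_intersection")
  }
  grid
}

#' Fit one concentration-response curve per subject replicate
#'
#' @param data Tidy data frame with columns `subject_id`, `log10_conc`,
#'   `response` (e.g. the output of [simulate_crc()]).
#' @param ... Passed to [fit_4pl()].
#' @return Named list of `fourpl_fit` objects, one per subject.
#' @seealso [summarize_crc_fits()]
#' @export
fit_crc_replicates <- function(data, ...) {
  stopifnot(all(c("subject_id", "log10_conc", "response") %in% names(data)))
  subjects <- unique(data$subject_id)
  fits <- lapply(subjects, function(s) {
    d <- data[data$subject_id == s, ]
    fit_4pl(d$log10_conc, d$response, ...)
  })
  names(fits) <- subjects
  fits
}

#' Summarize per-subject 4PL fits as mean and SEM
#'
#' Replicate handling follows the subject-level convention of organ-bath
#' studies: one fit per subject, then mean +/- SEM with n = number of
#' subjects.
#'
#' @param fits List of `fourpl_fit` objects (one per subject).
#' @return A one-row tibble with mean and SEM of `pec50`, `e_max`,
#'   `hill_slope` and the number of replicates `n`.
#' @export
summarize_crc_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  pec50 <- vapply(fits, `[[`, numeric(1), "pec50")
  emax <- vapply(fits, `[[`, numeric(1), "e_max")
  hill <- vapply(fits, `[[`, numeric(1), "hill_slope")
  tibble::tibble(
    n = length(fits),
    pec50_mean = mean(pec50), pec50_sem = sem(pec50),
    e_max_mean = mean(emax), e_max_sem = sem(emax),
    hill_slope_mean = mean(hill), hill_slope_sem = sem(hill)
  )
}
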