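#' Bliss Independence expected effect for two or three agents
#'
#' The Bliss Independence reference model assumes the combined agents act
#' independently; for fractional effects the expected combination effect is
#' `E(x,y) = Ex + Ey - Ex*Ey` for two agents and
#' `E(x,y,z) = Ex + Ey + Ez - Ex*Ey - Ex*Ez - Ey*Ez + ... ` equivalently
#' `1 - (1-Ex)(1-Ey)(1-Ez)` for three. Effects are fractions in \[0, 1\];
#' inputs slightly outside (the normalized-data band \[-0.05, 1.10\]) are
#' clipped to \[0, 1\] and the number of clipped values is recorded in the
#' `"n_clipped"` attribute, since the independence model is undefined outside
#' the unit interval. Values outside the band raise an error.
#'
#' @param e_x,e_y Fractional effects of the single agents (vectors recycle).
#' @param e_z Optional third agent's fractional effect.
#' @return Expected fractional effect(s), with attribute `n_clipped`.
#' @export
#' @examples
#' bliss_expected(0.2, 0.2)        # 0.36
#' bliss_expected(0.3, 0.3, 0.3)   # 0.657
bliss_expected <- function(e_x, e_y, e_z = NULL) {
  vals <- if (is.null(e_z)) cbind(e_x, e_y) else cbind(e_x, e_y, e_z)
  if (anyNA(vals) || !all(is.finite(vals))) {
    stop_airwaysyn("effects must be finite", "invalid_input")
  }
  if (any(vals < RESPONSE_TRUNC[1] | vals > RESPONSE_TRUNC[2])) {
    stop_airwaysyn(
      sprintf("fractional effects must lie within [%.2f, %.2f] before clipping",
              RESPONSE_TRUNC[1], RESPONSE_TRUNC[2]),
      "invalid_input"
    )
  }
  n_clipped <- sum(vals < 0 | vals > 1)
  v <- clip01(vals)
  out <- if (is.null(e_z)) {
    v[, 1] + v[, 2] - v[, 1] * v[, 2]
  } else {
    v[, 1] + v[, 2] + v[, 3] -
      v[, 1] * v[, 2] - v[, 1] * v[, 3] - v[, 2] * v[, 3] +
      v[, 1] * v[, 2] * v[, 3]
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

as_effect_matrix <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("drug", "subject_id", "effect") %in% names(effects)))
    wide <- tidyr::pivot_wider(effects[, c("subject_id", "drug", "effect")],
                               names_from = "drug", values_from = "effect")
    if (anyNA(wide)) {
      stop_airwaysyn("pairing error: subjects are not matched across drugs",
                     "pairing")
    }
    m <- as.matrix(wide[, setdiff(names(wide), "subject_id")])
    rownames(m) <- wide$subject_id
    return(m)
  }
  stopifnot(is.list(effects))
  len <- lengths(effects)
  if (length(unique(len)) != 1) {
    stop_airwaysyn("pairing error: drugs have unequal numbers of replicates",
                   "pairing")
  }
  do.call(cbind, effects)
}

#' Bliss expected effect with replicate uncertainty
#'
#' Computes the expected combination effect and its SEM from single-agent
#' replicate measurements, either by computing the Bliss expectation within
#' each subject and summarizing across subjects (`"by_subject"`, the default:
#' it matches the subject-level mean +/- SEM convention of n = 3 organ-bath
#' studies and respects within-subject correlation), or by first-order
#' (delta-method) variance propagation through the Bliss formula from the
#' per-drug means and SEMs (`"delta_method"`, for unpaired designs).
#'
#' @param effects Single-agent effects: either a named list of numeric vectors
#'   (one per drug, replicates in matching subject order) or a data frame with
#'   columns `drug`, `subject_id`, `effect`. Two or three drugs.
#' @param pairing `"by_subject"` (default) or `"delta_method"`.
#' @return An object of class `bliss_expected_est`: list with `mean`, `sem`,
#'   `per_subject` (NULL for the delta method), `n`, `method`, `n_clipped`.
#' @export
#' @examples
#' expected_with_uncertainty(list(gly = c(0.1, 0.2, 0.3), ind = c(0.1, 0.2, 0.3)))
expected_with_uncertainty <- function(effects,
                                      pairing = c("by_subject", "delta_method")) {
  pairing <- match.arg(pairing)
  m <- as_effect_matrix(effects)
  if (ncol(m) < 2 || ncol(m) > 3) {
    stop_airwaysyn("2 or 3 single-agent effect sets are required", "invalid_input")
  }
  if (nrow(m) < 2) {
    stop_airwaysyn("at least 2 replicates per drug are required", "insufficient_data")
  }

  if (pairing == "by_subject") {
    per <- bliss_expected(m[, 1], m[, 2], if (ncol(m) == 3) m[, 3])
    n_clipped <- attr(per, "n_clipped")
    per <- as.numeric(per)
    out <- list(mean = mean(per), sem = sem(per), per_subject = per,
                n = nrow(m), method = "by_subject", n_clipped = n_clipped)
  } else {
    mu <- colMeans(clip01(m))
    s <- apply(m, 2, sem)
    e <- bliss_expected(mu[1], mu[2], if (ncol(m) == 3) mu[3])
    n_clipped <- sum(m < 0 | m > 1)
    # dE/dE_i = prod_{j != i} (1 - E_j); first-order variance propagation
    grad <- vapply(seq_along(mu), function(i) prod(1 - mu[-i]), numeric(1))
    out <- list(mean = as.numeric(e), sem = sqrt(sum(grad^2 * s^2)),
                per_subject = NULL, n = nrow(m), method = "delta_method",
                n_clipped = n_clipped)
  }
  structure(out, class = "bliss_expected_est")
}

#' @export
print.bliss_expected_est <- function(x, ...) {
  cat(sprintf("Bliss expected effect: %.4f +/- %.4f (SEM, n = %d, %s)\n",
              x$mean, x$sem, x$n, x$method))
  invisible(x)
}

#' Classify a drug interaction against the Bliss expectation
#'
#' Compares observed combination replicates with the Bliss-expected effect via
#' a two-sided t-test and classifies the interaction: synergistic if
#' the observed effect exceeds the expectation (delta > 0) at p < alpha,
#' antagonistic if it falls short at p < alpha, additive otherwise. The delta
#' is reported in percentage points. The pooled-variance (Student) test is the
#' default because it is exactly calibrated for the small subject-replicate
#' designs this package targets (n = 3); the Welch variant is available for
#' unequal variances.
#'
#' @param observed Numeric vector of observed combination effects (fractions),
#'   at least 2 replicates.
#' @param expected A `bliss_expected_est` object (see
#'   [expected_with_uncertainty()]), a numeric vector of per-replicate expected
#'   effects, or a single expected value (tested one-sample).
#' @param alpha Significance level (default 0.05).
#' @param test `"student"` (pooled variance, default) or `"welch"`.
#' @param condition Optional label (effect level or time point) carried into
#'   the output.
#' @return A one-row tibble of class `bliss_assessment` with columns
#'   `condition`, `observed_mean`, `observed_sem`, `expected_mean`,
#'   `expected_sem`, `delta_pp` (percentage points), `p_value`,
#'   `classification`, `n_clipped`.
#' @export
assess_interaction <- function(observed, expected, alpha = 0.05,
                               test = c("student", "welch"),
                               condition = NA) {
  test <- match.arg(test)
  if (!is.numeric(observed) || length(observed) < 2) {
    stop_airwaysyn("insufficient data: at least 2 observed replicates are required",
                   "insufficient_data")
  }
  obs <- clip01(observed)
  n_clipped <- sum(observed < 0 | observed > 1)

  if (inherits(expected, "bliss_expected_est")) {
    exp_mean <- expected$mean
    exp_sem <- expected$sem
    exp_reps <- expected$per_subject
    n_clipped <- n_clipped + expected$n_clipped
  } else if (is.numeric(expected) && length(expected) > 1) {
    exp_reps <- as.numeric(clip01(expected))
    exp_mean <- mean(exp_reps)
    exp_sem <- sem(exp_reps)
  } else if (is_scalar_number(expected)) {
    exp_reps <- NULL
    exp_mean <- expected
    exp_sem <- 0
  } else {
    stop_airwaysyn("`expected` must be a bliss_expected_est object or numeric",
                   "invalid_input")
  }

  p <- if (!is.null(exp_reps)) two_sample_p(obs, exp_reps, test = test) else
    one_sample_p(obs, exp_mean)
  delta_pp <- 100 * (mean(obs) - exp_mean)
  classification <- if (p < alpha && delta_pp > 0) {
    "synergistic"
  } else if (p < alpha && delta_pp < 0) {
    "antagonistic"
  } else {
    "additive"
  }

  out <- tibble::tibble(
    condition = condition,
    observed_mean = mean(obs),
    observed_sem = sem(obs),
    expected_mean = exp_mean,
    expected_sem = exp_sem,
    delta_pp = delta_pp,
    p_value = p,
    classification = classification,
    n_clipped = n_clipped
  )
  class(out) <- c("bliss_assessment", class(out))
  out
}

#' Pearson correlation with coefficient of determination
#'
#' Thin wrapper around [stats::cor.test()] for worked examples such as
#' relating combination-induced cAMP increases to relaxant responses;
#' `r_squared` is exactly the square of the Pearson r.
#'
#' @param x,y Paired numeric vectors (at least 3 finite pairs, each with
#'   nonzero variance).
#' @return List with `pearson_r`, `r_squared`, `p_value`, `n`.
#' @export
#' @examples
#' correlate(1:5, c(1.1, 1.9, 3.2, 3.8, 5.1))
correlate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    stop_airwaysyn("at least 3 finite paired values are required", "insufficient_data")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_airwaysyn("undefined correlation: zero variance in x or y",
                   "undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(pearson_r = r, r_squared = r^2, p_value = ct$p.value, n = length(x))
}
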