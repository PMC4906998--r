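#' Normalize EFS contraction amplitudes to the pre-treatment control
#'
#' Relaxation is expressed as a percentage of the contraction evoked by the
#' control EFS trains preceding the treatment:
#' `relaxation = 100 * (1 - amplitude / reference)`.
#'
#' @param amplitude Contraction amplitudes after treatment.
#' @param pre_treatment_reference Mean pre-treatment control EFS amplitude
#'   (> 0). Recycled.
#' @return Relaxation in percent.
#' @export
#' @examples
#' normalize_efs(c(1, 0.8, 0), 1)   # 0, 20, 100 %
normalize_efs <- function(amplitude, pre_treatment_reference) {
  stopifnot(is.numeric(amplitude), is.numeric(pre_treatment_reference))
  if (any(pre_treatment_reference <= 0)) {
    stop_airwaysyn("pre-treatment EFS reference must be positive", "invalid_input")
  }
  100 * (1 - amplitude / pre_treatment_reference)
}

aicc <- function(rss, n, k) {
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a polynomial trend to an EFS relaxation trace
#'
#' Least-squares polynomial fit with the degree (1 to `max_degree`) selected
#' by the small-sample-corrected Akaike criterion (AICc). When several degrees
#' fit the data exactly (residual sum of squares at numerical zero), the
#' smallest such degree is chosen, so e.g. exactly linear data recover degree
#' 1. The degree cap (default 4) avoids Runge-type oscillation on long traces.
#'
#' @param time Time points (min) or a data frame with columns `time_min` and
#'   `response`.
#' @param response Relaxation values (any consistent scale; the trace mean or
#'   a single subject's trace).
#' @param max_degree Maximum polynomial degree considered.
#' @param window Optional `[lo, hi]` time window (min) restricting the fit,
#'   e.g. the treatment phase when estimating the onset t1/2.
#' @return Object of class `efs_trend`: list with `degree`, `coefficients`
#'   (intercept first), `rss`, `n`, `time_range`.
#' @export
fit_trend <- function(time, response = NULL, max_degree = 4, window = NULL) {
  if (is.data.frame(time)) {
    stopifnot(all(c("time_min", "response") %in% names(time)))
    response <- time$response
    time <- time$time_min
  }
  stopifnot(length(time) == length(response))
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]
    response <- response[keep]
  }
  n <- length(time)
  if (n < max_degree + 2) {
    stop_airwaysyn(
      sprintf("underdetermined trend fit: %d points for max degree %d (need >= %d)",
              n, max_degree, max_degree + 2),
      "invalid_input"
    )
  }

  scale2 <- max(mean(response^2), 1e-8)
  fits <- lapply(seq_len(max_degree), function(d) {
    m <- lm(response ~ poly(time, degree = d, raw = TRUE))
    rss <- sum(stats::residuals(m)^2)
    list(degree = d, model = m, rss = rss,
         aicc = aicc(max(rss, 1e-300), n, d + 2),
         exact = rss <= 1e-12 * n * scale2)
  })
  exact <- vapply(fits, `[[`, logical(1), "exact")
  best <- if (any(exact)) {
    fits[[which(exact)[1]]]
  } else {
    fits[[which.min(vapply(fits, `[[`, numeric(1), "aicc"))]]
  }

  structure(
    list(degree = best$degree,
         coefficients = unname(coef(best$model)),
         rss = best$rss, n = n, time_range = range(time)),
    class = "efs_trend"
  )
}

#' @export
predict.efs_trend <- function(object, time, ...) {
  drop(outer(time, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.efs_trend <- function(x, ...) {
  cat(sprintf("Polynomial trend, degree %d (n = %d, RSS = %.3e)\n",
              x$degree, x$n, x$rss))
  invisible(x)
}

trend_fun <- function(trend) {
  if (inherits(trend, "efs_trend")) {
    function(t) predict(trend, t)
  } else if (is.function(trend)) {
    trend
  } else {
    stop_airwaysyn("`trend` must be an efs_trend object or a function",
                   "invalid_input")
  }
}

#' Time-course metrics: maximal relaxation, onset t1/2 and plateau
#'
#' From a fitted (or closed-form) relaxation trend: `e_max` is the maximum of
#' the trend over the trace; `t_half` is the earliest time at which the trend
#' reaches half of `e_max` (root-finding on the trend; flagged undefined when
#' the trend starts above half-maximum or never crosses it before its peak);
#' `e_max_plateau` is the mean of the trend over the final `plateau_window_h`
#' hours, after trimming any terminal decline segment (points falling more
#' than 5 % of `e_max` below the running within-window maximum).
#'
#' Because a low-degree polynomial over 12 h cannot resolve a fast
#' (~20 min) onset, pass a locally fitted trend (e.g.
#' `fit_trend(trace, window = c(0, 60))`) as `onset_trend` when an accurate
#' t1/2 is required.
#'
#' @param trend An `efs_trend` or a function of time (min).
#' @param time_range Time range (min) over which to evaluate; defaults to the
#'   trend's fitted range.
#' @param onset_trend Optional trend used only for the t1/2 root-finding
#'   (defaults to `trend`).
#' @param plateau_window_h Width (h) of the terminal plateau window.
#' @param step Evaluation step (min) for the fine grid.
#' @return Object of class `tc_metrics`: list with `e_max_relaxation`,
#'   `t_half_min`, `t_half_defined`, `e_max_plateau`, `t_at_max`.
#' @export
#' @examples
#' compute_metrics(function(t) 40 * (1 - 2^(-t / 18.3)), time_range = c(0, 720))
compute_metrics <- function(trend, time_range = NULL, onset_trend = NULL,
                            plateau_window_h = 3, step = 0.25) {
  f <- trend_fun(trend)
  time_range <- time_range %||%
    (if (inherits(trend, "efs_trend")) trend$time_range else
       stop_airwaysyn("`time_range` is required for a function trend",
                      "invalid_input"))
  tt <- seq(time_range[1], time_range[2], by = step)
  vals <- f(tt)
  e_max <- max(vals)
  t_at_max <- tt[which.max(vals)]

  fo <- trend_fun(onset_trend %||% trend)
  half <- e_max / 2
  pre <- tt[tt <= t_at_max]
  g <- fo(pre) - half
  t_half <- NA_real_
  defined <- FALSE
  if (length(pre) >= 2) {
    if (g[1] >= 0) {
      t_half <- pre[1]
      defined <- TRUE
    } else {
      cross <- which(g[-1] >= 0 & g[-length(g)] < 0)
      if (length(cross) > 0) {
        i <- cross[1]
        t_half <- uniroot(function(t) fo(t) - half,
                          lower = pre[i], upper = pre[i + 1],
                          tol = 1e-8)$root
        defined <- TRUE
      }
    }
  }

  w0 <- max(time_range[1], time_range[2] - 60 * plateau_window_h)
  in_w <- tt >= w0
  wv <- vals[in_w]
  run_max <- cummax(wv)
  keep <- wv >= run_max - 0.05 * e_max
  last_keep <- max(which(keep))
  plateau <- mean(wv[seq_len(last_keep)])

  structure(
    list(e_max_relaxation = e_max, t_at_max = t_at_max,
         t_half_min = t_half, t_half_defined = defined,
         e_max_plateau = plateau),
    class = "tc_metrics"
  )
}

#' @export
print.tc_metrics <- function(x, ...) {
  cat(sprintf("E_max %.2f at t = %.1f min; t1/2 = %s min; plateau %.2f\n",
              x$e_max_relaxation, x$t_at_max,
              if (x$t_half_defined) sprintf("%.2f", x$t_half_min) else "undefined",
              x$e_max_plateau))
  invisible(x)
}

#' Observed-minus-expected synergism curve over an EFS time course
#'
#' At every time point, computes the per-subject Bliss expectation from the
#' single-agent traces (inputs clipped to \[0, 1\]), the per-subject observed
#' combination effect, their difference (delta, in percentage points) with
#' SEM, and a two-sided t-test per time point (pooled variance by default,
#' see [assess_interaction()]). A treatment-by-time
#' two-way ANOVA comparing observed and expected curves over the whole trace
#' is attached as the `"anova"` attribute.
#'
#' @param efs_data Tidy trace table with columns `subject_id`, `treatment`,
#'   `time_min`, `response` (fractions), e.g. from [simulate_efs_timecourse()]
#'   or from [read_bath_table()] after [normalize_efs()] (divide by 100).
#' @param drug_labels Labels of the single-agent treatments; default: every
#'   treatment except the combination and `"time_control"`.
#' @param combination_label Label of the combination trace.
#' @param alpha Per-time-point significance level.
#' @param test `"student"` (default) or `"welch"` per-time-point t-test.
#' @param interpolate Allow linear interpolation of single-agent traces onto
#'   the combination time grid when grids differ (recorded in the
#'   `"interpolated"` attribute)?
#' @return Tibble of class `synergism_curve` with columns `time_min`,
#'   `observed_mean`, `expected_mean`, `delta_pp`, `delta_sem_pp`, `p_value`,
#'   `significant`.
#' @export
synergism_curve <- function(efs_data, drug_labels = NULL,
                            combination_label = "combination",
                            alpha = 0.05, test = c("student", "welch"),
                            interpolate = FALSE) {
  test <- match.arg(test)
  stopifnot(all(c("subject_id", "treatment", "time_min", "response") %in%
                  names(efs_data)))
  treatments <- unique(efs_data$treatment)
  if (!combination_label %in% treatments) {
    stop_airwaysyn("combination trace not found", "invalid_input")
  }
  drug_labels <- drug_labels %||%
    setdiff(treatments, c(combination_label, "time_control"))
  if (length(drug_labels) < 2 || length(drug_labels) > 3) {
    stop_airwaysyn("2 or 3 single-agent traces are required", "invalid_input")
  }

  comb <- efs_data[efs_data$treatment == combination_label, ]
  grid <- sort(unique(comb$time_min))
  subjects <- sort(unique(comb$subject_id))
  interpolated <- FALSE

  get_trace <- function(treatment, subject) {
    d <- efs_data[efs_data$treatment == treatment &
                    efs_data$subject_id == subject, ]
    d <- d[order(d$time_min), ]
    if (identical(d$time_min, grid)) return(d$response)
    common <- intersect(d$time_min, grid)
    if (length(common) == 0) {
      stop_airwaysyn("disjoint time grids between treatments", "invalid_input")
    }
    if (!interpolate) {
      stop_airwaysyn(
        "time grids differ between treatments; set interpolate = TRUE to align them",
        "invalid_input"
      )
    }
    interpolated <<- TRUE
    stats::approx(d$time_min, d$response, xout = grid, rule = 2)$y
  }

  obs <- vapply(subjects, function(s) get_trace(combination_label, s),
                numeric(length(grid)))
  single <- lapply(drug_labels, function(l) {
    clip01(vapply(subjects, function(s) get_trace(l, s), numeric(length(grid))))
  })

  expd <- matrix(
    as.numeric(bliss_expected(as.numeric(single[[1]]), as.numeric(single[[2]]),
                              if (length(single) == 3) as.numeric(single[[3]]))),
    nrow = length(grid)
  )
  obs_c <- clip01(obs)

  delta <- obs_c - expd   # subjects in columns, time in rows
  p <- vapply(seq_along(grid),
              function(i) two_sample_p(obs_c[i, ], expd[i, ], test = test),
              numeric(1))

  out <- tibble::tibble(
    time_min = grid,
    observed_mean = rowMeans(obs_c),
    expected_mean = rowMeans(expd),
    delta_pp = 100 * rowMeans(delta),
    delta_sem_pp = 100 * apply(delta, 1, sem),
    p_value = p,
    significant = p < alpha & rowMeans(delta) > 0
  )

  long <- tibble::tibble(
    value = c(as.numeric(obs_c), as.numeric(expd)),
    group = rep(c("observed", "expected"),
                each = length(grid) * length(subjects)),
    time_f = factor(rep(rep(grid, times = length(subjects)), 2))
  )
  an <- summary(aov(value ~ group * time_f, data = long))[[1]]
  attr(out, "anova") <- an
  attr(out, "anova_p_group") <-
    an[trimws(rownames(an)) == "group", "Pr(>F)"]
  attr(out, "alpha") <- alpha
  attr(out, "interpolated") <- interpolated
  class(out) <- c("synergism_curve", class(out))
  out
}

parse_intervals <- function(intervals) {
  if (is.numeric(intervals) && is.null(dim(intervals))) {
    intervals <- list(intervals)
  }
  lapply(intervals, function(iv) {
    stopifnot(length(iv) == 2, iv[1] < iv[2])
    iv
  })
}

#' Interval AUC of the synergism curve
#'
#' Trapezoidal area under the observed-minus-expected delta curve (percentage
#' points) over time intervals in hours, yielding %*h, the standard summary
#' of the extent of synergistic interaction over time. Interval endpoints not
#' on the sampling grid are linearly interpolated; AUC is exactly additive
#' over adjacent intervals.
#'
#' @param delta_curve A [synergism_curve()] tibble (or any data frame with
#'   `time_min` and `delta_pp`).
#' @param intervals List of `c(start_h, end_h)` interval bounds in hours.
#' @return Tibble with `interval` label, `start_h`, `end_h`, `auc_pct_h`.
#' @export
#' @examples
#' dc <- data.frame(time_min = seq(0, 60, 5), delta_pp = 20)
#' auc_intervals(dc, intervals = list(c(0, 1)))   # 20 %*h
auc_intervals <- function(delta_curve,
                          intervals = list(c(0, 1), c(0, 3), c(0, 6),
                                           c(0, 9), c(0, 12))) {
  stopifnot(all(c("time_min", "delta_pp") %in% names(delta_curve)))
  intervals <- parse_intervals(intervals)
  t_h <- delta_curve$time_min / 60
  y <- delta_curve$delta_pp
  rng <- range(t_h)
  rows <- lapply(intervals, function(iv) {
    if (iv[1] < rng[1] - 1e-9 || iv[2] > rng[2] + 1e-9) {
      stop_airwaysyn(
        sprintf("interval [%g, %g] h lies beyond the data range [%g, %g] h",
                iv[1], iv[2], rng[1], rng[2]),
        "invalid_input"
      )
    }
    inside <- t_h > iv[1] & t_h < iv[2]
    tt <- c(iv[1], t_h[inside], iv[2])
    yy <- c(stats::approx(t_h, y, xout = iv[1])$y, y[inside],
            stats::approx(t_h, y, xout = iv[2])$y)
    tibble::tibble(interval = sprintf("%g-%g h", iv[1], iv[2]),
                   start_h = iv[1], end_h = iv[2],
                   auc_pct_h = pracma::trapz(tt, yy))
  })
  dplyr::bind_rows(rows)
}

#' Duration of synergism
#'
#' Length of the synergistic period, based on the longest contiguous run of
#' significantly synergistic time points (delta > 0 and p < alpha). When that
#' run begins within `onset_grace` minutes of treatment - the usual case,
#' since the synergy onset takes a few sampling steps to reach significance -
#' the duration is the elapsed time from treatment (t = 0) to the last point
#' of the run ("synergism for X h after treatment"); otherwise the run's own
#' span is returned. A single non-significant point flanked by significant
#' neighbours does not break a run (`gap_tolerance = 1`, switchable), since
#' 5-min sampling with n = 3 makes single-point dropouts likely. Returns 0
#' when no point is significant.
#'
#' @param delta_curve A [synergism_curve()] tibble (needs `time_min`,
#'   `delta_pp`, `p_value`).
#' @param alpha Significance level.
#' @param gap_tolerance Number of consecutive non-significant points tolerated
#'   inside a run (0 disables gap bridging).
#' @param onset_grace Time (min) within which the run must begin to be
#'   counted from treatment.
#' @return Duration in hours (grid resolution).
#' @export
duration_of_synergism <- function(delta_curve, alpha = 0.05,
                                  gap_tolerance = 1, onset_grace = 30) {
  stopifnot(all(c("time_min", "delta_pp", "p_value") %in% names(delta_curve)))
  d <- delta_curve[order(delta_curve$time_min), ]
  sig <- d$delta_pp > 0 & d$p_value < alpha
  if (!any(sig)) return(0)

  if (gap_tolerance > 0 && length(sig) > 2) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (!r$values[j] && r$lengths[j] <= gap_tolerance &&
          j > 1 && j < length(r$values)) {
        sig[starts[j]:ends[j]] <- TRUE
      }
    }
  }

  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_idx <- which(r$values)
  run_start_t <- d$time_min[starts[run_idx]]
  run_end_t <- d$time_min[ends[run_idx]]

  longest <- which.max(run_end_t - run_start_t)
  if (run_start_t[longest] <= onset_grace) {
    run_end_t[longest] / 60
  } else {
    (run_end_t[longest] - run_start_t[longest]) / 60
  }
}

#' Head-to-head comparison of two combinations (summary arithmetic)
#'
#' Worked-example comparison of two drug combinations from their summary
#' synergism metrics (as printed in a study report): per-interval AUC
#' differences, the mean difference over selected intervals, and differences
#' in onset t1/2, E_max at plateau, and duration of synergism. Differences
#' are `x - y`.
#'
#' @param x,y Named lists with elements `auc` (named numeric, %*h),
#'   `onset_t_half_min`, `e_max_plateau_pct`, `duration_h`.
#' @param auc_mean_intervals Names of the AUC intervals averaged for the
#'   headline AUC difference (default `c("0-3 h", "0-6 h")`).
#' @return List with `auc_differences` (tibble), `auc_mean_difference`,
#'   `onset_difference_min`, `e_max_plateau_difference_pct`,
#'   `duration_difference_h`.
#' @export
compare_synergism_summary <- function(x, y,
                                      auc_mean_intervals = c("0-3 h", "0-6 h")) {
  stopifnot(identical(sort(names(x$auc)), sort(names(y$auc))))
  ivs <- names(x$auc)
  auc_diff <- tibble::tibble(
    interval = ivs,
    auc_x = as.numeric(x$auc[ivs]),
    auc_y = as.numeric(y$auc[ivs]),
    difference = as.numeric(x$auc[ivs]) - as.numeric(y$auc[ivs])
  )
  missing_iv <- setdiff(auc_mean_intervals, ivs)
  if (length(missing_iv) > 0) {
    stop_airwaysyn(paste0("mismatched intervals: ", paste(missing_iv, collapse = ", ")),
                   "invalid_input")
  }
  list(
    auc_differences = auc_diff,
    auc_mean_difference =
      mean(auc_diff$difference[auc_diff$interval %in% auc_mean_intervals]),
    onset_difference_min = x$onset_t_half_min - y$onset_t_half_min,
    e_max_plateau_difference_pct = x$e_max_plateau_pct - y$e_max_plateau_pct,
    duration_difference_h = x$duration_h - y$duration_h
  )
}

#' Head-to-head comparison of two combinations with replicate tests
#'
#' Compares per-subject synergism metrics of two combinations: t-tests
#' for scalar metrics, and a combination-by-interval two-way ANOVA for the
#' AUC metrics (metric names starting with `"auc"`), the design used for
#' interval-resolved synergism comparisons.
#'
#' @param metrics_x,metrics_y Tidy tibbles with columns `subject_id`,
#'   `metric`, `value`; metric sets must match.
#' @param labels Length-2 character vector naming the combinations.
#' @return Tibble with `metric`, per-combination means, `difference`
#'   (x - y) and `p_value`; the AUC ANOVA table is in the `"anova_auc"`
#'   attribute.
#' @export
compare_combinations <- function(metrics_x, metrics_y,
                                 labels = c("x", "y")) {
  for (m in list(metrics_x, metrics_y)) {
    stopifnot(all(c("subject_id", "metric", "value") %in% names(m)))
  }
  mx <- sort(unique(metrics_x$metric))
  my <- sort(unique(metrics_y$metric))
  if (!identical(mx, my)) {
    stop_airwaysyn("mismatched metrics/intervals between combinations",
                   "invalid_input")
  }
  rows <- lapply(mx, function(m) {
    vx <- metrics_x$value[metrics_x$metric == m]
    vy <- metrics_y$value[metrics_y$metric == m]
    tibble::tibble(metric = m, mean_x = mean(vx), mean_y = mean(vy),
                   difference = mean(vx) - mean(vy),
                   p_value = two_sample_p(vx, vy))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[names(out) == "mean_x"] <- paste0("mean_", labels[1])
  names(out)[names(out) == "mean_y"] <- paste0("mean_", labels[2])

  auc_metrics <- grep("^auc", mx, value = TRUE)
  if (length(auc_metrics) >= 2) {
    long <- dplyr::bind_rows(
      dplyr::mutate(metrics_x[metrics_x$metric %in% auc_metrics, ],
                    combination = labels[1]),
      dplyr::mutate(metrics_y[metrics_y$metric %in% auc_metrics, ],
                    combination = labels[2])
    )
    an <- summary(aov(value ~ combination * metric, data = long))[[1]]
    attr(out, "anova_auc") <- an
    attr(out, "anova_auc_p_combination") <-
      an[trimws(rownames(an)) == "combination", "Pr(>F)"]
  }
  out
}
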