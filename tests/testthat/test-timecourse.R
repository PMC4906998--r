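test_that("EFS normalization maps amplitudes to percent relaxation", {
  expect_equal(normalize_efs(1, 1), 0)
  expect_equal(normalize_efs(0, 1), 100)
  expect_equal(normalize_efs(0.8, 1), 20)
  # affine invariance: rescaling amplitudes and reference together changes nothing
  amp <- c(1, 0.9, 0.5, 0.2)
  expect_equal(normalize_efs(amp * 3.7, 3.7), normalize_efs(amp, 1))
  expect_error(normalize_efs(1, 0), class = "airwaysyn_invalid_input")
})

test_that("polynomial trend selection recovers exact low-degree structure", {
  t <- seq(0, 720, by = 5)
  lin <- fit_trend(t, 3 + 0.05 * t)
  expect_equal(lin$degree, 1)
  expect_equal(lin$coefficients, c(3, 0.05), tolerance = 1e-9)

  quad <- fit_trend(t, 2 + 0.5 * t - 0.01 * t^2)
  expect_equal(quad$degree, 2)
  expect_lt(quad$rss, 1e-9)
  expect_equal(predict(quad, c(0, 100)), c(2, 2 + 50 - 100), tolerance = 1e-6)

  expect_error(fit_trend(1:4, 1:4, max_degree = 4), class = "airwaysyn_invalid_input")
})

test_that("time-course metrics match closed forms", {
  # saturating exponential with half-time 18.3 min
  m <- compute_metrics(function(t) 40 * (1 - 2^(-t / 18.3)),
                       time_range = c(0, 720))
  expect_true(m$t_half_defined)
  expect_equal(m$t_half_min, 18.3, tolerance = 1e-3)
  expect_equal(m$e_max_relaxation, 40, tolerance = 1e-3)
  expect_equal(m$e_max_plateau, 40, tolerance = 1e-3)

  # monotone increasing trend peaks at the end of the trace
  mi <- compute_metrics(function(t) t / 10, time_range = c(0, 720))
  expect_equal(mi$t_at_max, 720)
  expect_equal(mi$e_max_relaxation, 72)
  expect_equal(mi$t_half_min, 360, tolerance = 1e-6)

  # trend starting above half-maximum: earliest crossing is the trace start
  ms <- compute_metrics(function(t) 30 + t / 100, time_range = c(0, 720))
  expect_equal(ms$t_half_min, 0)
})

test_that("onset t1/2 from a treatment-window trend recovers the generator truth", {
  # ground-truth earliest half-maximum crossing of the noiseless combination
  tt <- seq(0, 720, by = 0.05)
  onset <- 1 - 2^(-tt / 18.3)
  comb <- pmin(1 - (1 - 0.2 * onset)^2 + 0.3 * ifelse(tt <= 540, onset, 0), 1)
  t_half_truth <- tt[min(which(comb >= max(comb) / 2))]

  ths <- sapply(1:10, function(s) {
    efs <- simulate_efs_timecourse(ref_truths, 0.2, quiet_cfg(seed = 7000 + s))
    cm <- dplyr::summarise(
      dplyr::group_by(efs[efs$treatment == "combination", ], time_min),
      response = mean(response), .groups = "drop"
    )
    compute_metrics(fit_trend(cm$time_min, cm$response),
                    onset_trend = fit_trend(cm$time_min, cm$response,
                                            window = c(0, 60)))$t_half_min
  })
  expect_lt(abs(mean(ths) - t_half_truth), 5)  # within one 5-min grid step
})

test_that("a null combination plateaus at the Bliss level in the fitted trend", {
  efs <- simulate_efs_timecourse(ref_truths, 0.2,
                                 quiet_cfg(seed = 31, synergy_delta = 0))
  cm <- dplyr::summarise(
    dplyr::group_by(efs[efs$treatment == "combination", ], time_min),
    response = mean(response), .groups = "drop"
  )
  m <- compute_metrics(fit_trend(cm$time_min, cm$response))
  # truth 0.36; SEM scale 0.05/sqrt(3) ~ 0.029
  expect_lt(abs(m$e_max_plateau - 0.36), 3 * 0.05 / sqrt(3))
})

test_that("the synergism curve is zero when observed equals expected", {
  t <- seq(0, 60, 5)
  base <- tidyr::expand_grid(subject_id = c("s1", "s2", "s3"), time_min = t)
  mk <- function(tr, resp) dplyr::mutate(base, treatment = tr, response = resp)
  eff <- rep(0.2, nrow(base))
  efs <- dplyr::bind_rows(
    mk("a", eff), mk("b", eff),
    mk("combination", rep(as.numeric(bliss_expected(0.2, 0.2)), nrow(base)))
  )
  sc <- synergism_curve(efs)
  expect_true(all(sc$delta_pp == 0))
  expect_true(all(sc$p_value == 1))
  expect_false(any(sc$significant))
})

test_that("the synergism curve recovers an injected window of synergy", {
  efs <- simulate_efs_timecourse(ref_truths, 0.2, quiet_cfg(seed = 77))
  sc <- synergism_curve(efs)
  inside <- sc$time_min >= 120 & sc$time_min <= 500
  outside <- sc$time_min >= 600
  expect_lt(abs(mean(sc$delta_pp[inside]) - 30), 5)
  expect_lt(abs(mean(sc$delta_pp[outside])), 5)
  expect_lt(attr(sc, "anova_p_group"), 1e-6)
  expect_error(synergism_curve(efs[efs$treatment != "combination", ]),
               class = "airwaysyn_invalid_input")
})

test_that("interval AUC matches closed-form areas and is additive", {
  # constant 20 % over the first hour
  dc <- delta_curve_tbl(seq(0, 60, 5), 20)
  expect_equal(auc_intervals(dc, intervals = list(c(0, 1)))$auc_pct_h, 20)

  # triangle: 0 at 0 h, 30 % at 6 h, 0 at 12 h -> area 180 %*h
  t <- seq(0, 720, 5)
  tri <- delta_curve_tbl(t, 30 * (1 - abs(t / 60 - 6) / 6))
  expect_equal(auc_intervals(tri, intervals = list(c(0, 12)))$auc_pct_h, 180)

  # additivity over adjacent intervals on random curves
  withr::with_seed(4, {
    for (i in 1:20) {
      rc <- delta_curve_tbl(t, rnorm(length(t), 10, 15))
      a <- auc_intervals(rc, intervals = list(c(0, 6), c(0, 3), c(3, 6)))
      expect_equal(a$auc_pct_h[1], a$auc_pct_h[2] + a$auc_pct_h[3],
                   tolerance = 1e-9)
    }
  })
  expect_error(auc_intervals(dc, intervals = list(c(0, 2))),
               class = "airwaysyn_invalid_input")
})

test_that("duration of synergism counts the significant run at grid resolution", {
  t <- seq(0, 720, 5)
  expect_equal(duration_of_synergism(delta_curve_tbl(t, 20, p_value = 0.001)), 12)
  expect_equal(duration_of_synergism(delta_curve_tbl(t, 20, p_value = 0.5)), 0)
  # negative delta is never synergistic, whatever the p-value
  expect_equal(duration_of_synergism(delta_curve_tbl(t, -20, p_value = 0.001)), 0)

  # single-gap tolerance bridges an isolated dropout
  p <- rep(0.001, length(t))
  p[t == 300] <- 0.4
  expect_equal(duration_of_synergism(delta_curve_tbl(t, 20, p)), 12)
  # without bridging the longest run (305-720 min) does not start at treatment,
  # so its own span is reported
  expect_equal(duration_of_synergism(delta_curve_tbl(t, 20, p), gap_tolerance = 0),
               (720 - 305) / 60)
})

test_that("the duration estimator under null synergy is almost always zero", {
  durs <- sapply(1:120, function(s) {
    efs <- simulate_efs_timecourse(ref_truths, 0.2,
                                   quiet_cfg(seed = 20000 + s, synergy_delta = 0))
    duration_of_synergism(synergism_curve(efs))
  })
  # bound frozen from a 300-simulation oracle run (zero fraction 0.74, max 0.5 h)
  expect_gt(mean(durs == 0), 0.65)
  expect_lt(max(durs), 1)
})

test_that("head-to-head comparison reproduces summary arithmetic and tests replicates", {
  gly_ind <- list(
    auc = c("0-1 h" = 20.22, "0-3 h" = 72.65, "0-6 h" = 127.26,
            "0-9 h" = 164.64, "0-12 h" = 175.43),
    onset_t_half_min = 18.30, e_max_plateau_pct = 25.93, duration_h = 9
  )
  acl_for <- list(
    auc = c("0-1 h" = 27.39, "0-3 h" = 108.25, "0-6 h" = 175.07,
            "0-9 h" = 186.40, "0-12 h" = 159.25),
    onset_t_half_min = 15.5, e_max_plateau_pct = 42.94, duration_h = 6
  )
  cmp <- compare_synergism_summary(acl_for, gly_ind)
  expect_equal(cmp$e_max_plateau_difference_pct, 17.01)
  expect_equal(cmp$auc_mean_difference, 41.705)
  expect_equal(cmp$duration_difference_h, -3)

  # replicate mode: t-tests per metric, ANOVA across AUC intervals
  withr::with_seed(9, {
    mk <- function(shift) tidyr::expand_grid(
      subject_id = c("s1", "s2", "s3"),
      metric = c("auc_0_3", "auc_0_6", "t_half", "duration_h")
    ) |>
      dplyr::mutate(value = c(70, 130, 18, 9)[match(metric, unique(metric))] +
                      shift + rnorm(dplyr::n(), 0, 2))
    out <- compare_combinations(mk(0), mk(30), labels = c("a", "b"))
  })
  expect_equal(nrow(out), 4)
  expect_true(all(out$difference < 0))
  expect_true(all(out$p_value < 0.05))
  expect_lt(attr(out, "anova_auc_p_combination"), 0.05)
  expect_error(compare_combinations(mk(0), mk(0)[mk(0)$metric != "t_half", ]),
               class = "airwaysyn_invalid_input")
})
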