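test_that("zero-noise simulation reproduces the generating sigmoid exactly", {
  cfg <- quiet_cfg(noise_sd = 0)
  d <- simulate_crc(ref_truths$glycopyrronium, cfg)
  tr <- ref_truths$glycopyrronium
  expect_equal(d$response,
               fourpl_response(d$log10_conc, tr$bottom, tr$top, tr$log_ec50,
                               tr$hill_slope),
               tolerance = 1e-12)
  expect_equal(length(unique(d$subject_id)), 3)
})

test_that("the seed fully determines the simulated tables", {
  a <- simulate_crc(ref_truths$indacaterol, quiet_cfg(seed = 7))
  b <- simulate_crc(ref_truths$indacaterol, quiet_cfg(seed = 7))
  expect_identical(a, b)
  c1 <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                 cfg = quiet_cfg(seed = 3))
  c2 <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                 cfg = quiet_cfg(seed = 3))
  expect_identical(c1$responses, c2$responses)
  e1 <- simulate_efs_timecourse(ref_truths, 0.2, quiet_cfg(seed = 3))
  e2 <- simulate_efs_timecourse(ref_truths, 0.2, quiet_cfg(seed = 3))
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_false(identical(a, simulate_crc(ref_truths$indacaterol, quiet_cfg(seed = 8))))
})

test_that("simulated responses stay inside the truncation band", {
  d <- simulate_crc(ref_truths$glycopyrronium, quiet_cfg(seed = 2, noise_sd = 0.3))
  expect_true(all(d$response >= -0.05 & d$response <= 1.10))
})

test_that("a null combination lies on the Bliss surface; injected synergy is recovered exactly", {
  # synergy_delta = 0, noise 0: observed equals the Bliss expectation
  sim0 <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                   cfg = quiet_cfg(noise_sd = 0, synergy_delta = 0),
                                   levels = seq(10, 90, 10))
  d0 <- sim0$responses
  for (lv in unique(d0$level_pct)) {
    obs <- unique(d0$response[d0$level_pct == lv &
                                d0$treatment == sim0$combination_label])
    expect_equal(obs, as.numeric(bliss_expected(lv / 100, lv / 100)),
                 tolerance = 1e-12)
  }

  # injected 0.30 at noise 0 comes back exactly as the observed-minus-expected delta
  sim <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                  cfg = quiet_cfg(noise_sd = 0, synergy_delta = 0.30),
                                  levels = 20)
  d <- sim$responses
  singles <- list(a = d$response[d$treatment == "glycopyrronium"],
                  b = d$response[d$treatment == "indacaterol"])
  e <- expected_with_uncertainty(singles)
  a <- assess_interaction(d$response[d$treatment == sim$combination_label], e)
  expect_equal(a$delta_pp, 30, tolerance = 1e-9)
})

test_that("levels outside a drug's attainable range are flagged missing", {
  sim <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                  cfg = quiet_cfg(), levels = c(20, 95))
  expect_false(any(sim$responses$attainable[sim$responses$level_pct == 95]))
  expect_true(all(is.na(sim$responses$response[sim$responses$level_pct == 95])))
  expect_true(all(sim$responses$attainable[sim$responses$level_pct == 20]))
  expect_true(is.na(sim$truth$expected[sim$truth$level_pct == 95]))
})

test_that("three-agent combinations use the three-way Bliss surface", {
  fsk <- drug_truth("forskolin", 0, 0.95, log_ec50 = -7.25, hill_slope = 1)
  sim <- simulate_combination_crc(ref_truths$glycopyrronium, ref_truths$indacaterol,
                                  fsk, cfg = quiet_cfg(noise_sd = 0, synergy_delta = 0),
                                  levels = 30)
  d <- sim$responses
  obs <- unique(d$response[d$treatment == sim$combination_label])
  expect_equal(obs, as.numeric(bliss_expected(0.3, 0.3, 0.3)), tolerance = 1e-12)
})

test_that("EFS traces plateau at the design effect and the null combination at the Bliss level", {
  cfg <- quiet_cfg(noise_sd = 0, synergy_delta = 0)
  efs <- simulate_efs_timecourse(ref_truths, per_drug_effect = 0.2, cfg)
  late <- efs[efs$time_min == 720, ]
  expect_equal(late$response[late$treatment == "glycopyrronium"],
               rep(0.2, 3), tolerance = 1e-9)
  expect_equal(late$response[late$treatment == "combination"],
               rep(1 - (1 - 0.2)^2, 3), tolerance = 1e-9)   # 0.36
  # noiseless time control is identically zero relaxation
  expect_true(all(efs$response[efs$treatment == "time_control"] == 0))
})

test_that("generator configs validate their invariants", {
  expect_error(synthetic_config(n_subjects = 1), class = "airwaysyn_invalid_input")
  expect_error(synthetic_config(noise_sd = -0.1), class = "airwaysyn_invalid_input")
  expect_error(synthetic_config(efs_grid = c(0, 5, 5)), class = "airwaysyn_invalid_input")
  expect_error(synthetic_config(wash_time = 800), class = "airwaysyn_invalid_input")
  expect_error(synthetic_config(synergy_delta = 1.5), class = "airwaysyn_invalid_input")
  expect_error(synthetic_config(synergy_window = c(0, 900)),
               class = "airwaysyn_invalid_input")
  expect_error(simulate_crc(ref_truths$glycopyrronium,
                            quiet_cfg(concentration_grid = numeric(0))),
               class = "airwaysyn_invalid_input")
  expect_error(simulate_efs_timecourse(ref_truths, per_drug_effect = 1.2,
                                       quiet_cfg()),
               class = "airwaysyn_invalid_input")
  expect_error(drug_truth("x", bottom = 0.5, top = 0.4, log_ec50 = -8),
               class = "airwaysyn_invalid_input")
})

test_that("the ensemble mean of replicate means converges to the generating curve", {
  tr <- ref_truths$glycopyrronium
  nsim <- 300
  grid <- tr$log_ec50 + seq(-3, 3, length.out = 9)
  mu <- fourpl_response(grid, tr$bottom, tr$top, tr$log_ec50, tr$hill_slope)
  acc <- matrix(0, nsim, length(grid))
  for (s in seq_len(nsim)) {
    d <- simulate_crc(tr, quiet_cfg(seed = 60000 + s))
    acc[s, ] <- tapply(d$response, d$log10_conc, mean)[as.character(sort(grid))]
  }
  se <- 0.05 / sqrt(nsim * 3)
  # interior grid points (truncation at the band edges is inactive there)
  interior <- mu > 0.15 & mu < 0.85
  expect_true(all(abs(colMeans(acc)[interior] - mu[interior]) < 3 * se))
})
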