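# Shared fixtures: built in code, no files.

ref_truths <- reference_truths()

quiet_cfg <- function(seed = 1, ...) {
  synthetic_config(seed = seed, ...)
}

# dense noiseless 4PL curve for fitting tests
noiseless_curve <- function(truth, n = 8, span = 3) {
  x <- seq(truth$log_ec50 - span, truth$log_ec50 + span, length.out = n)
  list(x = x, y = fourpl_response(x, truth$bottom, truth$top,
                                  truth$log_ec50, truth$hill_slope))
}

# synergism-curve-shaped tibble from explicit vectors
delta_curve_tbl <- function(time_min, delta_pp, p_value = 0.001) {
  tibble::tibble(time_min = time_min, delta_pp = delta_pp,
                 p_value = rep_len(p_value, length(time_min)))
}
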