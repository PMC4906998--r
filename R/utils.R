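# Internal helpers shared across modules.

# clip to the unit effect scale (Bliss Independence domain)
clip01 <- function(x) pmin(pmax(x, 0), 1)

# truncation band for simulated normalized responses
RESPONSE_TRUNC <- c(-0.05, 1.10)

truncate_response <- function(x) {
  pmin(pmax(x, RESPONSE_TRUNC[1]), RESPONSE_TRUNC[2])
}

# standard error of the mean
sem <- function(x) stats::sd(x) / sqrt(length(x))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_airwaysyn <- function(msg, class) {
  rlang::abort(msg, class = paste0("airwaysyn_", class))
}

# Two-sided two-sample t-test p-value robust to zero-variance degeneracies.
# Returns 1 when both samples are constant and equal, 0 when constant and
# different (the limit of the test statistic), stats::t.test otherwise.
# Pooled (Student) variance by default: it is exactly calibrated at the
# n = 3 subject-replicate scale; Welch is available for unequal variances.
two_sample_p <- function(x, y, test = c("student", "welch")) {
  test <- match.arg(test)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = (test == "student"))$p.value
}

one_sample_p <- function(x, mu) {
  if (stats::sd(x) == 0) {
    return(if (isTRUE(all.equal(mean(x), mu))) 1 else 0)
  }
  stats::t.test(x, mu = mu)$p.value
}
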