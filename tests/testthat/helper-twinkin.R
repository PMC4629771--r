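# Shared fixtures and independent oracles for the test suite.

# Numerical double-integration oracle for the bivariate standard-normal CDF:
# P(X <= h, Y <= k) = int_{-inf}^{h} phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx.
bvn_cdf_oracle <- function(h, k, rho) {
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2)),
    -Inf, h, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Orthant cell probabilities (both affected / one / neither) for an
# exchangeable pair at threshold t and liability correlation rho, via the
# integration oracle.
cell_probs_oracle <- function(t, rho) {
  q <- stats::pnorm(t, lower.tail = FALSE)
  p11 <- bvn_cdf_oracle(-t, -t, rho)
  c(p11 = p11, p10 = q - p11, p00 = 1 - 2 * q + p11)
}

# absolute-difference closeness assertion (waldo's tolerance is relative)
expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(unname(actual) - unname(expected))), tol)
}

# tiny hand-built cohort used by the data-model tests
toy_cohort <- function() {
  twin_cohort(data.frame(
    pair_id = c("p1", "p2", "p3"),
    zygosity = c("MZ", "DZ", "mz"),
    sex1 = c("male", "female", NA),
    sex2 = c("male", "male", "female"),
    age1 = c(10, 20, 30), age2 = c(10, 20, 30),
    asthma_1 = c(1L, 0L, NA), asthma_2 = c(1L, 1L, 0L),
    ige_1 = c(1.2, -0.5, 0.3), ige_2 = c(1.0, NA, 0.1),
    stringsAsFactors = FALSE),
    traits = c(asthma = "binary", ige = "continuous"))
}

# quick univariate simulated cohorts with fixed defaults
sim_cont <- function(n = 2000, a2 = 0.5, c2 = 0.3, d2 = 0,
                     e2 = 1 - a2 - c2 - d2, seed = 1) {
  simulate_continuous(generative_spec(
    n_mz = n, n_dz = n, kind = "continuous",
    components = c(a2 = a2, c2 = c2, d2 = d2, e2 = e2),
    traits = "y", seed = seed))
}

sim_bin <- function(n = 2000, a2 = 0.6, c2 = 0.2, e2 = 1 - a2 - c2,
                    prevalence = 0.1, seed = 1) {
  simulate_binary(generative_spec(
    n_mz = n, n_dz = n, kind = "binary",
    components = c(a2 = a2, c2 = c2, e2 = e2),
    prevalence = prevalence, traits = "y", seed = seed))
}
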