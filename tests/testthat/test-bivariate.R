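# Bivariate Cholesky fits, phenotypic decomposition and the
# direction-of-causation comparison.

test_that("continuous Cholesky fits recover genetic and environmental correlations", {
  lam <- bivariate_components(a2 = c(0.68, 0.58), e2 = c(0.32, 0.42),
                              rA = 0.90, rE = 0.30)
  co <- simulate_bivariate(generative_spec(
    5000, 5000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 41))
  fit <- fit_bivariate(co, "u", "v", family = "ACE", seed = 1)
  expect_true(fit$converged)
  expect_close(fit$rG, 0.90, 0.05)
  expect_close(fit$rE, 0.30, 0.06)
  expect_close(fit$components["A", 1], 0.68, 0.05)
  expect_close(fit$components["A", 2], 0.58, 0.05)
  # implied phenotypic correlation matches the sample double-entry value
  mz <- co$zygosity == "MZ"
  r_sample <- stats::cor(c(co$u_1, co$u_2), c(co$v_1, co$v_2))
  expect_close(fit$rP, r_sample, 0.02)
})

test_that("traits sharing no factors come out uncorrelated", {
  lam <- bivariate_components(a2 = c(0.6, 0.6), e2 = c(0.4, 0.4),
                              rA = 0, rE = 0)
  co <- simulate_bivariate(generative_spec(
    4000, 4000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 42))
  fit <- fit_bivariate(co, "u", "v", family = "ACE", seed = 1)
  expect_lt(abs(fit$rP), 0.05)
  expect_lt(abs(fit$rE), 0.1)
  expect_error(phenotypic_decomposition(
    structure(list(rP = 0, lambda = fit$lambda), class = "bivariate_fit")),
    "undefined")
})

test_that("the phenotypic decomposition sums to one and hits planted shares", {
  # construction oracle: choose blocks so A carries 81% of rP
  lam <- bivariate_components(a2 = c(0.75, 0.75), c2 = c(0.10, 0.10),
                              e2 = c(0.15, 0.15),
                              rA = 0.405 / 0.75, rC = 0.5, rE = 0.30)
  SA <- tcrossprod(lam$A); SC <- tcrossprod(lam$C); SE <- tcrossprod(lam$E)
  rP_true <- (SA + SC + SE)[1, 2]
  expect_close(rP_true, 0.50, 1e-10)
  expect_close(SA[1, 2] / rP_true, 0.81, 1e-10)
  co <- simulate_bivariate(generative_spec(
    10000, 10000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 43))
  fit <- fit_bivariate(co, "u", "v", family = "ACE", seed = 1)
  dec <- phenotypic_decomposition(fit)
  expect_close(sum(dec), 1, 1e-8)
  expect_close(dec[["a_share"]], 0.81, 0.09)
})

test_that("rG recovery holds across a grid of correlations and heritabilities", {
  grid <- expand.grid(rA = c(-0.9, -0.3, 0, 0.3, 0.9), a2x = c(0.7, 0.4))
  for (i in seq_len(nrow(grid))) {
    rA <- grid$rA[i]; a2 <- c(grid$a2x[i], 0.55)
    lam <- bivariate_components(a2 = a2, e2 = 1 - a2, rA = rA, rE = 0.2)
    co <- simulate_bivariate(generative_spec(
      2000, 2000, c("continuous", "continuous"), lambda = lam,
      traits = c("u", "v"), seed = 440 + i))
    fit <- fit_bivariate(co, "u", "v", family = "AE", n_starts = 2, seed = 1)
    expect_close(fit$rG, rA, 0.1)   # ~3 SE at n = 2000/zygosity
  }
})

test_that("derived correlations are invariant to trait order", {
  lam <- bivariate_components(a2 = c(0.6, 0.4), c2 = c(0.15, 0.2),
                              e2 = c(0.25, 0.4), rA = 0.5, rC = 0.3, rE = 0.1)
  co <- simulate_bivariate(generative_spec(
    3000, 3000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 45))
  f12 <- fit_bivariate(co, "u", "v", family = "ACE", seed = 1)
  f21 <- fit_bivariate(co, "v", "u", family = "ACE", seed = 1)
  expect_close(f12$rG, f21$rG, 0.02)
  expect_close(f12$rP, f21$rP, 0.005)
  expect_close(f12$genetic_share, f21$genetic_share, 0.03)
})

test_that("binary-binary liability fits recover the generating correlations", {
  lam <- bivariate_components(a2 = c(0.7, 0.65), e2 = c(0.3, 0.35),
                              rA = 0.6, rE = 0.2)
  co <- simulate_bivariate(generative_spec(
    20000, 20000, c("binary", "binary"), lambda = lam,
    prevalence = c(0.15, 0.25), traits = c("u", "v"), seed = 46))
  fit <- fit_bivariate(co, "u", "v", family = "AE", seed = 1)
  expect_close(fit$rG, 0.6, 0.08)
  expect_close(fit$thresholds, stats::qnorm(1 - c(0.15, 0.25)), 0.05)
  # twin-order invariance on the cell counts
  f2 <- fit_bivariate(swap_twins(co), "u", "v", family = "AE", seed = 1)
  expect_close(fit$rG, f2$rG, 1e-4)
})

test_that("mixed continuous-binary fits work through the conditional likelihood", {
  lam <- bivariate_components(a2 = c(0.6, 0.7), e2 = c(0.4, 0.3),
                              rA = 0.5, rE = 0.2)
  co <- simulate_bivariate(generative_spec(
    1500, 1500, c("continuous", "binary"), lambda = lam,
    prevalence = c(NA, 0.2), traits = c("lungf", "asthma"), seed = 47))
  fit <- fit_bivariate(co, "lungf", "asthma", family = "AE", n_starts = 2,
                       seed = 1)
  expect_close(fit$rG, 0.5, 0.15)
  # supplying the traits in the other order conditions identically
  f2 <- fit_bivariate(co, "asthma", "lungf", family = "AE", n_starts = 2,
                      seed = 1)
  expect_close(fit$rG, f2$rG, 1e-4)
})

test_that("the causal models are restrictions of the Cholesky fit", {
  lam <- bivariate_components(a2 = c(0.8, 0.2), e2 = c(0.2, 0.8), rA = 0.5,
                              rE = 0.3)
  co <- simulate_bivariate(generative_spec(
    2000, 2000, c("continuous", "continuous"), lambda = lam,
    traits = c("x", "y"), seed = 48))
  chol_fit <- fit_bivariate(co, "x", "y", family = "ACE", seed = 1)
  doc <- fit_direction_of_causation(co, "x", "y", seed = 1)
  expect_gte(chol_fit$loglik + 1e-4, doc$fit_XtoY$loglik)
  expect_gte(chol_fit$loglik + 1e-4, doc$fit_YtoX$loglik)
})

test_that("direction of causation is detected when strongly identified", {
  sim_causal <- function(beta, seed, n = 4000) {
    spec <- generative_spec(n, n, "continuous", c(a2 = 0.8, e2 = 0.2),
                            traits = "x", seed = seed)
    co <- simulate_continuous(spec)
    x <- cbind(co$x_1, co$x_2)
    set.seed(seed + 1)
    y <- beta * x + 0.9 * matrix(stats::rnorm(2 * nrow(x)), ncol = 2)
    twin_cohort(data.frame(pair_id = co$pair_id, zygosity = co$zygosity,
                           x_1 = x[, 1], x_2 = x[, 2],
                           y_1 = y[, 1], y_2 = y[, 2]),
                c(x = "continuous", y = "continuous"))
  }
  hits <- 0; n_rep <- 30
  for (i in seq_len(n_rep)) {
    doc <- fit_direction_of_causation(sim_causal(0.5, 5000 + 7 * i),
                                      "x", "y", seed = 1)
    if (doc$preferred == "XtoY") hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
  # relabeling symmetry: swapping the trait roles flips the preference
  co <- sim_causal(0.5, 99)
  d1 <- fit_direction_of_causation(co, "x", "y", seed = 1)
  d2 <- fit_direction_of_causation(co, "y", "x", seed = 1)
  expect_equal(d1$preferred, "XtoY")
  expect_equal(d2$preferred, "YtoX")
  expect_close(d1$delta_aic, -d2$delta_aic, 0.5)
})

test_that("a null causal path is declared indistinguishable", {
  lam <- bivariate_components(a2 = c(0.8, 0.2), e2 = c(0.2, 0.8),
                              rA = 0, rE = 0)
  co <- simulate_bivariate(generative_spec(
    3000, 3000, c("continuous", "continuous"), lambda = lam,
    traits = c("x", "y"), seed = 49))
  doc <- fit_direction_of_causation(co, "x", "y", seed = 1)
  expect_equal(doc$preferred, "indistinguishable")
})

test_that("binary traits are rejected by the causal comparison", {
  co <- sim_bin(n = 200, seed = 50)
  co2 <- sim_cont(n = 200, seed = 50)
  df <- cbind(as.data.frame(co), y2_1 = co2$y_1, y2_2 = co2$y_2)
  names(df)[names(df) == "y_1"] <- "b_1"; names(df)[names(df) == "y_2"] <- "b_2"
  coh <- twin_cohort(df, c(b = "binary", y2 = "continuous"))
  expect_error(fit_direction_of_causation(coh, "b", "y2"), "continuous")
})
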