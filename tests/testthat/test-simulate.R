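# The synthetic-cohort generator: latent-factor structure, thresholds,
# misclassification and ascertainment.

test_that("generative_spec enforces the variance-component invariants", {
  expect_error(generative_spec(10, 10, "continuous",
                               c(a2 = 0.5, e2 = 0.4)), "sum to 1")
  expect_error(generative_spec(10, 10, "continuous",
                               c(a2 = 0.3, c2 = 0.2, d2 = 0.2, e2 = 0.3)),
               "not identified")
  expect_error(generative_spec(10, 10, "continuous",
                               c(a2 = 1, e2 = 0)), "e2 must be positive")
  expect_error(generative_spec(10, 10, "binary",
                               c(a2 = 0.5, e2 = 0.5), prevalence = 1.2),
               "prevalence")
  bad <- list(A = matrix(c(0.7, 0, 0.2, 0.7), 2), E = diag(0.5, 2))
  expect_error(generative_spec(10, 10, "continuous", lambda = bad),
               "lower-triangular")
  bad2 <- bivariate_components(a2 = c(0.5, 0.5), e2 = c(0.5, 0.5))
  bad2$E <- bad2$E * 2
  expect_error(generative_spec(10, 10, "continuous", lambda = bad2),
               "total variances")
})

test_that("a fixed seed reproduces the cohort bit for bit", {
  a <- sim_cont(n = 200, seed = 11)
  b <- sim_cont(n = 200, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(sim_cont(n = 200, seed = 12))))
})

test_that("continuous phenotypes have the expected moments and twin covariances", {
  n <- 100000
  co <- sim_cont(n = n, a2 = 0.5, c2 = 0.3, seed = 2)
  y <- cbind(co$y_1, co$y_2)
  expect_equal(mean(y), 0, tolerance = 3 / sqrt(2 * n))
  expect_close(stats::var(as.vector(y)), 1, 0.01)
  mz <- co$zygosity == "MZ"
  expect_close(stats::cor(y[mz, 1], y[mz, 2]), 0.80, 0.01)
  expect_close(stats::cor(y[!mz, 1], y[!mz, 2]), 0.55, 0.01)
})

test_that("without genetics the zygosity groups are exchangeable", {
  co <- sim_cont(n = 100000, a2 = 0, c2 = 0.3, seed = 3)
  y <- cbind(co$y_1, co$y_2)
  mz <- co$zygosity == "MZ"
  expect_close(stats::cor(y[mz, 1], y[mz, 2]), 0.30, 0.01)
  expect_close(stats::cor(y[!mz, 1], y[!mz, 2]), 0.30, 0.01)
})

test_that("cross-twin covariances follow the classical expectations across random specs", {
  set.seed(77)
  for (i in 1:5) {
    sh <- abs(stats::rnorm(3)) + 0.2
    sh <- sh / sum(sh)
    use_d <- i %% 2 == 0
    comp <- if (use_d) c(a2 = sh[1], d2 = sh[2], e2 = sh[3])
    else c(a2 = sh[1], c2 = sh[2], e2 = sh[3])
    co <- simulate_continuous(generative_spec(
      30000, 30000, "continuous", comp, traits = "y", seed = 100 + i))
    y <- cbind(co$y_1, co$y_2)
    mz <- co$zygosity == "MZ"
    exp_mz <- expected_pair_covariance(comp, "MZ")[1, 2]
    exp_dz <- expected_pair_covariance(comp, "DZ")[1, 2]
    expect_close(stats::cov(y[mz, 1], y[mz, 2]), exp_mz, 0.02)
    expect_close(stats::cov(y[!mz, 1], y[!mz, 2]), exp_dz, 0.02)
  }
})

test_that("binary traits hit the target prevalence via the liability threshold", {
  co <- sim_bin(n = 50000, a2 = 0.79, c2 = 0.11, prevalence = 0.071, seed = 4)
  expect_close(mean(cbind(co$y_1, co$y_2)), 0.071, 0.003)
})

test_that("without familial components MZ and DZ concordances coincide", {
  co <- sim_bin(n = 50000, a2 = 0, c2 = 0, prevalence = 0.2, seed = 5)
  cc <- concordance_counts(co, "y")
  rmz <- probandwise_concordance(cc, "MZ")
  rdz <- probandwise_concordance(cc, "DZ")
  expect_close(rmz, rdz, 0.02)
  expect_close(rmz, 0.2, 0.02)  # no familiality: rate = prevalence
})

test_that("bivariate cohorts realize the Cholesky-implied covariances", {
  lam <- bivariate_components(a2 = c(0.6, 0.5), c2 = c(0.2, 0.1),
                              e2 = c(0.2, 0.4), rA = 0.7, rC = 0.4, rE = 0.1)
  co <- simulate_bivariate(generative_spec(
    50000, 50000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 6))
  SA <- tcrossprod(lam$A); SC <- tcrossprod(lam$C); SE <- tcrossprod(lam$E)
  u <- cbind(co$u_1, co$u_2); v <- cbind(co$v_1, co$v_2)
  mz <- co$zygosity == "MZ"
  # within person, cross trait
  expect_close(stats::cov(c(u), c(v)), (SA + SC + SE)[1, 2], 0.02)
  # cross twin, cross trait
  expect_close(stats::cov(c(u[mz, 1], u[mz, 2]), c(v[mz, 2], v[mz, 1])),
               (SA + SC)[1, 2], 0.02)
  expect_close(stats::cov(c(u[!mz, 1], u[!mz, 2]), c(v[!mz, 2], v[!mz, 1])),
               (0.5 * SA + SC)[1, 2], 0.02)
})

test_that("uncorrelated path matrices give independent traits", {
  lam <- bivariate_components(a2 = c(0.5, 0.5), e2 = c(0.5, 0.5),
                              rA = 0, rE = 0)
  co <- simulate_bivariate(generative_spec(
    20000, 20000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 7))
  expect_close(stats::cor(c(co$u_1, co$u_2), c(co$v_1, co$v_2)), 0, 0.02)
})

test_that("a single shared genetic factor gives the rG = 1 cross-correlation", {
  lam <- bivariate_components(a2 = c(0.6, 0.4), e2 = c(0.4, 0.6), rA = 1)
  co <- simulate_bivariate(generative_spec(
    50000, 50000, c("continuous", "continuous"), lambda = lam,
    traits = c("u", "v"), seed = 8))
  mz <- co$zygosity == "MZ"
  got <- stats::cor(c(co$u_1[mz], co$u_2[mz]), c(co$v_2[mz], co$v_1[mz]))
  expect_close(got, sqrt(0.6 * 0.4), 0.02)
})

test_that("misclassification follows the sensitivity/specificity mixture", {
  co <- sim_bin(n = 50000, a2 = 0.6, c2 = 0.2, prevalence = 0.10, seed = 9)
  same <- apply_misclassification(co, "y", 1, 1, seed = 1)
  expect_equal(as.data.frame(same), as.data.frame(co), ignore_attr = TRUE)
  noisy <- apply_misclassification(co, "y", 0.88, 0.89, seed = 1)
  truep <- mean(cbind(co$y_1, co$y_2))
  want <- truep * 0.88 + (1 - truep) * 0.11
  expect_close(mean(cbind(noisy$y_1, noisy$y_2)), want, 0.005)
  # the original cohort is untouched and the MZ-DZ liability gap shrinks
  r <- function(x, z) tetrachoric(concordance_counts(x, "y"), z, n_boot = 0)$rho
  gap_clean <- r(co, "MZ") - r(co, "DZ")
  gap_noisy <- r(noisy, "MZ") - r(noisy, "DZ")
  expect_lt(gap_noisy, gap_clean)
  expect_error(apply_misclassification(sim_cont(50), "y", 0.9, 0.9),
               "binary")
})

test_that("proband ascertainment keeps exactly the affected pairs and preserves concordance", {
  co <- sim_bin(n = 20000, a2 = 0.6, c2 = 0.2, prevalence = 0.15, seed = 10)
  y <- cbind(co$y_1, co$y_2)
  n_affected_pairs <- sum(y[, 1] == 1 | y[, 2] == 1)
  asc <- ascertain_probands(co, "y")
  expect_equal(nrow(asc), n_affected_pairs)
  expect_match(attr(asc, "provenance"), "ascertained")
  # probandwise concordance conditions on an affected twin, so it is
  # unchanged by dropping fully unaffected pairs
  for (z in c("MZ", "DZ"))
    expect_equal(probandwise_concordance(concordance_counts(asc, "y"), z),
                 probandwise_concordance(concordance_counts(co, "y"), z))
  expect_error(ascertain_probands(sim_cont(50), "y"), "binary")
})
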