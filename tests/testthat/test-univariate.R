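# Univariate variance-component fitting, model selection and comparison.

test_that("expected pair covariances substitute the shares correctly", {
  expect_equal(expected_pair_covariance(c(a2 = 0.9, e2 = 0.1), "MZ")[1, 2], 0.9)
  expect_equal(expected_pair_covariance(c(a2 = 0.9, e2 = 0.1), "DZ")[1, 2], 0.45)
  expect_equal(expected_pair_covariance(c(c2 = 0.4, e2 = 0.6), "MZ")[1, 2],
               expected_pair_covariance(c(c2 = 0.4, e2 = 0.6), "DZ")[1, 2])
  expect_equal(expected_pair_covariance(c(d2 = 0.4, e2 = 0.6), "DZ")[1, 2], 0.1)
  expect_equal(diag(expected_pair_covariance(c(a2 = 0.5, c2 = 0.3, e2 = 0.2),
                                             "MZ")), c(1, 1))
})

test_that("continuous AE fitting recovers a high heritability", {
  co <- simulate_continuous(generative_spec(
    5000, 5000, "continuous", c(a2 = 0.81, e2 = 0.19), traits = "ige",
    seed = 21))
  fit <- fit_continuous(co, "ige", model = "AE", seed = 1)
  expect_true(fit$converged)
  expect_close(fit$components[["a2"]], 0.81, 0.03)
  expect_equal(fit$h2_narrow, fit$components[["a2"]])
  expect_equal(sum(fit$components), 1, tolerance = 1e-6)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  # profile interval brackets the truth here
  expect_true(fit$ci["a2", 1] < 0.81 && 0.81 < fit$ci["a2", 2])
})

test_that("independent pair members give vanishing familial components", {
  co <- sim_cont(n = 4000, a2 = 0, c2 = 0, seed = 22)
  fit <- fit_continuous(co, "y", model = "ACE", ci_level = NULL, seed = 1)
  expect_lt(fit$components[["a2"]], 0.05)
  expect_lt(fit$components[["c2"]], 0.05)
})

test_that("ACE point estimates agree with the Falconer closed form at large n", {
  co <- sim_cont(n = 50000, a2 = 0.5, c2 = 0.3, seed = 23)
  fit <- fit_continuous(co, "y", model = "ACE", ci_level = NULL, seed = 1)
  icc <- intraclass_correlation(co, "y", n_boot = 0)
  rmz <- icc$r[icc$zygosity == "MZ"]; rdz <- icc$r[icc$zygosity == "DZ"]
  expect_close(fit$components[["a2"]], 2 * (rmz - rdz), 0.01)
  expect_close(fit$components[["c2"]], 2 * rdz - rmz, 0.01)
})

test_that("full-information handling uses half-missing pairs", {
  co <- sim_cont(n = 3000, a2 = 0.6, c2 = 0.2, seed = 24)
  co2 <- co
  co2$y_2[1:1500] <- NA   # half the MZ group loses one twin
  fit <- fit_continuous(co2, "y", model = "ACE", ci_level = NULL, seed = 1)
  expect_true(is.finite(fit$loglik))
  expect_close(fit$components[["a2"]], 0.6, 0.12)
})

test_that("liability ACE fitting recovers shares, threshold and prevalence", {
  co <- sim_bin(n = 20000, a2 = 0.6, c2 = 0.2, prevalence = 0.10, seed = 25)
  fit <- fit_binary(co, "y", model = "ACE", seed = 1)
  expect_true(fit$converged)
  expect_close(fit$components[["a2"]], 0.6, 0.08)
  expect_close(fit$components[["c2"]], 0.2, 0.08)
  expect_close(fit$prevalence, 0.10, 0.005)
  expect_true(fit$ci["a2", 1] < 0.6 && 0.6 < fit$ci["a2", 2])
})

test_that("identical MZ and DZ tables leave no genetic signal", {
  df <- data.frame(pair_id = sprintf("p%d", 1:400),
                   zygosity = rep(c("MZ", "DZ"), each = 200),
                   y_1 = rep(c(1L, 1L, 0L, 0L), 100),
                   y_2 = rep(c(1L, 0L, 1L, 0L), 100))
  co <- twin_cohort(df, c(y = "binary"))
  fit <- suppressWarnings(
    fit_binary(co, "y", model = "ACE", ci_level = NULL, seed = 1))
  expect_lt(fit$components[["a2"]], 0.02)
  fit2 <- fit_binary(co, "y", model = "ADE", ci_level = NULL, seed = 1)
  expect_lt(fit2$components[["d2"]], 0.02)
})

test_that("binary fits refuse uninformative tables", {
  df <- data.frame(pair_id = sprintf("p%d", 1:40),
                   zygosity = rep(c("MZ", "DZ"), each = 20),
                   y_1 = 0L, y_2 = 0L)
  co <- twin_cohort(df, c(y = "binary"))
  expect_error(fit_binary(co, "y"), "two concordance cells")
})

test_that("the saturated family follows the twice-DZ rule with ACE ties", {
  co_ace <- sim_cont(n = 20000, a2 = 0.4, c2 = 0.3, seed = 26)
  expect_equal(select_saturated(co_ace, "y"), "ACE")
  co_ade <- simulate_continuous(generative_spec(
    20000, 20000, "continuous", c(a2 = 0.4, d2 = 0.35, e2 = 0.25),
    traits = "y", seed = 27))
  expect_equal(select_saturated(co_ade, "y"), "ADE")
  bin <- sim_bin(n = 20000, a2 = 0.6, c2 = 0.2, prevalence = 0.1, seed = 28)
  expect_equal(select_saturated(bin, "y"), "ACE")
})

test_that("model comparisons are honest about nesting and power", {
  co <- sim_cont(n = 5000, a2 = 0.5, c2 = 0.3, seed = 29)
  full <- fit_continuous(co, "y", "ACE", ci_level = NULL, seed = 1)
  same <- fit_continuous(co, "y", "ACE", ci_level = NULL, seed = 2)
  cmp0 <- compare_models(full, same)
  expect_lt(abs(cmp0$lrt_stat), 1e-4)
  eonly <- fit_continuous(co, "y", "E", ci_level = NULL, seed = 1)
  cmpE <- compare_models(full, eonly)
  expect_lt(cmpE$p_value, 1e-6)
  expect_equal(cmpE$aic_preferred, "ACE")
  ae <- fit_continuous(co, "y", "AE", ci_level = NULL, seed = 1)
  de <- fit_continuous(co, "y", "DE", ci_level = NULL, seed = 1)
  expect_error(compare_models(ae, de), "not nested")
  # nesting monotonicity of the maximized log-likelihoods
  expect_gte(full$loglik + 1e-6, ae$loglik)
  expect_gte(ae$loglik + 1e-6, eonly$loglik)
})

test_that("dropping a truly absent C keeps the boundary LRT conservative", {
  # type-I rate of the nominal-0.05 AE-vs-ACE test under c2 = 0
  n_rep <- 200
  rej <- 0
  for (i in seq_len(n_rep)) {
    co <- simulate_continuous(generative_spec(
      400, 400, "continuous", c(a2 = 0.5, e2 = 0.5), traits = "y",
      seed = 3000 + i))
    full <- suppressWarnings(
      fit_continuous(co, "y", "ACE", n_starts = 2, ci_level = NULL,
                     seed = 1))
    ae <- fit_continuous(co, "y", "AE", n_starts = 2, ci_level = NULL,
                         seed = 1)
    p <- tryCatch(compare_models(full, ae)$p_value, error = function(e) 1)
    if (p < 0.05) rej <- rej + 1
  }
  # boundary makes the chi-square reference conservative; allow binomial slack
  expect_lte(rej / n_rep, 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("estimates are invariant to twin relabeling and affine rescaling", {
  co <- sim_cont(n = 3000, a2 = 0.5, c2 = 0.3, seed = 31)
  f1 <- fit_continuous(co, "y", "ACE", ci_level = NULL, seed = 1)
  f2 <- fit_continuous(swap_twins(co), "y", "ACE", ci_level = NULL, seed = 1)
  expect_equal(f1$components, f2$components, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  sc <- co
  sc$y_1 <- 3 * sc$y_1 + 7; sc$y_2 <- 3 * sc$y_2 + 7
  f3 <- fit_continuous(sc, "y", "ACE", ci_level = NULL, seed = 1)
  expect_equal(f1$components, f3$components, tolerance = 1e-6)
  expect_equal(f3$total_var, 9 * f1$total_var, tolerance = 1e-4)
  bin <- sim_bin(n = 5000, seed = 32)
  b1 <- fit_binary(bin, "y", "ACE", ci_level = NULL, seed = 1)
  b2 <- fit_binary(swap_twins(bin), "y", "ACE", ci_level = NULL, seed = 1)
  expect_equal(b1$components, b2$components, tolerance = 1e-10)
})

test_that("binary and continuous fits agree on h2 for a median split", {
  spec <- generative_spec(30000, 30000, "continuous",
                          c(a2 = 0.6, c2 = 0.15, e2 = 0.25), traits = "y",
                          seed = 33)
  co <- simulate_continuous(spec)
  fc <- fit_continuous(co, "y", "ACE", ci_level = NULL, seed = 1)
  bin <- as.data.frame(co)
  bin$y_1 <- as.integer(bin$y_1 > 0); bin$y_2 <- as.integer(bin$y_2 > 0)
  cb <- twin_cohort(bin, c(y = "binary"))
  fb <- fit_binary(cb, "y", "ACE", ci_level = NULL, seed = 1)
  expect_close(fb$h2_narrow, fc$h2_narrow, 0.05)
})

test_that("parametric-bootstrap self-consistency holds for the liability fit", {
  co <- sim_bin(n = 20000, a2 = 0.5, c2 = 0.25, prevalence = 0.15, seed = 34)
  fit <- fit_binary(co, "y", "ACE", ci_level = NULL, seed = 1)
  refit_spec <- generative_spec(
    20000, 20000, "binary",
    c(a2 = fit$components[["a2"]], c2 = fit$components[["c2"]],
      e2 = fit$components[["e2"]]),
    prevalence = fit$prevalence, traits = "y", seed = 35)
  refit <- fit_binary(simulate_binary(refit_spec), "y", "ACE",
                      ci_level = NULL, seed = 1)
  se <- 0.03  # approximate Fisher SE of a2-hat at this design
  expect_close(refit$components[["a2"]], fit$components[["a2"]], 3 * se)
})

test_that("the auto fitter attaches the nested-model ladder", {
  co <- sim_bin(n = 10000, a2 = 0.6, c2 = 0.2, prevalence = 0.1, seed = 36)
  fit <- fit_univariate(co, "y", model = "auto", ci_level = NULL, seed = 1)
  expect_equal(fit$model, "ACE")
  expect_named(fit$ladder, c("AE", "CE", "E"))
  expect_s3_class(fit$ladder$AE, "twin_model_comparison")
})
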