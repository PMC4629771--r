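# Maximum-likelihood ACE/ADE-family variance-component models for one trait.
# Continuous traits: per-pair bivariate-normal likelihood with
# full-information handling of half-missing pairs. Binary traits:
# multinomial likelihood of the concordance-cell counts under the
# liability-threshold model. Components are parameterized as unconstrained
# path loadings and squared, which enforces nonnegative variances without
# constrained optimization.

MODEL_COMPONENTS <- list(ACE = c("A", "C", "E"), ADE = c("A", "D", "E"),
                         AE = c("A", "E"), CE = c("C", "E"),
                         DE = c("D", "E"), E = "E")

zyg_weights <- function(zygosity) {
  switch(zygosity, MZ = c(r = 1, q = 1), DZ = c(r = 0.5, q = 0.25))
}

#' Expected twin-pair covariance matrix
#'
#' Under the classical twin model the cross-twin covariance is
#' \eqn{r_z \sigma_A^2 + q_z \sigma_D^2 + \sigma_C^2} with
#' \eqn{(r_z, q_z) = (1, 1)} for MZ and \eqn{(0.5, 0.25)} for DZ pairs;
#' the diagonal is the total variance.
#'
#' @param components named shares/variances \code{c(a2=, c2=, d2=, e2=)}
#'   (missing entries are 0).
#' @param zygosity "MZ" or "DZ".
#' @return 2x2 covariance matrix.
#' @export
expected_pair_covariance <- function(components, zygosity) {
  s <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  s[names(components)] <- components
  w <- zyg_weights(zygosity)
  tot <- sum(s)
  off <- w["r"] * s[["a2"]] + w["q"] * s[["d2"]] + s[["c2"]]
  matrix(c(tot, off, off, tot), 2)
}

# ---- continuous likelihood on sufficient statistics -------------------------

# symmetrized per-zygosity sufficient statistics; singletons kept for FIML
cont_suffstats <- function(cohort, trait) {
  m <- trait_matrix(cohort, trait)
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z) {
    mz <- m[cohort$zygosity == z, , drop = FALSE]
    both <- !is.na(mz[, 1]) & !is.na(mz[, 2])
    one <- xor(is.na(mz[, 1]), is.na(mz[, 2]))
    pp <- mz[both, , drop = FALSE]
    xs <- c(mz[one, 1], mz[one, 2]); xs <- xs[!is.na(xs)]
    list(n = nrow(pp),
         s1 = sum(pp), s2 = sum(pp^2), s12 = sum(pp[, 1] * pp[, 2]),
         ns = length(xs), ss1 = sum(xs), ss2 = sum(xs^2))
  })
}

cont_loglik <- function(mu, variances, stats_z) {
  ll <- 0
  for (z in c("MZ", "DZ")) {
    st <- stats_z[[z]]
    S <- expected_pair_covariance(variances, z)
    v <- S[1, 1]; cv <- S[1, 2]
    det <- v^2 - cv^2
    if (!is.finite(det) || det <= 0 || v <= 0) return(-Inf)
    if (st$n > 0) {
      qsum <- st$s2 - 2 * mu * st$s1 + 2 * st$n * mu^2
      qcross <- st$s12 - mu * st$s1 + st$n * mu^2
      ll <- ll - st$n * log(2 * pi) - st$n / 2 * log(det) -
        (v * qsum - 2 * cv * qcross) / (2 * det)
    }
    if (st$ns > 0) {
      ll <- ll - st$ns / 2 * log(2 * pi * v) -
        (st$ss2 - 2 * mu * st$ss1 + st$ns * mu^2) / (2 * v)
    }
  }
  ll
}

paths_to_variances <- function(paths, comps) {
  v <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  v[paste0(tolower(comps), "2")] <- paths^2
  v
}

#' Fit a univariate variance-component model to a continuous trait
#'
#' Maximizes the per-pair bivariate-normal log-likelihood with a common mean
#' and the zygosity-specific expected covariance over unconstrained path
#' loadings (variance = loading^2). Pairs with one missing twin contribute
#' their univariate marginal density (full-information maximum likelihood).
#' Multi-start quasi-Newton optimization; convergence requires the best
#' log-likelihood to be reproduced within 1e-6 by a second start.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait continuous trait name.
#' @param model one of "ACE", "ADE", "AE", "CE", "DE", "E".
#' @param n_starts seeded optimizer starts.
#' @param min_pairs minimum complete pairs required per zygosity.
#' @param ci_level profile-likelihood interval level (NULL skips CIs).
#' @param seed seed for the start jitter.
#' @return object of class \code{twin_fit}.
#' @export
fit_continuous <- function(cohort, trait, model = "ACE", n_starts = 5L,
                           min_pairs = 20L, ci_level = 0.95, seed = 1L) {
  model <- match.arg(model, names(MODEL_COMPONENTS))
  if (trait_kind(cohort, trait) != "continuous")
    stop("fit_continuous requires a continuous trait")
  check_both_zygosities(cohort)
  st <- cont_suffstats(cohort, trait)
  for (z in c("MZ", "DZ"))
    if (st[[z]]$n < min_pairs)
      stop("fewer than ", min_pairs, " complete ", z, " pairs")
  comps <- MODEL_COMPONENTS[[model]]
  k <- length(comps)

  # descriptive moments for starts and the selection-rule warning
  n_tot <- st$MZ$n + st$DZ$n
  mu0 <- (st$MZ$s1 + st$DZ$s1) / (2 * n_tot)
  v0 <- (st$MZ$s2 + st$DZ$s2) / (2 * n_tot) - mu0^2
  r_emp <- vapply(c("MZ", "DZ"), function(z) {
    s <- st[[z]]
    (s$s12 / s$n - (s$s1 / (2 * s$n))^2 * 1) / v0
  }, numeric(1))
  if (model == "ACE" && r_emp[1] > 2 * r_emp[2])
    warning("MZ correlation exceeds twice the DZ correlation; ",
            "an ADE model may be more appropriate than ACE")

  negll <- function(par) {
    ll <- cont_loglik(par[1], paths_to_variances(par[-1], comps), st)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base_shares <- falconer_start(r_emp[1], r_emp[2], comps)
  fits <- with_seed(derive_seed(seed, 8L), {
    lapply(seq_len(n_starts), function(i) {
      sh <- base_shares
      if (i > 1) {
        sh <- sh * stats::runif(k, 0.3, 1.7)
        sh <- sh / sum(sh)
      }
      par0 <- c(mu0, sqrt(sh * v0))
      tryCatch(stats::optim(par0, negll, method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-12)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimization failed for all starts")
  lls <- vapply(fits, function(f) -f$value, numeric(1))
  best <- fits[[which.max(lls)]]
  converged <- best$convergence == 0 &&
    (length(lls) < 2 || sort(-lls)[2] - min(-lls) < 1e-6)

  variances <- paths_to_variances(best$par[-1], comps)
  tot <- sum(variances)
  shares <- variances / tot
  fit <- new_twin_fit(model = model, trait = trait, kind = "continuous",
                      mu = best$par[1], total_var = tot,
                      paths = abs(stats::setNames(best$par[-1], comps)),
                      components = shares, threshold = NA_real_,
                      prevalence = NA_real_, loglik = -best$value,
                      n_params = length(best$par),
                      n_pairs = c(MZ = st$MZ$n, DZ = st$DZ$n),
                      converged = converged)
  if (!is.null(ci_level))
    fit$ci <- profile_ci_continuous(fit, st, comps, ci_level)
  fit
}

falconer_start <- function(rmz, rdz, comps) {
  a2 <- min(max(2 * (rmz - rdz), 0.05), 0.9)
  c2 <- min(max(2 * rdz - rmz, 0.05), 0.9)
  sh <- c(A = a2, C = c2, D = a2 / 2, E = max(1 - a2 - c2, 0.1))
  sh <- sh[comps]
  sh / sum(sh)
}

# profile-likelihood CI for each standardized share (continuous models):
# the constrained fit fixes the target share, keeps total variance and mean
# free, and splits the remaining share between the other components.
profile_ci_continuous <- function(fit, st, comps, level) {
  cutoff <- stats::qchisq(level, 1)
  llmax <- fit$loglik
  k <- length(comps)
  prof_dev <- function(target_idx, s) {
    others <- setdiff(seq_len(k), target_idx)
    obj <- function(par) {
      mu <- par[1]; tau2 <- exp(par[2])
      w <- if (k == 3) stats::plogis(par[3]) else 1
      sh <- numeric(k)
      sh[target_idx] <- s
      if (k == 1) sh[target_idx] <- 1
      if (k == 2) sh[others] <- 1 - s
      if (k == 3) sh[others] <- (1 - s) * c(w, 1 - w)
      ll <- cont_loglik(mu, paths_to_variances(sqrt(sh * tau2), comps), st)
      if (!is.finite(ll)) 1e10 else -ll
    }
    par0 <- c(fit$mu, log(fit$total_var), if (k == 3) 0)
    o <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    2 * (llmax + o$value)
  }
  share_names <- paste0(tolower(comps), "2")
  ci <- matrix(NA_real_, k, 2, dimnames = list(share_names, c("lower", "upper")))
  for (j in seq_len(k)) {
    if (k == 1) { ci[j, ] <- c(1, 1); next }
    hat <- fit$components[[share_names[j]]]
    f <- function(s) prof_dev(j, s) - cutoff
    lo <- if (hat <= 1e-4 || f(1e-4) < 0) 0 else
      tryCatch(stats::uniroot(f, c(1e-4, hat), tol = 1e-4)$root,
               error = function(e) NA_real_)
    up <- if (hat >= 1 - 1e-4 || f(1 - 1e-4) < 0) 1 else
      tryCatch(stats::uniroot(f, c(hat, 1 - 1e-4), tol = 1e-4)$root,
               error = function(e) NA_real_)
    ci[j, ] <- c(lo, up)
  }
  ci
}

# ---- binary (liability-threshold) likelihood --------------------------------

binary_negll <- function(par, counts, comps) {
  t <- par[1]
  k <- length(comps)
  raw <- if (k > 1) par[-1] else numeric(0)
  sh <- binary_shares(raw, comps)
  ll <- 0
  for (z in c("MZ", "DZ")) {
    w <- zyg_weights(z)
    rho <- w["r"] * sh[["a2"]] + w["q"] * sh[["d2"]] + sh[["c2"]]
    p <- pair_cell_probs(t, rho)
    cc <- counts[counts$zygosity == z, ]
    ll <- ll + cc$n_concordant * log(p["p11"]) +
      cc$n_discordant * log(2 * p["p10"]) +
      cc$n_unaffected * log(p["p00"])
  }
  -ll
}

# raw unconstrained params -> shares with e2 = 1/(1 + sum(raw^2))
binary_shares <- function(raw, comps) {
  sh <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 1)
  nonE <- setdiff(comps, "E")
  denom <- 1 + sum(raw^2)
  if (length(nonE))
    sh[paste0(tolower(nonE), "2")] <- raw^2 / denom
  sh["e2"] <- 1 / denom
  sh
}

#' Fit a liability-threshold variance-component model to a binary trait
#'
#' Maximizes the multinomial likelihood of the per-zygosity concordance-cell
#' counts. Cell probabilities are orthant probabilities of a standard
#' bivariate normal whose correlation is the model-implied liability
#' correlation \eqn{r_z a^2 + q_z d^2 + c^2}; a single threshold is shared
#' across twins and zygosity groups and the total liability variance is
#' fixed to 1, so the standardized shares are the parameters.
#'
#' @inheritParams fit_continuous
#' @param trait binary trait name.
#' @return object of class \code{twin_fit} with the fitted threshold and the
#'   implied population prevalence.
#' @export
fit_binary <- function(cohort, trait, model = "ACE", n_starts = 5L,
                       ci_level = 0.95, seed = 1L) {
  model <- match.arg(model, names(MODEL_COMPONENTS))
  if (trait_kind(cohort, trait) != "binary")
    stop("fit_binary requires a binary trait")
  check_both_zygosities(cohort)
  counts <- concordance_counts(cohort, trait)
  informative <- (counts$n_concordant > 0) + (counts$n_discordant > 0) +
    (counts$n_unaffected > 0)
  if (any(informative < 2))
    stop("each zygosity needs pairs in at least two concordance cells")
  if (all(counts$n_concordant == 0) && all(counts$n_discordant == 0))
    stop("no affected pairs: the liability model carries no information")
  comps <- MODEL_COMPONENTS[[model]]
  k <- length(comps)
  n_free <- 1L + (k - 1L)

  prev0 <- sum(2 * counts$n_concordant + counts$n_discordant) /
    (2 * sum(counts$n_concordant + counts$n_discordant + counts$n_unaffected))
  t0 <- stats::qnorm(1 - prev0)
  r_des <- vapply(c("MZ", "DZ"), function(z)
    tryCatch(tetra_fit(c(
      C = counts$n_concordant[counts$zygosity == z],
      D = counts$n_discordant[counts$zygosity == z],
      U = counts$n_unaffected[counts$zygosity == z]))$rho,
      error = function(e) NA_real_), numeric(1))
  if (model == "ACE" && !anyNA(r_des) && r_des[1] > 2 * r_des[2])
    warning("MZ liability correlation exceeds twice the DZ correlation; ",
            "an ADE model may be more appropriate than ACE")

  sh0 <- if (anyNA(r_des)) stats::setNames(rep(1 / k, k), comps) else
    falconer_start(r_des[1], r_des[2], comps)
  fits <- with_seed(derive_seed(seed, 9L), {
    lapply(seq_len(n_starts), function(i) {
      sh <- sh0
      if (i > 1) { sh <- sh * stats::runif(k, 0.3, 1.7); sh <- sh / sum(sh) }
      e2 <- max(sh[length(sh)], 0.02)
      raw0 <- if (k > 1) sqrt(pmax(sh[-length(sh)], 1e-4) / e2) else numeric(0)
      tryCatch(stats::optim(c(t0, raw0), binary_negll, counts = counts,
                            comps = comps, method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-12)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimization failed for all starts")
  lls <- vapply(fits, function(f) -f$value, numeric(1))
  best <- fits[[which.max(lls)]]
  converged <- best$convergence == 0 &&
    (length(lls) < 2 || sort(-lls)[2] - min(-lls) < 1e-6)

  sh <- binary_shares(if (k > 1) best$par[-1] else numeric(0), comps)
  boundary <- any(sh[paste0(tolower(setdiff(comps, "E")), "2")] < 1e-5)
  fit <- new_twin_fit(model = model, trait = trait, kind = "binary",
                      mu = NA_real_, total_var = 1,
                      paths = sqrt(sh[paste0(tolower(comps), "2")]),
                      components = sh, threshold = unname(best$par[1]),
                      prevalence = unname(stats::pnorm(best$par[1],
                                                       lower.tail = FALSE)),
                      loglik = -best$value, n_params = n_free,
                      n_pairs = c(MZ = sum(unlist(counts[counts$zygosity == "MZ", -1])),
                                  DZ = sum(unlist(counts[counts$zygosity == "DZ", -1]))),
                      converged = converged, boundary = boundary)
  if (!is.null(ci_level))
    fit$ci <- profile_ci_binary(fit, counts, comps, ci_level)
  fit
}

profile_ci_binary <- function(fit, counts, comps, level) {
  cutoff <- stats::qchisq(level, 1)
  llmax <- fit$loglik
  k <- length(comps)
  nonE <- setdiff(comps, "E")
  share_names <- paste0(tolower(comps), "2")
  ci <- matrix(NA_real_, k, 2, dimnames = list(share_names, c("lower", "upper")))
  prof_dev <- function(j, s) {
    obj <- function(par) {
      t <- par[1]
      w <- if (k == 3) stats::plogis(par[2]) else 1
      sh <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
      sh[share_names[j]] <- s
      others <- setdiff(share_names, share_names[j])
      if (k == 2) sh[others[1]] <- 1 - s
      if (k == 3) sh[others] <- (1 - s) * c(w, 1 - w)
      ll <- 0
      for (z in c("MZ", "DZ")) {
        wz <- zyg_weights(z)
        rho <- wz["r"] * sh[["a2"]] + wz["q"] * sh[["d2"]] + sh[["c2"]]
        p <- pair_cell_probs(t, rho)
        cc <- counts[counts$zygosity == z, ]
        ll <- ll + cc$n_concordant * log(p["p11"]) +
          cc$n_discordant * log(2 * p["p10"]) +
          cc$n_unaffected * log(p["p00"])
      }
      -ll
    }
    o <- stats::optim(c(fit$threshold, if (k == 3) 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    2 * (llmax + o$value)
  }
  for (j in seq_len(k)) {
    if (k == 1) { ci[j, ] <- c(1, 1); next }
    hat <- fit$components[[share_names[j]]]
    f <- function(s) prof_dev(j, s) - cutoff
    lo <- if (hat <= 1e-4 || f(1e-4) < 0) 0 else
      tryCatch(stats::uniroot(f, c(1e-4, hat), tol = 1e-4)$root,
               error = function(e) NA_real_)
    up <- if (hat >= 1 - 1e-4 || f(1 - 1e-4) < 0) 1 else
      tryCatch(stats::uniroot(f, c(hat, 1 - 1e-4), tol = 1e-4)$root,
               error = function(e) NA_real_)
    ci[j, ] <- c(lo, up)
  }
  ci
}

# ---- fit object, model selection, comparison --------------------------------

new_twin_fit <- function(..., boundary = FALSE) {
  x <- list(...)
  x$boundary <- boundary
  x$aic <- 2 * x$n_params - 2 * x$loglik
  x$h2_narrow <- unname(x$components[["a2"]])
  x$h2_broad <- unname(x$components[["a2"]] + x$components[["d2"]])
  x$ci <- NULL
  structure(x, class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%s trait '%s')\n", x$model, x$kind, x$trait))
  sh <- x$components[x$components > 0 | names(x$components) == "e2"]
  cat("  standardized components:",
      paste(sprintf("%s = %.3f", names(sh), sh), collapse = ", "), "\n")
  if (!is.na(x$threshold))
    cat(sprintf("  threshold = %.4f (implied prevalence %.4f)\n",
                x$threshold, x$prevalence))
  cat(sprintf("  logLik = %.3f, params = %d, AIC = %.3f\n",
              x$loglik, x$n_params, x$aic))
  if (!is.null(x$ci)) {
    for (i in seq_len(nrow(x$ci)))
      cat(sprintf("  %s 95%% profile CI [%.3f, %.3f]\n",
                  rownames(x$ci)[i], x$ci[i, 1], x$ci[i, 2]))
  }
  if (!x$converged) cat("  WARNING: convergence not confirmed\n")
  if (isTRUE(x$boundary)) cat("  NOTE: a variance share is at the 0 boundary\n")
  invisible(x)
}

#' Choose the saturated model family from the twin correlations
#'
#' ACE when the MZ correlation is at most twice the DZ correlation (evidence
#' compatible with shared environment), ADE when it exceeds twice the DZ
#' correlation (evidence of genetic non-additivity). Binary traits are
#' compared on the liability (tetrachoric) scale, continuous traits by the
#' double-entry intraclass correlation. Exact ties go to ACE.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait trait name.
#' @return "ACE" or "ADE".
#' @export
select_saturated <- function(cohort, trait) {
  kind <- trait_kind(cohort, trait)
  if (kind == "binary") {
    counts <- concordance_counts(cohort, trait)
    r <- vapply(c("MZ", "DZ"), function(z)
      tetra_fit(c(C = counts$n_concordant[counts$zygosity == z],
                  D = counts$n_discordant[counts$zygosity == z],
                  U = counts$n_unaffected[counts$zygosity == z]))$rho,
      numeric(1))
  } else {
    icc <- intraclass_correlation(cohort, trait, n_boot = 0)
    r <- stats::setNames(icc$r, icc$zygosity)
  }
  if (r[["MZ"]] <= 2 * r[["DZ"]]) "ACE" else "ADE"
}

#' Likelihood-ratio and AIC comparison of nested twin models
#'
#' @param full,nested \code{twin_fit} objects on the same data; the nested
#'   model's components must be a subset of the full model's.
#' @return object of class \code{twin_model_comparison} with the LRT
#'   statistic, degrees of freedom, chi-square p-value (conservative when a
#'   variance component sits on its zero boundary) and the AIC-preferred
#'   model.
#' @export
compare_models <- function(full, nested) {
  stopifnot(inherits(full, "twin_fit"), inherits(nested, "twin_fit"))
  if (full$trait != nested$trait || full$kind != nested$kind ||
      !identical(full$n_pairs, nested$n_pairs))
    stop("fits are not on the same data")
  cf <- MODEL_COMPONENTS[[full$model]]
  cn <- MODEL_COMPONENTS[[nested$model]]
  if (!all(cn %in% cf) || length(cn) >= length(cf) && full$model != nested$model)
    stop("models are not nested: ", nested$model, " within ", full$model)
  lrt <- 2 * (full$loglik - nested$loglik)
  if (lrt < -1e-6)
    stop("nested model fits better than the full model; check convergence")
  lrt <- max(lrt, 0)
  df <- full$n_params - nested$n_params
  p <- if (df > 0) stats::pchisq(lrt, df, lower.tail = FALSE) else 1
  structure(list(full = full$model, nested = nested$model,
                 lrt_stat = lrt, df = df, p_value = p,
                 aic_full = full$aic, aic_nested = nested$aic,
                 aic_preferred = if (full$aic <= nested$aic) full$model
                 else nested$model,
                 boundary_note = paste(
                   "chi-square reference is conservative when the dropped",
                   "variance component lies on its zero boundary")),
            class = "twin_model_comparison")
}

#' @export
print.twin_model_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: LRT = %.3f on %d df, p = %.4g; AIC prefers %s\n",
              x$nested, x$full, x$lrt_stat, x$df, x$p_value, x$aic_preferred))
  invisible(x)
}

#' Fit a univariate model, dispatching on the trait kind
#'
#' With \code{model = "auto"} the saturated family is chosen by
#' \code{\link{select_saturated}} and the full ladder of nested comparisons
#' (AE/CE or DE, then E) is attached.
#'
#' @inheritParams fit_continuous
#' @param model model name or "auto".
#' @return a \code{twin_fit}; with \code{model = "auto"}, the saturated fit
#'   carrying a \code{ladder} attribute of \code{\link{compare_models}}
#'   results.
#' @export
fit_univariate <- function(cohort, trait, model = "auto", ...) {
  kind <- trait_kind(cohort, trait)
  fitter <- if (kind == "binary") fit_binary else fit_continuous
  if (model != "auto") return(fitter(cohort, trait, model = model, ...))
  sat <- select_saturated(cohort, trait)
  full <- fitter(cohort, trait, model = sat, ...)
  nested_names <- if (sat == "ACE") c("AE", "CE", "E") else c("AE", "DE", "E")
  ladder <- lapply(nested_names, function(mn) {
    nf <- tryCatch(fitter(cohort, trait, model = mn, ...),
                   error = function(e) NULL)
    if (is.null(nf)) NULL else compare_models(full, nf)
  })
  names(ladder) <- nested_names
  full$ladder <- Filter(Negate(is.null), ladder)
  full
}
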