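#' Generative specification for synthetic twin cohorts
#'
#' Describes the latent-factor truth behind a simulated cohort: pair counts,
#' per-trait variance-component shares on the standardized (liability or
#' phenotype) scale, thresholds for binary traits via population prevalence,
#' and -- for two-trait specs -- lower-triangular path matrices defining
#' cross-trait factor loadings. Additive-genetic factors correlate 1 across
#' MZ and 0.5 across DZ co-twins, non-additive genetic factors 1 and 0.25,
#' shared environment 1 in both zygosity groups (equal-environments
#' assumption), non-shared environment 0.
#'
#' For a univariate spec supply \code{components = c(a2=, c2=, d2=, e2=)}
#' (omitted shares default to 0). For a bivariate spec supply \code{lambda},
#' a list with lower-triangular 2x2 matrices \code{A}, \code{E} and
#' optionally \code{C} or \code{D}, most conveniently built with
#' \code{\link{bivariate_components}}.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param kind "binary" or "continuous"; length 2 for bivariate specs.
#' @param components named shares summing to 1 (univariate specs).
#' @param lambda list of 2x2 lower-triangular path matrices (bivariate).
#' @param prevalence population proportion(s) affected, binary traits only.
#' @param traits trait name(s).
#' @param seed master integer seed; stage-specific sub-streams are derived
#'   from it deterministically.
#' @return object of class \code{generative_spec}.
#' @export
generative_spec <- function(n_mz, n_dz, kind, components = NULL,
                            lambda = NULL, prevalence = NULL,
                            traits = NULL, seed = 1L) {
  stopifnot(n_mz >= 1, n_dz >= 1)
  kind <- match.arg(kind, c("binary", "continuous"), several.ok = TRUE)
  n_traits <- if (!is.null(lambda)) 2L else 1L
  kind <- rep_len(kind, n_traits)
  if (is.null(traits))
    traits <- if (n_traits == 1) "trait" else c("trait1", "trait2")
  stopifnot(length(traits) == n_traits)

  if (n_traits == 1) {
    shares <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
    if (is.null(names(components)) ||
        !all(names(components) %in% names(shares)))
      stop("components must be named among a2, c2, d2, e2")
    shares[names(components)] <- components
    if (any(shares < 0)) stop("variance shares must be nonnegative")
    if (abs(sum(shares) - 1) > 1e-8)
      stop("variance shares must sum to 1 (got ", sum(shares), ")")
    if (shares["c2"] > 0 && shares["d2"] > 0)
      stop("C and D are not identified together in a twin design; ",
           "set one of c2, d2 to zero")
    if (shares["e2"] <= 0)
      stop("e2 must be positive (E includes measurement error)")
    components <- shares
  } else {
    lambda <- validate_lambda(lambda)
  }
  if (any(kind == "binary")) {
    if (is.null(prevalence)) stop("binary traits need a prevalence")
    prevalence <- rep_len(prevalence, n_traits)
    if (any(kind == "binary" & (prevalence <= 0 | prevalence >= 1)))
      stop("prevalence must lie strictly between 0 and 1")
  }
  structure(list(n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
                 kind = kind, components = components, lambda = lambda,
                 prevalence = prevalence, traits = traits,
                 seed = as.integer(seed)),
            class = "generative_spec")
}

validate_lambda <- function(lambda) {
  if (!is.list(lambda) || !all(c("A", "E") %in% names(lambda)))
    stop("lambda must be a list with at least matrices A and E")
  if (!is.null(lambda$C) && !is.null(lambda$D))
    stop("C and D path matrices are not identified together")
  for (nm in names(lambda)) {
    M <- lambda[[nm]]
    stopifnot(is.matrix(M), all(dim(M) == c(2, 2)))
    if (abs(M[1, 2]) > 1e-12)
      stop("lambda$", nm, " must be lower-triangular")
  }
  tot <- Reduce(`+`, lapply(lambda, tcrossprod))
  if (max(abs(diag(tot) - 1)) > 1e-8)
    stop("implied per-trait total variances must equal 1 (got ",
         paste(signif(diag(tot), 6), collapse = ", "), ")")
  lambda
}

#' Build bivariate path matrices from shares and factor correlations
#'
#' Convenience constructor for the lower-triangular Cholesky loadings of a
#' two-trait latent model: given per-trait variance shares and factor-level
#' correlations, each component covariance block is
#' \eqn{\mathrm{diag}(\sqrt{s}) R \mathrm{diag}(\sqrt{s})} and its
#' lower-triangular Cholesky factor becomes the loading matrix.
#'
#' @param a2,e2 length-2 additive-genetic and non-shared shares.
#' @param c2,d2 length-2 shared-environment / dominance shares (at most one
#'   nonzero).
#' @param rA,rC,rD,rE factor-level correlations between the two traits.
#' @return list of 2x2 lower-triangular matrices suitable for
#'   \code{\link{generative_spec}}.
#' @export
bivariate_components <- function(a2, e2, c2 = c(0, 0), d2 = c(0, 0),
                                 rA = 0, rC = 0, rD = 0, rE = 0) {
  stopifnot(length(a2) == 2, length(e2) == 2)
  tot <- a2 + c2 + d2 + e2
  if (max(abs(tot - 1)) > 1e-8)
    stop("per-trait shares must sum to 1")
  block <- function(s, r) {
    if (all(s == 0)) return(NULL)
    S <- diag(sqrt(s)) %*% matrix(c(1, r, r, 1), 2) %*% diag(sqrt(s))
    L <- t(chol(S + diag(1e-14, 2)))
    L[abs(L) < 1e-12] <- 0
    L
  }
  out <- list(A = block(a2, rA), C = block(c2, rC),
              D = block(d2, rD), E = block(e2, rE))
  out[!vapply(out, is.null, logical(1))]
}

# cross-twin correlation of each latent factor class by zygosity
factor_twin_cor <- function(component, zygosity) {
  r <- switch(component,
              A = c(MZ = 1, DZ = 0.5),
              D = c(MZ = 1, DZ = 0.25),
              C = c(MZ = 1, DZ = 1),
              E = c(MZ = 0, DZ = 0))
  unname(r[zygosity])
}

# n x 2 matrix of standard-normal factor scores with cross-twin correlation r,
# realized as sqrt(r) * common + sqrt(1-r) * unique (exact target correlation)
draw_factor_pair <- function(n, r) {
  if (r >= 1) {
    z <- stats::rnorm(n)
    return(cbind(z, z))
  }
  if (r <= 0) return(cbind(stats::rnorm(n), stats::rnorm(n)))
  zc <- stats::rnorm(n)
  cbind(sqrt(r) * zc + sqrt(1 - r) * stats::rnorm(n),
        sqrt(r) * zc + sqrt(1 - r) * stats::rnorm(n))
}

# liability matrices for one zygosity group under a univariate spec
simulate_liability_uni <- function(n, zygosity, shares) {
  out <- matrix(0, n, 2)
  for (comp in c("A", "C", "D", "E")) {
    s <- shares[[paste0(tolower(comp), "2")]]
    if (s > 0)
      out <- out + sqrt(s) *
        draw_factor_pair(n, factor_twin_cor(comp, zygosity))
  }
  out
}

# list(trait1 = n x 2, trait2 = n x 2) liabilities under a bivariate spec
simulate_liability_biv <- function(n, zygosity, lambda) {
  l1 <- matrix(0, n, 2); l2 <- matrix(0, n, 2)
  for (comp in names(lambda)) {
    L <- lambda[[comp]]
    r <- factor_twin_cor(comp, zygosity)
    f1 <- draw_factor_pair(n, r)
    f2 <- draw_factor_pair(n, r)
    l1 <- l1 + L[1, 1] * f1
    l2 <- l2 + L[2, 1] * f1 + L[2, 2] * f2
  }
  list(l1, l2)
}

assemble_cohort <- function(spec, values, provenance) {
  n <- spec$n_mz + spec$n_dz
  df <- data.frame(pair_id = sprintf("sim%06d", seq_len(n)),
                   zygosity = rep(c("MZ", "DZ"), c(spec$n_mz, spec$n_dz)),
                   stringsAsFactors = FALSE)
  for (i in seq_along(spec$traits)) {
    df[[paste0(spec$traits[i], "_1")]] <- values[[i]][, 1]
    df[[paste0(spec$traits[i], "_2")]] <- values[[i]][, 2]
  }
  schema <- stats::setNames(spec$kind, spec$traits)
  twin_cohort(df, traits = schema, provenance = provenance)
}

#' Simulate a continuous-trait twin cohort
#'
#' Phenotype = \eqn{a A + c C + d D + e E} with paths equal to the square
#' roots of the variance shares, so the population mean is 0 and the variance
#' 1; MZ and DZ cross-twin covariances equal the classical expectations
#' \eqn{a^2 + d^2 + c^2} and \eqn{0.5 a^2 + 0.25 d^2 + c^2}.
#'
#' @param spec a univariate continuous \code{\link{generative_spec}}.
#' @return a \code{\link{twin_cohort}}.
#' @export
simulate_continuous <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"), is.null(spec$lambda),
            spec$kind == "continuous")
  with_seed(derive_seed(spec$seed, 1L), {
    vals <- rbind(simulate_liability_uni(spec$n_mz, "MZ", spec$components),
                  simulate_liability_uni(spec$n_dz, "DZ", spec$components))
  })
  assemble_cohort(spec, list(vals),
                  sprintf("simulated continuous (a2=%.3g c2=%.3g d2=%.3g e2=%.3g, seed=%d)",
                          spec$components["a2"], spec$components["c2"],
                          spec$components["d2"], spec$components["e2"],
                          spec$seed))
}

#' Simulate a binary-trait twin cohort (liability-threshold model)
#'
#' A standard-normal liability is generated as in
#' \code{\link{simulate_continuous}} and dichotomized at the deterministic
#' threshold \eqn{t = \Phi^{-1}(1 - K)} for prevalence \eqn{K}; a twin is
#' affected iff its liability exceeds the threshold.
#'
#' @param spec a univariate binary \code{\link{generative_spec}} with a
#'   prevalence.
#' @return a \code{\link{twin_cohort}}.
#' @export
simulate_binary <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"), is.null(spec$lambda),
            spec$kind == "binary")
  thr <- stats::qnorm(1 - spec$prevalence[1])
  with_seed(derive_seed(spec$seed, 2L), {
    liab <- rbind(simulate_liability_uni(spec$n_mz, "MZ", spec$components),
                  simulate_liability_uni(spec$n_dz, "DZ", spec$components))
  })
  y <- matrix(as.integer(liab > thr), ncol = 2)
  assemble_cohort(spec, list(y),
                  sprintf("simulated binary (a2=%.3g c2=%.3g d2=%.3g e2=%.3g, K=%.4g, seed=%d)",
                          spec$components["a2"], spec$components["c2"],
                          spec$components["d2"], spec$components["e2"],
                          spec$prevalence[1], spec$seed))
}

#' Simulate a two-trait twin cohort from Cholesky path matrices
#'
#' Latent factors are shared across traits through the lower-triangular
#' loading matrices, so the cross-twin cross-trait covariance of traits
#' \eqn{i, j} equals \eqn{r_z (\Lambda_A \Lambda_A')_{ij} +
#' q_z (\Lambda_D \Lambda_D')_{ij} + (\Lambda_C \Lambda_C')_{ij}} with
#' \eqn{(r_z, q_z) = (1, 1)} for MZ and \eqn{(0.5, 0.25)} for DZ pairs.
#' Binary traits are thresholded at their prevalence quantile.
#'
#' @param spec a bivariate \code{\link{generative_spec}} (field
#'   \code{lambda} set).
#' @return a \code{\link{twin_cohort}} with two traits.
#' @export
simulate_bivariate <- function(spec) {
  stopifnot(inherits(spec, "generative_spec"), !is.null(spec$lambda))
  with_seed(derive_seed(spec$seed, 3L), {
    mz <- simulate_liability_biv(spec$n_mz, "MZ", spec$lambda)
    dz <- simulate_liability_biv(spec$n_dz, "DZ", spec$lambda)
  })
  vals <- list(rbind(mz[[1]], dz[[1]]), rbind(mz[[2]], dz[[2]]))
  for (i in 1:2) {
    if (spec$kind[i] == "binary") {
      thr <- stats::qnorm(1 - spec$prevalence[i])
      vals[[i]] <- matrix(as.integer(vals[[i]] > thr), ncol = 2)
    }
  }
  assemble_cohort(spec, vals,
                  sprintf("simulated bivariate (%s/%s, seed=%d)",
                          spec$kind[1], spec$kind[2], spec$seed))
}

#' Apply questionnaire misclassification to a binary trait
#'
#' Each observed value is flipped independently: a true 1 stays 1 with
#' probability \code{sensitivity}, a true 0 stays 0 with probability
#' \code{specificity} (the Danish screening question for asthma had
#' sensitivity 0.88 and specificity 0.89 against clinical examination).
#' The input cohort is not modified.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait binary trait name.
#' @param sensitivity,specificity reporting probabilities in (0, 1].
#' @param seed integer seed.
#' @return a new cohort with the noisy trait.
#' @export
apply_misclassification <- function(cohort, trait, sensitivity, specificity,
                                    seed = 1L) {
  if (trait_kind(cohort, trait) != "binary")
    stop("misclassification applies to binary traits only")
  stopifnot(sensitivity > 0, sensitivity <= 1,
            specificity > 0, specificity <= 1)
  out <- cohort
  with_seed(derive_seed(seed, 4L), {
    for (j in 1:2) {
      col <- paste0(trait, "_", j)
      v <- out[[col]]
      obs <- !is.na(v)
      u <- stats::runif(sum(obs))
      tv <- v[obs]
      keep <- ifelse(tv == 1, sensitivity, specificity)
      v[obs] <- ifelse(u <= keep, tv, 1L - tv)
      out[[col]] <- as.integer(v)
    }
  })
  attr(out, "provenance") <- paste0(attr(cohort, "provenance"),
                                    sprintf(" | misclassified %s (sens=%.3g spec=%.3g)",
                                            trait, sensitivity, specificity))
  out
}

#' Restrict a cohort to pairs with at least one affected twin
#'
#' Emulates proband ascertainment: only pairs in which at least one member
#' is affected for \code{trait} are retained. Probandwise concordance is by
#' definition unchanged by this selection; naive variance-component fits on
#' ascertained cohorts are biased (see the methods vignette).
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait binary trait name.
#' @return the ascertained sub-cohort.
#' @export
ascertain_probands <- function(cohort, trait) {
  if (trait_kind(cohort, trait) != "binary")
    stop("proband ascertainment applies to binary traits only")
  m <- trait_matrix(cohort, trait)
  keep <- !is.na(m[, 1]) & !is.na(m[, 2]) & (m[, 1] == 1 | m[, 2] == 1)
  subset_cohort(cohort, keep,
                paste0("ascertained through affected probands on ", trait))
}

#' Simulate an exposure-outcome twin cohort for co-twin control designs
#'
#' The exposure has its own A/C/E structure (binary via a liability
#' threshold, or continuous). The outcome liability is
#' \eqn{\gamma_A A_x + \gamma_C C_x + } residual A/C/E \eqn{ + \beta X},
#' where \eqn{A_x, C_x} are the exposure's own genetic and shared factors
#' (confounding paths) and \eqn{X} the realized exposure; the liability is
#' standardized to unit variance before thresholding, so \code{prevalence}
#' is the outcome's population rate whatever the wiring.
#'
#' @param n_mz,n_dz pair counts.
#' @param exposure list with \code{kind} ("binary"/"continuous"),
#'   \code{components} (a2/c2/e2 shares) and \code{prevalence} if binary.
#' @param outcome list with \code{components} and \code{prevalence}.
#' @param beta direct causal effect of the exposure on the outcome liability.
#' @param gamma_A,gamma_C loadings of the exposure's own A and C factors on
#'   the outcome liability (genetic / shared-environmental confounding).
#' @param seed integer seed.
#' @return a \code{\link{twin_cohort}} with traits \code{exposure} and
#'   \code{outcome}.
#' @export
simulate_cotwin <- function(n_mz, n_dz, exposure, outcome, beta = 0,
                            gamma_A = 0, gamma_C = 0, seed = 1L) {
  ek <- match.arg(exposure$kind, c("binary", "continuous"))
  es <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  es[names(exposure$components)] <- exposure$components
  os <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  os[names(outcome$components)] <- outcome$components
  stopifnot(abs(sum(es) - 1) < 1e-8, abs(sum(os) - 1) < 1e-8)

  sim_group <- function(n, zyg) {
    # exposure factors kept explicit so the outcome can reuse them
    Ax <- draw_factor_pair(n, factor_twin_cor("A", zyg))
    Cx <- draw_factor_pair(n, 1)
    Ex <- draw_factor_pair(n, 0)
    liab_x <- sqrt(es["a2"]) * Ax + sqrt(es["c2"]) * Cx + sqrt(es["e2"]) * Ex
    x <- if (ek == "binary") {
      matrix(as.integer(liab_x > stats::qnorm(1 - exposure$prevalence)),
             ncol = 2)
    } else liab_x
    resid <- simulate_liability_uni(n, zyg, as.list(os))
    raw <- gamma_A * Ax + gamma_C * Cx + resid + beta * x
    var_x <- if (ek == "binary")
      exposure$prevalence * (1 - exposure$prevalence) else 1
    # exposure value correlates with the confounding factors it loads on
    cov_xA <- if (ek == "binary") 0 else sqrt(es["a2"])
    cov_xC <- if (ek == "binary") 0 else sqrt(es["c2"])
    v <- gamma_A^2 + gamma_C^2 + 1 + beta^2 * var_x +
      2 * beta * (gamma_A * cov_xA + gamma_C * cov_xC)
    if (ek == "binary" && (gamma_A != 0 || gamma_C != 0)) {
      # empirical variance is the honest scale when the exposure is a
      # thresholded function of the confounding factors
      v <- stats::var(as.vector(raw))
    }
    liab_y <- raw / sqrt(v)
    y <- matrix(as.integer(liab_y > stats::qnorm(1 - outcome$prevalence)),
                ncol = 2)
    list(x = x, y = y)
  }
  with_seed(derive_seed(seed, 5L), {
    g_mz <- sim_group(n_mz, "MZ")
    g_dz <- sim_group(n_dz, "DZ")
  })
  df <- data.frame(pair_id = sprintf("sim%06d", seq_len(n_mz + n_dz)),
                   zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
                   exposure_1 = c(g_mz$x[, 1], g_dz$x[, 1]),
                   exposure_2 = c(g_mz$x[, 2], g_dz$x[, 2]),
                   outcome_1 = c(g_mz$y[, 1], g_dz$y[, 1]),
                   outcome_2 = c(g_mz$y[, 2], g_dz$y[, 2]),
                   stringsAsFactors = FALSE)
  twin_cohort(df, traits = c(exposure = ek, outcome = "binary"),
              provenance = sprintf(
                "simulated exposure-outcome cohort (beta=%.3g gamma_A=%.3g gamma_C=%.3g, seed=%d)",
                beta, gamma_A, gamma_C, seed))
}
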