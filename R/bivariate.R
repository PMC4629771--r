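# Two-trait Cholesky variance-component models. Continuous pairs use the
# per-pair 4-variate normal likelihood (on symmetrized sufficient
# statistics), binary pairs the multinomial over the 16 joint outcome cells
# with orthant probabilities of the 4-variate liability normal, and mixed
# pairs a conditional-normal factorization: the continuous margins enter as
# a bivariate normal density and the binary orthants are evaluated on the
# conditional distribution, avoiding 4-D integration per pair.

# component covariance blocks implied by a lambda list
lambda_blocks <- function(lambda) {
  lapply(lambda, tcrossprod)
}

# 4x4 covariance (order X1, Y1, X2, Y2) for one zygosity
biv_sigma <- function(blocks, zygosity) {
  w <- zyg_weights(zygosity)
  W <- Reduce(`+`, blocks)
  B <- matrix(0, 2, 2)
  if (!is.null(blocks$A)) B <- B + w["r"] * blocks$A
  if (!is.null(blocks$D)) B <- B + w["q"] * blocks$D
  if (!is.null(blocks$C)) B <- B + blocks$C
  # order (X1, Y1, X2, Y2): within-person block W, cross-twin block B
  rbind(cbind(W, B), cbind(t(B), W))
}

# ---- continuous-continuous --------------------------------------------------

biv_suffstats <- function(cohort, traitX, traitY) {
  mx <- trait_matrix(cohort, traitX)
  my <- trait_matrix(cohort, traitY)
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z) {
    sel <- cohort$zygosity == z
    V <- cbind(mx[sel, 1], my[sel, 1], mx[sel, 2], my[sel, 2])
    V <- V[stats::complete.cases(V), , drop = FALSE]
    Vs <- rbind(V, V[, c(3, 4, 1, 2)])          # double entry
    m <- colMeans(Vs)
    Sc <- crossprod(sweep(Vs, 2, m)) / nrow(Vs)
    list(n = nrow(V), m = m, Sc = Sc)
  })
}

biv_cont_loglik <- function(mu, blocks, st) {
  ll <- 0
  mu4 <- c(mu, mu)
  for (z in c("MZ", "DZ")) {
    S <- biv_sigma(blocks, z)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    d <- st[[z]]$m - mu4
    ll <- ll - st[[z]]$n / 2 *
      (4 * log(2 * pi) + logdet + sum(Sinv * st[[z]]$Sc) +
         drop(t(d) %*% Sinv %*% d))
  }
  ll
}

# lower-triangular 2x2 from 3 free entries
lt2 <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2, 2)

# ---- binary-binary ----------------------------------------------------------

# 16-cell counts per zygosity, pattern index bit order (x1, y1, x2, y2)
biv_cell_counts <- function(cohort, traitX, traitY) {
  mx <- trait_matrix(cohort, traitX)
  my <- trait_matrix(cohort, traitY)
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(z) {
    sel <- cohort$zygosity == z
    V <- cbind(mx[sel, 1], my[sel, 1], mx[sel, 2], my[sel, 2])
    V <- V[stats::complete.cases(V), , drop = FALSE]
    idx <- V[, 1] + 2 * V[, 2] + 4 * V[, 3] + 8 * V[, 4]
    tabulate(idx + 1, nbins = 16)
  })
}

# raw parameter vector -> unit-variance lambda list for the binary and mixed
# parameterizations: the non-shared loading of each constrained row is fixed
# to 1 before row-normalization, which enforces total variance 1 smoothly.
# comps is c("A", "E"), c("A", "C", "E") or c("A", "D", "E").
raw_to_lambda_binary <- function(raw, comps) {
  nonE <- setdiff(comps, "E")
  k <- length(nonE)
  lam <- list()
  for (i in seq_len(k)) lam[[nonE[i]]] <- lt2(raw[(3 * i - 2):(3 * i)])
  e21 <- raw[3 * k + 1]
  lam$E <- lt2(c(1, e21, 1))
  v1 <- 1 + sum(vapply(lam[nonE], function(L) L[1, 1]^2, numeric(1)))
  v2 <- 1 + e21^2 +
    sum(vapply(lam[nonE], function(L) L[2, 1]^2 + L[2, 2]^2, numeric(1)))
  s <- sqrt(c(v1, v2))
  lapply(lam, function(L) L / s)[c(nonE, "E")]
}

biv_bin_negll <- function(par, counts, comps) {
  t2 <- par[1:2]
  lambda <- raw_to_lambda_binary(par[-(1:2)], comps)
  blocks <- lambda_blocks(lambda)
  t4 <- c(t2[1], t2[2], t2[1], t2[2])
  nll <- 0
  for (z in c("MZ", "DZ")) {
    p <- binary_pair_cell_probs(t4, biv_sigma(blocks, z))
    nll <- nll - sum(counts[[z]] * log(p))
  }
  nll
}

# ---- mixed continuous (X) / binary (Y) --------------------------------------

raw_to_lambda_mixed <- function(raw, comps) {
  # X row on its free scale (first length(comps) entries), Y row normalized
  k <- length(comps)
  nonE <- setdiff(comps, "E")
  lam <- list()
  pos <- k
  for (nm in nonE) {
    lam[[nm]] <- lt2(c(raw[match(nm, comps)], raw[pos + 1], raw[pos + 2]))
    pos <- pos + 2
  }
  e21 <- raw[pos + 1]
  lam$E <- lt2(c(raw[match("E", comps)], e21, 1))
  v2 <- 1 + e21^2 +
    sum(vapply(lam[nonE], function(L) L[2, 1]^2 + L[2, 2]^2, numeric(1)))
  s <- sqrt(v2)
  lam <- lapply(lam, function(L) { L[2, ] <- L[2, ] / s; L })
  lam[c(nonE, "E")]
}

biv_mixed_negll <- function(par, data_z, comps) {
  muX <- par[1]; tY <- par[2]
  lambda <- raw_to_lambda_mixed(par[-(1:2)], comps)
  blocks <- lambda_blocks(lambda)
  nll <- 0
  for (z in c("MZ", "DZ")) {
    V <- data_z[[z]]
    if (!nrow(V)) next
    S <- biv_sigma(blocks, z)           # order (X1, Y1, X2, Y2)
    ox <- c(1, 3); oy <- c(2, 4)
    Sxx <- S[ox, ox]; Syx <- S[oy, ox]; Syy <- S[oy, oy]
    det <- Sxx[1, 1]^2 - Sxx[1, 2]^2
    if (det <= 0) return(Inf)
    x1 <- V[, 1] - muX; x2 <- V[, 3] - muX
    # bivariate normal density of the continuous margins
    q <- (Sxx[1, 1] * (x1^2 + x2^2) - 2 * Sxx[1, 2] * x1 * x2) / det
    nll <- nll + sum(log(2 * pi) + 0.5 * log(det) + q / 2)
    # conditional bivariate normal of the binary liabilities
    A <- Syx %*% solve(Sxx)
    Sc <- Syy - A %*% t(Syx)
    s1 <- sqrt(Sc[1, 1]); s2c <- sqrt(Sc[2, 2])
    rc <- Sc[1, 2] / (s1 * s2c)
    m1 <- A[1, 1] * x1 + A[1, 2] * x2
    m2 <- A[2, 1] * x1 + A[2, 2] * x2
    lo1 <- ifelse(V[, 2] == 1, tY, -Inf); up1 <- ifelse(V[, 2] == 1, Inf, tY)
    lo2 <- ifelse(V[, 4] == 1, tY, -Inf); up2 <- ifelse(V[, 4] == 1, Inf, tY)
    pr <- rect_bvn(lo1, up1, lo2, up2, m1, m2, s1, s2c, rc)
    nll <- nll - sum(log(pmax(pr, 1e-300)))
  }
  nll
}

# ---- public fit -------------------------------------------------------------

#' Bivariate Cholesky decomposition of two traits
#'
#' Fits lower-triangular path matrices \eqn{\Lambda_A}, \eqn{\Lambda_C}
#' (or \eqn{\Lambda_D}) and \eqn{\Lambda_E} by maximum likelihood and
#' derives the genetic, shared/dominance and non-shared correlations between
#' the traits, the phenotypic correlation, and the share of the phenotypic
#' correlation carried by each source. Continuous trait pairs use the
#' 4-variate normal likelihood; binary pairs the 16-cell orthant likelihood
#' on the liability scale (cost independent of the number of pairs); mixed
#' pairs the conditional-normal factorization. Binary liabilities have unit
#' variance by construction.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param traitX,traitY trait names.
#' @param family "ACE" or "ADE" (middle component C or D).
#' @param n_starts seeded optimizer starts.
#' @param seed start-jitter seed.
#' @return object of class \code{bivariate_fit}: lambda matrices, factor
#'   correlations \code{rG}, \code{rC}/\code{rD}, \code{rE}, phenotypic
#'   correlation \code{rP}, \code{genetic_share} of rP, thresholds,
#'   log-likelihood, AIC, convergence flag.
#' @export
fit_bivariate <- function(cohort, traitX, traitY, family = "ACE",
                          n_starts = 3L, seed = 1L) {
  family <- match.arg(family, c("ACE", "ADE", "AE"))
  kX <- trait_kind(cohort, traitX); kY <- trait_kind(cohort, traitY)
  check_both_zygosities(cohort)
  mid <- switch(family, ACE = "C", ADE = "D", AE = NULL)
  comps <- c("A", mid, "E")
  nc <- length(comps)
  swapped <- FALSE
  if (kX == "binary" && kY == "continuous") {
    # conditional factorization conditions on the continuous trait first;
    # all derived correlations are order-invariant
    tmp <- traitX; traitX <- traitY; traitY <- tmp
    tmp <- kX; kX <- kY; kY <- tmp
    swapped <- TRUE
  }
  setting <- paste(kX, kY, sep = "-")

  # moment-based starting values
  start_shares <- function(kind, trait) {
    f <- tryCatch({
      if (kind == "binary") {
        cc <- concordance_counts(cohort, trait)
        r <- vapply(c("MZ", "DZ"), function(z)
          tetra_fit(c(C = cc$n_concordant[cc$zygosity == z],
                      D = cc$n_discordant[cc$zygosity == z],
                      U = cc$n_unaffected[cc$zygosity == z]))$rho, numeric(1))
      } else {
        icc <- intraclass_correlation(cohort, trait, n_boot = 0)
        r <- stats::setNames(icc$r, icc$zygosity)
      }
      falconer_start(r[["MZ"]], r[["DZ"]], comps)
    }, error = function(e)
      stats::setNames(rep(1 / nc, nc), comps))
    pmax(f, 0.05) / sum(pmax(f, 0.05))
  }
  shX <- start_shares(kX, traitX); shY <- start_shares(kY, traitY)

  make_lambda0 <- function(rxy) {
    args <- list(a2 = c(shX[["A"]], shY[["A"]]),
                 e2 = c(shX[["E"]], shY[["E"]]), rA = rxy, rE = rxy)
    if (identical(mid, "C")) {
      args$c2 <- c(shX[["C"]], shY[["C"]]); args$rC <- rxy
    } else if (identical(mid, "D")) {
      args$d2 <- c(shX[["D"]], shY[["D"]]); args$rD <- rxy
    }
    do.call(bivariate_components, args)
  }

  if (setting == "continuous-continuous") {
    st <- biv_suffstats(cohort, traitX, traitY)
    n_pairs <- c(MZ = st$MZ$n, DZ = st$DZ$n)
    rxy0 <- stats::cov2cor(st$MZ$Sc)[1, 2]
    sdx <- sqrt(st$MZ$Sc[1, 1]); sdy <- sqrt(st$MZ$Sc[2, 2])
    build_par <- function(lam, jit) {
      lam <- lapply(lam, function(L) diag(c(sdx, sdy)) %*% L)
      c(st$MZ$m[1:2], unlist(lapply(seq_len(nc), function(i)
        lam[[comps[i]]][c(1, 2, 4)] * jit[(3 * i - 2):(3 * i)])))
    }
    negll <- function(par) {
      lambda <- lapply(seq_len(nc), function(i)
        lt2(par[2 + (3 * i - 2):(3 * i)]))
      names(lambda) <- comps
      ll <- biv_cont_loglik(par[1:2], lambda_blocks(lambda), st)
      if (!is.finite(ll)) 1e10 else -ll
    }
    n_par <- 2L + 3L * nc
  } else if (setting == "binary-binary") {
    counts <- biv_cell_counts(cohort, traitX, traitY)
    n_pairs <- c(MZ = sum(counts$MZ), DZ = sum(counts$DZ))
    mX <- trait_matrix(cohort, traitX); mY <- trait_matrix(cohort, traitY)
    pX <- mean(mX, na.rm = TRUE); pY <- mean(mY, na.rm = TRUE)
    ok <- stats::complete.cases(mX, mY)
    rxy0 <- tryCatch(polychoric_2x2(
      sum(mX[ok, 1] & mY[ok, 1]), sum(mX[ok, 1] & !mY[ok, 1]),
      sum(!mX[ok, 1] & mY[ok, 1]), sum(!mX[ok, 1] & !mY[ok, 1])),
      error = function(e) 0.2)
    build_par <- function(lam, jit) {
      nonE <- setdiff(comps, "E")
      # rows are renormalized inside the likelihood, so scaling by the
      # first-row non-shared loading is only a convenient reference point
      raw <- unlist(lapply(seq_along(nonE), function(i)
        lam[[nonE[i]]][c(1, 2, 4)] / lam$E[1, 1] * jit[(3 * i - 2):(3 * i)]))
      c(stats::qnorm(1 - pX), stats::qnorm(1 - pY), raw,
        lam$E[2, 1] / lam$E[2, 2])
    }
    negll <- function(par) biv_bin_negll(par, counts, comps)
    n_par <- 2L + 3L * nc - 2L
  } else {
    mx <- trait_matrix(cohort, traitX); my <- trait_matrix(cohort, traitY)
    data_z <- lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")),
                     function(z) {
                       sel <- cohort$zygosity == z
                       V <- cbind(mx[sel, 1], my[sel, 1], mx[sel, 2], my[sel, 2])
                       V[stats::complete.cases(V), , drop = FALSE]
                     })
    n_pairs <- c(MZ = nrow(data_z$MZ), DZ = nrow(data_z$DZ))
    allx <- c(data_z$MZ[, c(1, 3)], data_z$DZ[, c(1, 3)])
    ally <- c(data_z$MZ[, c(2, 4)], data_z$DZ[, c(2, 4)])
    sdx <- stats::sd(allx); pY <- mean(ally)
    rxy0 <- tryCatch(polyserial_cor(allx, ally), error = function(e) 0.2)
    build_par <- function(lam, jit) {
      nonE <- setdiff(comps, "E")
      row1 <- vapply(comps, function(nm) sdx * lam[[nm]][1, 1], numeric(1)) *
        jit[seq_len(nc)]
      row2 <- unlist(lapply(seq_along(nonE), function(i)
        lam[[nonE[i]]][c(2, 4)] / lam$E[2, 2] *
          jit[nc + (2 * i - 1):(2 * i)]))
      c(mean(allx), stats::qnorm(1 - pY), row1, row2,
        lam$E[2, 1] / lam$E[2, 2])
    }
    negll <- function(par) biv_mixed_negll(par, data_z, comps)
    n_par <- 2L + 3L * nc - 1L
  }
  if (any(n_pairs < 3)) stop("fewer than 3 complete pairs in a zygosity group")

  rxy0 <- min(max(rxy0, -0.9), 0.9)
  fits <- with_seed(derive_seed(seed, 10L), {
    lapply(seq_len(n_starts), function(i) {
      jit <- if (i == 1) rep(1, 3 * nc) else stats::runif(3 * nc, 0.6, 1.4)
      r0 <- if (i <= 2) rxy0 else rxy0 * stats::runif(1, 0.2, 1)
      par0 <- build_par(make_lambda0(r0), jit)
      tryCatch(stats::optim(par0, negll, method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-12)),
               error = function(e) NULL)
    })
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("optimization failed for all starts")
  lls <- vapply(fits, function(f) -f$value, numeric(1))
  best <- fits[[which.max(lls)]]
  converged <- best$convergence == 0 &&
    (length(lls) < 2 || sort(-lls)[2] - min(-lls) < 1e-4)

  par <- best$par
  if (setting == "continuous-continuous") {
    lambda <- lapply(seq_len(nc), function(i) lt2(par[2 + (3 * i - 2):(3 * i)]))
    names(lambda) <- comps
    mu <- par[1:2]; thresholds <- c(NA_real_, NA_real_)
  } else if (setting == "binary-binary") {
    lambda <- raw_to_lambda_binary(par[-(1:2)], comps)
    mu <- c(NA_real_, NA_real_); thresholds <- par[1:2]
  } else {
    lambda <- raw_to_lambda_mixed(par[-(1:2)], comps)
    mu <- c(par[1], NA_real_); thresholds <- c(NA_real_, par[2])
  }
  blocks <- lambda_blocks(lambda)
  W <- Reduce(`+`, blocks)
  fcor <- function(B) {
    if (is.null(B) || B[1, 1] < 1e-6 || B[2, 2] < 1e-6) return(NA_real_)
    B[1, 2] / sqrt(B[1, 1] * B[2, 2])
  }
  rP <- W[1, 2] / sqrt(W[1, 1] * W[2, 2])
  out <- structure(list(
    traits = if (swapped) c(traitY, traitX) else c(traitX, traitY),
    internal_order = c(traitX, traitY),
    family = family, setting = setting,
    lambda = lambda, mu = mu, thresholds = thresholds,
    rG = fcor(blocks$A), rE = fcor(blocks$E),
    rP = rP,
    genetic_share = if (abs(rP) > 1e-6) blocks$A[1, 2] / W[1, 2] else NA_real_,
    components = do.call(rbind, lapply(stats::setNames(comps, comps),
                                       function(nm) diag(blocks[[nm]]) / diag(W))),
    loglik = -best$value, n_params = n_par,
    aic = 2 * n_par + 2 * best$value,
    n_pairs = n_pairs, converged = converged),
    class = "bivariate_fit")
  if (!is.null(mid)) out[[paste0("r", mid)]] <- fcor(blocks[[mid]])
  if (is.na(out$rG))
    out$rG_note <- paste("genetic correlation undefined: at least one trait",
                         "has a vanishing additive-genetic variance")
  out
}

#' @export
print.bivariate_fit <- function(x, ...) {
  mid <- switch(x$family, ACE = "C", ADE = "D", AE = NULL)
  cat(sprintf("Bivariate %s Cholesky fit: %s ~ %s (%s)\n", x$family,
              x$traits[1], x$traits[2], x$setting))
  midtxt <- if (is.null(mid)) "" else
    sprintf(", r%s = %s", mid, fmt_or_na(x[[paste0("r", mid)]]))
  cat(sprintf("  rG = %s%s, rE = %s\n",
              fmt_or_na(x$rG), midtxt, fmt_or_na(x$rE)))
  cat(sprintf("  rP = %.3f, genetic share of rP = %s\n", x$rP,
              fmt_or_na(x$genetic_share)))
  cat(sprintf("  logLik = %.3f, AIC = %.3f\n", x$loglik, x$aic))
  if (!x$converged) cat("  WARNING: convergence not confirmed\n")
  if (!is.null(x$rG_note)) cat("  NOTE:", x$rG_note, "\n")
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)

#' Decompose the phenotypic correlation by source
#'
#' The within-person cross-trait covariance is the sum of the A, C (or D)
#' and E cross-trait covariances; dividing by the total gives the share of
#' the phenotypic correlation mediated by each source (pleiotropy for A).
#'
#' @param fit a \code{\link{fit_bivariate}} result.
#' @return named numeric vector of shares summing to 1.
#' @export
phenotypic_decomposition <- function(fit) {
  stopifnot(inherits(fit, "bivariate_fit"))
  if (abs(fit$rP) <= 1e-6)
    stop("phenotypic correlation is (numerically) zero: decomposition undefined")
  blocks <- lambda_blocks(fit$lambda)
  tot <- Reduce(`+`, blocks)[1, 2]
  out <- vapply(blocks, function(B) B[1, 2] / tot, numeric(1))
  names(out) <- paste0(tolower(names(blocks)), "_share")
  out
}

# ---- direction of causation -------------------------------------------------

doc_sigma <- function(par, zygosity) {
  # par: aX, eX, aY, eY, beta for the model X -> Y
  aX <- par[1]; eX <- par[2]; aY <- par[3]; eY <- par[4]; b <- par[5]
  r <- zyg_weights(zygosity)[["r"]]
  vX <- aX^2 + eX^2
  cX <- r * aX^2
  vY <- b^2 * vX + aY^2 + eY^2
  cY <- b^2 * cX + r * aY^2
  cXY <- b * vX       # within person
  cXxY <- b * cX      # cross twin
  M <- matrix(c(vX, cXY, cX, cXxY,
                cXY, vY, cXxY, cY,
                cX, cXxY, vX, cXY,
                cXxY, cY, cXY, vY), 4, 4)
  M
}

doc_negll <- function(par, st, flip) {
  mu <- par[1:2]
  ll <- 0
  for (z in c("MZ", "DZ")) {
    S <- doc_sigma(par[3:7], z)
    if (flip) {
      perm <- c(2, 1, 4, 3)   # model Y -> X expressed on (X1,Y1,X2,Y2)
      S <- S[perm, perm]
    }
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Sinv <- chol2inv(ch)
    d <- st[[z]]$m - c(mu, mu)
    ll <- ll - st[[z]]$n / 2 *
      (4 * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(Sinv * st[[z]]$Sc) +
         drop(t(d) %*% Sinv %*% d))
  }
  -ll
}

#' Direction-of-causation comparison for two continuous traits
#'
#' Fits two causal twin models by maximum likelihood: X causes Y (the
#' cross-twin cross-trait covariance is constrained to \eqn{\beta} times
#' X's own cross-twin covariance pattern) and Y causes X, each with
#' trait-specific additive-genetic and non-shared residual structure only.
#' The comparison is informative when the traits have clearly different
#' variance-component structures; when they are near-identical the two
#' models fit almost equally well and a warning is issued.
#'
#' @param cohort a \code{\link{twin_cohort}} with two continuous traits.
#' @param traitX,traitY trait names.
#' @param margin AIC difference below which the directions are declared
#'   indistinguishable.
#' @param seed start-jitter seed.
#' @return object of class \code{doc_result}: both fits (parameters, loglik,
#'   AIC) and \code{preferred} in \code{\{"XtoY", "YtoX",
#'   "indistinguishable"\}}.
#' @export
fit_direction_of_causation <- function(cohort, traitX, traitY, margin = 2,
                                       seed = 1L) {
  if (trait_kind(cohort, traitX) != "continuous" ||
      trait_kind(cohort, traitY) != "continuous")
    stop("the direction-of-causation comparison is implemented for ",
         "continuous trait pairs")
  st <- biv_suffstats(cohort, traitX, traitY)
  fit_dir <- function(flip) {
    sdx <- sqrt(st$MZ$Sc[1, 1]); sdy <- sqrt(st$MZ$Sc[2, 2])
    if (flip) { tmp <- sdx; sdx <- sdy; sdy <- tmp }
    starts <- with_seed(derive_seed(seed, 11L + flip), {
      lapply(1:3, function(i) {
        j <- if (i == 1) rep(1, 5) else stats::runif(5, 0.5, 1.5)
        c(st$MZ$m[1:2],
          c(sdx * 0.7, sdx * 0.7, sdy * 0.7, sdy * 0.7, 0.1) * j)
      })
    })
    fits <- lapply(starts, function(p0)
      tryCatch(stats::optim(p0, doc_negll, st = st, flip = flip,
                            method = "BFGS",
                            control = list(maxit = 2000, reltol = 1e-12)),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    best <- fits[[which.max(vapply(fits, function(f) -f$value, numeric(1)))]]
    list(par = stats::setNames(
      c(best$par[1:2], abs(best$par[3:6]), best$par[7]),
      c("muX", "muY", "a_cause", "e_cause", "a_effect", "e_effect", "beta")),
      loglik = -best$value, aic = 2 * 7 + 2 * best$value,
      converged = best$convergence == 0)
  }
  fXY <- fit_dir(FALSE)
  fYX <- fit_dir(TRUE)
  # identifiability depends on the traits having different structures
  h2 <- function(p) p["a_cause"]^2 / (p["a_cause"]^2 + p["e_cause"]^2)
  if (abs(h2(fXY$par) - h2(fYX$par)) < 0.05)
    warning("the two traits have near-identical variance structures; ",
            "the direction of causation is weakly identified")
  d <- fYX$aic - fXY$aic
  preferred <- if (abs(d) < margin) "indistinguishable"
  else if (d > 0) "XtoY" else "YtoX"
  structure(list(traitX = traitX, traitY = traitY,
                 fit_XtoY = fXY, fit_YtoX = fYX,
                 delta_aic = d, margin = margin, preferred = preferred),
            class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf("Direction of causation: %s vs %s\n", x$traitX, x$traitY))
  cat(sprintf("  %s -> %s: logLik %.3f, AIC %.3f (beta = %.3f)\n",
              x$traitX, x$traitY, x$fit_XtoY$loglik, x$fit_XtoY$aic,
              x$fit_XtoY$par["beta"]))
  cat(sprintf("  %s -> %s: logLik %.3f, AIC %.3f (beta = %.3f)\n",
              x$traitY, x$traitX, x$fit_YtoX$loglik, x$fit_YtoX$aic,
              x$fit_YtoX$par["beta"]))
  cat(sprintf("  preferred: %s (delta AIC %.2f, margin %.1f)\n",
              x$preferred, x$delta_aic, x$margin))
  invisible(x)
}
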