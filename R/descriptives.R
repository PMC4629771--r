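#' Concordance table for a binary trait
#'
#' Partitions the complete pairs of each zygosity group into concordant
#' affected (both twins affected), discordant (exactly one affected) and
#' concordant unaffected cells -- the sufficient statistic for all binary
#' descriptives and for the liability-threshold likelihood.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait binary trait name.
#' @return object of class \code{concordance_table}: a data frame with one
#'   row per zygosity and columns \code{n_concordant}, \code{n_discordant},
#'   \code{n_unaffected}.
#' @export
concordance_counts <- function(cohort, trait) {
  if (trait_kind(cohort, trait) != "binary")
    stop("concordance counts require a binary trait")
  cohort <- complete_pairs(cohort, trait)
  m <- trait_matrix(cohort, trait)
  s <- m[, 1] + m[, 2]
  out <- do.call(rbind, lapply(c("MZ", "DZ"), function(z) {
    sz <- s[cohort$zygosity == z]
    data.frame(zygosity = z,
               n_concordant = sum(sz == 2L),
               n_discordant = sum(sz == 1L),
               n_unaffected = sum(sz == 0L),
               stringsAsFactors = FALSE)
  }))
  structure(out, trait = trait, class = c("concordance_table", "data.frame"))
}

#' Probandwise concordance rate
#'
#' \eqn{2C / (2C + D)} where \eqn{C} is the number of concordant affected and
#' \eqn{D} the number of discordant pairs: the probability that a co-twin is
#' affected given an affected index twin. (These count symbols are unrelated
#' to the variance components C and D.)
#'
#' @param table a \code{\link{concordance_counts}} result, or a list/row with
#'   fields \code{n_concordant}, \code{n_discordant}.
#' @param zygosity "MZ" or "DZ" (required when \code{table} covers both).
#' @return rate in \code{[0, 1]}.
#' @export
probandwise_concordance <- function(table, zygosity = NULL) {
  if (inherits(table, "concordance_table")) {
    if (is.null(zygosity)) stop("zygosity must be given")
    row <- table[table$zygosity == zygosity, ]
    if (nrow(row) != 1) stop("unknown zygosity: ", zygosity)
  } else row <- table
  C <- row$n_concordant; D <- row$n_discordant
  if (2 * C + D <= 0)
    stop("probandwise concordance undefined: no affected twins")
  2 * C / (2 * C + D)
}

#' Ratio of MZ to DZ concordance rates
#'
#' A ratio near 2 is the classical signature of additive genetic influence;
#' well above 2 suggests non-additive genetic effects and below 2 a role of
#' shared environment.
#'
#' @param mz_rate,dz_rate probandwise concordance rates.
#' @return \code{mz_rate / dz_rate}.
#' @export
concordance_ratio <- function(mz_rate, dz_rate) {
  if (dz_rate <= 0) stop("DZ concordance rate must be positive")
  mz_rate / dz_rate
}

# double-entry correlation of an n x 2 matrix of pair values
double_entry_cor <- function(m) {
  stats::cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
}

#' Intraclass (twin-pair) correlation of a continuous trait
#'
#' Computed per zygosity by double entry -- each pair contributes both
#' orderings -- which makes the estimate exactly invariant to twin labels
#' and identical to the cross-twin covariance standardized by the pooled
#' variance. The confidence interval is a seeded percentile bootstrap over
#' pairs.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait continuous trait name.
#' @param conf level of the bootstrap interval.
#' @param n_boot bootstrap replicates (0 suppresses the interval).
#' @param seed bootstrap seed.
#' @return data frame with one row per zygosity: \code{r}, \code{lower},
#'   \code{upper}, \code{n_pairs}.
#' @export
intraclass_correlation <- function(cohort, trait, conf = 0.95,
                                   n_boot = 1000L, seed = 1L) {
  if (trait_kind(cohort, trait) != "continuous")
    stop("intraclass correlation requires a continuous trait")
  cohort <- complete_pairs(cohort, trait)
  m <- trait_matrix(cohort, trait)
  out <- lapply(c("MZ", "DZ"), function(z) {
    mz <- m[cohort$zygosity == z, , drop = FALSE]
    if (nrow(mz) < 3)
      stop("fewer than 3 complete ", z, " pairs for trait ", trait)
    r <- double_entry_cor(mz)
    lo <- up <- NA_real_
    if (n_boot > 0) {
      bs <- with_seed(derive_seed(seed, 6L), {
        vapply(seq_len(n_boot), function(i) {
          idx <- sample.int(nrow(mz), replace = TRUE)
          double_entry_cor(mz[idx, , drop = FALSE])
        }, numeric(1))
      })
      q <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                           na.rm = TRUE, names = FALSE)
      lo <- q[1]; up <- q[2]
    }
    data.frame(zygosity = z, r = r, lower = lo, upper = up,
               n_pairs = nrow(mz), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# negative log-likelihood of (C, D, U) counts under equal thresholds
tetra_negll <- function(par, C, D, U) {
  rho <- tanh(par[1]); t <- par[2]
  p <- pair_cell_probs(t, rho)
  -(C * log(p["p11"]) + D * log(2 * p["p10"]) + U * log(p["p00"]))
}

#' Tetrachoric correlation of a twin pair's binary trait
#'
#' Maximum-likelihood correlation of the latent bivariate standard-normal
#' liabilities, with a single threshold shared by both twins (twins are
#' exchangeable). The likelihood is the multinomial over the concordant
#' affected / discordant / concordant unaffected cells, whose probabilities
#' are orthant probabilities of the bivariate normal. The correlation is
#' optimized on the Fisher-z scale so the estimate stays inside (-1, 1);
#' |rho| > 0.999 is flagged as a boundary solution.
#'
#' @param x either a \code{\link{concordance_counts}} row (give
#'   \code{zygosity}), a named vector \code{c(C=, D=, U=)}, or a 2x2 matrix
#'   of cross-twin counts (rows twin 1 affected/unaffected, columns twin 2),
#'   which is symmetrized by double entry.
#' @param zygosity row selector when \code{x} is a concordance table.
#' @param conf,n_boot,seed percentile-bootstrap interval settings
#'   (\code{n_boot = 0} suppresses it).
#' @return object of class \code{liability_cor}: list with \code{rho},
#'   \code{threshold}, \code{prevalence}, \code{ci}, \code{n_pairs},
#'   \code{loglik}, \code{boundary}.
#' @export
tetrachoric <- function(x, zygosity = NULL, conf = 0.95, n_boot = 1000L,
                        seed = 1L) {
  if (inherits(x, "concordance_table")) {
    row <- x[x$zygosity == zygosity, ]
    if (nrow(row) != 1) stop("unknown zygosity: ", zygosity)
    counts <- c(C = row$n_concordant, D = row$n_discordant,
                U = row$n_unaffected)
  } else if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    counts <- c(C = x[1, 1], D = x[1, 2] + x[2, 1], U = x[2, 2])
  } else {
    counts <- c(C = x[["C"]], D = x[["D"]], U = x[["U"]])
  }
  est <- tetra_fit(counts)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && !est$boundary) {
    n <- sum(counts)
    probs <- counts / n
    bs <- with_seed(derive_seed(seed, 7L), {
      draws <- stats::rmultinom(n_boot, n, probs)
      apply(draws, 2, function(cc) {
        cc <- as.vector(cc)
        f <- try(tetra_fit(c(C = cc[1], D = cc[2], U = cc[3])), silent = TRUE)
        if (inherits(f, "try-error")) NA_real_ else f$rho
      })
    })
    ci <- stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  structure(list(rho = est$rho, threshold = est$threshold,
                 prevalence = stats::pnorm(est$threshold, lower.tail = FALSE),
                 ci = ci, n_pairs = sum(counts), loglik = est$loglik,
                 boundary = est$boundary),
            class = "liability_cor")
}

tetra_fit <- function(counts) {
  C <- counts[["C"]]; D <- counts[["D"]]; U <- counts[["U"]]
  n <- C + D + U
  if (n == 0) stop("empty concordance table")
  prev <- (2 * C + D) / (2 * n)
  if (prev <= 0 || prev >= 1)
    stop("degenerate margin (prevalence ", prev, "): ",
         "liability correlation is at the boundary; all pairs are ",
         if (prev <= 0) "unaffected" else "affected")
  t0 <- stats::qnorm(1 - prev)
  start <- c(atanh(0.5), t0)
  opt <- stats::optim(start, tetra_negll, C = C, D = D, U = U,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  rho <- tanh(opt$par[1])
  list(rho = rho, threshold = opt$par[2], loglik = -opt$value,
       boundary = abs(rho) > 0.999)
}

#' @export
print.liability_cor <- function(x, ...) {
  cat(sprintf("Liability-scale correlation: rho = %.4f (threshold %.4f, prevalence %.4f)\n",
              x$rho, x$threshold, x$prevalence))
  if (!anyNA(x$ci))
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f], n = %d pairs\n",
                x$ci[1], x$ci[2], x$n_pairs))
  if (x$boundary) cat("  NOTE: boundary solution (|rho| > 0.999)\n")
  invisible(x)
}

# two-step polychoric for a cross-classified 2x2 count table with
# potentially different margins (thresholds from margins, rho by ML)
polychoric_2x2 <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p1 <- (n11 + n10) / n   # margin of variable 1
  p2 <- (n11 + n01) / n
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("degenerate margin in 2x2 table")
  t1 <- stats::qnorm(1 - p1); t2 <- stats::qnorm(1 - p2)
  nll <- function(z) {
    rho <- tanh(z)
    p11 <- pbvn(-t1, -t2, rho)
    p10 <- max(p1 - p11, 1e-300)
    p01 <- max(p2 - p11, 1e-300)
    p00 <- max(1 - p1 - p2 + p11, 1e-300)
    -(n11 * log(max(p11, 1e-300)) + n10 * log(p10) +
        n01 * log(p01) + n00 * log(p00))
  }
  opt <- stats::optimize(nll, c(-6, 6))
  tanh(opt$minimum)
}

# two-step polyserial correlation: x continuous, y binary (threshold from
# the margin, rho by per-observation ML)
polyserial_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  p <- mean(y)
  if (p <= 0 || p >= 1) stop("degenerate binary margin")
  t <- stats::qnorm(1 - p)
  xs <- (x - mean(x)) / stats::sd(x)
  nll <- function(z) {
    rho <- tanh(z)
    s <- sqrt(max(1 - rho^2, 1e-12))
    pa <- stats::pnorm((t - rho * xs) / s, lower.tail = FALSE)
    pa <- pmin(pmax(pa, 1e-12), 1 - 1e-12)
    -sum(ifelse(y == 1, log(pa), log(1 - pa)))
  }
  opt <- stats::optimize(nll, c(-6, 6))
  tanh(opt$minimum)
}

#' Cross-twin cross-trait correlation matrices
#'
#' For each zygosity group, the symmetric matrix whose diagonal holds the
#' twin-pair correlation of each trait (double-entry intraclass for
#' continuous traits, tetrachoric for binary traits) and whose off-diagonal
#' entries hold the cross-twin cross-trait correlation (trait i on one twin
#' against trait j on the co-twin, double-entered). A larger MZ than DZ
#' cross-trait entry indicates shared genetic variance between the traits.
#' Binary-binary entries are polychoric, mixed entries polyserial, both on
#' the liability scale.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param traits character vector of at least two trait names.
#' @return named list with matrices \code{MZ} and \code{DZ}.
#' @export
cross_twin_cross_trait_matrix <- function(cohort, traits) {
  stopifnot(length(traits) >= 2)
  sch <- trait_schema(cohort)
  if (!all(traits %in% names(sch))) stop("unknown trait(s)")
  out <- lapply(c("MZ", "DZ"), function(z) {
    sub <- subset_cohort(cohort, cohort$zygosity == z)
    k <- length(traits)
    M <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
    for (i in seq_len(k)) for (j in seq_len(i)) {
      mi <- trait_matrix(sub, traits[i])
      mj <- trait_matrix(sub, traits[j])
      # double entry: trait i on twin 1 vs trait j on twin 2, both orders
      xi <- c(mi[, 1], mi[, 2]); xj <- c(mj[, 2], mj[, 1])
      ok <- !is.na(xi) & !is.na(xj)
      if (sum(ok) < 3)
        stop("fewer than 3 complete observations for cell (",
             traits[i], ", ", traits[j], ") in ", z, " pairs")
      ki <- sch[[traits[i]]]; kj <- sch[[traits[j]]]
      r <- if (ki == "continuous" && kj == "continuous") {
        stats::cor(xi[ok], xj[ok])
      } else if (ki == "binary" && kj == "binary") {
        yi <- xi[ok]; yj <- xj[ok]
        polychoric_2x2(sum(yi == 1 & yj == 1), sum(yi == 1 & yj == 0),
                       sum(yi == 0 & yj == 1), sum(yi == 0 & yj == 0))
      } else {
        if (ki == "binary") polyserial_cor(xj[ok], xi[ok])
        else polyserial_cor(xi[ok], xj[ok])
      }
      M[i, j] <- M[j, i] <- r
    }
    M
  })
  names(out) <- c("MZ", "DZ")
  out
}
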