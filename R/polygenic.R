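# Variance-components heritability: y ~ N(X beta, sigma2_g * K + sigma2_e * I)
# with K a relatedness matrix on the 2*Phi scale. A single symmetric
# eigendecomposition K = U D U' rotates the model to independent errors with
# variances sigma2_t * (h2 * d_i + 1 - h2); beta and the total variance are
# profiled out, leaving a 1-D likelihood in h2 on [0, 1].

# profile log-likelihood machinery on rotated data
profile_ll <- function(h2, ytil, Xtil, d, reml = FALSE) {
  n <- length(ytil)
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  XtWX <- crossprod(Xtil, Xtil * w)
  XtWy <- crossprod(Xtil, ytil * w)
  b <- solve(XtWX, XtWy)
  r <- ytil - Xtil %*% b
  rss <- sum(w * r^2)
  if (reml) {
    p <- ncol(Xtil)
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  }
  list(ll = as.numeric(ll), s2 = s2, beta = drop(b), XtWX = XtWX)
}

# maximize over h2 in [0,1]; returns optimum details
optimize_h2 <- function(ytil, Xtil, d, reml = FALSE, tol = 1e-8) {
  f <- function(h) profile_ll(h, ytil, Xtil, d, reml)$ll
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = tol)
  cand <- c(0, opt$maximum, 1)
  lls <- c(f(0), opt$objective, f(1))
  best <- which.max(lls)
  h2 <- cand[best]
  boundary <- best != 2 || h2 < 1e-6 || h2 > 1 - 1e-6
  if (h2 < 1e-6) h2 <- 0
  if (h2 > 1 - 1e-6) h2 <- 1
  list(h2 = h2, ll = max(lls), boundary = boundary, f = f)
}

#' Fit the polygenic variance-components model
#'
#' Maximum-likelihood estimation of narrow-sense heritability
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` under
#' `y ~ N(X beta, sigma2_g K + sigma2_e I)`. The kinship matrix is
#' eigendecomposed once; the likelihood is then maximized over `h2` on
#' `[0, 1]` by Brent search with the fixed effects and the total variance
#' profiled out, so convergence needs no starting values. ML is the
#' default (the likelihood-ratio test below is ML-based, as in SOLAR);
#' REML is available via `reml = TRUE`.
#'
#' The standard error of `h2` comes from the curvature of the profile
#' log-likelihood at the optimum (numerical second derivative); at a
#' boundary optimum (`h2` exactly 0 or 1) the delta method is invalid and
#' the SE is reported as `NA` with `boundary = TRUE`.
#'
#' The kinship matrix is normalized internally to unit mean diagonal, so
#' fits (`h2`, the LRT and its p-value, and the reported variance
#' components) are invariant to a global rescaling of K — the Phi vs 2*Phi
#' scale choice does not matter. Eigenvalues of
#' indefinite (postprocessed empirical) matrices are clipped at
#' `clip_tol`; the number of clipped eigenvalues is reported. A kinship
#' matrix numerically equal to the identity carries no relatedness signal
#' and raises an unidentifiability error.
#'
#' @param y named numeric trait vector (typically from [prepare_trait()]).
#' @param k a `kinship_matrix` covering the samples in `y`.
#' @param x optional fixed-effect design matrix (rownames = sample ids);
#'   default intercept only, appropriate for pre-residualized traits.
#' @param eig optional precomputed `eigen(kin_values(k)[ids, ids],
#'   symmetric = TRUE)` for the aligned samples — pass this when fitting
#'   many traits on one kinship matrix.
#' @param reml use REML instead of ML.
#' @param clip_tol eigenvalue floor for indefinite matrices.
#' @return An object of class `polygenic_fit`: `h2, h2_se, sigma2_g,
#'   sigma2_e, loglik_full, loglik_null, lambda_lrt, p_value, n,
#'   kinship_source, boundary, n_clipped`.
#' @export
fit_polygenic <- function(y, k, x = NULL, eig = NULL, reml = FALSE,
                          clip_tol = 1e-8) {
  ids <- intersect(names(y)[!is.na(y)], kin_ids(k))
  n <- length(ids)
  if (n < 2) stop("fewer than 2 samples shared between trait and kinship")
  if (n < 30) warning("only ", n, " samples; h2 estimates will be unstable")
  yv <- y[ids]
  if (is.null(eig)) {
    kv <- kin_values(k)[ids, ids]
    if (max(abs(kv - diag(n))) < 1e-8)
      stop(errorCondition(
        "kinship matrix is numerically the identity: no relatedness signal, h2 is unidentifiable",
        class = c("kinherit_unidentifiable_error", "error")))
    if (!all(is.finite(kv))) stop("kinship matrix has non-finite entries")
    eig <- eigen(kv, symmetric = TRUE)
  }
  # normalize to unit mean diagonal (trace/n) so h2 is invariant to a global
  # rescaling of K — the Phi vs 2*Phi ambiguity is absorbed here; variance
  # components are reported on this normalized scale, so
  # h2 = sigma2_g / (sigma2_g + sigma2_e) holds exactly
  tr_scale <- sum(eig$values) / n
  d <- eig$values / tr_scale
  n_clip <- sum(d < clip_tol)
  d <- pmax(d, clip_tol)
  X <- if (is.null(x)) matrix(1, n, 1, dimnames = list(ids, "(Intercept)")) else {
    if (!is.null(rownames(x))) x[ids, , drop = FALSE] else x
  }
  ytil <- drop(crossprod(eig$vectors, yv))
  Xtil <- crossprod(eig$vectors, X)

  opt <- optimize_h2(ytil, Xtil, d, reml)
  at <- profile_ll(opt$h2, ytil, Xtil, d, reml)
  ll_null <- profile_ll(0, ytil, Xtil, d, reml)$ll
  s2_tot <- at$s2
  lam <- max(0, 2 * (opt$ll - ll_null))
  p <- if (lam <= 0) 1 else 0.5 * stats::pchisq(lam, df = 1, lower.tail = FALSE)

  se <- NA_real_
  if (!opt$boundary) {
    h <- min(1e-3, opt$h2 / 2, (1 - opt$h2) / 2)
    d2 <- (opt$f(opt$h2 + h) - 2 * opt$ll + opt$f(opt$h2 - h)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }

  structure(list(h2 = opt$h2, h2_se = se,
                 sigma2_g = opt$h2 * s2_tot, sigma2_e = (1 - opt$h2) * s2_tot,
                 loglik_full = opt$ll, loglik_null = ll_null,
                 lambda_lrt = lam, p_value = p, n = n,
                 kinship_source = k$source, boundary = opt$boundary,
                 n_clipped = n_clip, reml = reml),
            class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("<polygenic_fit> h2 = %.3f (SE %s), p = %.3g, n = %d [%s kinship%s]\n",
              x$h2, ifelse(is.na(x$h2_se), "NA", sprintf("%.3f", x$h2_se)),
              x$p_value, x$n, x$kinship_source,
              if (x$boundary) ", boundary" else ""))
  cat(sprintf("  sigma2_g = %.4f, sigma2_e = %.4f, logL = %.2f (null %.2f)\n",
              x$sigma2_g, x$sigma2_e, x$loglik_full, x$loglik_null))
  invisible(x)
}

#' Boundary-corrected likelihood-ratio test for h2 > 0
#'
#' The null hypothesis `sigma2_g = 0` puts the parameter on the boundary of
#' its space, so the LRT statistic is distributed as an equal mixture of a
#' point mass at zero and chi-square with 1 df. The p-value is
#' `0.5 * P(chisq_1 >= Lambda)` for `Lambda > 0`, and 1 when `Lambda = 0`
#' (the point-mass convention: no evidence at all).
#'
#' @param fit a `polygenic_fit` (or a nonnegative statistic `Lambda`).
#' @return p-value in `(0, 1]`.
#' @export
lrt_h2 <- function(fit) {
  lam <- if (inherits(fit, "polygenic_fit")) fit$lambda_lrt else fit
  lam <- max(0, lam)
  if (lam == 0) 1 else 0.5 * stats::pchisq(lam, df = 1, lower.tail = FALSE)
}

#' Heritability table for several traits and kinship matrices
#'
#' Convenience wrapper producing one row per (trait, kinship) combination:
#' the shape of a standard heritability results table (phenotype, kinship
#' source, h2, p, SE, n).
#'
#' @param traits named list of trait vectors.
#' @param kinships named list of `kinship_matrix` objects.
#' @param ... passed to [fit_polygenic()].
#' @return Data frame with columns `phenotype, kinship, h2, p_value, h2_se,
#'   n`.
#' @export
heritability_table <- function(traits, kinships, ...) {
  rows <- list()
  for (tn in names(traits)) for (kn in names(kinships)) {
    f <- fit_polygenic(traits[[tn]], kinships[[kn]], ...)
    rows[[length(rows) + 1L]] <- data.frame(
      phenotype = tn, kinship = kn, h2 = f$h2, p_value = f$p_value,
      h2_se = f$h2_se, n = f$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
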