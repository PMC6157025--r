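# Independent oracles and shared fixtures. The dense-matrix likelihood and
# the lm()-based LRT are written without reference to the package's
# eigendecomposition path so they can serve as cross-checks.

# Gaussian profile log-likelihood via explicit V = h2*K + (1-h2)*I inversion
oracle_ll <- function(h2, y, K, X = matrix(1, length(y), 1)) {
  n <- length(y)
  V <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V)
  b <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% y))
  r <- y - X %*% b
  s2 <- drop(crossprod(r, Vi %*% r)) / n
  as.numeric(-0.5 * (n * log(2 * pi * s2) + determinant(V)$modulus + n))
}

oracle_fit_h2 <- function(y, K, X = matrix(1, length(y), 1)) {
  opt <- stats::optimize(function(h) oracle_ll(h, y, K, X), c(0, 1),
                         maximum = TRUE, tol = 1e-8)
  ll0 <- oracle_ll(0, y, K, X)
  ll1 <- oracle_ll(1 - 1e-12, y, K, X)
  cand <- rbind(c(0, ll0), c(opt$maximum, opt$objective), c(1, ll1))
  cand[which.max(cand[, 2]), ]
}

# ordinary-regression likelihood-ratio p-value for one dosage covariate
ols_lrt_p <- function(y, d) {
  lam <- 2 * (stats::logLik(stats::lm(y ~ d)) - stats::logLik(stats::lm(y ~ 1)))
  stats::pchisq(as.numeric(lam), df = 1, lower.tail = FALSE)
}

# random valid pedigree: parents always precede children, marriages may be
# consanguineous (exercises inbreeding in the kinship recursion)
random_pedigree <- function(seed, n_max = 20) {
  set.seed(seed)
  id <- c("I1", "I2"); fa <- c(NA, NA); mo <- c(NA, NA)
  sx <- c("male", "female")
  k <- 2L
  while (k < n_max) {
    males <- which(sx == "male"); females <- which(sx == "female")
    k <- k + 1L
    id[k] <- paste0("I", k)
    if (stats::runif(1) < 0.25 || !length(males) || !length(females)) {
      fa[k] <- NA; mo[k] <- NA
    } else {
      fa[k] <- id[males[sample.int(length(males), 1)]]
      mo[k] <- id[females[sample.int(length(females), 1)]]
    }
    sx[k] <- sample(c("male", "female"), 1)
  }
  pedigree(rep("R", k), id, fa, mo, sx)
}

# pedigree of unrelated individuals (founder couples), for i.i.d. samples
founders_only_pedigree <- function(n) {
  fam <- rep(sprintf("U%04d", seq_len(ceiling(n / 2))), each = 2)[seq_len(n)]
  pedigree(fam, sprintf("%s_I%d", fam, rep(1:2, length.out = n)),
           rep(NA, n), rep(NA, n), rep(c("male", "female"), length.out = n))
}

# shared medium-size study, built once per test run
.fixtures <- new.env(parent = emptyenv())
shared_study <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_study(sim_config(n_families = 20,
                                                 n_snps = 3000,
                                                 true_h2 = 0.5, seed = 42))
  }
  .fixtures$study
}
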