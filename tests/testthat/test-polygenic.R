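test_that("eigendecomposition likelihood agrees with a dense-inversion oracle", {
  ped <- random_pedigree(17, n_max = 20)
  K <- kin_values(pedigree_kinship(ped))
  n <- nrow(K)
  set.seed(18)
  L <- t(chol(K + diag(1e-8, n)))
  y <- setNames(drop(sqrt(0.6) * L %*% rnorm(n) + sqrt(0.4) * rnorm(n)),
                rownames(K))
  fit <- suppressWarnings(fit_polygenic(y, pedigree_kinship(ped)))  # small n
  # oracle on the unit-mean-diagonal scale the fit reports h2 on
  ora <- oracle_fit_h2(y[rownames(K)], K / mean(diag(K)))
  expect_equal(fit$loglik_full, ora[2], tolerance = 1e-6)
  expect_equal(fit$h2, ora[1], tolerance = 1e-3)
  expect_equal(fit$loglik_null, oracle_ll(0, y[rownames(K)], K / mean(diag(K))),
               tolerance = 1e-6)
  expect_equal(fit$h2, fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e),
               tolerance = 1e-10)
})

test_that("fits are invariant to the kinship scale (Phi vs 2*Phi)", {
  st <- shared_study()
  y <- prepare_trait(st$pheno, "trait", "pre")
  f1 <- fit_polygenic(y, st$kinship)
  k2 <- kinship_matrix(2 * kin_values(st$kinship), source = "pedigree")
  f2 <- fit_polygenic(y, k2)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-5)
  expect_equal(f1$lambda_lrt, f2$lambda_lrt, tolerance = 1e-5)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-6)
  # variance components are reported on the normalized (unit mean diagonal)
  # kinship scale, so they are scale-free too
  expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-4)
})

test_that("null traits give near-zero heritability and nominal rejections", {
  cfg <- sim_config(n_families = 10, n_snps = 10, true_h2 = 0, seed = 51)
  ped <- simulate_pedigree(cfg)
  k <- pedigree_kinship(ped)
  eig <- eigen(kin_values(k), symmetric = TRUE)
  h2 <- p <- numeric(200)
  for (r in 1:200) {
    ph <- simulate_trait(ped, k, cfg, seed = 1000 + r, eig = eig)
    y <- inverse_normal(average_visits(ph, "trait", "pre"))
    f <- fit_polygenic(y, k, eig = eig)
    h2[r] <- f$h2; p[r] <- f$p_value
  }
  expect_lt(median(h2), 0.05)
  expect_gt(mean(p <= 0.05), 0.01)
  expect_lt(mean(p <= 0.05), 0.11)
})

test_that("a pure breeding-value trait is estimated as fully heritable", {
  ped <- simulate_pedigree(sim_config(n_families = 60))
  k <- pedigree_kinship(ped)
  eig <- eigen(kin_values(k), symmetric = TRUE)
  ids <- kin_ids(k)
  h2 <- vapply(1:5, function(s) {
    set.seed(520 + s)
    g <- setNames(drop(eig$vectors %*% (sqrt(pmax(eig$values, 0)) *
                                          rnorm(length(ids)))), ids)
    fit_polygenic(g, k, eig = eig)$h2
  }, numeric(1))
  expect_gte(mean(h2), 0.95)
  expect_gte(min(h2), 0.9)
})

test_that("identity kinship raises an unidentifiability error, boundary flags SE", {
  set.seed(53)
  y <- setNames(rnorm(100), paste0("S", 1:100))
  expect_error(fit_polygenic(y, kinship_matrix(diag(100))),
               class = "kinherit_unidentifiable_error")
  # independent trait on a related sample: h2 often lands on the 0 boundary
  st <- shared_study()
  y2 <- setNames(rnorm(length(kin_ids(st$kinship))), kin_ids(st$kinship))
  f <- fit_polygenic(y2, st$kinship)
  if (f$boundary) expect_true(is.na(f$h2_se))
})

test_that("boundary-corrected LRT p-values follow the half-chi-square mixture", {
  expect_equal(lrt_h2(0), 1)
  expect_equal(lrt_h2(3.841), 0.025, tolerance = 1e-3)
  expect_equal(lrt_h2(-2), 1)  # negative statistics clip to no evidence
  f <- structure(list(lambda_lrt = 3.841), class = "polygenic_fit")
  expect_equal(lrt_h2(f), 0.025, tolerance = 1e-3)
})

test_that("moderate-scale recovery of a known heritability", {
  cfg <- sim_config(n_families = 20, n_snps = 10, true_h2 = 0.5, seed = 55)
  ped <- simulate_pedigree(cfg)
  k <- pedigree_kinship(ped)
  eig <- eigen(kin_values(k), symmetric = TRUE)
  h2 <- vapply(1:30, function(r) {
    ph <- simulate_trait(ped, k, cfg, seed = 2000 + r, eig = eig)
    y <- prepare_trait(ph, "trait", "pre")
    fit_polygenic(y, k, eig = eig)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.5), 3 * sd(h2) / sqrt(30))
})

test_that("REML is accepted and close to ML away from boundaries", {
  st <- shared_study()
  y <- prepare_trait(st$pheno, "trait", "pre")
  fml <- fit_polygenic(y, st$kinship)
  frl <- fit_polygenic(y, st$kinship, reml = TRUE)
  expect_true(frl$reml)
  expect_equal(fml$h2, frl$h2, tolerance = 0.05)
})
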