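#' Genetic relationship matrix (GRM) from SNP dosages
#'
#' Allelic-correlation (VanRaden-type) estimator:
#' `K(i,j) = (1/m) * sum_s (g_is - 2 p_s)(g_js - 2 p_s) / (2 p_s (1 - p_s))`
#' over the `m` SNPs passing the minor-allele-frequency floor. Under random
#' mating the expectation of an off-diagonal entry is 2*Phi for the pair, so
#' the result is directly comparable with [pedigree_kinship()]. Missing
#' dosages are mean-imputed to `2 p_s` (i.e. contribute zero), the standard
#' convention for this estimator.
#'
#' Frequencies default to [allele_frequencies()] computed from the analyzed
#' samples themselves. SNPs with undefined frequency or MAF below `maf_min`
#' are excluded and counted.
#'
#' @param g a `genotype_matrix`.
#' @param freqs optional alternate-allele frequency vector aligned to `g`.
#' @param maf_min minor-allele-frequency floor (default 0.01; avoids
#'   near-zero denominators).
#' @return An object of class `empirical_kinship_report`: list with
#'   `kinship` (an unpostprocessed `kinship_matrix`, source `"empirical"`),
#'   `n_snps_used`, `n_snps_excluded`, `diagonal_summary` (min, max, mean,
#'   sd of the raw diagonal) and `estimator`.
#' @export
grm <- function(g, freqs = NULL, maf_min = 0.01) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  if (length(freqs) != ncol(g$dosages))
    stop("freqs must align with the SNP columns of g")
  maf <- pmin(freqs, 1 - freqs)
  use <- !is.na(maf) & is.finite(maf) & maf >= maf_min
  m <- sum(use)
  if (m == 0) stop("no usable SNPs after the MAF floor")
  d <- g$dosages[, use, drop = FALSE]
  p <- freqs[use]
  z <- sweep(d, 2, 2 * p, "-")
  z[is.na(z)] <- 0                      # mean imputation
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  k <- tcrossprod(z) / m
  dg <- diag(k)
  structure(list(
    kinship = kinship_matrix(k, source = "empirical",
                             meta = list(estimator = "allelic-correlation",
                                         n_snps = m)),
    n_snps_used = m,
    n_snps_excluded = ncol(g$dosages) - m,
    diagonal_summary = c(min = min(dg), max = max(dg), mean = mean(dg),
                         sd = stats::sd(dg)),
    estimator = "allelic-correlation"),
    class = "empirical_kinship_report")
}

#' @export
print.empirical_kinship_report <- function(x, ...) {
  cat(sprintf("<empirical_kinship_report> %s, %d SNPs used (%d excluded)\n",
              x$estimator, x$n_snps_used, x$n_snps_excluded))
  cat(sprintf("  raw diagonal: min %.3f max %.3f mean %.3f sd %.3f\n",
              x$diagonal_summary["min"], x$diagonal_summary["max"],
              x$diagonal_summary["mean"], x$diagonal_summary["sd"]))
  invisible(x)
}

#' Postprocess an empirical kinship matrix
#'
#' Two steps, in this order: (1) every strictly negative off-diagonal entry
#' is set to zero ("removing" a matrix entry is not meaningful, so removal
#' is interpreted as zeroing); (2) each entry is rescaled as
#' `K(i,j) / sqrt(K(i,i) * K(j,j))` so the diagonal equals exactly 1. The
#' per-pair rescaling is what makes a widely spread raw diagonal land on 1;
#' a single global divisor could not. The operation is idempotent and
#' preserves the sign and within-row ordering of off-diagonal entries.
#'
#' Zeroing negatives can make the matrix indefinite; the minimum eigenvalue
#' after postprocessing is recorded in `meta$min_eigenvalue` so downstream
#' model fitting can clip. A non-positive diagonal entry is a data error.
#'
#' @param k a `kinship_matrix` with strictly positive diagonal.
#' @return A postprocessed `kinship_matrix`; `meta$n_negatives_zeroed` and
#'   `meta$min_eigenvalue` record what was done.
#' @export
postprocess_kinship <- function(k) {
  v <- k$values
  dg <- diag(v)
  if (any(dg <= 0))
    stop("non-positive self-relatedness for sample(s): ",
         paste(k$ids[dg <= 0], collapse = ", "))
  neg <- v < 0
  diag(neg) <- FALSE
  n_neg <- sum(neg) / 2
  v[neg] <- 0
  s <- 1 / sqrt(diag(v))
  v <- v * tcrossprod(s)
  diag(v) <- 1
  min_ev <- min(eigen(v, symmetric = TRUE, only.values = TRUE)$values)
  meta <- k$meta
  meta$n_negatives_zeroed <- n_neg
  meta$min_eigenvalue <- min_ev
  kinship_matrix(v, source = k$source, postprocessed = TRUE, meta = meta)
}

#' Compare two kinship matrices over their common samples
#'
#' Quantifies how close an empirical matrix is to a pedigree-derived one
#' (or any other pair): Pearson correlation, RMSE and mean difference of
#' the off-diagonal entries over common pairs, plus per-matrix diagonal
#' summaries (the self-relatedness diagnostic). If a pedigree is supplied,
#' the mean difference is additionally stratified by expected relationship
#' class derived from the pedigree 2*Phi values.
#'
#' @param k1,k2 `kinship_matrix` objects with >= 2 overlapping sample ids.
#' @param ped optional `kin_pedigree` for relationship-class stratification.
#' @return A list of class `kinship_comparison` with elements `n_common`,
#'   `correlation`, `rmse`, `mean_diff`, `diagonal` (2-row summary) and
#'   optionally `by_class`.
#' @export
compare_kinships <- function(k1, k2, ped = NULL) {
  ids <- intersect(k1$ids, k2$ids)
  if (length(ids) < 2) stop("fewer than 2 overlapping samples")
  v1 <- k1$values[ids, ids]; v2 <- k2$values[ids, ids]
  ut <- upper.tri(v1)
  a <- v1[ut]; b <- v2[ut]
  dsum <- function(v) c(min = min(diag(v)), max = max(diag(v)),
                        mean = mean(diag(v)), sd = stats::sd(diag(v)))
  out <- list(n_common = length(ids),
              correlation = stats::cor(a, b),
              rmse = sqrt(mean((a - b)^2)),
              mean_diff = mean(a - b),
              diagonal = rbind(k1 = dsum(v1), k2 = dsum(v2)))
  if (!is.null(ped)) {
    kp <- pedigree_kinship(ped)
    common <- intersect(ids, kp$ids)
    vp <- kp$values[common, common]
    w1 <- v1[common, common][upper.tri(vp)]
    w2 <- v2[common, common][upper.tri(vp)]
    cls <- relationship_degree(vp[upper.tri(vp)] / 2)
    out$by_class <- do.call(rbind, lapply(split(seq_along(cls), cls), function(i)
      data.frame(class = cls[i[1]], n_pairs = length(i),
                 mean_k1 = mean(w1[i]), mean_k2 = mean(w2[i]),
                 mean_diff = mean(w1[i] - w2[i]))))
    rownames(out$by_class) <- NULL
  }
  class(out) <- "kinship_comparison"
  out
}

#' @export
print.kinship_comparison <- function(x, ...) {
  cat(sprintf("<kinship_comparison> %d common samples\n", x$n_common))
  cat(sprintf("  off-diagonal: r = %.4f, RMSE = %.4f, mean diff = %+.4f\n",
              x$correlation, x$rmse, x$mean_diff))
  if (!is.null(x$by_class)) { cat("  by relationship class:\n"); print(x$by_class) }
  invisible(x)
}
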