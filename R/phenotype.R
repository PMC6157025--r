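# Trait preparation: visit averaging, founder-based PCA covariates,
# covariate residualization, rank-based inverse-normal transform.

#' Average visit replicates into a single phase value
#'
#' Each trait is measured at two visits within a phase (pre- or
#' post-intervention). When both are present they are averaged; when only
#' one is, the single measurement is used; when neither is, the value is
#' missing and the sample drops out downstream.
#'
#' Visit columns follow the `<trait>_<phase><visit>` convention
#' (e.g. `tg_pre1`, `tg_pre2`); pass `cols` to override.
#'
#' @param pheno a phenotype data frame with an `id` column.
#' @param trait trait name prefix.
#' @param phase `"pre"` or `"post"`.
#' @param cols optional explicit pair of visit column names.
#' @return Named numeric vector (names = sample ids).
#' @export
average_visits <- function(pheno, trait, phase = c("pre", "post"),
                           cols = NULL) {
  phase <- match.arg(phase)
  if (is.null(cols)) cols <- paste0(trait, "_", phase, 1:2)
  miss <- setdiff(cols, names(pheno))
  if (length(miss)) stop("visit columns not found: ", paste(miss, collapse = ", "))
  v <- as.matrix(pheno[, cols, drop = FALSE])
  out <- rowMeans(v, na.rm = TRUE)
  out[rowSums(!is.na(v)) == 0] <- NA
  names(out) <- pheno$id
  out
}

#' Principal components fit on pedigree founders, projected to all samples
#'
#' Controls for population stratification without letting family structure
#' dominate the PCs: dosages are standardized using founder allele
#' frequencies, the PCA is fit on founders only, and every sample
#' (founder or not) is scored by projecting its standardized dosages onto
#' the founder loadings. Founders' projected scores equal their fit scores
#' by construction. SNPs monomorphic among founders are dropped.
#'
#' @param g a `genotype_matrix` (pruned set recommended).
#' @param ped a `kin_pedigree` identifying the founders.
#' @param n_pcs number of components (default 4).
#' @return Samples x `n_pcs` score matrix (`PC1..PCk`) with sample ids as
#'   rownames; founder loadings in the `rotation` attribute.
#' @export
founder_pca <- function(g, ped, n_pcs = 4) {
  ids <- rownames(g$dosages)
  founders <- intersect(sample_ids(ped)[ped$founder], ids)
  if (length(founders) < n_pcs)
    stop("fewer genotyped founders (", length(founders), ") than requested PCs")
  df <- g$dosages[founders, , drop = FALSE]
  pf <- colMeans(df, na.rm = TRUE) / 2
  poly <- !is.na(pf) & pf > 0 & pf < 1
  std <- function(d) {
    z <- sweep(d[, poly, drop = FALSE], 2, 2 * pf[poly], "-")
    z[is.na(z)] <- 0
    sweep(z, 2, sqrt(2 * pf[poly] * (1 - pf[poly])), "/")
  }
  zf <- std(df)
  pc <- stats::prcomp(zf, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  scores <- std(g$dosages) %*% rot
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  attr(scores, "rotation") <- rot
  attr(scores, "founders") <- founders
  scores
}

# design matrix for the standard covariate model: age, sex and their
# interactions (age*sex, age^2, age^2*sex), center, smoking, PCs 1-4
covariate_design <- function(pheno, covariates) {
  n <- nrow(pheno)
  cols <- list(`(Intercept)` = rep(1, n))
  sex_male <- NULL
  if (any(c("sex", "age_sex", "age2_sex") %in% covariates)) {
    s <- pheno$sex
    sex_male <- if (is.numeric(s)) as.numeric(s) else as.numeric(decode_sex(s) == "male")
  }
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = pheno$age,
      sex = sex_male,
      age_sex = pheno$age * sex_male,
      age2 = pheno$age^2,
      age2_sex = pheno$age^2 * sex_male,
      smoking = if (is.numeric(pheno$smoking)) pheno$smoking else
        as.numeric(factor(pheno$smoking)) - 1,
      center = NULL,  # expanded below
      {
        if (!cv %in% names(pheno)) stop("covariate column not found: ", cv)
        v <- pheno[[cv]]
        if (is.numeric(v)) v else as.numeric(factor(v)) - 1
      })
    if (cv == "center") {
      f <- factor(pheno$center)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0("center", levels(f)[-1])
        for (k in seq_len(ncol(mm))) cols[[colnames(mm)[k]]] <- mm[, k]
      }
    }
  }
  cols <- cols[!vapply(cols, is.null, logical(1))]
  do.call(cbind, cols)
}

#' Default covariate specification
#'
#' Age, sex, their interactions (age x sex, age^2, age^2 x sex), study
#' center, smoking, and founder principal components 1-4. All listed
#' covariates are always included (no significance screening), which keeps
#' the residualization deterministic.
#' @export
default_covariates <- function()
  c("age", "sex", "age_sex", "age2", "age2_sex", "center", "smoking",
    paste0("PC", 1:4))

#' Residualize a trait on covariates
#'
#' Ordinary least-squares residuals of the trait on the covariate design.
#' Only complete cases (trait and all covariates observed) are used; the
#' sample ids and count actually used are recorded. A rank-deficient
#' design is an error naming the collinear columns.
#'
#' @param y named numeric trait vector (names = sample ids).
#' @param pheno phenotype data frame with `id` and the covariate columns
#'   (PC columns may instead be supplied via `pcs`).
#' @param covariates character vector of covariate names (see
#'   [default_covariates()]).
#' @param pcs optional score matrix from [founder_pca()]; its columns are
#'   merged into the design by sample id.
#' @return Named numeric residual vector with attributes `covariates` and
#'   `n`.
#' @export
residualize <- function(y, pheno, covariates = default_covariates(),
                        pcs = NULL) {
  pheno <- as.data.frame(pheno)
  if (!is.null(pcs)) {
    idx <- match(pheno$id, rownames(pcs))
    for (k in colnames(pcs)) pheno[[k]] <- pcs[idx, k]
  }
  covariates <- covariates[covariates %in% c("age", "sex", "age_sex", "age2",
                                             "age2_sex", "center", "smoking") |
                           covariates %in% names(pheno)]
  i <- match(pheno$id, names(y))
  yv <- y[i]
  X <- covariate_design(pheno, covariates)
  cc <- !is.na(yv) & stats::complete.cases(X)
  Xc <- X[cc, , drop = FALSE]
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrx$pivot[(qrx$rank + 1):ncol(Xc)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  r <- qr.resid(qrx, yv[cc])
  names(r) <- pheno$id[cc]
  attr(r, "covariates") <- covariates
  attr(r, "n") <- sum(cc)
  r
}

#' Rank-based inverse-normal transform
#'
#' Maps values to Gaussian quantiles via the Blom offset,
#' `z_i = qnorm((r_i - 0.375) / (n + 0.25))` with average ranks for ties,
#' then standardizes so the result has mean exactly 0 and sample SD exactly
#' 1. The transform is monotone (rank-preserving) and invariant to affine
#' transformations of the input.
#'
#' @param x numeric vector (NAs preserved); at least 3 non-missing values,
#'   not all equal.
#' @return Transformed vector with the same names/length as `x`.
#' @export
inverse_normal <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("inverse_normal needs at least 3 non-missing values")
  v <- x[ok]
  if (max(v) == min(v)) stop("inverse_normal is undefined for a constant vector")
  z <- stats::qnorm((rank(v, ties.method = "average") - 0.375) / (n + 0.25))
  z <- (z - mean(z)) / stats::sd(z)
  out <- x
  out[ok] <- z
  out
}

#' Full trait-preparation pipeline
#'
#' Visit averaging, founder-PC covariates, covariate residualization and
#' inverse-normalization, in that order, yielding an analysis-ready trait
#' on the standard-normal scale.
#'
#' @inheritParams average_visits
#' @inheritParams residualize
#' @return Named numeric vector (mean 0, SD 1 over its `n` samples).
#' @export
prepare_trait <- function(pheno, trait, phase = c("pre", "post"),
                          covariates = default_covariates(), pcs = NULL) {
  y <- average_visits(pheno, trait, phase)
  r <- residualize(y, pheno, covariates, pcs = pcs)
  out <- inverse_normal(r)
  attributes(out) <- attributes(r)
  names(out) <- names(r)
  out
}
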