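# Study simulator: three-generation pedigrees, gene-dropped SNP genotypes
# and traits with specified heritability, covariate effects, optional QTL
# and visit-level replicates. Every generator is a deterministic function
# of its configuration and seed, which makes the simulator usable as a
# Monte-Carlo oracle for the analysis modules.

#' Simulation configuration
#'
#' Defaults emulate a large family-based lipid study: 60 three-generation
#' families (two grandparents, three adult children with married-in
#' spouses, two grandchildren per couple: 14 members, ~840 individuals
#' total), 10,000 independent biallelic SNPs with uniform allele
#' frequencies, and a lipid-like trait measured at two pre- and two
#' post-intervention visits with modest covariate effects.
#'
#' `true_h2` is the narrow-sense heritability of the phase-averaged
#' phenotype: the additive genetic variance is `true_h2 * (1 - q)` (q the
#' optional QTL variance fraction) and the individual environmental
#' variance is chosen so that after averaging the two visit replicates
#' (each with independent noise `visit_noise_sd`) the genetic fraction is
#' exactly `true_h2`. This requires
#' `(1 - true_h2) * (1 - q) >= visit_noise_sd^2 / 2`.
#'
#' @param n_families number of families.
#' @param n_children adult children per founding couple.
#' @param n_grandchildren grandchildren per child couple.
#' @param n_snps number of SNPs.
#' @param maf_range uniform range for alternate-allele frequencies,
#'   within `(0, 0.5]`.
#' @param true_h2 heritability of the phase-averaged trait, in `[0, 1]`.
#' @param qtl optional `list(snp = index, frac = variance fraction)` for a
#'   single causal SNP.
#' @param age_slope,sex_effect,center_effects,smoking_effect fixed
#'   covariate effects on the trait (trait units; the trait's residual SD
#'   is 1).
#' @param visit_noise_sd SD of the independent per-visit measurement noise.
#' @param post_shift additive intervention effect on post-phase visits.
#' @param trait_name prefix for the visit columns.
#' @param ld_rho adjacent-SNP haplotype-copying probability in `[0, 1)`;
#'   0 (default) gives independent SNPs, larger values give block LD.
#' @param subpop_fst optional Balding-Nichols divergence between two founder
#'   subpopulations (families assigned alternately), for stratification
#'   tests.
#' @param planted_swap optional length-2 character vector of sample ids
#'   whose genotype rows are exchanged by [simulate_study()].
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 60, n_children = 3, n_grandchildren = 2,
                       n_snps = 10000, maf_range = c(0.05, 0.5),
                       true_h2 = 0.4, qtl = NULL, age_slope = 0.02,
                       sex_effect = 0.3, center_effects = c(0, 0.2),
                       smoking_effect = 0.2, visit_noise_sd = 0.5,
                       post_shift = 0, trait_name = "trait", ld_rho = 0,
                       subpop_fst = NULL, planted_swap = NULL, seed = 1) {
  stopifnot(n_families >= 1, true_h2 >= 0, true_h2 <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, ld_rho >= 0, ld_rho < 1)
  q <- if (is.null(qtl)) 0 else qtl$frac
  if (true_h2 + q > 1) stop("true_h2 + QTL variance fraction exceeds 1")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a multi-family three-generation pedigree
#'
#' Families follow the template in [sim_config()]. Ids are globally unique
#' (`F001_I01`, ...). Children's sexes alternate; each married-in spouse is
#' a founder of the opposite sex. A `generation` column (0 = grandparents)
#' is carried for age assignment.
#'
#' @param cfg a `sim_config`.
#' @return A `kin_pedigree` with an extra `generation` column.
#' @export
simulate_pedigree <- function(cfg) {
  fam <- id <- fa <- mo <- sx <- character(0)
  gen <- integer(0)
  for (f in seq_len(cfg$n_families)) {
    fid <- sprintf("F%03d", f)
    nm <- function(k) sprintf("%s_I%02d", fid, k)
    k <- 0
    add <- function(father, mother, sex, g) {
      k <<- k + 1
      fam <<- c(fam, fid); id <<- c(id, nm(k))
      fa <<- c(fa, father); mo <<- c(mo, mother)
      sx <<- c(sx, sex); gen <<- c(gen, g)
      nm(k)
    }
    gf <- add(NA, NA, "male", 0L)
    gm <- add(NA, NA, "female", 0L)
    for (c in seq_len(cfg$n_children)) {
      csex <- if (c %% 2 == 1) "female" else "male"
      child <- add(gf, gm, csex, 1L)
      spouse <- add(NA, NA, if (csex == "female") "male" else "female", 1L)
      for (gk in seq_len(cfg$n_grandchildren)) {
        if (csex == "female") add(spouse, child, if (gk %% 2) "male" else "female", 2L)
        else add(child, spouse, if (gk %% 2) "male" else "female", 2L)
      }
    }
  }
  ped <- pedigree(fam, id, fa, mo, sx)
  ped$generation <- gen
  ped
}

#' Drop alleles through a pedigree
#'
#' Founder haplotypes are drawn from Hardy-Weinberg proportions at the
#' supplied frequencies; each child inherits one uniformly chosen allele
#' per parent per SNP (SNPs segregate independently — no linkage between
#' markers). With `ld_rho > 0`, founder haplotypes are built by Markov
#' copying so adjacent SNPs are correlated (block LD), for testing LD
#' pruning. With `subpops`/`fst` set, founder frequencies diverge between
#' two subpopulations under the Balding-Nichols model.
#'
#' SNPs are laid out on 22 nominal autosomes in equal blocks.
#'
#' @param ped a `kin_pedigree`.
#' @param freqs vector of alternate-allele frequencies in `(0, 1)`.
#' @param seed integer seed.
#' @param ld_rho adjacent-SNP copying probability.
#' @param subpops optional named vector mapping family id to `1`/`2`.
#' @param fst Balding-Nichols divergence used with `subpops`.
#' @return A `genotype_matrix` over all pedigree members.
#' @export
gene_drop <- function(ped, freqs, seed = 1, ld_rho = 0, subpops = NULL,
                      fst = NULL) {
  stopifnot(all(freqs > 0), all(freqs < 1))
  set.seed(seed)
  n <- nrow(ped); m <- length(freqs)
  ids <- sample_ids(ped)
  fa_idx <- attr(ped, "fa_idx"); mo_idx <- attr(ped, "mo_idx")

  pop_freqs <- list(freqs)
  pop_of <- rep(1L, n)
  if (!is.null(subpops) && !is.null(fst) && fst > 0) {
    bn <- function(p) stats::rbeta(m, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    pop_freqs <- list(pmin(pmax(bn(freqs), 1e-4), 1 - 1e-4),
                      pmin(pmax(bn(freqs), 1e-4), 1 - 1e-4))
    pop_of <- as.integer(subpops[ped$fam])
  }

  founder_hap <- function(p) {
    h <- stats::rbinom(m, 1L, p)
    if (ld_rho > 0 && m > 1) {
      copy <- stats::runif(m) < ld_rho
      copy[1] <- FALSE
      src <- cummax(seq_len(m) * (!copy))   # index of last freshly drawn SNP
      h <- h[src]
    }
    h
  }
  H1 <- H2 <- matrix(0L, n, m)
  for (i in attr(ped, "order")) {
    if (is.na(fa_idx[i])) {
      p <- pop_freqs[[pop_of[i]]]
      H1[i, ] <- founder_hap(p)
      H2[i, ] <- founder_hap(p)
    } else {
      fsel <- stats::runif(m) < 0.5
      H1[i, ] <- ifelse(fsel, H1[fa_idx[i], ], H2[fa_idx[i], ])
      msel <- stats::runif(m) < 0.5
      H2[i, ] <- ifelse(msel, H1[mo_idx[i], ], H2[mo_idx[i], ])
    }
  }
  dos <- H1 + H2
  storage.mode(dos) <- "double"
  rownames(dos) <- ids
  chrom <- as.character(ceiling(seq_len(m) / ceiling(m / 22)))
  pos <- seq_len(m)
  for (ch in unique(chrom)) pos[chrom == ch] <- seq_len(sum(chrom == ch)) * 1000L
  genotype_matrix(dos, data.frame(
    snp_id = sprintf("snp%05d", seq_len(m)), chrom = chrom, pos = pos,
    ref = "A", alt = "C", stringsAsFactors = FALSE))
}

#' Monte-Carlo kinship by founder-allele dropping
#'
#' Drops uniquely labelled founder alleles through the pedigree `n_drops`
#' times and estimates each pair's kinship coefficient as the proportion of
#' drops in which a randomly chosen allele from each is identical by
#' descent (averaged over the four allele pairings). Serves as the
#' independent oracle for [pedigree_kinship()].
#'
#' @param ped a `kin_pedigree`.
#' @param n_drops number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return List with `k2` (2*Phi estimate matrix, inbreeding-corrected
#'   diagonal `1 + F_hat`) and `se` (Monte-Carlo standard error of each
#'   `k2` entry).
#' @export
mc_kinship <- function(ped, n_drops = 20000, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  ids <- sample_ids(ped)
  fa_idx <- attr(ped, "fa_idx"); mo_idx <- attr(ped, "mo_idx")
  L1 <- L2 <- matrix(0L, n, n_drops)
  lab <- 0L
  for (i in attr(ped, "order")) {
    if (is.na(fa_idx[i])) {
      L1[i, ] <- lab + 1L; L2[i, ] <- lab + 2L; lab <- lab + 2L
    } else {
      fsel <- stats::runif(n_drops) < 0.5
      L1[i, ] <- ifelse(fsel, L1[fa_idx[i], ], L2[fa_idx[i], ])
      msel <- stats::runif(n_drops) < 0.5
      L2[i, ] <- ifelse(msel, L1[mo_idx[i], ], L2[mo_idx[i], ])
    }
  }
  k2 <- se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      sh <- 1 + (L1[i, ] == L2[i, ])          # per-drop 2*phi(i,i) = 1 + F_ind
    } else {
      sh <- 0.5 * ((L1[i, ] == L1[j, ]) + (L1[i, ] == L2[j, ]) +
                   (L2[i, ] == L1[j, ]) + (L2[i, ] == L2[j, ]))
    }
    k2[i, j] <- k2[j, i] <- mean(sh)
    se[i, j] <- se[j, i] <- stats::sd(sh) / sqrt(n_drops)
  }
  list(k2 = k2, se = se)
}

#' Simulate trait and covariate measurements
#'
#' Trait model: fixed covariate effects (age slope, sex difference, center
#' offsets, smoking) + optional QTL dosage effect + additive genetic value
#' `g ~ N(0, sigma2_g K)` (sampled through the symmetric eigen square root
#' of K, so any positive semidefinite matrix works) + individual
#' environment `e ~ N(0, sigma2_e I)`. Each of the four visit measurements
#' (two pre, two post) adds independent `N(0, visit_noise_sd^2)` noise;
#' post visits add `post_shift`. Variances are budgeted so the
#' phase-averaged trait has residual variance 1 and heritability exactly
#' `cfg$true_h2` (see [sim_config()]).
#'
#' Ages are drawn per generation band (grandparents 55-75, parents 30-50,
#' grandchildren 15-28); study center is assigned per family and smoking
#' at random, so covariates are confounder-free by construction.
#'
#' @param ped a `kin_pedigree` (with a `generation` column, as produced by
#'   [simulate_pedigree()]).
#' @param k a positive semidefinite `kinship_matrix`.
#' @param cfg a `sim_config`.
#' @param genotypes `genotype_matrix`, required when `cfg$qtl` is set.
#' @param seed seed (default `cfg$seed + 1`, so the same configuration can
#'   regenerate genotypes and traits independently).
#' @param eig optional precomputed eigendecomposition of the kinship
#'   matrix over the pedigree samples (for replicate loops).
#' @return A `phenotype_table` data frame: `fam, id, sex, age, center,
#'   smoking`, four visit columns, and the latent components in attributes
#'   `genetic_value` and `latent`.
#' @export
simulate_trait <- function(ped, k, cfg, genotypes = NULL,
                           seed = cfg$seed + 1, eig = NULL) {
  set.seed(seed)
  ids <- sample_ids(ped)
  n <- length(ids)
  q <- if (is.null(cfg$qtl)) 0 else cfg$qtl$frac
  sigma2_g <- cfg$true_h2 * (1 - q)
  sigma2_e <- (1 - cfg$true_h2) * (1 - q) - cfg$visit_noise_sd^2 / 2
  if (sigma2_e < 0)
    stop("infeasible variance budget: visit noise exceeds the environmental variance")

  if (is.null(eig)) eig <- eigen(kin_values(k)[ids, ids], symmetric = TRUE)
  rt <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * stats::rnorm(n))
  gval <- sqrt(sigma2_g) * drop(rt)

  gen <- if ("generation" %in% names(ped)) ped$generation else rep(1L, n)
  age <- c(stats::runif(n, 55, 75), stats::runif(n, 30, 50),
           stats::runif(n, 15, 28))[gen * n + seq_len(n)]
  center <- rep_len(seq_along(cfg$center_effects), length(unique(ped$fam)))
  names(center) <- unique(ped$fam)
  center <- center[ped$fam]
  smoking <- stats::rbinom(n, 1, 0.25)
  sexm <- as.numeric(ped$sex == "male")

  fixed <- cfg$age_slope * (age - mean(age)) + cfg$sex_effect * sexm +
    cfg$center_effects[center] + cfg$smoking_effect * smoking
  if (q > 0) {
    if (is.null(genotypes)) stop("QTL requested but no genotypes supplied")
    dsn <- genotypes$dosages[ids, cfg$qtl$snp]
    vd <- stats::var(dsn)
    if (vd == 0) stop("QTL SNP is monomorphic in the sample")
    fixed <- fixed + sqrt(q / vd) * (dsn - mean(dsn))
  }
  latent <- fixed + gval + stats::rnorm(n, 0, sqrt(sigma2_e))

  visit <- function(shift) latent + shift + stats::rnorm(n, 0, cfg$visit_noise_sd)
  out <- data.frame(fam = ped$fam, id = ids, sex = ped$sex, age = age,
                    center = paste0("C", center), smoking = smoking,
                    stringsAsFactors = FALSE)
  out[[paste0(cfg$trait_name, "_pre1")]] <- visit(0)
  out[[paste0(cfg$trait_name, "_pre2")]] <- visit(0)
  out[[paste0(cfg$trait_name, "_post1")]] <- visit(cfg$post_shift)
  out[[paste0(cfg$trait_name, "_post2")]] <- visit(cfg$post_shift)
  attr(out, "genetic_value") <- stats::setNames(gval, ids)
  attr(out, "latent") <- stats::setNames(latent, ids)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a complete study
#'
#' Pedigree, pedigree kinship, allele frequencies, gene-dropped genotypes
#' (with the optional planted sample swap applied to genotype rows only —
#' the phenotype keeps its labels, emulating a sample-handling error) and
#' phenotypes.
#'
#' @param cfg a `sim_config`.
#' @return List with `ped`, `kinship`, `freqs`, `genotypes`, `pheno`,
#'   `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  freqs <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  subpops <- NULL
  if (!is.null(cfg$subpop_fst)) {
    fams <- unique(ped$fam)
    subpops <- stats::setNames(rep_len(1:2, length(fams)), fams)
  }
  g <- gene_drop(ped, freqs, seed = cfg$seed, ld_rho = cfg$ld_rho,
                 subpops = subpops, fst = cfg$subpop_fst)
  if (!is.null(cfg$planted_swap)) {
    sw <- cfg$planted_swap
    stopifnot(length(sw) == 2, all(sw %in% rownames(g$dosages)))
    g$dosages[sw, ] <- g$dosages[rev(sw), ]
  }
  k <- pedigree_kinship(ped)
  ph <- simulate_trait(ped, k, cfg, genotypes = g)
  list(ped = ped, kinship = k, freqs = freqs, genotypes = g, pheno = ph,
       config = cfg)
}

#' Write a simulated study to disk
#'
#' Writes the pedigree (LINKAGE), genotypes (dosage layout) and phenotype
#' CSV under a common prefix, in the formats the readers consume.
#'
#' @param study output of [simulate_study()].
#' @param prefix path prefix.
#' @return The file paths written, invisibly.
#' @export
write_study <- function(study, prefix) {
  f_ped <- paste0(prefix, ".ped.txt")
  write_pedigree(study$ped, f_ped, dialect = "linkage")
  f_g <- write_genotypes(study$genotypes, prefix, format = "dosage")
  f_ph <- paste0(prefix, ".pheno.csv")
  utils::write.csv(study$pheno, f_ph, row.names = FALSE)
  invisible(c(f_ped, f_g, f_ph))
}
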