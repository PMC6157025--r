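#' Construct a genotype matrix
#'
#' Holds biallelic SNP dosages (alternate-allele counts 0/1/2, NA for
#' missing) for a set of samples, together with per-SNP metadata. SNPs are
#' sorted by (chromosome, position) on construction; chromosome order is
#' numeric where possible (1..22 before "X"-like labels).
#'
#' @param dosages numeric samples x SNPs matrix with sample ids as rownames
#'   and SNP ids as colnames; entries in \{0, 1, 2, NA\}.
#' @param snps data frame with columns `snp_id, chrom, pos, ref, alt`
#'   aligned to the columns of `dosages`.
#' @return An object of class `genotype_matrix` (list with elements
#'   `dosages` and `snps`).
#' @export
genotype_matrix <- function(dosages, snps) {
  stopifnot(is.matrix(dosages), nrow(snps) == ncol(dosages))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(snps)))
    stop("snps metadata must have columns: ", paste(need, collapse = ", "))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id in metadata")
  if (any(snps$pos < 1)) stop("positions are 1-based; pos < 1 found")
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  bad <- !grepl("^[ACGT]$", snps$ref) | !grepl("^[ACGT]$", snps$alt)
  if (any(bad))
    stop("non-ACGT alleles at: ", paste(utils::head(snps$snp_id[bad], 5), collapse = ", "))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  colnames(dosages) <- snps$snp_id
  chrnum <- suppressWarnings(as.numeric(snps$chrom))
  ord <- order(is.na(chrnum), chrnum, snps$chrom, snps$pos)
  structure(list(dosages = dosages[, ord, drop = FALSE],
                 snps = snps[ord, , drop = FALSE]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %d chromosome(s), %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snps$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read genotypes from PED/MAP, dosage-table or VCF files
#'
#' `"ped+map"` reads PLINK-style text files: `path` is the `.ped` file
#' (columns fam, id, fa, mo, sex, phenotype, then two allele columns per
#' SNP, `0` = missing) and `map` its `.map` companion (chrom, snp_id, cM,
#' pos). PED files do not designate an effect allele, so the alternate
#' allele is taken as the rarer of the two observed alleles (ties broken
#' alphabetically: the later base is alt).
#'
#' `"dosage"` reads a delimited table with an `id` column followed by one
#' numeric 0/1/2 column per SNP; `map` may point to a SNP metadata table
#' (`snp_id, chrom, pos, ref, alt`, tab- or comma-delimited). Without
#' metadata, SNPs are placed consecutively on chromosome "1" with A/C
#' placeholder alleles.
#'
#' `"vcf"` uses the vcfR package; multi-allelic records are skipped and the
#' skip count is recorded in the `n_multiallelic_skipped` attribute.
#'
#' @param path main genotype file.
#' @param format one of `"ped+map"`, `"dosage"`, `"vcf"`.
#' @param map companion metadata file (see details).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("ped+map", "dosage", "vcf"),
                           map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  switch(format,
         "ped+map" = read_ped_map(path, map),
         "dosage" = read_dosage_table(path, map),
         "vcf" = read_vcf_dosages(path))
}

read_ped_map <- function(ped_path, map_path) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  pd <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- nrow(mp)
  if (ncol(pd) != 6 + 2 * m)
    stop(sprintf("sample columns mismatch: map lists %d SNPs but ped has %d allele columns",
                 m, ncol(pd) - 6))
  ids <- pd[[2]]
  a1 <- as.matrix(pd[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(pd[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  dos <- matrix(NA_real_, nrow(pd), m)
  ref <- alt <- character(m)
  for (s in seq_len(m)) {
    als <- c(a1[, s], a2[, s])
    obs <- sort(unique(als[!is.na(als)]))
    if (length(obs) > 2) stop("more than two alleles at ", mp[[2]][s])
    if (any(!obs %in% c("A", "C", "G", "T")))
      stop("non-ACGT alleles at ", mp[[2]][s])
    if (length(obs) == 0) obs <- c("A", "C")
    if (length(obs) == 1) obs <- c(obs, setdiff(c("A", "C"), obs)[1])
    f2 <- mean(als == obs[2], na.rm = TRUE)
    if (f2 > 0.5) obs <- rev(obs)   # alt = minor; tie keeps alphabetical order
    ref[s] <- obs[1]; alt[s] <- obs[2]
    dos[, s] <- (a1[, s] == alt[s]) + (a2[, s] == alt[s])
  }
  rownames(dos) <- ids
  genotype_matrix(dos, data.frame(snp_id = mp[[2]], chrom = mp[[1]],
                                  pos = as.integer(mp[[4]]), ref = ref,
                                  alt = alt, stringsAsFactors = FALSE))
}

read_dosage_table <- function(path, map_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          sep = "")
  ids <- as.character(df[[1]])
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- ids
  m <- ncol(dos)
  if (!is.null(map_path)) {
    sn <- utils::read.delim(map_path, stringsAsFactors = FALSE, sep = "")
    if (ncol(sn) == 1)
      sn <- utils::read.csv(map_path, stringsAsFactors = FALSE)
    sn <- sn[match(colnames(dos), sn$snp_id), , drop = FALSE]
    if (anyNA(sn$snp_id)) stop("SNP metadata does not cover all dosage columns")
  } else {
    sn <- data.frame(snp_id = colnames(dos), chrom = "1", pos = seq_len(m),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  genotype_matrix(dos, sn)
}

read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi) message(n_multi, " multi-allelic record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  alt_count <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- t(apply(gt, 2, alt_count))
  if (nrow(fix) == 1) dos <- matrix(dos, ncol = 1, dimnames = list(colnames(gt), NULL))
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  g <- genotype_matrix(dos, data.frame(snp_id = snp_id, chrom = fix$CHROM,
                                       pos = as.integer(fix$POS),
                                       ref = fix$REF, alt = fix$ALT,
                                       stringsAsFactors = FALSE))
  attr(g, "n_multiallelic_skipped") <- n_multi
  g
}

#' Write genotypes
#'
#' `"dosage"` writes `<prefix>.dose.tsv` (id + one column per SNP) and
#' `<prefix>.snps.tsv` (metadata); this layout round-trips dosages exactly.
#' `"ped+map"` writes PLINK-style text files using the stored ref/alt bases
#' (`<prefix>.ped`, `<prefix>.map`).
#'
#' @param g a `genotype_matrix`.
#' @param prefix output path prefix.
#' @param format `"dosage"` or `"ped+map"`.
#' @param ped optional `kin_pedigree` supplying fam/fa/mo/sex columns for
#'   the PED file; samples absent from it are written as unrelated.
#' @return The file paths written, invisibly.
#' @export
write_genotypes <- function(g, prefix, format = c("dosage", "ped+map"),
                            ped = NULL) {
  format <- match.arg(format)
  if (format == "dosage") {
    f1 <- paste0(prefix, ".dose.tsv"); f2 <- paste0(prefix, ".snps.tsv")
    df <- data.frame(id = rownames(g$dosages), g$dosages, check.names = FALSE)
    utils::write.table(df, f1, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(g$snps, f2, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(c(f1, f2)))
  }
  f1 <- paste0(prefix, ".ped"); f2 <- paste0(prefix, ".map")
  ids <- rownames(g$dosages)
  fam <- ids; fa <- mo <- rep("0", length(ids)); sx <- rep("0", length(ids))
  if (!is.null(ped)) {
    i <- match(ids, sample_ids(ped))
    hit <- !is.na(i)
    fam[hit] <- ped$fam[i[hit]]
    fa[hit] <- ifelse(is.na(ped$fa[i[hit]]), "0", ped$fa[i[hit]])
    mo[hit] <- ifelse(is.na(ped$mo[i[hit]]), "0", ped$mo[i[hit]])
    sx[hit] <- c(male = "1", female = "2", unknown = "0")[ped$sex[i[hit]]]
  }
  m <- ncol(g$dosages)
  al <- matrix("0", nrow(g$dosages), 2 * m)
  for (s in seq_len(m)) {
    d <- g$dosages[, s]
    al[, 2 * s - 1] <- ifelse(is.na(d), "0", ifelse(d >= 1, g$snps$alt[s], g$snps$ref[s]))
    al[, 2 * s] <- ifelse(is.na(d), "0", ifelse(d == 2, g$snps$alt[s], g$snps$ref[s]))
  }
  utils::write.table(cbind(fam, ids, fa, mo, sx, "-9", al), f1,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(g$snps$chrom, g$snps$snp_id, 0, g$snps$pos), f2,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}

#' Alternate-allele frequencies
#'
#' `freq = sum(dosages) / (2 * non-missing count)` per SNP. SNPs with every
#' call missing get `NaN` and are listed in the `undefined` attribute;
#' downstream estimators exclude them.
#'
#' @param g a `genotype_matrix`.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
allele_frequencies <- function(g) {
  d <- g$dosages
  nn <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * nn)
  f[nn == 0] <- NaN
  names(f) <- g$snps$snp_id
  attr(f, "undefined") <- g$snps$snp_id[nn == 0]
  f
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the p^2 : 2pq : q^2 expectation, with the allele
#' frequency estimated from the same counts. Monomorphic SNPs return p = 1
#' (no departure is testable). Vectorized over SNPs.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop("hwe_test needs a positive total count")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
  o <- cbind(n_AA, n_Aa, n_aa)
  chi2 <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
  out <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  out[p == 0 | p == 1] <- 1
  out
}

#' Hardy-Weinberg p-values for every SNP in a genotype matrix
#'
#' @param g a `genotype_matrix`.
#' @return Named vector of HWE p-values.
#' @export
hwe_pvalues <- function(g) {
  d <- g$dosages
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  p <- hwe_test(n0, n1, n2)
  names(p) <- g$snps$snp_id
  p
}

#' Windowed LD pruning of a genotype matrix
#'
#' Greedy pruning in the style of PLINK `--indep-pairwise`: within a sliding
#' window of `window_snps` markers (advancing by `step_snps`, per
#' chromosome), while any retained pair has squared Pearson correlation of
#' dosages above `r2_threshold`, one member of the pair is removed — the one
#' with the lower minor-allele frequency, ties going to the later marker in
#' input order. Window units are marker counts, the PLINK convention when no
#' "kb" suffix is given. Missing dosages enter the correlation through
#' pairwise-complete observations.
#'
#' The retained set is stable: re-pruning it at the same parameters removes
#' nothing.
#'
#' @param g a `genotype_matrix`.
#' @param window_snps,step_snps window size and step, in SNPs.
#' @param r2_threshold squared-correlation cutoff in `(0, 1]`.
#' @return Character vector of retained SNP ids (in map order).
#' @export
ld_prune <- function(g, window_snps = 2000, step_snps = 10, r2_threshold = 0.1) {
  stopifnot(window_snps >= step_snps, step_snps >= 1,
            r2_threshold > 0, r2_threshold <= 1)
  f <- allele_frequencies(g)
  maf <- pmin(f, 1 - f)
  keep_all <- character(0)
  for (chr in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == chr)
    keep_all <- c(keep_all, g$snps$snp_id[idx[prune_chrom(
      g$dosages[, idx, drop = FALSE], maf[idx], window_snps, step_snps,
      r2_threshold)]])
  }
  keep_all
}

# One chromosome. Windows overlap heavily, and retained pairs inside an
# already-processed span are known clean, so each step only tests pairs that
# involve a marker newly entering the window.
prune_chrom <- function(d, maf, W, S, thr) {
  m <- ncol(d)
  keep <- rep(TRUE, m)
  if (m < 2) return(which(keep))
  use <- if (anyNA(d)) "pairwise.complete.obs" else "everything"
  start <- 1L; seen <- 0L
  repeat {
    end <- min(start + W - 1L, m)
    win <- which(keep[seq_len(end)])
    win <- win[win >= start]
    new <- win[win > seen]
    if (length(new) && length(win) >= 2L) {
      r2 <- suppressWarnings(cor(d[, new, drop = FALSE],
                                 d[, win, drop = FALSE], use = use))^2
      r2[is.na(r2)] <- 0
      hits <- which(r2 > thr, arr.ind = TRUE)
      if (nrow(hits)) {
        i <- new[hits[, 1]]; j <- win[hits[, 2]]
        ok <- i != j
        pi <- pmin(i, j)[ok]; pj <- pmax(i, j)[ok]
        pr2 <- r2[hits][ok]
        dup <- duplicated(cbind(pi, pj))
        pi <- pi[!dup]; pj <- pj[!dup]; pr2 <- pr2[!dup]
        for (h in order(pr2, decreasing = TRUE)) {
          a <- pi[h]; b <- pj[h]
          if (keep[a] && keep[b]) {
            drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
            keep[drop] <- FALSE
          }
        }
      }
    }
    seen <- end
    if (end >= m) break
    start <- start + S
  }
  which(keep)
}

#' Standard SNP QC: HWE filter then LD pruning
#'
#' Applies the usual marker screen before relationship inference: drop SNPs
#' departing from Hardy-Weinberg equilibrium at `hwe_p`, then LD-prune the
#' remainder.
#'
#' @param g a `genotype_matrix`.
#' @param hwe_p HWE exclusion threshold (SNPs with p below it are removed).
#' @param window_snps,step_snps,r2_threshold see [ld_prune()].
#' @return A pruned `genotype_matrix`; exclusion counts are in the
#'   `qc_counts` attribute.
#' @export
qc_snps <- function(g, hwe_p = 0.05, window_snps = 2000, step_snps = 10,
                    r2_threshold = 0.1) {
  hp <- hwe_pvalues(g)
  pass <- names(hp)[hp >= hwe_p]
  g1 <- subset_snps(g, pass)
  kept <- ld_prune(g1, window_snps, step_snps, r2_threshold)
  out <- subset_snps(g1, kept)
  attr(out, "qc_counts") <- c(input = ncol(g$dosages),
                              hwe_removed = ncol(g$dosages) - length(pass),
                              ld_removed = length(pass) - length(kept),
                              retained = length(kept))
  out
}

#' Subset a genotype matrix to a set of SNP ids
#'
#' @param g a `genotype_matrix`.
#' @param snp_ids SNP ids to keep (order from the map is preserved).
#' @export
subset_snps <- function(g, snp_ids) {
  keep <- g$snps$snp_id %in% snp_ids
  genotype_matrix(g$dosages[, keep, drop = FALSE], g$snps[keep, , drop = FALSE])
}
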