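# Pairwise relationship inference from genotypes: PLINK --genome style
# method-of-moments IBD estimation on IBS counts, class calls, and
# discordance screening against the recorded pedigree.

# Per-SNP conditional IBS probabilities given the IBD state, with allele
# frequencies treated as known:
#   P(IBS0|Z0)=2p^2q^2  P(IBS1|Z0)=4p^3q+4pq^3  P(IBS2|Z0)=p^4+q^4+4p^2q^2
#   P(IBS1|Z1)=2pq      P(IBS2|Z1)=p^2+q^2      P(IBS2|Z2)=1
ibs_expectations <- function(p) {
  q <- 1 - p
  c(e0_z0 = sum(2 * p^2 * q^2),
    e1_z0 = sum(4 * p^3 * q + 4 * p * q^3),
    e2_z0 = sum(p^4 + q^4 + 4 * p^2 * q^2),
    e1_z1 = sum(2 * p * q),
    e2_z1 = sum(p^2 + q^2))
}

solve_mom <- function(N0, N1, N2, ex, m) {
  z0 <- N0 / ex["e0_z0"]
  z1 <- (N1 - z0 * ex["e1_z0"]) / ex["e1_z1"]
  z2 <- (N2 - z0 * ex["e2_z0"] - z1 * ex["e2_z1"]) / m
  z <- cbind(z0, z1, z2)
  z[z < 0] <- 0                         # truncate, then renormalize
  z / rowSums(z)
}

#' Method-of-moments IBD estimate for one pair of samples
#'
#' Counts identity-by-state (IBS) sharing across SNPs and solves the
#' method-of-moments system for the proportions of the genome shared
#' 0, 1 and 2 alleles identical by descent, using the expected IBS
#' distribution given each IBD state computed from allele frequencies.
#' Raw estimates are projected onto the probability simplex by truncating
#' negatives to zero and renormalizing. The implied kinship estimate is
#' `0.25*ibd1 + 0.5*ibd2` (on the Phi scale: 0.5 for a duplicate, 0.25 for
#' parent-offspring). Use an LD-pruned marker set: the moment estimator
#' assumes independent markers.
#'
#' @param d1,d2 aligned dosage vectors (0/1/2, NA allowed).
#' @param freqs alternate-allele frequencies aligned to the vectors.
#' @return Named vector `(ibd0, ibd1, ibd2, kinship_hat)`.
#' @export
moment_ibd <- function(d1, d2, freqs) {
  stopifnot(length(d1) == length(d2), length(freqs) == length(d1))
  ok <- !is.na(d1) & !is.na(d2) & !is.na(freqs)
  m <- sum(ok)
  if (m == 0) stop("no SNPs with calls in both samples")
  if (m < 200)
    warning("only ", m, " informative SNPs; IBD estimates will be noisy")
  ibs <- 2 - abs(d1[ok] - d2[ok])
  ex <- ibs_expectations(freqs[ok])
  z <- solve_mom(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2), ex, m)
  c(ibd0 = z[1, 1], ibd1 = z[1, 2], ibd2 = z[1, 3],
    kinship_hat = 0.25 * z[1, 2] + 0.5 * z[1, 3])
}

#' IBD estimates for many pairs at once
#'
#' Same estimator as [moment_ibd()], computed for all sample pairs (or a
#' requested subset) via indicator-matrix cross-products, which makes an
#' all-pairs scan over hundreds of samples and 10^4 markers practical.
#' With missing dosages, IBS counts use SNPs called in both samples and the
#' expected counts are rescaled by the pair's shared-call fraction.
#'
#' @param g a `genotype_matrix` (LD-pruned set recommended).
#' @param freqs optional frequency vector (default from `g`).
#' @param pairs optional 2-column matrix/data.frame of sample ids; default
#'   all unordered pairs.
#' @return Data frame: `id1, id2, m, ibd0, ibd1, ibd2, kinship_hat`.
#' @export
ibd_estimates <- function(g, freqs = NULL, pairs = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  ok <- !is.na(freqs) & is.finite(freqs) & freqs > 0 & freqs < 1
  d <- g$dosages[, ok, drop = FALSE]
  p <- freqs[ok]
  m <- ncol(d)
  if (m == 0) stop("no polymorphic SNPs with defined frequencies")
  if (m < 200) warning("only ", m, " informative SNPs; IBD estimates will be noisy")
  ex <- ibs_expectations(p)

  called <- !is.na(d)
  a0 <- (d == 0) & called; a1 <- (d == 1) & called; a2 <- (d == 2) & called
  storage.mode(a0) <- storage.mode(a1) <- storage.mode(a2) <- "double"
  ibs2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)
  ibs0 <- tcrossprod(a0, a2); ibs0 <- ibs0 + t(ibs0)
  mc <- if (all(called)) matrix(m, nrow(d), nrow(d)) else
    tcrossprod(matrix(as.double(called), nrow(d)))
  ibs1 <- mc - ibs0 - ibs2

  ids <- rownames(d)
  if (is.null(pairs)) {
    ut <- which(upper.tri(mc), arr.ind = TRUE)
    i <- ut[, 1]; j <- ut[, 2]
  } else {
    i <- match(as.character(pairs[[1]]), ids)
    j <- match(as.character(pairs[[2]]), ids)
    if (anyNA(i) || anyNA(j)) stop("pair ids absent from genotype matrix")
  }
  sel <- cbind(i, j)
  scale <- mc[sel] / m                 # expectation rescale for shared calls
  z0 <- ibs0[sel] / (ex["e0_z0"] * scale)
  z1 <- (ibs1[sel] - z0 * ex["e1_z0"] * scale) / (ex["e1_z1"] * scale)
  z2 <- (ibs2[sel] - z0 * ex["e2_z0"] * scale - z1 * ex["e2_z1"] * scale) / mc[sel]
  zz <- cbind(z0, z1, z2)
  zz[zz < 0] <- 0
  zz <- zz / rowSums(zz)
  data.frame(id1 = ids[i], id2 = ids[j], m = mc[sel],
             ibd0 = zz[, 1], ibd1 = zz[, 2], ibd2 = zz[, 3],
             kinship_hat = 0.25 * zz[, 2] + 0.5 * zz[, 3],
             stringsAsFactors = FALSE)
}

# kinship-hat class boundaries at powers of 2 (2^-1.5, 2^-2.5, ...)
.kin_bounds <- c(mz = 2^-1.5, deg1 = 2^-2.5, deg2 = 2^-3.5, deg3 = 2^-4.5)

#' Classify a pairwise relationship from IBD estimates
#'
#' Kinship-hat intervals with edges at powers of 2 — 0.354, 0.177, 0.0884,
#' 0.0442 — bound MZ/duplicate, 1st, 2nd, 3rd degree and unrelated; within
#' the 1st-degree band, `ibd0 < 0.1` calls parent-offspring (which shares
#' one allele IBD everywhere) and `ibd0 >= 0.1` full siblings.
#' Monotone in `kinship_hat`: increasing it never moves the call further
#' from MZ/duplicate.
#'
#' @param ibd0,ibd1,ibd2 IBD-sharing proportions (vectorized).
#' @param kinship_hat kinship estimates (default recomputed from ibd1/ibd2).
#' @return Character vector of classes: `"MZ/duplicate"`,
#'   `"parent-offspring"`, `"full-sibling"`, `"2nd-degree"`,
#'   `"3rd-degree"`, `"unrelated"`.
#' @export
classify_relationship <- function(ibd0, ibd1, ibd2,
                                  kinship_hat = 0.25 * ibd1 + 0.5 * ibd2) {
  b <- .kin_bounds
  kinship_hat <- unname(kinship_hat)
  ifelse(kinship_hat > unname(b["mz"]), "MZ/duplicate",
  ifelse(kinship_hat > unname(b["deg1"]),
         ifelse(unname(ibd0) < 0.1, "parent-offspring", "full-sibling"),
  ifelse(kinship_hat > unname(b["deg2"]), "2nd-degree",
  ifelse(kinship_hat > unname(b["deg3"]), "3rd-degree", "unrelated"))))
}

# degree-level label from an exact pedigree kinship coefficient (Phi scale)
relationship_degree <- function(phi) {
  b <- unname(.kin_bounds)
  phi <- unname(phi)
  ifelse(phi > b[1], "MZ/duplicate",
  ifelse(phi > b[2], "1st-degree",
  ifelse(phi > b[3], "2nd-degree",
  ifelse(phi > b[4], "3rd-degree", "unrelated"))))
}

#' Named genealogical relationship for pairs of pedigree members
#'
#' Labels a within-family pair by its genealogical relationship
#' (parent-offspring, full-sibling, half-sibling, grandparent-grandchild,
#' avuncular, first-cousin), falling back to the degree implied by the
#' exact kinship coefficient for anything else.
#'
#' @param ped a `kin_pedigree`.
#' @param id1,id2 sample ids (as in [sample_ids()]).
#' @return Character vector of relationship names.
#' @export
relationship_name <- function(ped, id1, id2) {
  ids <- sample_ids(ped)
  i <- match(id1, ids); j <- match(id2, ids)
  if (anyNA(i) || anyNA(j)) stop("ids absent from pedigree")
  fa <- attr(ped, "fa_idx"); mo <- attr(ped, "mo_idx")
  k2 <- kin_values(pedigree_kinship(ped))
  parents <- function(a) { p <- c(fa[a], mo[a]); p[!is.na(p)] }
  sib <- function(x, y)  # full or half siblings
    !identical(x, y) && length(intersect(parents(x), parents(y))) > 0
  mapply(function(a, b) {
    pa <- parents(a); pb <- parents(b)
    if (a %in% pb || b %in% pa) return("parent-offspring")
    if (length(pa) == 2 && length(pb) == 2 && setequal(pa, pb))
      return("full-sibling")
    if (length(intersect(pa, pb)) == 1) return("half-sibling")
    grandparents <- function(x) unlist(lapply(parents(x), parents))
    if (a %in% grandparents(b) || b %in% grandparents(a))
      return("grandparent-grandchild")
    if (any(vapply(pb, function(p) sib(a, p), logical(1))) ||
        any(vapply(pa, function(p) sib(b, p), logical(1))))
      return("avuncular")
    if (length(pa) && length(pb) &&
        any(outer(pa, pb, Vectorize(sib))))
      return("first-cousin")
    relationship_degree(k2[a, b] / 2)
  }, i, j)
}

#' Relationship calls for within- and cross-pedigree pairs
#'
#' Runs [ibd_estimates()] and attaches, for every pair, the inferred class
#' ([classify_relationship()]) and the class expected from the recorded
#' pedigree: the named genealogical relationship for within-family pairs,
#' `"cross-pedigree"` otherwise. A pair is discordant when its inferred
#' class differs from its expected degree-level class (avuncular,
#' half-sibling and grandparent-grandchild all map to 2nd degree, and so
#' on, so named relationships are compared at the degree they imply).
#'
#' @param ped a `kin_pedigree` covering the genotyped samples.
#' @param g a `genotype_matrix` (LD/HWE-pruned set recommended).
#' @param freqs optional allele-frequency vector.
#' @param within_only if `TRUE` (default) compute calls for within-family
#'   pairs only, plus cross-family pairs with elevated kinship found by the
#'   all-pairs scan.
#' @return Data frame of class `relationship_calls`: `id1, id2, fam1, fam2,
#'   expected_name, expected_class, inferred_class, ibd0, ibd1, ibd2,
#'   kinship_hat, discordant`.
#' @export
relationship_calls <- function(ped, g, freqs = NULL, within_only = TRUE) {
  ids <- sample_ids(ped)
  geno_ids <- rownames(g$dosages)
  common <- intersect(ids, geno_ids)
  if (length(common) < 2) stop("fewer than 2 genotyped pedigree members")
  est <- ibd_estimates(g, freqs)
  est <- est[est$id1 %in% common & est$id2 %in% common, ]
  fam <- ped$fam[match(est$id1, ids)]
  fam2 <- ped$fam[match(est$id2, ids)]
  est$fam1 <- fam; est$fam2 <- fam2
  within <- fam == fam2
  est$inferred_class <- classify_relationship(est$ibd0, est$ibd1, est$ibd2,
                                              est$kinship_hat)
  est$expected_name <- NA_character_
  est$expected_class <- "cross-pedigree"
  if (any(within)) {
    nm <- relationship_name(ped, est$id1[within], est$id2[within])
    est$expected_name[within] <- nm
    est$expected_class[within] <- expected_degree_class(ped, est$id1[within],
                                                        est$id2[within], nm)
  }
  est$discordant <- within & est$inferred_class != est$expected_class
  if (within_only) {
    elevated <- !within & est$kinship_hat > .kin_bounds["deg3"]
    est <- est[within | elevated, ]
  }
  class(est) <- c("relationship_calls", "data.frame")
  est
}

# expected class in the inferred-class vocabulary: named relationship mapped
# to the degree band it implies, PO and full sibs kept distinct
expected_degree_class <- function(ped, id1, id2, nm) {
  k2 <- kin_values(pedigree_kinship(ped))
  phi <- k2[cbind(match(id1, sample_ids(ped)), match(id2, sample_ids(ped)))] / 2
  out <- relationship_degree(phi)
  out[nm == "parent-offspring"] <- "parent-offspring"
  out[nm == "full-sibling"] <- "full-sibling"
  out[out == "1st-degree"] <- "full-sibling"  # e.g. double-cousin corner cases
  out
}

#' Pedigree discordance report
#'
#' The sample-swap screen: tabulates within-pedigree pairs whose inferred
#' relationship class contradicts the recorded pedigree, lists cross-pedigree
#' pairs with kinship above the 3rd-degree bound, counts each individual's
#' discordant pairs, and proposes an exclusion list. A swapped or mislabelled
#' sample contradicts essentially all of its within-family pairs while its
#' innocent relatives each contradict only the pair involving it, so the
#' proposed exclusions are the individuals discordant in more than half of
#' their within-family pairs; `flagged` lists everyone with at least one
#' discordance.
#'
#' @param ped a `kin_pedigree`.
#' @param calls a `relationship_calls` data frame from
#'   [relationship_calls()].
#' @return A list of class `discordance_report`: `discordant_pairs`,
#'   `cross_pedigree`, `flagged` (id, n_discordant, n_pairs, fraction),
#'   `proposed_exclusions`.
#' @export
pedigree_discordance <- function(ped, calls) {
  within <- calls$fam1 == calls$fam2
  wc <- calls[within, , drop = FALSE]
  disc <- wc[wc$discordant, , drop = FALSE]
  ids <- unique(c(wc$id1, wc$id2))
  n_pairs <- table(factor(c(wc$id1, wc$id2), levels = ids))
  n_disc <- table(factor(c(disc$id1, disc$id2), levels = ids))
  flagged <- data.frame(id = ids, n_discordant = as.integer(n_disc),
                        n_pairs = as.integer(n_pairs),
                        fraction = as.numeric(n_disc) / as.numeric(n_pairs),
                        stringsAsFactors = FALSE)
  flagged <- flagged[flagged$n_discordant > 0, , drop = FALSE]
  flagged <- flagged[order(-flagged$fraction, -flagged$n_discordant), ]
  structure(list(
    discordant_pairs = disc,
    cross_pedigree = calls[!within, , drop = FALSE],
    flagged = flagged,
    proposed_exclusions = flagged$id[flagged$fraction > 0.5]),
    class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  cat(sprintf("<discordance_report> %d discordant within-pedigree pair(s), %d elevated cross-pedigree pair(s)\n",
              nrow(x$discordant_pairs), nrow(x$cross_pedigree)))
  if (nrow(x$flagged)) {
    cat("  flagged individuals:\n")
    print(utils::head(x$flagged, 10))
  }
  cat("  proposed exclusions:",
      if (length(x$proposed_exclusions))
        paste(x$proposed_exclusions, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Write a relationship-screen report
#'
#' @param report a `discordance_report`.
#' @param prefix output path prefix; writes `<prefix>.calls.csv` and
#'   `<prefix>.exclude.txt`.
#' @export
write_discordance <- function(report, prefix) {
  f1 <- paste0(prefix, ".calls.csv")
  f2 <- paste0(prefix, ".exclude.txt")
  utils::write.csv(rbind(report$discordant_pairs, report$cross_pedigree),
                   f1, row.names = FALSE)
  writeLines(report$proposed_exclusions, f2)
  invisible(c(f1, f2))
}
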