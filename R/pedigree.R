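#' @keywords internal
ped_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "kinherit_pedigree_error")))
}

#' Construct and validate a pedigree
#'
#' A pedigree is a set of genealogy records, one per individual, naming the
#' individual's family, father and mother. Founders are individuals with both
#' parents unrecorded; they are assumed mutually unrelated and non-inbred.
#'
#' Validation enforces: unique ids within a family; both parents recorded or
#' both missing (half-specified parentage is an error, matching LINKAGE
#' conventions); named parents present in the same family; fathers male and
#' mothers female (unknown sex is allowed only for individuals who are never
#' parents); and an acyclic parent graph.
#'
#' @param fam,id,fa,mo character vectors; missing parents coded `"0"`, `""`
#'   or `NA`.
#' @param sex `"male"`/`"female"`/`"unknown"`, or the LINKAGE codes 1/2/0.
#' @return A data frame of class `kin_pedigree` with columns
#'   `fam, id, fa, mo, sex, founder` and an attribute `order` giving a
#'   parents-before-children evaluation order (ties by input order).
#' @export
pedigree <- function(fam, id, fa, mo, sex) {
  fam <- as.character(fam); id <- as.character(id)
  fa <- as.character(fa); mo <- as.character(mo)
  norm_parent <- function(p) { p[p %in% c("0", "") | is.na(p)] <- NA; p }
  fa <- norm_parent(fa); mo <- norm_parent(mo)
  sex <- decode_sex(sex)
  n <- length(id)
  stopifnot(length(fam) == n, length(fa) == n, length(mo) == n, length(sex) == n)

  key <- paste(fam, id, sep = "\r")
  if (anyDuplicated(key))
    ped_error("kinherit_duplicate_id_error",
              paste("duplicate individual id within family:",
                    paste(unique(id[duplicated(key)]), collapse = ", ")))
  half <- xor(is.na(fa), is.na(mo))
  if (any(half))
    ped_error("kinherit_half_parentage_error",
              paste("individuals with exactly one recorded parent:",
                    paste(id[half], collapse = ", ")))

  fa_idx <- ifelse(is.na(fa), NA_integer_, match(paste(fam, fa, sep = "\r"), key))
  mo_idx <- ifelse(is.na(mo), NA_integer_, match(paste(fam, mo, sep = "\r"), key))
  bad <- (!is.na(fa) & is.na(fa_idx)) | (!is.na(mo) & is.na(mo_idx))
  if (any(bad))
    ped_error("kinherit_missing_parent_error",
              paste("named parent not present in the same family for:",
                    paste(id[bad], collapse = ", ")))

  is_father <- seq_len(n) %in% fa_idx
  is_mother <- seq_len(n) %in% mo_idx
  if (any(is_father & sex != "male"))
    ped_error("kinherit_parent_sex_error",
              paste("father records must be male:",
                    paste(id[is_father & sex != "male"], collapse = ", ")))
  if (any(is_mother & sex != "female"))
    ped_error("kinherit_parent_sex_error",
              paste("mother records must be female:",
                    paste(id[is_mother & sex != "female"], collapse = ", ")))

  # Kahn topological sort over the parent graph; leftover nodes imply a cycle
  # (an individual that is its own ancestor). Ties resolved by input order.
  n_par <- (!is.na(fa_idx)) + (!is.na(mo_idx))
  children <- split(rep(seq_len(n), 2L), c(fa_idx, mo_idx))
  order_idx <- integer(0)
  ready <- which(n_par == 0L)
  remaining <- n_par
  while (length(ready)) {
    ready <- sort(ready)
    order_idx <- c(order_idx, ready)
    nxt <- integer(0)
    for (i in ready) {
      kids <- children[[as.character(i)]]
      for (k in kids) {
        remaining[k] <- remaining[k] - 1L
        if (remaining[k] == 0L) nxt <- c(nxt, k)
      }
    }
    ready <- nxt
  }
  if (length(order_idx) < n)
    ped_error("kinherit_cycle_error",
              paste("cyclic parentage involving:",
                    paste(id[setdiff(seq_len(n), order_idx)], collapse = ", ")))

  out <- data.frame(fam = fam, id = id, fa = fa, mo = mo, sex = sex,
                    founder = is.na(fa) & is.na(mo),
                    stringsAsFactors = FALSE)
  attr(out, "order") <- order_idx
  attr(out, "fa_idx") <- fa_idx
  attr(out, "mo_idx") <- mo_idx
  class(out) <- c("kin_pedigree", "data.frame")
  out
}

decode_sex <- function(sex) {
  s <- tolower(as.character(sex))
  map <- c("1" = "male", "2" = "female", "0" = "unknown",
           "m" = "male", "f" = "female", "u" = "unknown",
           "male" = "male", "female" = "female", "unknown" = "unknown")
  out <- unname(map[s])
  out[is.na(out) | is.na(s)] <- "unknown"
  out
}

#' Globally unique sample ids for a pedigree
#'
#' Individual ids are unique within a family; when they are also unique
#' across families they are used as-is, otherwise `fam:id` is used.
#' These ids key every matrix produced downstream.
#'
#' @param ped a `kin_pedigree`.
#' @export
sample_ids <- function(ped) {
  if (anyDuplicated(ped$id)) paste(ped$fam, ped$id, sep = ":") else ped$id
}

#' Read a pedigree file
#'
#' @param path pedigree file.
#' @param dialect `"linkage"` for the classic whitespace-delimited five-column
#'   layout (family, individual, father, mother, sex with 1=male 2=female),
#'   or `"solar-csv"` for a headered CSV with columns
#'   `famid,id,fa,mo,sex` (SOLAR-style names; `family/father/mother` also
#'   accepted).
#' @return A validated `kin_pedigree`.
#' @export
read_pedigree <- function(path, dialect = c("linkage", "solar-csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "linkage") {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) < 5) stop("LINKAGE pedigree needs >= 5 columns")
    pedigree(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]])
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    names(df) <- tolower(names(df))
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
      stop("solar-csv pedigree missing column: ", ..1)
    }
    pedigree(pick("famid", "family", "fam"), pick("id", "individual"),
             pick("fa", "father"), pick("mo", "mother"), pick("sex"))
  }
}

#' Write a pedigree file
#'
#' @inheritParams read_pedigree
#' @param ped a `kin_pedigree`.
#' @export
write_pedigree <- function(ped, path, dialect = c("linkage", "solar-csv")) {
  dialect <- match.arg(dialect)
  fa <- ifelse(is.na(ped$fa), "0", ped$fa)
  mo <- ifelse(is.na(ped$mo), "0", ped$mo)
  if (dialect == "linkage") {
    sx <- c(male = "1", female = "2", unknown = "0")[ped$sex]
    utils::write.table(data.frame(ped$fam, ped$id, fa, mo, sx), path,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(famid = ped$fam, id = ped$id, fa = fa,
                                mo = mo, sex = ped$sex),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Expected kinship matrix from pedigree structure
#'
#' Computes kinship coefficients Phi by the standard recursion: founders are
#' unrelated and non-inbred; for a non-founder i with parents f and m,
#' `Phi(i,j) = (Phi(f,j) + Phi(m,j))/2` for any j that is not a descendant
#' of i, and `Phi(i,i) = (1 + Phi(f,m))/2`. Individuals are processed in a
#' parents-first order so both conditions hold. The returned matrix is on
#' the 2*Phi (numerator-relationship) scale: diagonal `1 + F` with F the
#' inbreeding coefficient, 0.5 for parent-offspring and full siblings.
#'
#' @param ped a `kin_pedigree`.
#' @return A `kinship_matrix` with `source = "pedigree"` over all pedigree
#'   members, ordered as in the input.
#' @export
pedigree_kinship <- function(ped) {
  n <- nrow(ped)
  ids <- sample_ids(ped)
  fa_idx <- attr(ped, "fa_idx"); mo_idx <- attr(ped, "mo_idx")
  ord <- attr(ped, "order")
  phi <- matrix(0, n, n)
  done <- integer(0)
  for (i in ord) {
    if (is.na(fa_idx[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fa_idx[i]; m <- mo_idx[i]
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      if (length(done)) {
        v <- 0.5 * (phi[f, done] + phi[m, done])
        phi[i, done] <- v
        phi[done, i] <- v
      }
    }
    done <- c(done, i)
  }
  dimnames(phi) <- list(ids, ids)
  kinship_matrix(2 * phi, source = "pedigree")
}
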