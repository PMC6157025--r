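#' Construct a kinship matrix object
#'
#' Container for a symmetric relatedness matrix on the 2*Phi scale
#' (Phi = kinship coefficient), where a non-inbred individual has
#' diagonal 1 and a parent-offspring pair has off-diagonal 0.5.
#' Both pedigree-derived and empirical (GRM) matrices use this scale,
#' so the two are directly exchangeable in the polygenic model.
#'
#' @param values square symmetric numeric matrix with row/column names
#'   giving sample ids (unnamed matrices get `S1..Sn`).
#' @param source `"pedigree"` or `"empirical"`.
#' @param postprocessed logical; has [postprocess_kinship()] been applied.
#' @param meta optional list of provenance details.
#' @return An object of class `kinship_matrix`.
#' @export
kinship_matrix <- function(values, source = c("empirical", "pedigree"),
                           postprocessed = FALSE, meta = list()) {
  source <- match.arg(source)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("kinship values must be a square matrix")
  if (is.null(rownames(values)))
    rownames(values) <- colnames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values)))
    stop("row and column names of a kinship matrix must agree")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-8)
    stop("kinship matrix is not symmetric (max |K - t(K)| = ", signif(asym, 3), ")")
  values <- (values + t(values)) / 2
  structure(list(ids = rownames(values), values = values, source = source,
                 postprocessed = isTRUE(postprocessed), meta = meta),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d samples, source=%s%s\n", length(x$ids),
              x$source, if (x$postprocessed) ", postprocessed" else ""))
  d <- diag(x$values)
  cat(sprintf("  diagonal: min %.4f / mean %.4f / max %.4f\n",
              min(d), mean(d), max(d)))
  invisible(x)
}

#' @rdname kinship_matrix
#' @param k a `kinship_matrix`.
#' @export
kin_ids <- function(k) k$ids

#' @rdname kinship_matrix
#' @export
kin_values <- function(k) k$values

#' Subset a kinship matrix to a set of sample ids
#'
#' @param k a `kinship_matrix`.
#' @param ids character vector of sample ids (must all be present).
#' @return A `kinship_matrix` restricted to `ids`, in the given order.
#' @export
kin_subset <- function(k, ids) {
  miss <- setdiff(ids, k$ids)
  if (length(miss))
    stop("samples absent from kinship matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  kinship_matrix(k$values[ids, ids, drop = FALSE], source = k$source,
                 postprocessed = k$postprocessed, meta = k$meta)
}

#' Write a kinship matrix to CSV
#'
#' Square layout has an `id` header column followed by one column per sample;
#' long layout has columns `id1,id2,value` covering the upper triangle
#' including the diagonal.
#'
#' @param k a `kinship_matrix`.
#' @param path output file.
#' @param layout `"square"` or `"long"`.
#' @export
write_kinship <- function(k, path, layout = c("square", "long")) {
  layout <- match.arg(layout)
  if (layout == "square") {
    df <- data.frame(id = k$ids, k$values, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    ut <- which(upper.tri(k$values, diag = TRUE), arr.ind = TRUE)
    df <- data.frame(id1 = k$ids[ut[, 1]], id2 = k$ids[ut[, 2]],
                     value = k$values[ut])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a kinship matrix from CSV
#'
#' Accepts the two layouts written by [write_kinship()]; the layout is
#' detected from the header. Use this to import externally computed
#' empirical matrices (e.g. LDAK or IBDLD output reshaped to CSV) so they
#' can be compared with, or substituted for, the built-in estimators.
#'
#' @param path CSV file.
#' @param source provenance label recorded on the object.
#' @param postprocessed whether the stored matrix has already been
#'   negative-zeroed and diagonal-scaled.
#' @return A `kinship_matrix`.
#' @export
import_kinship <- function(path, source = c("empirical", "pedigree"),
                           postprocessed = FALSE) {
  source <- match.arg(source)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("id1", "id2", "value")) && ncol(df) == 3) {
    ids <- unique(c(df$id1, df$id2))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(df$id1, ids), match(df$id2, ids))] <- df$value
    m[cbind(match(df$id2, ids), match(df$id1, ids))] <- df$value
  } else {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    if (!identical(colnames(m), ids))
      stop("square kinship CSV header does not match its id column")
    storage.mode(m) <- "double"
  }
  kinship_matrix(m, source = source, postprocessed = postprocessed,
                 meta = list(file = path))
}
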