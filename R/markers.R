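#' Marker quality control
#'
#' Discards markers with more than `max_missing` missing calls and markers
#' with minor allele frequency below `min_maf` (boundary semantics: strictly
#' greater missingness is removed, strictly smaller MAF is removed). MAF is
#' computed from observed (non-missing) calls. Lines are never removed.
#'
#' @param M Integer matrix, lines x markers, codes 0/1/2 with `NA` for
#'   missing (count of the minor allele).
#' @param max_missing Maximum tolerated missing fraction per marker.
#' @param min_maf Minimum tolerated minor allele frequency.
#' @return The filtered matrix with an attribute `qc_report`: list with
#'   counts of markers removed by each rule and the thresholds used.
#' @export
qc_markers <- function(M, max_missing = 0.30, min_maf = 0.05) {
  stopifnot(is.matrix(M))
  bad_codes <- !(M %in% c(0L, 1L, 2L, NA))
  if (any(bad_codes)) stop("marker codes must be 0, 1, 2 or NA")
  n <- nrow(M)
  miss_frac <- colMeans(is.na(M))
  pbar <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(pbar, 1 - pbar)
  maf[is.nan(maf)] <- 0  # all-missing column
  fail_miss <- miss_frac > max_missing
  fail_maf <- !fail_miss & maf < min_maf
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) {
    stop("all ", ncol(M), " markers removed by QC; review max_missing (",
         max_missing, ") and min_maf (", min_maf, ")")
  }
  out <- M[, keep, drop = FALSE]
  attr(out, "qc_report") <- list(
    n_in = ncol(M), n_removed_missing = sum(fail_miss),
    n_removed_maf = sum(fail_maf), n_kept = sum(keep),
    max_missing = max_missing, min_maf = min_maf)
  out
}

#' Impute and standardize marker codes
#'
#' Missing codes are replaced by the marker's observed mean; each column is
#' then centered and scaled to unit (sample) standard deviation.
#'
#' @param M QC'd marker matrix (see [qc_markers()]).
#' @return Numeric matrix `X` with column means 0 and column sds 1; attribute
#'   `p` holds the marker count.
#' @export
impute_and_standardize <- function(M) {
  stopifnot(is.matrix(M))
  X <- M
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas) > 0) X[nas] <- mu[nas[, 2]]
  X <- sweep(X, 2, colMeans(X), `-`)
  sds <- sqrt(colSums(X^2) / (nrow(X) - 1))
  if (any(sds < 1e-12)) {
    stop("zero-variance marker after imputation (column ",
         which(sds < 1e-12)[1], "); it should have been removed by the MAF filter")
  }
  X <- sweep(X, 2, sds, `/`)
  attr(X, "p") <- ncol(X)
  X
}

#' Build the genomic relationship matrix G
#'
#' `G = X X' / p` from the column-standardized genotype matrix; the mean of
#' its diagonal is ~1.
#'
#' @param X Standardized genotypes (see [impute_and_standardize()]).
#' @return A [kernel] named `"G"` over the line ids (rownames of `X`).
#' @export
build_G <- function(X) {
  stopifnot(is.matrix(X))
  p <- ncol(X)
  if (p == 0) stop("no markers: cannot build G")
  G <- tcrossprod(X) / p
  kernel(G, ids = rownames(X), name = "G", provenance = "XX'/p")
}

#' Read a marker matrix
#'
#' TSV with a header row of marker ids; first column holds line ids, the
#' remaining columns hold codes 0/1/2 with `NA` for missing.
#'
#' @param path File path.
#' @return Integer matrix lines x markers with dimnames.
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate line ids in marker file: ", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "integer"
  rownames(M) <- ids
  M
}

#' Write a marker matrix as TSV
#'
#' @param M Marker matrix with line ids as rownames.
#' @param path Output path.
#' @export
write_markers <- function(M, path) {
  df <- data.frame(GID = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
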