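#' Read / write a protein x voxel intensity matrix TSV
#'
#' Rows are protein accessions, columns voxel ids, cells log2 intensities;
#' an empty cell is a missing value.
#'
#' @param m numeric matrix with accession rownames and voxel-id colnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(protein = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every voxel (column) onto a common intensity distribution: after
#' normalization the sorted values of each column equal the row-wise means
#' of the column-sorted input. Applied to log2 intensities after the
#' fully-quantified filter. Idempotent.
#'
#' @param m complete numeric matrix (proteins x voxels).
#' @return matrix of the same shape with dimnames preserved.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m))
    stop("matrix contains missing values; apply fully_quantified() first",
         call. = FALSE)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Keep only fully quantified proteins
#'
#' Label-free quantitation across voxels leaves gaps; downstream network
#' and map analyses use only rows quantified in every voxel.
#'
#' @param m numeric matrix with possible `NA` entries.
#' @return the rows of `m` with no missing entries, order preserved.
#' @export
fully_quantified <- function(m) {
  keep <- rowSums(is.na(m)) == 0L
  if (!any(keep))
    stop("no protein is quantified in every voxel", call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Per-protein standard error across voxels
#'
#' The spatial-variability score: sample standard deviation of a
#' protein's log2 intensities across voxels divided by the square root of
#' the number of voxels.
#'
#' @param m complete numeric matrix (proteins x voxels), >= 2 voxels.
#' @return named numeric vector, one SE per protein.
#' @export
spatial_se <- function(m) {
  if (ncol(m) < 2L) stop("need >= 2 voxels to compute SE", call. = FALSE)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  apply(m, 1L, stats::sd) / sqrt(ncol(m))
}

#' Filter the most spatially variable proteins
#'
#' Retains proteins whose intensity SE across voxels strictly exceeds the
#' cutoff (default 0.18), i.e. the proteins whose abundance actually
#' changes over the slide; flat housekeeping background falls below it.
#'
#' @param m complete numeric matrix.
#' @param cutoff SE threshold; retained iff `SE > cutoff` (strict).
#' @return An `se_filter` list: `se` (all proteins), `cutoff`, `retained`
#'   (accessions), and `matrix` (the retained rows of `m`).
#' @export
se_filter <- function(m, cutoff = 0.18) {
  se <- spatial_se(m)
  retained <- names(se)[se > cutoff]
  structure(list(se = se, cutoff = cutoff, retained = retained,
                 matrix = m[retained, , drop = FALSE]),
            class = "se_filter")
}

#' @export
print.se_filter <- function(x, ...) {
  cat(sprintf("se_filter: %d / %d proteins retained at SE > %g\n",
              length(x$retained), length(x$se), x$cutoff))
  invisible(x)
}

#' Voxel-voxel Pearson correlation
#'
#' Reproducibility summary: correlation of the full protein intensity
#' profiles of every pair of voxels.
#'
#' @param m complete numeric matrix with >= 3 proteins.
#' @return symmetric voxel x voxel correlation matrix, unit diagonal.
#' @export
voxel_correlation <- function(m) {
  if (nrow(m) < 3L) stop("need >= 3 proteins", call. = FALSE)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  v <- apply(m, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance voxel column(s): ",
         paste(colnames(m)[v == 0], collapse = ", "), call. = FALSE)
  stats::cor(m)
}
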