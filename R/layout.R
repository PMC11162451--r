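#' Build a rectangular voxel layout
#'
#' A voxelated slide is modelled as a rectangular grid of unit-square
#' polygons numbered row-major from 1. Voxels can be flagged as excluded
#' (e.g. dropped for contamination) without being deleted, so that the
#' slide geometry stays intact for plotting while downstream analyses use
#' only the retained voxels. The default study layout is a 4 x 5 grid with
#' voxels 2, 5 and 8 excluded, leaving 17 analysis voxels.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param excluded integer ids of voxels to flag as excluded; must lie in
#'   `1..n_rows*n_cols`.
#' @return An object of class `voxel_layout`: a list with `n_rows`,
#'   `n_cols`, and `voxels`, a data frame with columns `voxel_id`, `row`,
#'   `col`, `excluded`, plus a `polygons` list of 4 x 2 vertex matrices in
#'   slide coordinates (column units x, row units y).
#' @examples
#' lay <- generate_layout(4, 5, c(2, 5, 8))
#' sum(!lay$voxels$excluded)  # 17
#' @export
generate_layout <- function(n_rows = 4L, n_cols = 5L, excluded = integer()) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1L, n_cols >= 1L)
  n <- as.integer(n_rows) * as.integer(n_cols)
  excluded <- as.integer(excluded)
  if (anyNA(excluded) || any(excluded < 1L | excluded > n))
    stop("excluded voxel ids must lie in 1..", n, call. = FALSE)
  ids <- seq_len(n)
  row <- (ids - 1L) %/% n_cols + 1L
  col <- (ids - 1L) %% n_cols + 1L
  polygons <- lapply(ids, function(i) {
    x0 <- col[i] - 1L; y0 <- row[i] - 1L
    cbind(x = c(x0, x0 + 1, x0 + 1, x0),
          y = c(y0, y0, y0 + 1, y0 + 1))
  })
  voxels <- data.frame(voxel_id = ids, row = row, col = col,
                       excluded = ids %in% excluded)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 voxels = voxels, polygons = polygons),
            class = "voxel_layout")
}

#' Retained (analysis) voxel ids of a layout
#' @param layout a `voxel_layout`.
#' @return integer vector of non-excluded voxel ids, ascending.
#' @export
retained_voxels <- function(layout) {
  stopifnot(inherits(layout, "voxel_layout"))
  layout$voxels$voxel_id[!layout$voxels$excluded]
}

#' @export
print.voxel_layout <- function(x, ...) {
  cat(sprintf("voxel_layout: %d x %d grid, %d voxels (%d retained, %d excluded)\n",
              x$n_rows, x$n_cols, nrow(x$voxels),
              sum(!x$voxels$excluded), sum(x$voxels$excluded)))
  invisible(x)
}

#' Write / read a voxel layout as JSON
#'
#' One record per voxel: `{voxel_id, polygon: [[x,y], ...], excluded}`.
#'
#' @param layout a `voxel_layout`.
#' @param path file path.
#' @return `write_layout_json` returns `path` invisibly; `read_layout_json`
#'   returns a `voxel_layout` (grid dimensions recovered from the polygon
#'   extents).
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "voxel_layout"))
  recs <- lapply(seq_len(nrow(layout$voxels)), function(i) {
    list(voxel_id = layout$voxels$voxel_id[i],
         polygon = apply(layout$polygons[[i]], 1, as.numeric, simplify = FALSE),
         excluded = layout$voxels$excluded[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  recs <- jsonlite::read_json(path)
  ids <- vapply(recs, function(r) as.integer(r$voxel_id), integer(1))
  polys <- lapply(recs, function(r)
    do.call(rbind, lapply(r$polygon, function(v) c(x = v[[1]], y = v[[2]]))))
  for (p in polys)
    if (nrow(p) < 3L) stop("polygon with fewer than 3 vertices", call. = FALSE)
  excl <- vapply(recs, function(r) isTRUE(r$excluded), logical(1))
  xmax <- max(vapply(polys, function(p) max(p[, 1]), numeric(1)))
  ymax <- max(vapply(polys, function(p) max(p[, 2]), numeric(1)))
  lay <- generate_layout(as.integer(ymax), as.integer(xmax), ids[excl])
  ord <- match(lay$voxels$voxel_id, ids)
  lay$polygons <- polys[ord]
  lay
}
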