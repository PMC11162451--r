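#' Term-summed spatial intensity map
#'
#' For a named protein set (an annotation term's members), the per-voxel
#' summed intensity. The matrix holds log2 intensities, so the default
#' linear scale back-transforms (`2^x`) before summing — summing log
#' intensities has no physical meaning, though a log2-scale sum is
#' available for comparison. Members absent from the matrix are reported,
#' not an error.
#'
#' @param m complete numeric matrix of log2 intensities (proteins x
#'   voxels).
#' @param members accessions in the term.
#' @param term name of the term (carried along for labelling).
#' @param scale `"linear"` (default) or `"log2"`.
#' @return A `term_map` list: `term`, `values` (named per-voxel sums),
#'   `members_used`, `members_absent`, `scale`.
#' @export
term_summed_intensity <- function(m, members, term = "term",
                                  scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  present <- intersect(members, rownames(m))
  if (length(present) == 0L)
    stop("no term member present in the matrix", call. = FALSE)
  sub <- m[present, , drop = FALSE]
  if (scale == "linear") sub <- 2^sub
  structure(list(term = term, values = colSums(sub),
                 members_used = present,
                 members_absent = setdiff(members, present),
                 scale = scale),
            class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("term_map %s: %d members (%d absent), %s scale\n",
              x$term, length(x$members_used), length(x$members_absent),
              x$scale))
  print(round(x$values, 3))
  invisible(x)
}

#' Rescale per-voxel values to the unit interval
#'
#' Linear min-max scaling for the heatmap colour ramp: the minimum maps
#' to 0, the maximum to 1. When all values are equal the range is
#' degenerate and every voxel maps to the neutral mid-ramp 0.5.
#'
#' @param values named numeric vector (>= 1 voxel, all finite).
#' @return named numeric vector in `[0,1]`.
#' @export
heatmap_scale <- function(values) {
  if (inherits(values, "term_map")) values <- values$values
  if (length(values) == 0L || !all(is.finite(values)))
    stop("values must be non-empty and finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(stats::setNames(rep(0.5, length(values)),
                                               names(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

ramp_fill <- function(s) {
  # dark blue (0,0,139) -> dark red (139,0,0), linear in s
  sprintf("rgb(%d,0,%d)", as.integer(round(139 * s)),
          as.integer(round(139 * (1 - s))))
}

#' Render a voxel choropleth as SVG
#'
#' One polygon per voxel: retained voxels filled along a linear dark-blue
#' to dark-red ramp by their scaled value, excluded voxels (and retained
#' voxels lacking a value, with a warning) filled grey. The output is a
#' standalone SVG document; rendering is deterministic.
#'
#' @param layout a [generate_layout()] `voxel_layout`.
#' @param scaled named per-voxel scalars in `[0,1]` (names = voxel ids;
#'   keys must be retained voxels).
#' @param path optional file to write to.
#' @param cell_px pixel size of one grid cell (default 60).
#' @return the SVG document as a single character string (invisibly when
#'   `path` is given).
#' @export
render_svg <- function(layout, scaled, path = NULL, cell_px = 60) {
  stopifnot(inherits(layout, "voxel_layout"))
  ids <- as.character(layout$voxels$voxel_id)
  ret <- as.character(retained_voxels(layout))
  if (length(setdiff(names(scaled), ret)))
    stop("scaled values given for non-retained voxels: ",
         paste(setdiff(names(scaled), ret), collapse = ", "), call. = FALSE)
  missing_vox <- setdiff(ret, names(scaled))
  if (length(missing_vox))
    warning("no value for retained voxel(s) ",
            paste(missing_vox, collapse = ", "), "; rendered grey")
  w <- layout$n_cols * cell_px
  h <- layout$n_rows * cell_px
  polys <- vapply(seq_along(ids), function(i) {
    p <- layout$polygons[[i]] * cell_px
    id <- ids[i]
    fill <- if (layout$voxels$excluded[i] || !(id %in% names(scaled)))
      "rgb(128,128,128)" else ramp_fill(scaled[[id]])
    pts <- paste(sprintf("%g,%g", p[, 1], p[, 2]), collapse = " ")
    sprintf(paste0('  <polygon points="%s" fill="%s" stroke="black"',
                   ' stroke-width="1"/>\n',
                   '  <text x="%g" y="%g" font-size="%g"',
                   ' text-anchor="middle" fill="white">%s</text>'),
            pts, fill, mean(p[, 1]), mean(p[, 2]) + cell_px * 0.1,
            cell_px * 0.25, id)
  }, character(1))
  svg <- paste0(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">\n'),
            w, h, w, h),
    paste(polys, collapse = "\n"), "\n</svg>\n")
  if (!is.null(path)) {
    writeLines(svg, path, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Hypergeometric term enrichment
#'
#' Local over-representation test of a query protein set against a term
#' membership table: per term, the upper-tail hypergeometric probability
#' of observing at least the seen overlap given the term's size in the
#' universe, Benjamini-Hochberg adjusted across tested terms. Empty terms
#' (no member in the universe) are skipped.
#'
#' @param query protein accessions (must all lie in `universe`).
#' @param annotation named list: term -> member accessions.
#' @param universe background accession set.
#' @return data frame `term`, `overlap`, `term_size`, `p`, `fdr`, sorted
#'   ascending by `p`.
#' @export
hypergeometric_enrichment <- function(query, annotation, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(setdiff(query, universe)))
    stop("query proteins outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "),
         call. = FALSE)
  stopifnot(length(annotation) >= 1L, !is.null(names(annotation)))
  rows <- lapply(names(annotation), function(term) {
    members <- intersect(annotation[[term]], universe)
    if (length(members) == 0L) return(NULL)
    ov <- length(intersect(query, members))
    p <- stats::phyper(ov - 1L, length(members),
                       length(universe) - length(members),
                       length(query), lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = length(members), p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no term has members in the universe", call. = FALSE)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a term membership table
#'
#' Two dialects: a two-column TSV (`term_id`, `accession`, one row per
#' membership) or GMT (one term per line: id, description, then members).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gmt"`.
#' @return named list term -> member accessions.
#' @export
read_terms <- function(path, format = c("tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    return(split(df[[2]], df[[1]]))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, character(1), 1L))
}
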