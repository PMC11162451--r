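#' Protein-protein spatial correlation
#'
#' Signed Pearson correlation between the spatial intensity profiles
#' (rows) of every protein pair — the raw co-regulation signal behind the
#' adjacency network.
#'
#' @param m complete numeric matrix (proteins x voxels), >= 3 voxels.
#' @return symmetric protein x protein correlation matrix, unit diagonal.
#' @export
protein_correlation <- function(m) {
  if (ncol(m) < 3L) stop("need >= 3 voxels", call. = FALSE)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  v <- apply(m, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance protein row(s): ",
         paste(rownames(m)[v == 0], collapse = ", "), call. = FALSE)
  stats::cor(t(m))
}

#' Soft-threshold co-regulation adjacency
#'
#' Maps signed correlations to connection strengths in `[0,1]` with a
#' soft power that suppresses weak links while keeping the network
#' weighted: unsigned mode `a = |r|^beta` (anti-correlated partners stay
#' adjacent), signed mode `a = ((1+r)/2)^beta` (anti-correlation maps to
#' 0). Defaults follow the weighted co-expression convention: beta 6
#' unsigned, 12 signed.
#'
#' @param r signed Pearson matrix (e.g. [protein_correlation()]).
#' @param beta soft power, >= 1.
#' @param mode `"unsigned"` or `"signed"`.
#' @return An `adjacency_matrix` list: `adjacency` (strengths, unit
#'   diagonal), `correlation` (the signed input, kept so inverse partners
#'   remain identifiable), `beta`, `mode`.
#' @export
soft_adjacency <- function(r, beta = if (mode == "signed") 12 else 6,
                           mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  stopifnot(beta >= 1)
  a <- if (mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  structure(list(adjacency = a, correlation = r, beta = beta, mode = mode),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("adjacency_matrix: %d proteins, %s mode, beta = %g\n",
              nrow(x$adjacency), x$mode, x$beta))
  invisible(x)
}

as_adjacency <- function(a) {
  if (inherits(a, "adjacency_matrix")) a$adjacency else a
}

#' Topological overlap matrix
#'
#' Smooths an adjacency matrix by shared-neighbour structure:
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' connectivities `k_i = sum_{u != i} a_iu`, unit diagonal. Two proteins
#' overlap topologically when they are connected to the same part of the
#' network, which stabilises module detection against single noisy
#' correlations.
#'
#' @param a an `adjacency_matrix` or plain adjacency matrix.
#' @return symmetric matrix in `[0,1]` with unit diagonal.
#' @export
topological_overlap <- function(a) {
  a <- as_adjacency(a)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a          # sum over all u of a_iu a_uj excludes i,j via zero diag
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Seed-protein neighborhood
#'
#' The proteins most strongly co-regulated with a chosen seed, ranked by
#' adjacency (descending, ties broken by ascending accession; the seed is
#' excluded from its own list). Selection is either the top `k` proteins
#' or all proteins on one side of an adjacency threshold — `"ge"` keeps
#' strong partners (`a >= t`), `"le"` keeps weak ones (`a <= t`), kept
#' configurable because published neighbourhood cutoffs have been stated
#' in both directions.
#'
#' @param a an `adjacency_matrix` or plain adjacency matrix.
#' @param seed seed accession (must be a row of the matrix).
#' @param k number of neighbors for the top-k rule.
#' @param threshold adjacency threshold (used when `k` is `NULL`).
#' @param direction `"ge"` or `"le"`, threshold-rule direction.
#' @return A `seed_neighborhood` list: `seed`, `neighbors` (data frame
#'   `protein`, `adjacency`, and `correlation` if available), `rule`.
#' @export
seed_neighborhood <- function(a, seed, k = 23L, threshold = NULL,
                              direction = c("ge", "le")) {
  direction <- match.arg(direction)
  adj <- as_adjacency(a)
  if (!seed %in% rownames(adj))
    stop("seed protein not found: ", seed, call. = FALSE)
  v <- adj[seed, ]
  v <- v[names(v) != seed]
  ord <- order(-v, names(v))
  v <- v[ord]
  if (is.null(k)) {
    keep <- if (direction == "ge") v >= threshold else v <= threshold
    v <- v[keep]
    rule <- list(type = "threshold", threshold = threshold,
                 direction = direction)
  } else {
    v <- utils::head(v, k)
    rule <- list(type = "top_k", k = k)
  }
  nb <- data.frame(protein = names(v), adjacency = as.numeric(v))
  if (inherits(a, "adjacency_matrix"))
    nb$correlation <- a$correlation[seed, nb$protein]
  structure(list(seed = seed, neighbors = nb, rule = rule),
            class = "seed_neighborhood")
}

#' @export
print.seed_neighborhood <- function(x, ...) {
  cat(sprintf("seed_neighborhood of %s: %d neighbors (%s rule)\n",
              x$seed, nrow(x$neighbors), x$rule$type))
  print(utils::head(x$neighbors, 10), row.names = FALSE)
  invisible(x)
}

#' Inversely regulated partners of a seed protein
#'
#' Proteins whose spatial profile is strongly anti-correlated with the
#' seed (`r <= -t`), most negative first — candidates for opposing
#' regulation (e.g. keratins moving against a hormonally induced marker).
#'
#' @param r signed Pearson matrix or an `adjacency_matrix` (its
#'   correlation component is used).
#' @param seed seed accession.
#' @param t threshold in `(0, 1]`.
#' @return data frame `protein`, `correlation`, sorted ascending by
#'   correlation.
#' @export
inverse_partners <- function(r, seed, t = 0.6) {
  if (inherits(r, "adjacency_matrix")) r <- r$correlation
  stopifnot(t > 0, t <= 1)
  if (!seed %in% rownames(r))
    stop("seed protein not found: ", seed, call. = FALSE)
  v <- r[seed, ]
  v <- v[names(v) != seed]
  v <- v[v <= -t]
  v <- v[order(v, names(v))]
  data.frame(protein = names(v), correlation = as.numeric(v),
             row.names = NULL)
}

#' Thresholded weighted edge list
#'
#' Undirected edges `(i < j)` among the given nodes with adjacency at or
#' above the threshold, weight = adjacency.
#'
#' @param a an `adjacency_matrix` or plain adjacency matrix.
#' @param nodes accessions to include (default: all).
#' @param t edge threshold; edges kept iff `a_ij >= t`.
#' @return data frame `source`, `target`, `weight`.
#' @export
edge_list <- function(a, nodes = NULL, t = 0) {
  adj <- as_adjacency(a)
  if (is.null(nodes)) nodes <- rownames(adj)
  miss <- setdiff(nodes, rownames(adj))
  if (length(miss))
    stop("nodes absent from adjacency: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nodes <- sort(nodes)
  sub <- adj[nodes, nodes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub >= t, arr.ind = TRUE)
  out <- data.frame(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                    weight = sub[idx])
  out[order(out$source, out$target), , drop = FALSE]
}

#' Write an edge list as GraphML
#'
#' @param edges data frame from [edge_list()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Detect co-regulation modules
#'
#' Average-linkage hierarchical clustering on the topological-overlap
#' dissimilarity `1 - TOM`, cut at a fixed height; clusters of size 1 get
#' the unassigned label `"0"`, real modules are labelled `"1"`, `"2"`, ...
#' by decreasing size.
#'
#' @param a an `adjacency_matrix` or plain adjacency matrix (>= 2
#'   proteins).
#' @param cut_height dissimilarity at which the tree is cut (default
#'   0.5).
#' @return named character vector: module label per protein.
#' @export
detect_modules <- function(a, cut_height = 0.5) {
  adj <- as_adjacency(a)
  stopifnot(nrow(adj) >= 2L)
  tom <- topological_overlap(adj)
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  real <- names(sizes)[sizes > 1L]
  real <- real[order(-sizes[real], as.integer(real))]
  lab <- stats::setNames(rep("0", length(cl)), names(cl))
  for (i in seq_along(real)) lab[cl == as.integer(real[i])] <- as.character(i)
  lab
}
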