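#' Sum spectral counts per protein
#'
#' Spectral counts are a rough abundance proxy; summing them per protein
#' over all peptide records gives the count table used for rank-abundance
#' curves and cross-dataset comparisons (e.g. to argue that keratins rank
#' consistently across preparations and are not handling contaminants).
#'
#' @param records peptide records (see [validate_peptide_records()]).
#' @return data frame `protein`, `count`, accessions unique, sorted by
#'   accession.
#' @export
sum_spectral_counts <- function(records) {
  validate_peptide_records(records)
  if (nrow(records) == 0L)
    return(data.frame(protein = character(), count = integer()))
  s <- tapply(records$spectral_count, records$protein, sum)
  out <- data.frame(protein = names(s), count = as.integer(s))
  out[order(out$protein), , drop = FALSE]
}

#' Rank proteins by spectral count
#'
#' Descending count, ties broken by ascending accession for a
#' deterministic ordinal position; a `mean_rank` column carries the
#' tie-averaged rank used for concordance statistics.
#'
#' @param table a count table (`protein`, `count`).
#' @return data frame `rank` (ordinal), `mean_rank`, `protein`, `count`.
#' @export
rank_proteins <- function(table) {
  stopifnot(nrow(table) >= 1L)
  ord <- order(-table$count, table$protein)
  out <- table[ord, c("protein", "count"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$mean_rank <- rank(-out$count, ties.method = "average")
  rownames(out) <- NULL
  out[, c("rank", "mean_rank", "protein", "count")]
}

#' Rank concordance of two count tables on a protein subset
#'
#' Spearman rank correlation of the tie-averaged abundance ranks of the
#' proteins in `subset` that appear in both tables. Ranks are taken
#' within each full table, then restricted to the subset, so a protein's
#' rank reflects its position in its whole dataset.
#'
#' @param t1,t2 count tables (`protein`, `count`).
#' @param subset protein accessions to compare (>= 3 must be present in
#'   both tables).
#' @return Spearman coefficient in `[-1, 1]`.
#' @export
rank_concordance <- function(t1, t2, subset) {
  r1 <- rank_proteins(t1); r2 <- rank_proteins(t2)
  common <- intersect(intersect(subset, r1$protein), r2$protein)
  if (length(common) < 3L)
    stop("insufficient overlap: only ", length(common),
         " subset proteins present in both tables (need >= 3)",
         call. = FALSE)
  a <- r1$mean_rank[match(common, r1$protein)]
  b <- r2$mean_rank[match(common, r2$protein)]
  stats::cor(a, b, method = "spearman")
}
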