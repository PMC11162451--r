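#' Per-voxel semi-tryptic peptide fraction
#'
#' Fraction of unique peptides (distinct sequence + modification set per
#' voxel) classified [classify_termini()] as `semi_tryptic`, per voxel.
#' Digestion of fixed tissue is harsh, so the semi-tryptic rate is a core
#' digest quality metric; well-behaved voxels sit in the low percent
#' range.
#'
#' @param records peptide records (see [validate_peptide_records()]).
#' @param rule a [cleavage_rule()].
#' @return named numeric vector, one fraction in `[0,1]` per voxel.
#' @export
semi_tryptic_fraction <- function(records, rule = cleavage_rule()) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  cls <- classify_termini(u$peptide, u$prev_aa, u$next_aa, rule)
  vapply(split(cls == "semi_tryptic", u$voxel), mean, numeric(1))
}

#' Per-voxel miscleaved peptide fraction
#'
#' Fraction of unique peptides per voxel retaining at least one internal
#' rule-conforming cleavage site ([internal_sites()] > 0).
#'
#' @inheritParams semi_tryptic_fraction
#' @return named numeric vector per voxel.
#' @export
miscleavage_fraction <- function(records, rule = cleavage_rule()) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  mis <- internal_sites(u$peptide, rule) > 0L
  vapply(split(mis, u$voxel), mean, numeric(1))
}

#' Lysine:arginine cleavage preference
#'
#' Trypsin cleaves both K and R but not with equal efficiency; the K:R
#' ratio is measured in two contexts: the C-terminal residue of each
#' identified peptide (protein C-terminal peptides excluded, as their
#' terminus is not a cleavage event), and the residue immediately
#' upstream of the peptide's N-terminus (protein N-terminal peptides
#' excluded).
#'
#' @inheritParams semi_tryptic_fraction
#' @return list with elements `c_term` and `upstream`, each the K count
#'   divided by the R count in that context.
#' @export
kr_cleavage_ratio <- function(records, rule = cleavage_rule()) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  last <- substr(u$peptide, nchar(u$peptide), nchar(u$peptide))
  ct <- last[u$next_aa != "-"]
  up <- u$prev_aa[u$prev_aa != "-"]
  ratio <- function(x, context) {
    nr <- sum(x == "R")
    if (nr == 0L)
      stop("undefined K:R ratio: no arginine events in ", context,
           " context", call. = FALSE)
    sum(x == "K") / nr
  }
  list(c_term = ratio(ct, "C-terminal"), upstream = ratio(up, "upstream"))
}

# bin observed shifts to catalog entries within tolerance; unmatched
# shifts keep their own value rounded to 4 decimals
bin_shift <- function(shift, catalog) {
  tol <- attr(catalog, "match_tolerance")
  vapply(shift, function(s) {
    d <- abs(catalog$shift - s)
    if (min(d) <= tol) catalog$shift[which.min(d)] else round(s, 4)
  }, numeric(1))
}

#' Mass-shift frequency table
#'
#' Open searches report a delta mass per peptide; this summarises how
#' often each (catalog-binned) mass shift occurs, as a percentage of all
#' unique peptides. A peptide carrying the same shift at several positions
#' counts once for that shift; a peptide with two distinct shifts counts
#' once for each. Shifts in `exclusions` (e.g. the fixed
#' carbamidomethylation and common methionine oxidation the search
#' already models) are dropped before ranking.
#'
#' @inheritParams semi_tryptic_fraction
#' @param exclusions numeric mass shifts to drop (matched within the
#'   catalog tolerance).
#' @param top_n number of rows to keep (default 8), ranked by frequency,
#'   ties broken by ascending shift.
#' @param catalog a `mod_catalog` used for binning and naming.
#' @return data frame with columns `shift`, `name`, `n_peptides`,
#'   `frequency_pct`.
#' @export
mass_shift_table <- function(records, exclusions = numeric(), top_n = 8L,
                             catalog = default_catalog()) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  n_total <- nrow(u)
  mods <- parse_modifications(u$assigned_modifications)
  tol <- attr(catalog, "match_tolerance")
  shifts <- unlist(lapply(mods, function(m) unique(bin_shift(m$shift, catalog))))
  if (length(exclusions))
    shifts <- shifts[vapply(shifts, function(s)
      all(abs(s - exclusions) > tol), logical(1))]
  if (length(shifts) == 0L)
    return(data.frame(shift = numeric(), name = character(),
                      n_peptides = integer(), frequency_pct = numeric()))
  tab <- table(shifts)
  shift <- as.numeric(names(tab))
  nm <- vapply(shift, function(s) {
    hit <- annotate_mass_shift(s, catalog)
    if (length(hit)) hit[1] else "unannotated"
  }, character(1))
  out <- data.frame(shift = shift, name = nm,
                    n_peptides = as.integer(tab),
                    frequency_pct = 100 * as.integer(tab) / n_total)
  out <- out[order(-out$frequency_pct, out$shift), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Residue distribution of a mass shift
#'
#' For the unique peptides carrying a given shift, the percentage borne by
#' each amino acid at the modified position. Peptides with several events
#' of the shift contribute each event with weight 1/(number of events), so
#' percentages sum to 100.
#'
#' @inheritParams mass_shift_table
#' @param shift mass shift of interest in Da.
#' @return named numeric vector of percentages per residue (sums to 100);
#'   empty (with a warning) when no peptide carries the shift.
#' @export
residue_distribution <- function(records, shift,
                                 catalog = default_catalog()) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  tol <- attr(catalog, "match_tolerance")
  mods <- parse_modifications(u$assigned_modifications)
  w <- list()
  n_carrier <- 0L
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    hit <- which(abs(m$shift - shift) <= tol)
    if (length(hit) == 0L) next
    n_carrier <- n_carrier + 1L
    res <- substr(rep(u$peptide[i], length(hit)), m$pos[hit], m$pos[hit])
    for (r in res) w[[r]] <- (if (is.null(w[[r]])) 0 else w[[r]]) +
        1 / length(hit)
  }
  if (n_carrier == 0L) {
    warning("no peptide carries mass shift ", shift)
    return(stats::setNames(numeric(), character()))
  }
  out <- 100 * unlist(w) / n_carrier
  sort(out, decreasing = TRUE)
}

#' Miscleavage x methylation stratification
#'
#' Assigns every unique peptide to exactly one of five categories:
#' tryptic-unmodified, tryptic-modified, miscleaved-unmodified,
#' miscleaved with lysine methylation (the nominal +14 Da shift on K),
#' and miscleaved with other modifications. Reported as fractions of the
#' total plus, for the miscleaved-and-modified subset, the conditional
#' split between methyl-K and other modifications — the comparison that
#' exposes whether lysine methylation blocks tryptic cleavage.
#'
#' @inheritParams semi_tryptic_fraction
#' @param methyl_shift mass shift of methylation (default +14.0157 Da).
#' @param tolerance Da window for matching the methyl shift.
#' @return list with `fractions` (named, sums to 1), `counts`, and
#'   `conditional` (named fractions over miscleaved-and-modified peptides;
#'   empty when that subset is empty).
#' @export
miscleavage_modification_stratification <- function(records,
                                                    rule = cleavage_rule(),
                                                    methyl_shift = 14.0157,
                                                    tolerance = 0.01) {
  validate_peptide_records(records)
  u <- dedupe_records(records)
  mods <- parse_modifications(u$assigned_modifications)
  mis <- internal_sites(u$peptide, rule) > 0L
  modified <- vapply(mods, nrow, integer(1)) > 0L
  methylK <- vapply(seq_along(mods), function(i) {
    m <- mods[[i]]
    any(abs(m$shift - methyl_shift) <= tolerance &
          substr(rep(u$peptide[i], nrow(m)), m$pos, m$pos) == "K")
  }, logical(1))
  cat5 <- ifelse(!mis & !modified, "tryptic_unmodified",
          ifelse(!mis, "tryptic_modified",
          ifelse(!modified, "miscleaved_unmodified",
          ifelse(methylK, "miscleaved_methylK", "miscleaved_other_modified"))))
  lev <- c("tryptic_unmodified", "tryptic_modified", "miscleaved_unmodified",
           "miscleaved_methylK", "miscleaved_other_modified")
  counts <- table(factor(cat5, levels = lev))
  fractions <- as.numeric(counts) / nrow(u)
  names(fractions) <- lev
  sub <- cat5[mis & modified]
  conditional <- if (length(sub) == 0L) stats::setNames(numeric(), character())
    else {
      ct <- table(factor(sub, levels = c("miscleaved_methylK",
                                         "miscleaved_other_modified")))
      stats::setNames(as.numeric(ct) / length(sub), names(ct))
    }
  list(fractions = fractions, counts = counts, conditional = conditional,
       category = stats::setNames(cat5, paste(u$voxel, u$peptide,
                                              u$assigned_modifications)))
}

#' Region counts for overlapping identification sets
#'
#' Venn-style membership counts: for two or more labelled identifier sets
#' (peptides or proteins identified by different search engines), the
#' number of elements in every membership pattern. Counts sum to the size
#' of the union.
#'
#' @param sets named list of character vectors (>= 2).
#' @return data frame with one row per non-empty membership pattern:
#'   columns `pattern` (labels joined by `&`) and `count`.
#' @export
identification_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab))
  out[order(-out$count, out$pattern), , drop = FALSE]
}

#' Subcellular localization distribution by keyword annotation
#'
#' Percentage of proteins annotated to each listed location; a protein
#' annotated to several locations counts in each (so the listed
#' percentages can sum above 100), and proteins carrying none of the
#' listed locations are reported as `not_annotated`.
#'
#' @param proteins character vector of protein accessions.
#' @param annotation data frame with columns `accession` and `location`
#'   (one row per protein-location pair).
#' @param locations ordered character vector of locations to report.
#' @return named numeric vector of percentages (locations then
#'   `not_annotated`), of the total number of proteins.
#' @export
subcellular_distribution <- function(proteins, annotation, locations) {
  stopifnot(length(locations) >= 1L)
  proteins <- unique(proteins)
  n <- length(proteins)
  ann <- annotation[annotation$accession %in% proteins &
                      annotation$location %in% locations, , drop = FALSE]
  pct <- vapply(locations, function(loc)
    100 * length(unique(ann$accession[ann$location == loc])) / n, numeric(1))
  annotated <- unique(ann$accession)
  c(pct, not_annotated = 100 * (n - length(annotated)) / n)
}
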