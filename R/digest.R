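#' Tryptic cleavage rule
#'
#' Trypsin cleaves C-terminal to lysine and arginine; cleavage is
#' suppressed when the following residue is proline (the convention of the
#' common search engines, configurable off with
#' `suppress_before = character()`).
#'
#' @param residues residues cleaved after (default K, R).
#' @param suppress_before residues that block cleavage when they follow a
#'   site (default P).
#' @param max_missed maximum internal sites retained in a digestion
#'   product (default 2).
#' @return A `cleavage_rule` list.
#' @export
cleavage_rule <- function(residues = c("K", "R"), suppress_before = "P",
                          max_missed = 2L) {
  stopifnot(length(residues) >= 1L, max_missed >= 0L)
  structure(list(residues = toupper(residues),
                 suppress_before = toupper(suppress_before),
                 max_missed = as.integer(max_missed)),
            class = "cleavage_rule")
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% AA_ALPHABET))
    stop("sequence contains characters outside the amino-acid alphabet: ",
         sequence, call. = FALSE)
  chars
}

# 1-based positions i such that cleavage occurs between i and i+1
cleavage_sites <- function(chars, rule) {
  n <- length(chars)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  i[chars[i] %in% rule$residues & !(chars[i + 1L] %in% rule$suppress_before)]
}

#' In-silico proteolytic digestion
#'
#' Cuts a protein sequence at every site allowed by the cleavage rule and
#' emits every contiguous product with at most `rule$max_missed` retained
#' internal sites, together with its flanking residues (`"-"` at the
#' protein termini) and missed-cleavage count.
#'
#' @param sequence protein sequence, uppercase one-letter codes.
#' @param rule a [cleavage_rule()].
#' @return data frame with columns `peptide`, `prev_aa`, `next_aa`,
#'   `n_missed`, `start`, ordered by start position then length.
#' @examples
#' in_silico_digest("MKWVTFISLLR", cleavage_rule(max_missed = 0))
#' @export
in_silico_digest <- function(sequence, rule = cleavage_rule()) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  sites <- cleavage_sites(chars, rule)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  k <- length(starts)
  out <- list()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + rule$max_missed)) {
      s <- starts[i]; e <- ends[j]
      out[[length(out) + 1L]] <- data.frame(
        peptide = paste(chars[s:e], collapse = ""),
        prev_aa = if (s == 1L) "-" else chars[s - 1L],
        next_aa = if (e == n) "-" else chars[e + 1L],
        n_missed = j - i,
        start = s,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, nchar(res$peptide)), , drop = FALSE]
}

#' Classify a peptide's termini against a cleavage rule
#'
#' A C-terminus conforms when the peptide ends in a cleavage residue not
#' followed by a suppressing residue, or sits at the protein C-terminus
#' (`next_aa == "-"`). An N-terminus conforms when the preceding residue
#' is a cleavage residue and the first peptide residue does not suppress
#' it, or the peptide sits at the protein N-terminus. Both conforming:
#' `fully_tryptic`; exactly one: `semi_tryptic`; neither: `non_tryptic`.
#'
#' @param peptide peptide sequence(s).
#' @param prev_aa,next_aa flanking residues (`"-"` at protein termini).
#' @param rule a [cleavage_rule()].
#' @return character vector in
#'   `c("fully_tryptic", "semi_tryptic", "non_tryptic")`.
#' @export
classify_termini <- function(peptide, prev_aa, next_aa,
                             rule = cleavage_rule()) {
  first <- substr(peptide, 1L, 1L)
  last <- substr(peptide, nchar(peptide), nchar(peptide))
  c_ok <- (last %in% rule$residues & !(next_aa %in% rule$suppress_before)) |
    next_aa == "-"
  n_ok <- (prev_aa %in% rule$residues & !(first %in% rule$suppress_before)) |
    prev_aa == "-"
  ifelse(c_ok & n_ok, "fully_tryptic",
         ifelse(c_ok | n_ok, "semi_tryptic", "non_tryptic"))
}

#' Count internal (missed) cleavage sites within a peptide
#'
#' @param peptide peptide sequence(s).
#' @param rule a [cleavage_rule()].
#' @return integer vector: number of rule-conforming sites at positions
#'   `1..len-1` of each peptide.
#' @export
internal_sites <- function(peptide, rule = cleavage_rule()) {
  vapply(peptide, function(p)
    length(cleavage_sites(strsplit(p, "")[[1]], rule)),
    integer(1), USE.NAMES = FALSE)
}
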