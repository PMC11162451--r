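#' Peptide identification tables
#'
#' The peptide-level interchange format mirrors open-search summary
#' output: one row per identified peptide occurrence with columns
#' `peptide`, `prev_aa`, `next_aa`, `protein`, `voxel`, `spectral_count`
#' and `assigned_modifications`, the latter a semicolon-separated list of
#' `position:mass_shift` events with 1-based positions within the peptide
#' (empty string = unmodified).
#'
#' @param records a peptide record data frame.
#' @return `validate_peptide_records` returns the records invisibly after
#'   checking the contract; errors otherwise.
#' @export
validate_peptide_records <- function(records) {
  need <- c("peptide", "prev_aa", "next_aa", "protein", "voxel",
            "spectral_count", "assigned_modifications")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("peptide table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) return(invisible(records))
  if (any(nchar(records$peptide) == 0L) ||
      any(records$peptide != toupper(records$peptide)))
    stop("peptide sequences must be non-empty and uppercase", call. = FALSE)
  if (any(records$spectral_count < 1L))
    stop("spectral_count must be >= 1", call. = FALSE)
  mods <- parse_modifications(records$assigned_modifications)
  bad <- vapply(seq_len(nrow(records)), function(i) {
    m <- mods[[i]]
    nrow(m) > 0L && (any(m$pos < 1L) || any(m$pos > nchar(records$peptide[i])))
  }, logical(1))
  if (any(bad))
    stop("modification positions outside 1..len(peptide)", call. = FALSE)
  invisible(records)
}

#' Parse `pos:shift` modification strings
#'
#' @param x character vector of semicolon-separated `position:mass_shift`
#'   event lists; `""` or `NA` means unmodified.
#' @return list of data frames with columns `pos` (integer) and `shift`
#'   (numeric), one per input string.
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s))
      return(data.frame(pos = integer(), shift = numeric()))
    ev <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(pos = vapply(ev, function(e) as.integer(e[1]), integer(1)),
               shift = vapply(ev, function(e) as.numeric(e[2]), numeric(1)))
  })
}

format_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0L) return("")
    paste(sprintf("%d:%.4f", m$pos, m$shift), collapse = ";")
  }, character(1))
}

# counting unit: distinct (sequence, modification-set) per voxel
dedupe_records <- function(records) {
  key <- paste(records$voxel, records$peptide, records$assigned_modifications,
               sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Read / write a peptide table TSV
#' @param records a peptide record data frame.
#' @param path file path.
#' @return `read_peptide_tsv` returns a validated record data frame.
#' @export
write_peptide_tsv <- function(records, path) {
  validate_peptide_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_peptide_tsv
#' @export
read_peptide_tsv <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = list(assigned_modifications = "character",
                                             peptide = "character"))
  rec$assigned_modifications[is.na(rec$assigned_modifications)] <- ""
  validate_peptide_records(rec)
  rec
}
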