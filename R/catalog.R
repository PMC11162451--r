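#' Bundled modification catalog
#'
#' Monoisotopic mass shifts computed from standard atomic masses
#' (H 1.00782503207, C 12 exactly, N 14.0030740048, O 15.9949146196 Da):
#' methylation +CH2, oxidation/hydroxylation +O, formylation +CO (the
#' nominal +28 Da adduct frequent on lysine in fixed tissue), dihydroxy
#' +O2, carbamidomethylation +C2H3NO, acetylation +C2H2O. Eligible
#' residues reflect the residues these adducts are observed on in
#' open-search summaries of FFPE digests.
#'
#' @param match_tolerance Da window for matching an observed delta mass to
#'   a catalog entry (default 0.01).
#' @return A `mod_catalog`: data frame with columns `name`, `shift`,
#'   `residues` (string of one-letter codes), and attribute
#'   `match_tolerance`.
#' @export
default_catalog <- function(match_tolerance = 0.01) {
  h <- 1.00782503207; c12 <- 12; n <- 14.0030740048; o <- 15.9949146196
  entries <- data.frame(
    name = c("methylation", "oxidation/hydroxylation", "formylation",
             "dihydroxy", "carbamidomethyl", "acetylation"),
    shift = c(c12 + 2 * h,            # CH2
              o,                      # O
              c12 + o,                # CO
              2 * o,                  # O2
              2 * c12 + 3 * h + n + o,  # C2H3NO
              2 * c12 + 2 * h + o),   # C2H2O
    residues = c("KR", "MPKWYF", "K", "PWMF", "C", "K"),
    stringsAsFactors = FALSE
  )
  stopifnot(match_tolerance > 0)
  structure(entries, match_tolerance = match_tolerance,
            class = c("mod_catalog", "data.frame"))
}

#' Annotate an observed mass shift against a catalog
#'
#' Returns every catalog entry whose monoisotopic shift lies within the
#' catalog's match tolerance of `delta`, nearest first. An empty character
#' vector means the shift is unannotated.
#'
#' @param delta observed mass shift in Da.
#' @param catalog a `mod_catalog` (default [default_catalog()]).
#' @return character vector of candidate modification names.
#' @examples
#' annotate_mass_shift(14.0156)  # "methylation"
#' annotate_mass_shift(15.9949)  # "oxidation/hydroxylation"
#' @export
annotate_mass_shift <- function(delta, catalog = default_catalog()) {
  stopifnot(nrow(catalog) > 0L, is.finite(delta))
  tol <- attr(catalog, "match_tolerance")
  d <- abs(catalog$shift - delta)
  hit <- which(d <= tol)
  catalog$name[hit[order(d[hit])]]
}
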