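#' Simulation configuration
#'
#' Bundles every parameter of the synthetic spatial-proteomics generator.
#' The layout defaults mirror the study design this package targets: a
#' 4 x 5 macrodissected grid with voxels 2, 5 and 8 excluded, leaving 17
#' analysis voxels. Intensity defaults plant two spatially co-regulated
#' modules of 10 proteins (gradient and hotspot profiles, 20% of members
#' anti-correlated) on a log2 baseline of 20 with noise SD 0.1 and 10%
#' missing values outside the fully-quantified module core. The loading
#' of 4 log2 units makes module members "spatially changed" in the sense
#' of the conventional SE > 0.18 variability cutoff (over 17 voxels that
#' cutoff demands a per-protein spatial SD of about 0.74 log2 units). Digest
#' defaults reproduce the QC levels reported for well-behaved FFPE
#' digests: 2% semi-tryptic, 11% base miscleavage, oxidation 6% /
#' dihydroxy 3% / formylation 1% of peptides, lysine methylation 3% with
#' a 0.9 probability that a methylated lysine escapes cleavage (so almost
#' every methyl-K peptide is miscleaved).
#'
#' @param n_rows,n_cols,excluded_voxels layout grid (see
#'   [generate_layout()]).
#' @param n_modules,proteins_per_module,n_background_proteins planted
#'   module structure.
#' @param module_profiles spatial pattern per module: `"gradient"`
#'   (linear in retained-voxel index), `"hotspot"` (1 on a centre voxel,
#'   decaying as `exp(-grid distance)`), or `"uniform"`.
#' @param loading_mean effect size lambda: module members get
#'   `x = mu + lambda * s(voxel) + noise`.
#' @param anti_fraction fraction of each module's members with negated
#'   loading.
#' @param baseline_mean log2-intensity baseline mu.
#' @param noise_sd log2-intensity noise SD (>= 0).
#' @param missing_rate probability an entry outside the fully-quantified
#'   core is missing (missing completely at random).
#' @param core_size number of proteins (module proteins first) always
#'   fully quantified; `NULL` = all module proteins.
#' @param n_peptides number of peptide records to draw.
#' @param p_semi per-peptide probability of a semi-tryptic terminus.
#' @param p_misclv per-peptide probability of a retained missed cleavage.
#' @param mod_catalog_probs named list of modification entries, each
#'   `list(shift =, prob =, residues = named weights)`; `prob` is the
#'   per-peptide probability of carrying the shift and `residues` the
#'   sampling weights over target residues.
#' @param p_methyl_K per-peptide probability of lysine methylation
#'   (+14.0157 Da on K).
#' @param methyl_misclv_coupling probability that a methylated C-terminal
#'   lysine escapes cleavage, i.e. the peptide is extended through it and
#'   becomes miscleaved with an internal methyl-K.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_rows = 4L, n_cols = 5L,
                       excluded_voxels = c(2L, 5L, 8L),
                       n_modules = 2L, proteins_per_module = 10L,
                       n_background_proteins = 30L,
                       module_profiles = c("gradient", "hotspot"),
                       loading_mean = 4, anti_fraction = 0.2,
                       baseline_mean = 20, noise_sd = 0.1,
                       missing_rate = 0.1, core_size = NULL,
                       n_peptides = 5000L, p_semi = 0.02,
                       p_misclv = 0.11,
                       mod_catalog_probs = default_mod_probs(),
                       p_methyl_K = 0.03,
                       methyl_misclv_coupling = 0.9,
                       seed = 1L) {
  module_profiles <- rep_len(module_profiles, n_modules)
  stopifnot(all(module_profiles %in% c("gradient", "hotspot", "uniform")),
            noise_sd >= 0,
            all(c(anti_fraction, missing_rate, p_semi, p_misclv,
                  p_methyl_K, methyl_misclv_coupling) >= 0),
            all(c(anti_fraction, missing_rate, p_semi, p_misclv,
                  p_methyl_K, methyl_misclv_coupling) <= 1))
  cfg <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
              excluded_voxels = as.integer(excluded_voxels),
              n_modules = as.integer(n_modules),
              proteins_per_module = as.integer(proteins_per_module),
              n_background_proteins = as.integer(n_background_proteins),
              module_profiles = module_profiles,
              loading_mean = loading_mean, anti_fraction = anti_fraction,
              baseline_mean = baseline_mean, noise_sd = noise_sd,
              missing_rate = missing_rate, core_size = core_size,
              n_peptides = as.integer(n_peptides), p_semi = p_semi,
              p_misclv = p_misclv, mod_catalog_probs = mod_catalog_probs,
              p_methyl_K = p_methyl_K,
              methyl_misclv_coupling = methyl_misclv_coupling,
              seed = as.integer(seed))
  n <- cfg$n_rows * cfg$n_cols
  if (n < length(cfg$excluded_voxels) + 1L)
    stop("grid too small for the excluded set", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Default per-peptide modification probabilities
#'
#' Oxidation/hydroxylation mostly on proline, dihydroxy on proline,
#' formylation on lysine — the mass-shift landscape characteristic of
#' fixed-tissue digests. Lysine methylation is configured separately
#' (`p_methyl_K`) because of its coupling to miscleavage.
#' @return named list of modification entries.
#' @export
default_mod_probs <- function() {
  list(
    oxidation = list(shift = 15.9949, prob = 0.06,
                     residues = c(P = 0.6, M = 0.2, K = 0.1,
                                  W = 0.05, Y = 0.05)),
    dihydroxy = list(shift = 31.9898, prob = 0.03,
                     residues = c(P = 0.7, W = 0.15, M = 0.15)),
    formylation = list(shift = 27.9949, prob = 0.01, residues = c(K = 1))
  )
}

METHYL_SHIFT <- 14.0157

# residue composition used for synthetic proteins (human-proteome-like,
# with workable levels of K, R, P and M for digestion and modification)
AA_COMPOSITION <- c(A = .08, C = .02, D = .05, E = .06, F = .04, G = .07,
                    H = .02, I = .05, K = .06, L = .09, M = .03, N = .04,
                    P = .07, Q = .04, R = .06, S = .07, T = .05, V = .06,
                    W = .02, Y = .02)

#' Generate a synthetic protein FASTA
#'
#' Random sequences drawn residue-wise from a human-like composition; a
#' synthetic stand-in for a real proteome database. The default size
#' (200 proteins of 400 residues, a tryptic pool of roughly 6500
#' peptides) keeps repeated observations of the same peptide within one
#' voxel rare, so unique-peptide statistics track per-observation rates.
#'
#' @param n_proteins number of sequences.
#' @param length residues per sequence.
#' @param seed integer seed.
#' @param accessions optional accession names (default `SYN0001`...).
#' @return named character vector of sequences.
#' @export
random_fasta <- function(n_proteins = 200L, length = 400L, seed = 1L,
                         accessions = NULL) {
  set.seed(seed)
  if (is.null(accessions))
    accessions <- sprintf("SYN%04d", seq_len(n_proteins))
  seqs <- vapply(seq_len(n_proteins), function(i)
    paste(sample(names(AA_COMPOSITION), length, replace = TRUE,
                 prob = AA_COMPOSITION), collapse = ""),
    character(1))
  stats::setNames(seqs, accessions)
}

#' Read / write FASTA
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @return `read_fasta` returns a named character vector (accession =
#'   first whitespace-delimited header token).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

module_profile <- function(profile, module_index, n_modules, layout) {
  ret <- retained_voxels(layout)
  n <- length(ret)
  s <- switch(profile,
    gradient = if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1),
    uniform = rep(1, n),
    hotspot = {
      centre <- ret[max(1L, round((module_index - 0.5) / n_modules * n))]
      vx <- layout$voxels
      cc <- vx[vx$voxel_id == centre, ]
      idx <- match(ret, vx$voxel_id)
      d <- sqrt((vx$row[idx] - cc$row)^2 + (vx$col[idx] - cc$col)^2)
      exp(-d)
    },
    stop("unknown profile: ", profile, call. = FALSE))
  stats::setNames(s, ret)
}

#' Generate a synthetic intensity matrix with planted spatial modules
#'
#' The generative model is `x_pv = mu_p + lambda_p * s_m(p)(v) + eps_pv`
#' with iid Gaussian noise: every protein shares the baseline `mu`,
#' module members carry loading `+/- lambda` on their module's spatial
#' profile `s_m`, background proteins have `lambda = 0`. Entries outside
#' the fully-quantified core are set missing completely at random. The
#' random stream is consumed in a fixed order (noise matrix, then
#' missingness mask), so a config reproduces its matrix bit-identically.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (log2 intensities, `NA` = missing),
#'   `layout`, and `truth` (`module` per protein, `loading`, and the
#'   per-module `profiles` matrix over retained voxels).
#' @export
generate_intensity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- generate_layout(config$n_rows, config$n_cols,
                            config$excluded_voxels)
  ret <- retained_voxels(layout)
  if (length(ret) < 2L)
    stop("need >= 2 retained voxels", call. = FALSE)
  n_mod_prot <- config$n_modules * config$proteins_per_module
  proteins <- c(
    unlist(lapply(seq_len(config$n_modules), function(m)
      sprintf("M%d_P%02d", m, seq_len(config$proteins_per_module)))),
    if (config$n_background_proteins > 0L)
      sprintf("BG_P%03d", seq_len(config$n_background_proteins)))
  module <- c(rep(seq_len(config$n_modules),
                  each = config$proteins_per_module),
              rep(0L, config$n_background_proteins))
  n_anti <- floor(config$anti_fraction * config$proteins_per_module)
  within <- c(rep(seq_len(config$proteins_per_module),
                  times = config$n_modules),
              rep(0L, config$n_background_proteins))
  sign <- ifelse(module == 0L, 0,
                 ifelse(within > config$proteins_per_module - n_anti, -1, 1))
  loading <- sign * config$loading_mean
  profiles <- vapply(seq_len(config$n_modules), function(m)
    module_profile(config$module_profiles[m], m, config$n_modules, layout),
    numeric(length(ret)))
  profiles <- matrix(profiles, nrow = length(ret),
                     dimnames = list(ret, seq_len(config$n_modules)))
  set.seed(config$seed)
  signal <- t(vapply(seq_along(proteins), function(p) {
    s <- if (module[p] == 0L) rep(0, length(ret)) else profiles[, module[p]]
    config$baseline_mean + loading[p] * s
  }, numeric(length(ret))))
  noise <- matrix(stats::rnorm(length(proteins) * length(ret),
                               sd = config$noise_sd),
                  nrow = length(proteins))
  m <- signal + noise
  dimnames(m) <- list(proteins, ret)
  core_size <- if (is.null(config$core_size)) n_mod_prot
    else min(config$core_size, length(proteins))
  if (config$missing_rate > 0 && length(proteins) > core_size) {
    mask <- matrix(stats::runif(length(m)) < config$missing_rate,
                   nrow = nrow(m))
    mask[seq_len(core_size), ] <- FALSE
    m[mask] <- NA_real_
  }
  list(matrix = m, layout = layout,
       truth = list(module = stats::setNames(module, proteins),
                    loading = stats::setNames(loading, proteins),
                    core = proteins[seq_len(core_size)],
                    profiles = profiles))
}

# digest one protein into 0-missed fragments with flanks and, for each,
# the left/right extension used to plant miscleavages
digest_fragments <- function(accession, sequence, rule) {
  d <- in_silico_digest(sequence, rule_zero_missed(rule))
  d$protein <- accession
  d$frag <- seq_len(nrow(d))
  d
}

rule_zero_missed <- function(rule) {
  r <- rule; r$max_missed <- 0L; r
}

#' Generate a synthetic peptide identification table
#'
#' Draws peptides from the in-silico tryptic digest of the supplied
#' proteins and plants, in this order: missed cleavages (a drawn fragment
#' is merged with its neighbour with probability `p_misclv`),
#' modifications (per-peptide Bernoulli counts per catalog entry, target
#' residues sampled by the entry's weights, events placed on uniformly
#' chosen occurrences), lysine methylation with its miscleavage coupling
#' (a methylated C-terminal lysine escapes cleavage with probability
#' `methyl_misclv_coupling`, merging the peptide with the next fragment
#' so the methyl-K becomes internal), and semi-tryptic termini (1-3
#' residues trimmed from one terminus, validated to yield a semi-tryptic
#' classification without disturbing planted events or junctions).
#' Ground-truth flags are recorded by construction, so category counts
#' always equal re-classification of the emitted table.
#'
#' @param config a [sim_config()].
#' @param proteins named character vector of protein sequences (e.g.
#'   [random_fasta()] or [read_fasta()]).
#' @return list with `records` (a peptide table, see
#'   [validate_peptide_records()]) and `truth` (per-record flags
#'   `semi_tryptic`, `miscleaved`, `methylK`, `category`, plus per-shift
#'   planted peptide counts `shift_counts`).
#' @export
generate_peptide_table <- function(config, proteins) {
  stopifnot(inherits(config, "sim_config"), length(proteins) >= 1L)
  rule <- cleavage_rule()
  layout <- generate_layout(config$n_rows, config$n_cols,
                            config$excluded_voxels)
  ret <- retained_voxels(layout)
  frags <- do.call(rbind, lapply(names(proteins), function(acc)
    digest_fragments(acc, proteins[[acc]], rule)))
  n_by_prot <- table(frags$protein)
  pool <- frags[nchar(frags$peptide) >= 7L & nchar(frags$peptide) <= 35L, ]
  if (nrow(pool) == 0L)
    stop("digestion produced no pool peptides of length 7..35",
         call. = FALSE)
  set.seed(config$seed)
  n <- config$n_peptides
  draw <- pool[sample.int(nrow(pool), n, replace = TRUE), ]
  rownames(draw) <- NULL

  rec <- data.frame(peptide = draw$peptide, prev_aa = draw$prev_aa,
                    next_aa = draw$next_aa, protein = draw$protein,
                    stringsAsFactors = FALSE)
  # junction guards: distance of the merged cleavage site from each
  # terminus (0 = not merged)
  jn <- integer(n); jc <- integer(n)
  mods <- replicate(n, data.frame(pos = integer(), shift = numeric(),
                                  residue = character()), simplify = FALSE)

  extend <- function(i) {
    # merge the drawn fragment with its right neighbour (left if the
    # fragment is protein C-terminal); FALSE when the protein has a
    # single fragment
    f <- frags[frags$protein == rec$protein[i], ]
    k <- draw$frag[i]
    if (k < nrow(f)) {
      nxt <- f[f$frag == k + 1L, ]
      jc[i] <<- nchar(nxt$peptide)
      jn[i] <<- nchar(rec$peptide[i])
      rec$peptide[i] <<- paste0(rec$peptide[i], nxt$peptide)
      rec$next_aa[i] <<- nxt$next_aa
    } else if (k > 1L) {
      prv <- f[f$frag == k - 1L, ]
      jn[i] <<- nchar(prv$peptide)
      jc[i] <<- nchar(rec$peptide[i])
      if (nrow(mods[[i]]))
        mods[[i]]$pos <<- mods[[i]]$pos + nchar(prv$peptide)
      rec$peptide[i] <<- paste0(prv$peptide, rec$peptide[i])
      rec$prev_aa[i] <<- prv$prev_aa
    } else return(FALSE)
    TRUE
  }

  # 1. planted missed cleavages
  want_mis <- stats::runif(n) < config$p_misclv
  for (i in which(want_mis)) want_mis[i] <- extend(i)

  # 2. modifications (catalog entries, then lysine methylation)
  entries <- config$mod_catalog_probs
  entries$methylation <- list(shift = METHYL_SHIFT, prob = config$p_methyl_K,
                              residues = c(K = 1))
  shift_counts <- stats::setNames(integer(length(entries)), names(entries))
  methyl_events <- integer()
  contains <- list()  # residue-type presence cache (sequences static here)
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (e$prob <= 0) next
    k_ev <- stats::rbinom(1L, n, e$prob)
    if (k_ev == 0L) next
    types <- sample(names(e$residues), k_ev, replace = TRUE,
                    prob = e$residues)
    has_shift <- logical(n)
    for (tp in types) {
      if (is.null(contains[[tp]]))
        contains[[tp]] <- grepl(tp, rec$peptide, fixed = TRUE)
      elig <- which(!has_shift & contains[[tp]])
      if (length(elig) == 0L) next
      i <- elig[sample.int(length(elig), 1L)]
      occ <- gregexpr(tp, rec$peptide[i], fixed = TRUE)[[1]]
      pos <- occ[sample.int(length(occ), 1L)]
      mods[[i]] <- rbind(mods[[i]],
                         data.frame(pos = as.integer(pos), shift = e$shift,
                                    residue = tp))
      has_shift[i] <- TRUE
      shift_counts[nm] <- shift_counts[nm] + 1L
      if (nm == "methylation") methyl_events <- c(methyl_events, i)
    }
  }

  # 3. methylation-miscleavage coupling: a methylated C-terminal K
  #    escapes cleavage and the peptide is merged with the next fragment
  for (i in methyl_events) {
    if (want_mis[i]) next  # already miscleaved
    mK <- mods[[i]]$pos[abs(mods[[i]]$shift - METHYL_SHIFT) < 1e-9]
    at_cterm <- any(mK == nchar(rec$peptide[i]))
    if (at_cterm && stats::runif(1) < config$methyl_misclv_coupling)
      want_mis[i] <- extend(i)
  }

  # 4. semi-tryptic termini
  want_semi <- stats::runif(n) < config$p_semi
  is_semi <- logical(n)
  for (i in which(want_semi)) {
    term1 <- sample(c("N", "C"), 1L)
    len1 <- sample.int(3L, 1L)
    cands <- unique(rbind(data.frame(term = term1, len = len1),
                          expand.grid(term = c("N", "C"), len = 1:3,
                                      stringsAsFactors = FALSE)))
    for (ci in seq_len(nrow(cands))) {
      tm <- cands$term[ci]; tl <- cands$len[ci]
      p <- rec$peptide[i]; L <- nchar(p)
      if (L - tl < 5L) next
      if (tm == "N" && jn[i] > 0L && tl >= jn[i]) next
      if (tm == "C" && jc[i] > 0L && tl >= jc[i]) next
      if (nrow(mods[[i]])) {
        lo <- if (tm == "N") tl + 1L else 1L
        hi <- if (tm == "C") L - tl else L
        if (any(mods[[i]]$pos < lo | mods[[i]]$pos > hi)) next
      }
      if (tm == "N") {
        np <- substr(p, tl + 1L, L); npr <- substr(p, tl, tl)
        nnx <- rec$next_aa[i]
      } else {
        np <- substr(p, 1L, L - tl); npr <- rec$prev_aa[i]
        nnx <- substr(p, L - tl + 1L, L - tl + 1L)
      }
      if (classify_termini(np, npr, nnx, rule) != "semi_tryptic") next
      if (tm == "N") {
        if (nrow(mods[[i]])) mods[[i]]$pos <- mods[[i]]$pos - tl
        rec$peptide[i] <- np; rec$prev_aa[i] <- npr
        if (jn[i] > 0L) { jn[i] <- jn[i] - tl }
      } else {
        rec$peptide[i] <- np; rec$next_aa[i] <- nnx
        if (jc[i] > 0L) { jc[i] <- jc[i] - tl }
      }
      is_semi[i] <- TRUE
      break
    }
  }

  # 5. voxel assignment and spectral counts
  rec$voxel <- ret[sample.int(length(ret), n, replace = TRUE)]
  rec$spectral_count <- 1L + stats::rpois(n, 0.5)
  rec$assigned_modifications <- format_modifications(
    lapply(mods, function(m) m[order(m$pos), c("pos", "shift")]))

  modified <- vapply(mods, nrow, integer(1)) > 0L
  methylK <- vapply(mods, function(m)
    any(abs(m$shift - METHYL_SHIFT) < 1e-9 & m$residue == "K"), logical(1))
  category <- ifelse(!want_mis & !modified, "tryptic_unmodified",
              ifelse(!want_mis, "tryptic_modified",
              ifelse(!modified, "miscleaved_unmodified",
              ifelse(methylK, "miscleaved_methylK",
                     "miscleaved_other_modified"))))
  validate_peptide_records(rec)
  list(records = rec,
       truth = list(semi_tryptic = is_semi, miscleaved = want_mis,
                    methylK = methylK, category = category,
                    shift_counts = shift_counts,
                    events = mods))
}

#' Per-protein spectral-count table, optionally resampled
#'
#' Sums spectral counts per protein; with `resample = TRUE` the total
#' count mass is redrawn from a multinomial over the observed protein
#' proportions, mimicking a second dataset of the same depth.
#'
#' @param config a [sim_config()] (its seed drives the resampling).
#' @param records a peptide table.
#' @param resample draw a perturbed replicate instead of the plain sums.
#' @return data frame `protein`, `count`.
#' @export
generate_spectral_counts <- function(config, records, resample = FALSE) {
  tab <- sum_spectral_counts(records)
  if (!resample) return(tab)
  set.seed(config$seed)
  total <- sum(tab$count)
  tab$count <- as.integer(stats::rmultinom(1L, total,
                                           tab$count / total))
  tab
}
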