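RUN_CONFIG_DEFAULTS <- list(
  matrix = NULL, peptides = NULL, fasta = NULL, layout = NULL, terms = NULL,
  stages = c("qc", "rank", "spatial", "network", "termmap"),
  se_cutoff = 0.18, beta = 6, mode = "unsigned", top_k = 23L,
  edge_threshold = 0.1, inverse_threshold = 0.6, scale = "linear",
  seed_protein = NULL, term = NULL, top_n_shifts = 8L,
  proline_rule = TRUE, quantile_norm = TRUE,
  out_dir = "voxelprot_out", seed = 1L,
  log_level = "info", simulate = FALSE, sim = NULL)

#' Parse and validate a pipeline run configuration
#'
#' YAML file with a strict schema: unknown keys are rejected, defaults
#' are filled for absent keys (`se_cutoff` 0.18, `top_k` 23, unsigned
#' adjacency with beta 6). Referenced input paths must exist unless
#' `simulate: true`, in which case inputs are generated from the bundled
#' synthetic conditions.
#'
#' @param path YAML config file.
#' @return A validated `run_config` list.
#' @export
parse_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(RUN_CONFIG_DEFAULTS, user, keep.null = TRUE)
  if (!is.numeric(cfg$se_cutoff) || cfg$se_cutoff < 0)
    stop("config error: se_cutoff must be a non-negative number",
         call. = FALSE)
  if (!is.numeric(cfg$beta) || cfg$beta < 1)
    stop("config error: beta must be >= 1", call. = FALSE)
  if (!cfg$mode %in% c("unsigned", "signed"))
    stop("config error: mode must be unsigned or signed", call. = FALSE)
  if (!cfg$scale %in% c("linear", "log2"))
    stop("config error: scale must be linear or log2", call. = FALSE)
  if (!is.null(cfg$sim)) {
    badsim <- setdiff(names(cfg$sim),
                      setdiff(names(formals(sim_config)), "seed"))
    if (length(badsim))
      stop("config error: unknown sim key(s): ",
           paste(badsim, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(cfg$stages, RUN_CONFIG_DEFAULTS$stages)
  if (length(bad))
    stop("config error: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!isTRUE(cfg$simulate))
    for (key in c("matrix", "peptides", "fasta", "layout", "terms")) {
      p <- cfg[[key]]
      if (!is.null(p) && !file.exists(p))
        stop("config error: ", key, " path does not exist: ", p,
             call. = FALSE)
    }
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

#' Run the full downstream pipeline
#'
#' Executes the enabled stages in order (qc, rank, spatial, network,
#' termmap) over user inputs or, with `simulate: true`, over data from
#' the bundled synthetic conditions, writing per-stage outputs into
#' `out_dir` plus a JSON manifest with an MD5 hash per file. The same
#' config and seed reproduce identical hashes.
#'
#' @param config a `run_config` from [parse_run_config()], or a path to
#'   a YAML config.
#' @return the manifest (named list of output files and hashes),
#'   invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- parse_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name) files <<- c(files, file.path(config$out_dir, name))

  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    fasta <- random_fasta(seed = config$seed)
    sim <- generate_intensity(scfg)
    pep <- generate_peptide_table(scfg, fasta)
    m_raw <- sim$matrix; layout <- sim$layout; records <- pep$records
    terms <- list(module1 = names(sim$truth$module)[sim$truth$module == 1L])
    write_matrix_tsv(m_raw, file.path(config$out_dir, "matrix.tsv"))
    emit("matrix.tsv")
    write_peptide_tsv(records, file.path(config$out_dir, "peptides.tsv"))
    emit("peptides.tsv")
    write_layout_json(layout, file.path(config$out_dir, "layout.json"))
    emit("layout.json")
    if (is.null(config$seed_protein)) config$seed_protein <- "M1_P01"
    if (is.null(config$term)) config$term <- "module1"
  } else {
    m_raw <- if (!is.null(config$matrix)) read_matrix_tsv(config$matrix)
    layout <- if (!is.null(config$layout)) read_layout_json(config$layout)
    records <- if (!is.null(config$peptides))
      read_peptide_tsv(config$peptides)
    terms <- if (!is.null(config$terms)) read_terms(config$terms)
  }

  rule <- if (isTRUE(config$proline_rule)) cleavage_rule()
    else cleavage_rule(suppress_before = character())

  if ("qc" %in% config$stages && !is.null(records)) {
    log_msg(config, "qc stage")
    qc <- list(
      semi_tryptic = semi_tryptic_fraction(records, rule),
      miscleavage = miscleavage_fraction(records, rule),
      kr_ratio = kr_cleavage_ratio(records, rule),
      mass_shifts = mass_shift_table(records, top_n = config$top_n_shifts),
      stratification = miscleavage_modification_stratification(
        records, rule)[c("fractions", "conditional")])
    jsonlite::write_json(qc, file.path(config$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    emit("qc_report.json")
  }
  if ("rank" %in% config$stages && !is.null(records)) {
    log_msg(config, "rank stage")
    counts <- sum_spectral_counts(records)
    utils::write.table(rank_proteins(counts),
                       file.path(config$out_dir, "rank_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("rank_table.tsv")
  }

  m <- NULL; filt <- NULL
  if (!is.null(m_raw)) {
    m <- fully_quantified(m_raw)
    # quantile normalization assumes most proteins are spatially flat;
    # switch it off for small matrices dominated by changing proteins
    if (isTRUE(config$quantile_norm)) m <- quantile_normalize(m)
    filt <- se_filter(m, config$se_cutoff)
  }
  if ("spatial" %in% config$stages && !is.null(m)) {
    log_msg(config, "spatial stage: ", length(filt$retained),
            " proteins pass SE > ", config$se_cutoff)
    se_tab <- data.frame(protein = names(filt$se), se = filt$se,
                         retained = names(filt$se) %in% filt$retained)
    utils::write.table(se_tab, file.path(config$out_dir, "se_filter.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("se_filter.tsv")
  }
  if ("network" %in% config$stages && !is.null(m)) {
    log_msg(config, "network stage")
    r <- protein_correlation(m)
    adj <- soft_adjacency(r, beta = config$beta, mode = config$mode)
    seed_p <- config$seed_protein
    if (is.null(seed_p)) seed_p <- filt$retained[1]
    nb <- seed_neighborhood(adj, seed_p, k = config$top_k)
    utils::write.table(nb$neighbors,
                       file.path(config$out_dir, "seed_neighborhood.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("seed_neighborhood.tsv")
    inv <- inverse_partners(adj, seed_p, t = config$inverse_threshold)
    utils::write.table(inv,
                       file.path(config$out_dir, "inverse_partners.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("inverse_partners.tsv")
    ed <- edge_list(adj, c(seed_p, nb$neighbors$protein),
                    t = config$edge_threshold)
    utils::write.table(ed, file.path(config$out_dir, "seed_network.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("seed_network.tsv")
    write_graphml(ed, file.path(config$out_dir, "seed_network.graphml"))
    emit("seed_network.graphml")
  }
  if ("termmap" %in% config$stages && !is.null(m) && !is.null(layout) &&
      !is.null(terms) && !is.null(config$term)) {
    log_msg(config, "termmap stage")
    tm <- term_summed_intensity(m, terms[[config$term]], config$term,
                                scale = config$scale)
    render_svg(layout, heatmap_scale(tm),
               path = file.path(config$out_dir, "term_map.svg"))
    emit("term_map.svg")
    jsonlite::write_json(as.list(tm$values),
                         file.path(config$out_dir, "term_map.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("term_map.json")
  }

  manifest <- list(
    complete = TRUE,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = as.character(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
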