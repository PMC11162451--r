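test_that("identical configs give bit-identical outputs", {
  cfg <- sim_config(n_peptides = 300L, seed = 42L)
  fa <- random_fasta(n_proteins = 10, length = 300, seed = 42L)
  a <- generate_peptide_table(cfg, fa)
  b <- generate_peptide_table(cfg, fa)
  expect_identical(a, b)
  ia <- generate_intensity(cfg)
  ib <- generate_intensity(cfg)
  expect_identical(ia$matrix, ib$matrix)
})

test_that("noise-free intensities reproduce the closed-form matrix", {
  cfg <- sim_config(n_rows = 1L, n_cols = 3L, excluded_voxels = integer(),
                    n_modules = 1L, proteins_per_module = 2L,
                    n_background_proteins = 1L,
                    module_profiles = "gradient", loading_mean = 1,
                    anti_fraction = 0, baseline_mean = 10, noise_sd = 0,
                    missing_rate = 0, seed = 1L)
  sim <- generate_intensity(cfg)
  expect_equal(unname(sim$matrix["M1_P01", ]), c(10, 10.5, 11))
  expect_equal(unname(sim$matrix["BG_P001", ]), c(10, 10, 10))
})

test_that("degenerate digest parameters yield a purely tryptic table", {
  cfg <- sim_config(n_peptides = 200L, p_semi = 0, p_misclv = 0,
                    p_methyl_K = 0,
                    mod_catalog_probs = list(), seed = 2L)
  fa <- random_fasta(n_proteins = 10, length = 300, seed = 2L)
  out <- generate_peptide_table(cfg, fa)
  cls <- classify_termini(out$records$peptide, out$records$prev_aa,
                          out$records$next_aa)
  expect_true(all(cls == "fully_tryptic"))
  expect_true(all(internal_sites(out$records$peptide) == 0L))
  expect_true(all(out$records$assigned_modifications == ""))
})

test_that("full methylation-miscleavage coupling flags every internal methyl-K", {
  cfg <- sim_config(n_peptides = 500L, p_methyl_K = 0.2,
                    methyl_misclv_coupling = 1, p_misclv = 0,
                    mod_catalog_probs = list(), seed = 3L)
  fa <- random_fasta(n_proteins = 20, seed = 3L)
  out <- generate_peptide_table(cfg, fa)
  rec <- out$records
  mods <- parse_modifications(rec$assigned_modifications)
  # internal AND cleavable: a methyl-K in front of proline was never a
  # tryptic site, so it cannot witness a missed cleavage
  internal_methylK <- vapply(seq_len(nrow(rec)), function(i) {
    m <- mods[[i]]
    nrow(m) > 0L &&
      any(abs(m$shift - 14.0157) < 0.01 & m$pos < nchar(rec$peptide[i]) &
            substring(rec$peptide[i], m$pos, m$pos) == "K" &
            substring(rec$peptide[i], m$pos + 1L, m$pos + 1L) != "P")
  }, logical(1))
  expect_true(all(out$truth$miscleaved[internal_methylK]))
  expect_true(all(internal_sites(rec$peptide[internal_methylK]) > 0L))
})

test_that("ground-truth categories equal exhaustive re-classification", {
  out <- default_sim()$peptides
  rec <- out$records
  mods <- parse_modifications(rec$assigned_modifications)
  mis <- internal_sites(rec$peptide) > 0L
  modified <- vapply(mods, nrow, integer(1)) > 0L
  methylK <- vapply(seq_len(nrow(rec)), function(i) {
    m <- mods[[i]]
    nrow(m) > 0L &&
      any(abs(m$shift - 14.0157) < 0.01 &
            substring(rec$peptide[i], m$pos, m$pos) == "K")
  }, logical(1))
  recls <- ifelse(!mis & !modified, "tryptic_unmodified",
           ifelse(!mis, "tryptic_modified",
           ifelse(!modified, "miscleaved_unmodified",
           ifelse(methylK, "miscleaved_methylK",
                  "miscleaved_other_modified"))))
  expect_identical(recls, out$truth$category)
  expect_identical(mis, out$truth$miscleaved)
  cls <- classify_termini(rec$peptide, rec$prev_aa, rec$next_aa)
  expect_identical(cls == "semi_tryptic", out$truth$semi_tryptic)
})

test_that("miscleavage estimate recovers the generator rate within 3 sigma", {
  cfg <- sim_config(n_peptides = 5000L, p_misclv = 0.12, p_methyl_K = 0,
                    mod_catalog_probs = list(), p_semi = 0, seed = 3L)
  fa <- random_fasta(seed = 3L)
  out <- generate_peptide_table(cfg, fa)
  rec <- out$records
  u <- rec[!duplicated(paste(rec$voxel, rec$peptide,
                             rec$assigned_modifications)), ]
  est <- mean(internal_sites(u$peptide) > 0L)
  expect_lt(abs(est - 0.12), 3 * sqrt(0.12 * 0.88 / 5000))
})

test_that("spectral counts equal per-protein record counts", {
  rec <- make_records(c("AAAK", "AAAK", "AAAK", "CCCR"),
                      protein = c("P1", "P1", "P1", "P2"),
                      spectral_count = 1L)
  tab <- generate_spectral_counts(sim_config(), rec)
  expect_equal(tab$count[tab$protein == "P1"], 3L)
  expect_equal(tab$count[tab$protein == "P2"], 1L)
})

test_that("modification residue odds are recovered by the residue distribution", {
  # oxidation restricted to P and M at 3:1 odds -> P fraction near 75%
  cfg <- sim_config(n_peptides = 5000L, p_methyl_K = 0, p_misclv = 0,
                    p_semi = 0,
                    mod_catalog_probs = list(
                      oxidation = list(shift = 15.9949, prob = 0.06,
                                       residues = c(P = 3, M = 1))),
                    seed = 17L)
  out <- generate_peptide_table(cfg, random_fasta(seed = 17L))
  rd <- residue_distribution(out$records, 15.9949)
  n_ev <- sum(out$truth$shift_counts["oxidation"])
  expect_lt(abs(rd[["P"]] / 100 - 0.75), 3 * sqrt(0.75 * 0.25 / n_ev))
  # frequency also tracks the per-peptide probability
  tab <- mass_shift_table(out$records)
  expect_lt(abs(tab$frequency_pct[1] / 100 - 0.06),
            3 * sqrt(0.06 * 0.94 / 5000))
})
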