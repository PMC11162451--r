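test_that("semi-tryptic and miscleavage fractions count unique peptides per voxel", {
  # 80 unique peptides in one voxel, 2 semi-tryptic -> 0.025
  full <- make_records(sprintf("AAPTIDEK%02dR", 1:78))
  semi <- make_records(c("VTFISLLR", "AVAQYSDK"), prev_aa = "W")
  rec <- rbind(full, semi)
  expect_equal(unname(semi_tryptic_fraction(rec)), 2 / 80)
  expect_equal(unname(semi_tryptic_fraction(full)), 0)

  # duplicates of the same (sequence, modification) collapse
  dup <- rbind(full, full)
  expect_equal(unname(semi_tryptic_fraction(dup)), 0)

  rec2 <- make_records(c("AKAAAR", "CCCK", "DDDR", "EEEK"))
  expect_equal(unname(miscleavage_fraction(rec2)), 0.25)
})

test_that("K:R cleavage ratio is computed per context with exclusions", {
  # C-term residues K,K,R,R,R,R -> 0.5; protein C-terminal peptides excluded
  rec <- make_records(c("AAAK", "CCCK", "DDDR", "EEER", "FFFR", "GGGR"),
                      prev_aa = "R", next_aa = "A")
  r <- kr_cleavage_ratio(rec)
  expect_equal(r$c_term, 0.5)
  # symmetric input -> 1.0
  rec2 <- make_records(c("AAAK", "DDDR"), prev_aa = c("K", "R"))
  r2 <- kr_cleavage_ratio(rec2)
  expect_equal(r2$c_term, 1)
  expect_equal(r2$upstream, 1)
  # all prev_aa at protein N-terminus -> undefined upstream ratio
  rec3 <- make_records(c("AAAK", "DDDR"), prev_aa = "-")
  expect_error(kr_cleavage_ratio(rec3), "upstream")
  # peptides at the protein C-terminus carry no cleavage event
  rec4 <- make_records(c("AAAK", "DDDR"), next_aa = "-")
  expect_error(kr_cleavage_ratio(rec4), "C-terminal")
})

test_that("mass-shift table counts peptides once per shift and honors exclusions", {
  # 6 of 100 peptides carry +15.9949 -> 6%
  plain <- make_records(sprintf("AAA%02dPEPK", 1:94))
  ox <- make_records(sprintf("MMM%02dPEPK", 1:6),
                     assigned_modifications = "1:15.9949")
  tab <- mass_shift_table(rbind(plain, ox))
  expect_equal(tab$frequency_pct, 6)
  expect_equal(tab$name, "oxidation/hydroxylation")

  # a peptide with the same shift twice counts once; two shifts count twice
  rec <- make_records(c("MAMAPEPK", "MCCCPEPK"),
                      assigned_modifications = c("1:15.9949;3:15.9949",
                                                 "1:15.9949;2:57.0215"))
  tab2 <- mass_shift_table(rec)
  expect_equal(tab2$n_peptides[tab2$name == "oxidation/hydroxylation"], 2L)
  expect_equal(tab2$n_peptides[tab2$name == "carbamidomethyl"], 1L)

  # excluding every observed shift empties the table
  tab3 <- mass_shift_table(rec, exclusions = c(15.9949, 57.0215))
  expect_equal(nrow(tab3), 0L)
})

test_that("residue distribution weights multi-event peptides fractionally", {
  rec <- make_records(c("KAAAPEPR", "PAAAKEPR"),
                      assigned_modifications = c("1:14.0157", "1:14.0157"))
  d <- residue_distribution(rec, 14.0157)
  expect_equal(sort(names(d)), c("K", "P"))
  expect_equal(unname(d[c("K", "P")]), c(50, 50))
  expect_equal(sum(d), 100)

  # all events on K -> 100% K
  recK <- make_records("KAAAPEPR", assigned_modifications = "1:14.0157")
  expect_equal(residue_distribution(recK, 14.0157), c(K = 100))

  expect_warning(d0 <- residue_distribution(recK, 31.9898), "no peptide")
  expect_length(d0, 0)
})

test_that("miscleavage/methylation stratification is exhaustive and exclusive", {
  rec <- rbind(
    make_records(sprintf("AAA%dPEPK", 1:7)),                    # tryptic unmod
    make_records("MAAAPEPK", assigned_modifications = "1:15.9949"),
    make_records("AAAKAPEPR"),                                  # miscleaved unmod
    make_records("AAAKAPEPR", assigned_modifications = "4:14.0157"))
  s <- miscleavage_modification_stratification(rec)
  expect_equal(unname(s$fractions),
               c(0.7, 0.1, 0.1, 0.1, 0.0))
  expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(s$conditional["miscleaved_methylK"]), 1)

  # no miscleaved-modified peptides -> empty conditional, not an error
  s2 <- miscleavage_modification_stratification(rec[1:9, ])
  expect_length(s2$conditional, 0)
})

test_that("identification overlap equals brute-force membership enumeration", {
  out <- identification_overlap(list(s1 = c("a", "b", "c"),
                                     s2 = c("b", "c", "d")))
  expect_equal(out$count[out$pattern == "s1&s2"], 2L)
  expect_equal(out$count[out$pattern == "s1"], 1L)
  expect_equal(out$count[out$pattern == "s2"], 1L)

  same <- identification_overlap(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(same$pattern, "a&b")
  expect_equal(same$count, 5L)

  set.seed(42)
  sets <- lapply(1:3, function(i) sample(sprintf("P%03d", 1:200), 100))
  names(sets) <- c("A", "B", "C")
  out3 <- identification_overlap(sets)
  expect_equal(sum(out3$count), length(unique(unlist(sets))))
  # brute force: enumerate every element's membership pattern
  uni <- unique(unlist(sets))
  pat <- vapply(uni, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&"), character(1))
  expect_equal(out3$count[match(names(table(pat)), out3$pattern)],
               as.integer(table(pat)))
})

test_that("subcellular distribution is multi-label with a not-annotated bin", {
  ann <- data.frame(accession = c("P1", "P2", "P3"),
                    location = c("cytoplasm", "cytoplasm", "nucleus"))
  d <- subcellular_distribution(c("P1", "P2", "P3", "P4"), ann,
                                c("cytoplasm", "nucleus"))
  expect_equal(unname(d), c(50, 25, 25))

  ann2 <- data.frame(accession = c("P1", "P1"),
                     location = c("cytoplasm", "nucleus"))
  d2 <- subcellular_distribution(c("P1", "P2"), ann2,
                                 c("cytoplasm", "nucleus"))
  expect_equal(unname(d2), c(50, 50, 50))  # multi-label can exceed 100 summed

  d3 <- subcellular_distribution(c("P1", "P2"),
                                 ann2[0, ], c("cytoplasm"))
  expect_equal(unname(d3["not_annotated"]), 100)
})
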