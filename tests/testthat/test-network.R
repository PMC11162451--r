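test_that("protein correlation matches a brute-force Pearson oracle", {
  set.seed(4)
  m <- matrix(rnorm(50 * 17), 50, 17,
              dimnames = list(sprintf("P%02d", 1:50), 1:17))
  r <- protein_correlation(m)
  expect_equal(r, oracle_pearson(m), tolerance = 1e-10)

  m2 <- rbind(A = m[1, ], B = m[1, ], C = 2 * mean(m[1, ]) - m[1, ])
  r2 <- protein_correlation(m2)
  expect_equal(r2["A", "B"], 1)
  expect_equal(r2["A", "C"], -1)

  mz <- rbind(m[1:3, ], FLAT = rep(2, 17))
  expect_error(protein_correlation(mz), "FLAT")
})

test_that("soft adjacency applies the power transform by mode", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  a <- soft_adjacency(r, beta = 6, mode = "unsigned")
  expect_equal(a$adjacency["A", "B"], 0.5^6)
  expect_equal(unname(diag(a$adjacency)), c(1, 1))

  rn <- r; rn["A", "B"] <- rn["B", "A"] <- -1
  expect_equal(soft_adjacency(rn, mode = "signed")$adjacency["A", "B"], 0)
  rn["A", "B"] <- rn["B", "A"] <- -0.5
  expect_equal(soft_adjacency(rn, beta = 6,
                              mode = "unsigned")$adjacency["A", "B"], 0.5^6)

  # monotone in |r| for fixed beta, and rank-preserving across beta
  set.seed(1)
  v <- sort(runif(10))
  expect_true(all(diff(v^6) > 0))
  expect_error(soft_adjacency(r, beta = 0.5), "beta")
})

test_that("topological overlap equals the brute-force triple loop", {
  tri <- matrix(1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tomt <- topological_overlap(tri)
  expect_equal(unname(tomt), matrix(1, 3, 3))

  a <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  a["A", "B"] <- a["B", "A"] <- 1
  a["A", "C"] <- a["C", "A"] <- 1
  diag(a) <- 1
  expect_equal(topological_overlap(a)["B", "C"], 0.5)

  set.seed(8)
  n <- 20
  rnd <- matrix(runif(n * n), n, n)
  rnd <- (rnd + t(rnd)) / 2
  diag(rnd) <- 1
  dimnames(rnd) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
  tom <- topological_overlap(rnd)
  expect_equal(tom, oracle_tom(rnd), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, t(tom))
})

test_that("seed neighborhoods rank by adjacency with deterministic ties", {
  set.seed(10)
  m <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(c("S", "A", "B", "C"), 1:8))
  adj <- soft_adjacency(protein_correlation(m))
  nb <- seed_neighborhood(adj, "S", k = 2)
  v <- sort(adj$adjacency["S", c("A", "B", "C")], decreasing = TRUE)
  expect_equal(nb$neighbors$protein, names(v)[1:2])      # exhaustive sort
  expect_equal(nb$neighbors$adjacency, unname(v)[1:2])

  all_nb <- seed_neighborhood(adj, "S", k = 10)
  expect_setequal(all_nb$neighbors$protein, c("A", "B", "C"))
  expect_error(seed_neighborhood(adj, "GTR1"), "not found")
})

test_that("noise-free planted modules are recovered exactly", {
  sim <- noise_free_sim()
  m <- sim$intensity$matrix
  truth <- sim$intensity$truth
  r <- protein_correlation(m)
  # same module, same sign -> r = 1; opposite sign -> r = -1
  expect_equal(r["M1_P01", "M1_P02"], 1, tolerance = 1e-12)
  expect_equal(r["M1_P01", "M1_P09"], -1, tolerance = 1e-12)  # anti member
  adj <- soft_adjacency(r)
  nb <- seed_neighborhood(adj, "M1_P01",
                          k = sum(truth$module == 1L) - 1L)
  expect_setequal(nb$neighbors$protein,
                  setdiff(names(truth$module)[truth$module == 1L], "M1_P01"))
  # inverse partners at sigma = 0 are the negated-loading members, r = -1
  inv <- inverse_partners(adj, "M1_P01", t = 0.99)
  anti <- names(truth$loading)[truth$loading < 0 & truth$module == 1L]
  expect_setequal(inv$protein, anti)
  expect_equal(inv$correlation, rep(-1, length(anti)), tolerance = 1e-12)
  # modules match planted labels exactly
  lab <- detect_modules(adj, cut_height = 0.5)
  expect_equal(length(unique(lab)), 2L)
  split1 <- names(lab)[lab == lab[["M1_P01"]]]
  expect_setequal(split1, names(truth$module)[truth$module == 1L])
})

test_that("neighborhoods, inverse partners and modules are recovered under noise", {
  cfg <- sim_config(noise_sd = 0.1, missing_rate = 0, seed = 7L)
  sim <- generate_intensity(cfg)
  truth <- sim$truth
  adj <- soft_adjacency(protein_correlation(sim$matrix))
  for (seedp in c("M1_P01", "M2_P05")) {
    mod <- truth$module[[seedp]]
    partners <- setdiff(names(truth$module)[truth$module == mod], seedp)
    nb <- seed_neighborhood(adj, seedp, k = 10)
    recall <- mean(partners %in% nb$neighbors$protein)
    expect_gte(recall, 0.9)
  }
  # inverse partners at moderate noise
  cfg2 <- sim_config(noise_sd = 0.05, anti_fraction = 0.3,
                     missing_rate = 0, seed = 5L)
  sim2 <- generate_intensity(cfg2)
  adj2 <- soft_adjacency(protein_correlation(sim2$matrix))
  anti <- names(sim2$truth$loading)[sim2$truth$loading < 0 &
                                      sim2$truth$module == 1L]
  inv <- inverse_partners(adj2, "M1_P01", t = 0.6)
  expect_gte(mean(anti %in% inv$protein), 0.9)
  # module labels agree with ground truth (adjusted Rand)
  mod_prot <- names(sim2$truth$module)[sim2$truth$module > 0]
  lab <- detect_modules(adj2$adjacency[mod_prot, mod_prot], cut_height = 0.5)
  ari <- mclust::adjustedRandIndex(lab[mod_prot],
                                   sim2$truth$module[mod_prot])
  expect_gte(ari, 0.9)
})

test_that("edge lists respect the threshold", {
  a <- matrix(c(1, .9, .2, .9, 1, .5, .2, .5, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(nrow(edge_list(a, t = 0.4)), 2L)
  expect_equal(nrow(edge_list(a, t = 0)), 3L)      # complete graph
  expect_equal(nrow(edge_list(a, t = 0.95)), 0L)   # above max off-diagonal
  ed <- edge_list(a, t = 0.4)
  expect_true(all(ed$weight >= 0.4))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(ed, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("block adjacency yields one module per block", {
  blk <- matrix(0, 6, 6, dimnames = list(LETTERS[1:6], LETTERS[1:6]))
  blk[1:3, 1:3] <- 1; blk[4:6, 4:6] <- 1
  lab <- detect_modules(blk, cut_height = 0.5)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:3])), 1L)
  expect_equal(length(unique(lab[4:6])), 1L)
  all1 <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  expect_equal(length(unique(detect_modules(all1, 0.5))), 1L)
})
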