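# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities from first principles (triple loops, enumeration)
# rather than calling the package's own implementations.

oracle_pearson <- function(m) {
  # textbook covariance-based Pearson between the rows of m
  n <- nrow(m)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- m[i, ]; y <- m[j, ]
    out[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  out
}

oracle_tom <- function(a) {
  # direct triple-loop evaluation of the topological-overlap formula
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(1, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (s + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

oracle_hyper_tail <- function(overlap, term_size, universe_size, query_size) {
  # exhaustive sum of the hypergeometric upper tail
  ks <- overlap:min(term_size, query_size)
  sum(vapply(ks, function(k)
    choose(term_size, k) * choose(universe_size - term_size, query_size - k),
    numeric(1))) / choose(universe_size, query_size)
}

oracle_spearman <- function(r1, r2) {
  # closed form for distinct ranks: 1 - 6 sum d^2 / (n (n^2 - 1))
  n <- length(r1)
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

# small hand-built peptide table
make_records <- function(peptide, prev_aa = "K", next_aa = "A",
                         protein = "P1", voxel = 1L, spectral_count = 1L,
                         assigned_modifications = "") {
  if (length(peptide) == 0L)
    return(data.frame(peptide = character(), prev_aa = character(),
                      next_aa = character(), protein = character(),
                      voxel = integer(), spectral_count = integer(),
                      assigned_modifications = character()))
  data.frame(peptide = peptide, prev_aa = prev_aa, next_aa = next_aa,
             protein = protein, voxel = voxel,
             spectral_count = spectral_count,
             assigned_modifications = assigned_modifications,
             stringsAsFactors = FALSE)
}
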