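# Shared synthetic fixtures, generated once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_sim <- function() fixture("default_sim", function() {
  cfg <- sim_config(seed = 7L)
  fa <- random_fasta(seed = 7L)
  list(config = cfg, fasta = fa,
       peptides = generate_peptide_table(cfg, fa),
       intensity = generate_intensity(cfg))
})

noise_free_sim <- function() fixture("noise_free_sim", function() {
  cfg <- sim_config(noise_sd = 0, missing_rate = 0,
                    n_background_proteins = 0L, anti_fraction = 0.2,
                    seed = 11L)
  list(config = cfg, intensity = generate_intensity(cfg))
})
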