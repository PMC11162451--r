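# End-to-end demo on bundled synthetic conditions.
simulate: true
seed: 1
out_dir: voxelprot_out
log_level: info
# Noise-free planted modules so the seed network recovers them exactly;
# quantile normalization is off because the demo matrix is dominated by
# module proteins (see the methods vignette).
quantile_norm: false
top_k: 9
sim:
  noise_sd: 0
  missing_rate: 0
  n_background_proteins: 0
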