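# Minimal end-to-end pipeline configuration (simulate -> extract -> stats
# -> classify). Unknown keys are rejected; omitted keys take defaults.
seed: 7
out_dir: oculokit_out
simulate:
  n_per_group: 10
classifier:
  n_subsamples: 500
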