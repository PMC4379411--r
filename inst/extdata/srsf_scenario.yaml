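# Example pipeline configuration: the bundled SRSF-like replacement scenario.
# Run with:
#   Rscript inst/cli/splicevo.R run --config inst/extdata/srsf_scenario.yaml --out srsf_run/
simulation:
  scenario: srsf
  seed: 3
pipeline:
  outgroup: fungus_A
  nmd_threshold_nt: 50
  min_overhang: 10
  min_fold: 2.0
  min_len: 200
  bootstrap_reps: 0
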