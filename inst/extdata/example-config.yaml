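# Example pipeline configuration: a small synthetic study that runs in
# a few minutes (the all-pairs relatedness scan dominates).  Omitted
# keys take the documented defaults (the QC thresholds default to the
# published values).
simulation:
  n_target: 2000
  m_variants: 800
  seed: 42
qc:
  pihat_max: 0.1875
analysis:
  alpha_overall: 0.05
  n_models: 4
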