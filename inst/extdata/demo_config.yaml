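# Demonstration pipeline configuration: a small simulated two-stage cohort
# with opposite dominant coupling direction between stages.
paths:
  out_dir: gpdcpipe_demo
simulate:
  n_sessions_per_stage: 5
  base_diag: 0.3
  order: 1
  prep_edges:
    source: [AF07]
    target: [TP10]
    strength: [0.4]
  gen_edges:
    source: [TP10]
    target: [AF07]
    strength: [0.4]
seed: 20
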