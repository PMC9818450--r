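# Demonstration run: three synthetic cohorts sized like a typical
# multi-cohort post-transplant AML study (69 / 77 / 134 samples), 30 genes,
# one planted prognostic gene (G0001, hazard ratio 2.5 per SD), 35%
# censoring. The screen should recover G0001 as the sole intersection hit.
seed: 1
endpoint: OS
horizon: 36
gates:
  auc: 0.5
  sens: 0.5
  spec: 0.5
  alpha: 0.05
confounders: [age, sex, wbc, transplant, eln]
gate_mode: strict
simulate:
  n_genes: 30
  planted_beta: 0.9162907318741551  # log(2.5)
  censoring_fraction: 0.35
  n_samples: [69, 77, 134]
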