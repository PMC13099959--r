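# Default end-to-end configuration: pooled M-factor competition screen on
# SSA at three pH levels, quantified at cycles 0 and 5.
seed: 1
outdir: matefit-out
library:
  wt_peptide: YTPKVPYMC
  variable_positions: [1, 2, 3, 4, 5, 6, 7, 8]
simulate:
  profiles: default          # "default" or "recapitulation"
  cycles: 5
  replicates: 3
  reads_per_sample: 400000
  error_rate: 0.001
  drift_cells: 15300000      # ~1e5 cells per genotype at assembly
  read_length: 75
  generations: 8
  conditions:
    - {medium: SSA, pH: 4.0, temperature_C: 30, mating_permissive: true}
    - {medium: SSA, pH: 5.5, temperature_C: 30, mating_permissive: true}
    - {medium: SSA, pH: 7.0, temperature_C: 30, mating_permissive: true}
fitness:
  reference_pH: 5.5
  pseudocount: 0.5
  fc_threshold: 2
  alpha: 0.05
  adjust_method: BH
quantify:
  min_reads: 400000
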