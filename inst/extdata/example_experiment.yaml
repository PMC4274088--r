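# Desk-scale experiment configuration for run_experiment.R.
# Field names mirror experimentConfig() / cohortConfig().
cohort:
  nPerGroup: {NC: 10, TPD: 8, NTPD: 6}
  nRois: 64
  nModules: 4
  nVolumes: 180
  tr: 2.0
  rWithin: 0.4
  rBetween: 0.1
  affectedNodes: [1, 2, 3, 4, 5, 6]
  effectDelta: 0.25
  cerebellumNodes: [57, 58, 59, 60, 61, 62, 63, 64]
  nuisanceLoading: 0.3
  seed: 7
prep: {drop: 5, lowHz: 0.01, highHz: 0.1}
net: {alpha: 0.05, positiveOnly: true}
metrics: {nNulls: 50, smallworldSubjectsPerGroup: 3}
selection:
  nPermutations: 500
  alpha: 0.05
  metrics: [eLocal, eNodal]
classify:
  contrasts: [mixed_vs_nc, tpd_vs_nc]
  mode: nested
  nPermutations: 500
templates: [with_cerebellum, without_cerebellum]
seed: 7
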