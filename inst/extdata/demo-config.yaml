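# Demo configuration for runPipeline(): a small synthetic two-cohort study
# with one delta band-power effect and one directed delta coupling.
seed: 42
cohort:
  nPerGroup: 12
  durationS: 60
  sampleRate: 250
  noiseSd: 0.5
  mocaLink: -2.0
  bandEffects:
    - {group: MCI, band: delta, electrode: Fz, multiplier: 1.5}
    - {group: MCI, band: delta, electrode: CP1, multiplier: 1.5}
  couplings:
    - {group: MCI, source: PO3, target: CP5, band: delta, strength: 0.4, lag: 2}
preprocess:
  lo: 1
  hi: 30
  epochLengthS: 5
welch:
  segmentS: 2
  overlapFrac: 0.5
connectivity:
  order: 2
  nSurrogates: 100
  alpha: 0.05
  gridStep: 0.5
stats:
  alpha: 0.05
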