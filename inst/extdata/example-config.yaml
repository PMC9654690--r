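# Example run configuration: any omitted parameter keeps its package default.
seg:
  cellRadiusRange: [7, 12]
  minObjectAreaPx: 40
  adaptiveBlockFrac: 0.125
foci:
  focusMinAreaPx: 4
  focusMaxAreaPx: 150
  thresholdMethod: per-nucleus-otsu
micronuclei:
  mnMinAreaPx: 4
  mnMaxAreaFrac: 0.5
  maxDistancePx: 30
fucci:
  seed: 11
imputation:
  width: 1.3
  downshift: 1.8
  seed: 11
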