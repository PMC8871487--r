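# Example pipeline configuration (overrides merge onto defaultConfig()).
nPatients: 50
modality: CT-like
perturbation:
  nVariants: 100
  amplitude: 2
  noiseCorrelation: 2
features:
  bins: 32
  wavelet: true
signatures:
  high: 0.99
  low: 0.75
cv:
  nFolds: 5
  maxK: 5
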