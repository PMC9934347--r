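{
  "nSubjects": 2,
  "nSlices": 3,
  "gridRows": 48,
  "gridCols": 48,
  "noiseSigma": 2,
  "seed": 7
}
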