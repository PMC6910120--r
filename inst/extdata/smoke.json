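{
  "mode": "with-signal",
  "J": [8],
  "fwhm": [15],
  "sigma": [5],
  "amp": [2],
  "Q": 51,
  "center": 25,
  "iterations": 1,
  "seed": 7,
  "design": "one-sample",
  "alpha": 0.05
}
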