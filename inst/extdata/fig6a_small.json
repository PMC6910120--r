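{
  "mode": "with-signal",
  "J": [10],
  "fwhm": [20],
  "sigma": [0.5, 1, 2, 3, 5, 10, 20],
  "amp": [2],
  "Q": 101,
  "center": 50,
  "iterations": 1000,
  "seed": 2026,
  "design": "one-sample",
  "alpha": 0.05
}
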