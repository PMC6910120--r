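{
  "mode": "no-signal",
  "J": [5, 10, 25],
  "fwhm": [10, 20, 30],
  "Q": 101,
  "iterations": 1000,
  "seed": 2026,
  "design": "one-sample",
  "alpha": 0.05
}
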