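# Shared test utilities.

# Wrap a crafted t continuum as a tfield without going through data
# (for interval / threshold logic tests).
fake_tfield <- function(t, df = 9L, fwhm = 20) {
  structure(list(t = as.numeric(t), df = as.integer(df), fwhm = fwhm,
                 Q = length(t), residuals = NULL, design = "one-sample"),
            class = "tfield")
}

# Brute-force Benjamini-Hochberg oracle: checks all Q inequalities
# explicitly, independently of fdr_critical_p()'s vectorized path.
bh_brute_force <- function(p, alpha) {
  Q <- length(p)
  ps <- sort(p)
  pstar <- NA_real_
  for (i in Q:1) {
    if (ps[i] <= i * alpha / Q) { pstar <- ps[i]; break }
  }
  pstar
}

# Mean-model residuals of a sample matrix.
centered <- function(x) sweep(unclass(x), 2, colMeans(x))
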