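# Smooth 1-D Gaussian field generation and synthetic dataset assembly.
#
# A "continuum sample" is a J x Q matrix: J registered observations of a
# dependent variable sampled at Q nodes spanning 0-100% of a movement cycle.
# Noise smoothness is parameterized by the FWHM (in node units) of the
# Gaussian kernel that, convolved with white Gaussian noise, reproduces the
# temporal autocorrelation of the data's residuals.

# Smallest meaningful smoothness: below ~half a node the generator and the
# FWHM estimator both degenerate to white noise.
FWHM_MIN <- 0.5

# per-session cache of convolution operators, keyed by (Q, fwhm)
.kernel_cache <- new.env(parent = emptyenv())

# Gaussian convolution operator mapping white noise on a padded domain of
# length Q + 2h to a smooth unit-variance field on Q nodes. The padding
# (h = half-width of the kernel support, 3 SDs) avoids wrap-around
# correlation so boundary nodes have the same covariance as interior ones.
smoothing_operator <- function(Q, fwhm) {
  key <- paste(Q, format(fwhm, digits = 12), sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  sdk <- fwhm / sqrt(8 * log(2))
  h <- max(1L, as.integer(ceiling(3 * sdk)))
  k <- exp(-(seq(-h, h))^2 / (2 * sdk^2))
  k <- k / sqrt(sum(k^2))  # exact unit population variance at every node
  K <- matrix(0, Q + 2L * h, Q)
  for (x in seq_len(Q)) K[x:(x + 2L * h), x] <- k
  op <- list(K = K, h = h, kernel = k)
  .kernel_cache[[key]] <- op
  op
}

#' Construct a continuum sample
#'
#' Wraps a numeric J x Q matrix (rows = observations, columns = nodes) as a
#' `continuum_sample`, validating that all entries are finite and that at
#' least two observations are present. Node x (0-based, `0 .. Q-1`) maps to
#' `100 * x / (Q - 1)` percent of the registered cycle.
#'
#' @param values numeric matrix, J rows (observations) by Q columns (nodes).
#' @return a `continuum_sample` (numeric matrix subclass).
#' @export
#' @examples
#' y <- continuum_sample(matrix(rnorm(40), 4, 10))
#' dim(y)
continuum_sample <- function(values) {
  values <- assert_matrix(values, "values")
  if (nrow(values) < 2L) stopf("a continuum sample needs J >= 2 observations, got %d", nrow(values))
  if (ncol(values) < 2L) stopf("a continuum sample needs Q >= 2 nodes, got %d", ncol(values))
  class(values) <- c("continuum_sample", class(matrix()))
  values
}

#' @export
print.continuum_sample <- function(x, ...) {
  cat(sprintf("continuum_sample: J = %d observations x Q = %d nodes\n",
              nrow(x), ncol(x)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Generate smooth 1-D Gaussian noise
#'
#' Draws J independent smooth Gaussian fields on Q nodes. Each field is white
#' Gaussian noise convolved with a Gaussian kernel of the given full-width-at-
#' half-maximum (FWHM, node units); the kernel is scaled so every node has
#' exactly unit population variance, and white noise is generated on a padded
#' domain (3 kernel SDs each side) so boundary nodes are not wrap-correlated.
#' The lag-`d` autocorrelation is `exp(-2 * log(2) * d^2 / fwhm^2)`.
#'
#' @param J number of observations (>= 2).
#' @param Q number of nodes (>= 2).
#' @param fwhm smoothness in node units (> 0); values below 0.5 are clamped
#'   to 0.5 with a warning, where the field is indistinguishable from white
#'   noise.
#' @param seed optional integer seed; identical seed and parameters give
#'   bit-identical output, and the caller's RNG state is left untouched.
#' @return a [continuum_sample()], J x Q.
#' @seealso [estimate_fwhm()] for recovering `fwhm` from residuals.
#' @export
#' @examples
#' y <- generate_noise(8, 101, fwhm = 20, seed = 1)
#' round(apply(y, 2, var)[1:5], 2)
generate_noise <- function(J, Q, fwhm, seed = NULL) {
  J <- assert_count(J, "J", lower = 2L)
  Q <- assert_count(Q, "Q", lower = 2L)
  fwhm <- assert_number(fwhm, "fwhm")
  if (fwhm <= 0) stopf("`fwhm` must be > 0, got %s", fwhm)
  if (fwhm < FWHM_MIN) {
    warning(sprintf("fwhm = %g clamped to %g (white-noise floor)", fwhm, FWHM_MIN),
            call. = FALSE)
    fwhm <- FWHM_MIN
  }
  op <- smoothing_operator(Q, fwhm)
  white <- with_seed(seed, matrix(stats::rnorm(J * (Q + 2L * op$h)), J))
  continuum_sample(white %*% op$K)
}

#' Gaussian pulse signal
#'
#' The true-signal model: `g[x] = amp * exp(-(x - center)^2 / (2 * sigma^2))`
#' on nodes `x = 0 .. Q-1`. Because generated noise has unit variance, `amp`
#' is the signal-to-noise ratio at the pulse peak. `sigma = 0` or `amp = 0`
#' denotes the no-signal case (all-zero continuum). The center may lie
#' outside `[0, Q-1]`, in which case only the pulse tail enters the domain.
#'
#' @param Q number of nodes (>= 2).
#' @param center pulse center in node units (fractional and out-of-domain
#'   values allowed).
#' @param sigma pulse breadth, standard-deviation node units (>= 0).
#' @param amp pulse amplitude in noise-SD units (= SNR).
#' @return numeric vector of length Q.
#' @export
#' @examples
#' g <- gaussian_pulse(101, center = 50, sigma = 3, amp = 2.3)
#' g[51]                    # = amp at the center node
#' g[48] / g[51]            # = exp(-1/2) one sigma away
gaussian_pulse <- function(Q, center, sigma, amp) {
  Q <- assert_count(Q, "Q", lower = 2L)
  center <- assert_number(center, "center")
  sigma <- assert_number(sigma, "sigma", lower = 0)
  amp <- assert_number(amp, "amp")
  x <- seq_len(Q) - 1
  if (sigma == 0 || amp == 0) return(numeric(Q))
  amp * exp(-(x - center)^2 / (2 * sigma^2))
}

#' Synthesize a complete dataset (signal + smooth noise)
#'
#' Builds the synthetic datasets used throughout the simulation experiments:
#' smooth unit-variance Gaussian noise plus a Gaussian pulse, arranged for a
#' one-sample, paired, or regression design. In every design `amp` is the
#' peak systematic effect of the *analyzed* continuum in units of its noise
#' SD:
#'
#' * `one-sample`: one sample, every observation offset by the pulse.
#' * `paired`: two samples whose difference carries the pulse; each sample
#'   receives noise scaled by `1/sqrt(2)` so the paired difference has unit
#'   noise variance (keeping `amp` = SNR of the tested effect).
#' * `regression`: one sample in which observation j receives the pulse
#'   scaled by its centered covariate value, so `amp` is the regression
#'   slope at the pulse peak per covariate unit. The default covariate is
#'   the observation index `1:J`.
#'
#' @param J observations per sample (>= 2; >= 3 for regression).
#' @param Q number of nodes.
#' @param fwhm noise smoothness (node units).
#' @param center,sigma,amp Gaussian pulse parameters, see [gaussian_pulse()].
#' @param design `"one-sample"`, `"paired"`, or `"regression"`.
#' @param covariate numeric length-J vector for the regression design
#'   (default `1:J`); must be non-constant.
#' @param seed optional integer seed (reproducible output).
#' @return a list of class `synth_dataset` with elements `design`, `signal`
#'   (the length-Q true pulse), and either `sample` (one-sample/regression,
#'   plus `covariate`) or `sampleA`/`sampleB` (paired; the pulse is added to
#'   `sampleB`).
#' @export
#' @examples
#' d <- synthesize_dataset(10, 101, fwhm = 20, center = 50, sigma = 5,
#'                         amp = 1, design = "one-sample", seed = 1)
#' dim(d$sample)
synthesize_dataset <- function(J, Q, fwhm, center, sigma, amp,
                               design = c("one-sample", "paired", "regression"),
                               covariate = NULL, seed = NULL) {
  design <- match.arg(design)
  J <- assert_count(J, "J", lower = 2L)
  g <- gaussian_pulse(Q, center, sigma, amp)
  out <- switch(design,
    "one-sample" = {
      noise <- generate_noise(J, Q, fwhm, seed = seed)
      list(sample = continuum_sample(unclass(noise) +
                                       matrix(g, J, Q, byrow = TRUE)))
    },
    "paired" = {
      both <- generate_noise(2L * J, Q, fwhm, seed = seed)
      a <- unclass(both)[seq_len(J), , drop = FALSE] / sqrt(2)
      b <- unclass(both)[J + seq_len(J), , drop = FALSE] / sqrt(2)
      list(sampleA = continuum_sample(a),
           sampleB = continuum_sample(b + matrix(g, J, Q, byrow = TRUE)))
    },
    "regression" = {
      if (J < 3L) stopf("regression design needs J >= 3, got %d", J)
      if (is.null(covariate)) covariate <- seq_len(J)
      if (!is.numeric(covariate) || length(covariate) != J)
        stopf("covariate must be numeric of length J = %d, got length %d",
              J, length(covariate))
      if (any(!is.finite(covariate)) || stats::sd(covariate) == 0)
        stopf("covariate must be finite and non-constant")
      noise <- generate_noise(J, Q, fwhm, seed = seed)
      xc <- covariate - mean(covariate)
      list(sample = continuum_sample(unclass(noise) + outer(xc, g)),
           covariate = covariate)
    })
  structure(c(out, list(design = design, signal = g)),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("synth_dataset (%s design), Q = %d nodes, peak |signal| = %.3g\n",
              x$design, length(x$signal), max(abs(x$signal))))
  invisible(x)
}
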