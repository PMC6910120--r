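# Node-wise t-statistic continua (SPM{t}).
#
# Each test statistic is computed independently at every node; the resulting
# length-Q t continuum, its degrees of freedom, and the smoothness (FWHM)
# estimated from the model residuals together parameterize domain-wide
# inference (see threshold_rft, threshold_fdr).

new_tfield <- function(t, df, residuals, design) {
  fwhm <- estimate_fwhm(residuals)
  structure(list(t = as.numeric(t), df = as.integer(df), fwhm = fwhm,
                 Q = length(t), residuals = residuals, design = design),
            class = "tfield")
}

#' @export
print.tfield <- function(x, ...) {
  cat(sprintf("SPM{t} continuum (%s): Q = %d nodes, df = %d, FWHM = %.2f\n",
              x$design, x$Q, x$df, x$fwhm))
  cat(sprintf("  max |t| = %.3f at node %d\n",
              max(abs(x$t)), which.max(abs(x$t)) - 1L))
  invisible(x)
}

check_finite_sd <- function(s, what) {
  bad <- which(s == 0)
  if (length(bad))
    stopf("zero variance at node(s) %s: t is infinite (%s)",
          paste(bad - 1L, collapse = ", "), what)
}

#' One-sample t continuum
#'
#' Node-wise one-sample t statistic `t[x] = mean[x] / (sd[x] / sqrt(J))`
#' with `df = J - 1`. Residuals are the mean-centered observations; the
#' residual FWHM is estimated and stored on the result.
#'
#' @param sample J x Q matrix or [continuum_sample()], J >= 2.
#' @return a `tfield`: list with `t` (length Q), `df`, `fwhm`, `Q`,
#'   `residuals`.
#' @export
#' @examples
#' y <- generate_noise(10, 101, 20, seed = 1)
#' one_sample_t(y)
one_sample_t <- function(sample) {
  y <- assert_matrix(sample, "sample")
  J <- nrow(y)
  if (J < 2L) stopf("one-sample t needs J >= 2, got %d", J)
  m <- colMeans(y)
  res <- sweep(y, 2, m)
  s <- sqrt(colSums(res^2) / (J - 1))
  check_finite_sd(s, "one-sample t")
  new_tfield(m / (s / sqrt(J)), J - 1L, res, "one-sample")
}

#' Paired t continuum
#'
#' Node-wise paired t test of `sampleA - sampleB`: identical to the
#' one-sample t of the paired differences, with `df = J - 1`.
#'
#' @param sampleA,sampleB J x Q matrices of identical shape, J >= 2.
#' @return a `tfield`; see [one_sample_t()].
#' @export
paired_t <- function(sampleA, sampleB) {
  a <- assert_matrix(sampleA, "sampleA")
  b <- assert_matrix(sampleB, "sampleB")
  if (!identical(dim(a), dim(b)))
    stopf("paired samples must have identical shape: %dx%d vs %dx%d",
          nrow(a), ncol(a), nrow(b), ncol(b))
  tf <- one_sample_t(a - b)
  tf$design <- "paired"
  tf
}

#' Linear-regression t continuum
#'
#' Node-wise t statistic of the slope in a simple linear regression of node
#' values on a covariate, with `df = J - 2`. Residuals are the regression
#' fit residuals. A node where the fit is exact (zero residual variance)
#' raises a perfect-fit error rather than reporting an infinite t.
#'
#' @param sample J x Q matrix, J >= 3.
#' @param covariate numeric length-J vector, non-constant.
#' @return a `tfield`; see [one_sample_t()].
#' @export
#' @examples
#' d <- synthesize_dataset(8, 101, 15, 50, 10, 0.8, "regression", seed = 2)
#' regression_t(d$sample, d$covariate)
regression_t <- function(sample, covariate) {
  y <- assert_matrix(sample, "sample")
  J <- nrow(y)
  if (J < 3L) stopf("regression t needs J >= 3, got %d", J)
  if (!is.numeric(covariate) || length(covariate) != J)
    stopf("covariate must be numeric of length J = %d", J)
  if (any(!is.finite(covariate))) stopf("covariate contains non-finite values")
  xc <- covariate - mean(covariate)
  sxx <- sum(xc^2)
  if (sxx == 0) stopf("constant covariate: regression design is degenerate")
  slope <- colSums(y * xc) / sxx
  fit <- matrix(colMeans(y), J, ncol(y), byrow = TRUE) + outer(xc, slope)
  res <- y - fit
  sse <- colSums(res^2)
  perfect <- which(sse <= 0 | sse < .Machine$double.eps * colSums(y^2))
  if (length(perfect))
    stopf("perfect linear fit at node(s) %s: t is unbounded",
          paste(perfect - 1L, collapse = ", "))
  se <- sqrt(sse / (J - 2) / sxx)
  new_tfield(slope / se, J - 2L, res, "regression")
}
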