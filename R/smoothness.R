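# Residual smoothness (FWHM) estimation.

#' Estimate residual smoothness (FWHM)
#'
#' Estimates the full-width-at-half-maximum of the Gaussian kernel whose
#' convolution with white noise matches the temporal smoothness of a set of
#' residual continua. This is the 1-D reduction of the standard gradient
#' estimator: residuals are variance-normalized per node, forward differences
#' are taken over the Q-1 inter-node intervals, and the mean squared gradient
#' lambda-hat gives `FWHM = sqrt(4 * log(2) / lambda)`. A single dataset-wide
#' value is returned (pooled over observations and intervals); the estimate
#' is invariant to rescaling the residuals and is clamped to `[0.5, 2 * Q]`.
#'
#' @param residuals J x Q numeric matrix of model residuals (observations
#'   minus model fit), J >= 2, Q >= 3.
#' @return estimated FWHM in node units.
#' @seealso [generate_noise()], whose `fwhm` this estimator recovers on pure
#'   noise (within ~5% mean relative error at small J).
#' @export
#' @examples
#' y <- generate_noise(50, 101, fwhm = 20, seed = 1)
#' r <- sweep(y, 2, colMeans(y))       # mean-model residuals
#' estimate_fwhm(r)
estimate_fwhm <- function(residuals) {
  r <- assert_matrix(residuals, "residuals")
  J <- nrow(r); Q <- ncol(r)
  if (J < 2L) stopf("FWHM estimation needs J >= 2 residual curves, got %d", J)
  if (Q < 3L) stopf("FWHM estimation needs Q >= 3 nodes, got %d", Q)
  v <- colMeans(r^2)
  if (all(v == 0)) stopf("residuals are identically zero: smoothness undefined")
  if (any(v == 0)) stopf("zero residual variance at node(s) %s",
                         paste(which(v == 0) - 1L, collapse = ", "))
  rn <- sweep(r, 2, sqrt(v), "/")
  grad <- rn[, -1L, drop = FALSE] - rn[, -Q, drop = FALSE]
  lambda <- mean(grad^2)
  if (lambda == 0) stopf("residuals are constant along the domain: smoothness undefined")
  min(max(sqrt(4 * log(2) / lambda), FWHM_MIN), 2 * Q)
}
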