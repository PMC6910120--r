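# Domain-wide critical thresholds and suprathreshold intervals.
#
# All four thresholds follow the two-tailed convention: alpha/2 per tail,
# node-wise p-values two-tailed. The FDR threshold may be undefined (no node
# survives the Benjamini-Hochberg step-up rule); the undefined case is
# represented explicitly as NA.

#' Two-tailed node-wise p-values of a t continuum
#'
#' `p[x] = 2 * P(T_df > |t[x]|)`, each in (0, 1].
#'
#' @param tfield a `tfield` (see [one_sample_t()]), or a numeric vector of t
#'   values together with `df`.
#' @param df degrees of freedom; taken from `tfield` when it is a `tfield`.
#' @return numeric vector of p-values, length Q.
#' @export
p_from_t <- function(tfield, df = NULL) {
  if (inherits(tfield, "tfield")) {
    t <- tfield$t; df <- tfield$df
  } else {
    t <- tfield
    if (is.null(df)) stopf("`df` is required when `tfield` is a plain vector")
  }
  if (any(!is.finite(t))) stopf("t continuum contains non-finite values")
  df <- assert_number(df, "df", lower = 1)
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Uncorrected (0-D) critical threshold
#'
#' Two-tailed critical t value for a single node: `qt(1 - alpha/2, df)`.
#' This is the threshold a researcher would use after extracting a scalar
#' metric from the continuum; applied node-wise it ignores multiplicity.
#'
#' @param alpha Type I error rate, in (0, 1).
#' @param df degrees of freedom.
#' @return critical t threshold.
#' @export
threshold_uncorrected <- function(alpha, df) {
  alpha <- assert_alpha(alpha)
  df <- assert_number(df, "df", lower = 1)
  stats::qt(1 - alpha / 2, df)
}

#' Bonferroni critical threshold
#'
#' Two-tailed critical t value at per-node level `alpha / Q`. For smooth
#' (positively correlated) continua this bound is conservative.
#'
#' @inheritParams threshold_uncorrected
#' @param Q number of nodes (tests), >= 1.
#' @return critical t threshold; equals [threshold_uncorrected()] at `Q = 1`.
#' @export
threshold_bonferroni <- function(alpha, df, Q) {
  alpha <- assert_alpha(alpha)
  df <- assert_number(df, "df", lower = 1)
  Q <- assert_count(Q, "Q", lower = 1L)
  stats::qt(1 - alpha / (2 * Q), df)
}

# Expected Euler characteristic of the excursion set of a smooth 1-D t-field
# above u: EC(u) = P(T > u) + resels * sqrt(4 log 2) / (2 pi) *
# (1 + u^2/df)^(-(df-1)/2), with resels = (Q - 1) / fwhm.
expected_ec <- function(u, df, resels) {
  stats::pt(u, df, lower.tail = FALSE) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Random field theory critical threshold
#'
#' The critical height u at which the expected Euler characteristic of the
#' suprathreshold set of a smooth null t-field equals `alpha / 2` per tail,
#' i.e. the height whose domain-wide (family-wise) exceedance probability is
#' approximately `alpha` for two-tailed inference. The field's effective
#' number of independent smoothness units is the resel count
#' `(Q - 1) / fwhm`; the expected EC is used directly as the tail
#' probability (the standard high-threshold approximation). The root is
#' bracketed and solved to absolute tolerance 1e-6.
#'
#' @inheritParams threshold_bonferroni
#' @param fwhm field smoothness in node units (> 0), typically estimated
#'   from residuals with [estimate_fwhm()].
#' @return critical t threshold.
#' @export
#' @examples
#' threshold_rft(0.05, df = 9, Q = 101, fwhm = 20)
threshold_rft <- function(alpha, df, Q, fwhm) {
  alpha <- assert_alpha(alpha)
  df <- assert_number(df, "df", lower = 1)
  Q <- assert_count(Q, "Q", lower = 2L)
  fwhm <- assert_number(fwhm, "fwhm")
  if (fwhm <= 0) stopf("`fwhm` must be > 0, got %s", fwhm)
  resels <- (Q - 1) / fwhm
  f <- function(u) expected_ec(u, df, resels) - alpha / 2
  lower <- 0
  upper <- max(threshold_uncorrected(alpha, df), 1)
  it <- 0L
  while (f(upper) > 0 && it < 60L) {
    upper <- upper * 2
    it <- it + 1L
  }
  if (f(upper) > 0)
    stopf(paste0("RFT threshold: no root below u = %g ",
                 "(alpha = %g, df = %g, Q = %d, fwhm = %g, resels = %g)"),
          upper, alpha, df, Q, fwhm, resels)
  stats::uniroot(f, c(lower, upper), tol = 1e-6)$root
}

#' Benjamini-Hochberg critical p-value
#'
#' Sorts p-values ascending as `p(1) .. p(Q)` and returns the highest p-value
#' satisfying the step-up inequality `p(i) <= i * alpha / Q`, or `NA` when no
#' index satisfies it (no discovery). The largest-satisfying-index
#' formulation is tie-safe: equal p-values share the decision of their
#' highest rank.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level, in (0, 1).
#' @return the critical p-value `p*`, or `NA_real_`. Nodes with `p <= p*`
#'   are the BH discoveries.
#' @export
#' @examples
#' fdr_critical_p(c(0.010, 0.020, 0.040, 0.060), 0.05)  # 0.020
fdr_critical_p <- function(p, alpha) {
  alpha <- assert_alpha(alpha)
  if (!is.numeric(p) || !length(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("`p` must be p-values in [0, 1]")
  Q <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(Q) * alpha / Q)
  if (!length(ok)) return(NA_real_)
  ps[max(ok)]
}

#' False-discovery-rate critical threshold
#'
#' Converts the Benjamini-Hochberg critical p-value of a t continuum's
#' two-tailed node-wise p-values into a critical t value
#' `qt(1 - p*/2, df)`. Returns `NA` (the undefined sentinel) when no node
#' satisfies the step-up inequality, i.e. no node is significant; unlike the
#' other three thresholds, this one adapts to the observed signal.
#'
#' @param tfield a `tfield`.
#' @param alpha FDR level, in (0, 1).
#' @return critical t threshold with attribute `p_crit` (the BH critical
#'   p-value), or `NA_real_` when undefined.
#' @export
threshold_fdr <- function(tfield, alpha = 0.05) {
  if (!inherits(tfield, "tfield")) stopf("`tfield` must be a tfield object")
  p <- p_from_t(tfield)
  pstar <- fdr_critical_p(p, alpha)
  if (is.na(pstar)) return(NA_real_)
  structure(stats::qt(1 - pstar / 2, tfield$df), p_crit = pstar)
}

#' All four critical thresholds of a t continuum
#'
#' Computes the uncorrected, Bonferroni, RFT, and FDR thresholds of a
#' `tfield` at level `alpha` (two-tailed throughout). The RFT threshold uses
#' the field's estimated residual FWHM.
#'
#' @param tfield a `tfield`.
#' @param alpha significance / FDR level, default 0.05.
#' @return a `threshold_set`: list with `alpha`, `df`, `Q`, `fwhm`, and
#'   numeric `uncorrected`, `bonferroni`, `rft`, `fdr` (`fdr` is `NA` when
#'   undefined, flagged by `fdr_defined`).
#' @export
#' @examples
#' y <- generate_noise(10, 101, 20, seed = 3)
#' threshold_set(one_sample_t(y))
threshold_set <- function(tfield, alpha = 0.05) {
  if (!inherits(tfield, "tfield")) stopf("`tfield` must be a tfield object")
  alpha <- assert_alpha(alpha)
  fdr <- threshold_fdr(tfield, alpha)
  structure(list(
    alpha = alpha, df = tfield$df, Q = tfield$Q, fwhm = tfield$fwhm,
    uncorrected = threshold_uncorrected(alpha, tfield$df),
    bonferroni = threshold_bonferroni(alpha, tfield$df, tfield$Q),
    rft = threshold_rft(alpha, tfield$df, tfield$Q, tfield$fwhm),
    fdr = as.numeric(fdr),
    fdr_defined = !is.na(fdr)
  ), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("critical t thresholds (two-tailed, alpha = %g, df = %d, Q = %d, FWHM = %.2f)\n",
              x$alpha, x$df, x$Q, x$fwhm))
  cat(sprintf("  uncorrected : %.4f\n", x$uncorrected))
  cat(sprintf("  RFT         : %.4f\n", x$rft))
  if (x$fdr_defined) cat(sprintf("  FDR         : %.4f\n", x$fdr))
  else               cat("  FDR         : undefined (no BH discovery)\n")
  cat(sprintf("  Bonferroni  : %.4f\n", x$bonferroni))
  invisible(x)
}

#' Suprathreshold significance intervals
#'
#' Maximal runs of consecutive nodes where `|t|` strictly exceeds a
#' threshold. Intervals are half-open in 0-based node coordinates
#' (`[start, end)`) and closed in percent-of-cycle display, where node x
#' maps to `100 * x / (Q - 1)` percent.
#'
#' @param tfield a `tfield`.
#' @param threshold finite critical t value.
#' @return data frame with one row per interval: `start`, `end` (half-open
#'   node indices), `start_pct`, `end_pct` (closed, percent of cycle).
#'   Zero rows when no node exceeds the threshold.
#' @export
significant_intervals <- function(tfield, threshold) {
  if (!inherits(tfield, "tfield")) stopf("`tfield` must be a tfield object")
  threshold <- assert_number(threshold, "threshold")
  above <- abs(tfield$t) > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  Q <- tfield$Q
  data.frame(
    start = starts[keep] - 1L,
    end = ends[keep],                       # half-open
    start_pct = 100 * (starts[keep] - 1L) / (Q - 1),
    end_pct = 100 * (ends[keep] - 1L) / (Q - 1)
  )
}
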