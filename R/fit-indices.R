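# Fit evaluation: chi-square from the minimized ML discrepancy, incremental
# indices against the independence baseline, parsimony (RMSEA) and absolute
# (SRMR) fit, with the conventional threshold labels.

#' Chi-square statistic from the minimized discrepancy
#' @param fml_min Minimized ML discrepancy.
#' @param N Sample size (>= 2).
#' @return `(N - 1) * fml_min`.
#' @export
chi_square <- function(fml_min, N) {
  stopifnot(fml_min >= 0, N >= 2)
  (N - 1) * fml_min
}

#' Comparative fit index
#'
#' `1 - max(chi_i - d_i, 0) / max(chi_i - d_i, chi_b - d_b, 0)`; the 0/0
#' case (both model and baseline fit no worse than their degrees of freedom)
#' is defined as 1. Always in \[0, 1\].
#'
#' @param chi_i,d_i Proposed-model chi-square and degrees of freedom.
#' @param chi_b,d_b Baseline-model chi-square and degrees of freedom.
#' @return CFI in \[0, 1\].
#' @export
cfi <- function(chi_i, d_i, chi_b, d_b) {
  num <- max(chi_i - d_i, 0)
  den <- max(chi_i - d_i, chi_b - d_b, 0)
  if (den == 0) return(1)
  1 - num / den
}

#' Tucker-Lewis index
#'
#' `((chi_b/d_b) - (chi_i/d_i)) / ((chi_b/d_b) - 1)`. Not clamped: values
#' slightly above 1 occur when the proposed model fits better than its
#' degrees of freedom.
#'
#' @inheritParams cfi
#' @return TLI (may exceed 1).
#' @export
tli <- function(chi_i, d_i, chi_b, d_b) {
  stopifnot(d_i >= 1, d_b >= 1)
  rb <- chi_b / d_b
  if (abs(rb - 1) < .Machine$double.eps^0.5) {
    stop("baseline chi-square per degree of freedom equals 1: TLI undefined")
  }
  (rb - chi_i / d_i) / (rb - 1)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(chi_i - d_i, 0) / (d_i * (n - 1)))`; a negative radicand
#' (model fitting better than its degrees of freedom) clamps to 0.
#'
#' @param chi_i,d_i Proposed-model chi-square and degrees of freedom
#'   (`d_i >= 1`).
#' @param n Sample size (>= 2).
#' @return RMSEA >= 0.
#' @export
rmsea <- function(chi_i, d_i, n) {
  stopifnot(d_i >= 1, n >= 2)
  sqrt(max(chi_i - d_i, 0) / (d_i * (n - 1)))
}

#' Standardized root mean square residual
#'
#' Root mean of the squared standardized residuals between the observed and
#' implied covariances over the lower triangle including the diagonal. By
#' default residuals are standardized on the correlation scale, dividing by
#' `sqrt(C_ii * C_jj)`; `rooted = FALSE` divides by the unrooted product
#' `C_ii * C_jj` instead (the two coincide for unit-diagonal `C`).
#'
#' @param C Observed covariance matrix.
#' @param sigma Implied covariance matrix, same order.
#' @param rooted Use the correlation-scale (square-rooted) denominator
#'   (default `TRUE`).
#' @return SRMR >= 0.
#' @export
srmr <- function(C, sigma, rooted = TRUE) {
  p <- nrow(C)
  stopifnot(ncol(C) == p, nrow(sigma) == p, ncol(sigma) == p)
  d <- diag(C)
  if (any(d <= 0)) stop("zero or negative diagonal in C: SRMR undefined")
  denom <- outer(d, d)
  if (rooted) denom <- sqrt(denom)
  R <- (C - sigma) / denom
  lower <- lower.tri(R, diag = TRUE)
  sqrt(sum(R[lower]^2) / (p * (p + 1) / 2))
}

#' Fit indices for a fitted model
#'
#' Fits the independence baseline (free variances, no covariances) to the
#' same sample moments with the same optimizer, then assembles chi-square,
#' CFI, TLI, RMSEA and SRMR.
#'
#' @param fit A `sem_fit`.
#' @param rooted SRMR denominator convention, see [srmr()].
#' @return An object of class `fit_indices`.
#' @export
fit_indices <- function(fit, rooted = TRUE) {
  stopifnot(inherits(fit, "sem_fit"))
  S <- fit$S
  N <- fit$N
  base_spec <- baseline_model(fit$spec$observed_vars)
  base_fit <- fit_sem(S, base_spec, N = N, se = FALSE)
  chi_i <- chi_square(fit$fml_min, N)
  chi_b <- chi_square(base_fit$fml_min, N)
  d_i <- fit$dof
  d_b <- degrees_of_freedom(base_spec)
  structure(list(
    chi_square = chi_i, dof = d_i,
    baseline_chi_square = chi_b, baseline_dof = d_b,
    cfi = cfi(chi_i, d_i, chi_b, d_b),
    # just-identified models reproduce S exactly: perfect-fit convention
    tli = if (d_i >= 1) tli(chi_i, d_i, chi_b, d_b) else 1,
    rmsea = if (d_i >= 1) rmsea(chi_i, d_i, N) else 0,
    srmr = srmr(S, fit$implied_cov, rooted = rooted),
    n = N
  ), class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi^2 = %.3f (df %d), baseline chi^2 = %.3f (df %d)\n",
              x$chi_square, x$dof, x$baseline_chi_square, x$baseline_dof))
  cat(sprintf("CFI = %.4f  TLI = %.4f  RMSEA = %.4f  SRMR = %.4f  (n = %d)\n",
              x$cfi, x$tli, x$rmsea, x$srmr, as.integer(x$n)))
  invisible(x)
}

#' Threshold labels for fit indices
#'
#' RMSEA: excellent < 0.01, good < 0.05, mediocre < 0.08, else poor (strict
#' inequalities). CFI and TLI: high-quality iff strictly above 0.90. SRMR:
#' adequate iff strictly below 0.08.
#'
#' @param indices A `fit_indices` (or a list with `cfi`, `tli`, `rmsea`,
#'   `srmr`).
#' @return Named character vector of quality labels.
#' @export
assess_fit <- function(indices) {
  r <- indices$rmsea
  rl <- if (r < 0.01) "excellent" else if (r < 0.05) "good"
        else if (r < 0.08) "mediocre" else "poor"
  c(rmsea = rl,
    cfi = if (indices$cfi > 0.90) "high" else "not-high",
    tli = if (!is.na(indices$tli) && indices$tli > 0.90) "high" else "not-high",
    srmr = if (indices$srmr < 0.08) "adequate" else "not-adequate")
}

#' Structured fit report
#'
#' Raw indices, the thresholds applied, the resulting labels, and the
#' chi-square bookkeeping, as a list suitable for JSON serialization.
#'
#' @param fit A `sem_fit`.
#' @param rooted SRMR convention, see [srmr()].
#' @return A list.
#' @export
fit_report <- function(fit, rooted = TRUE) {
  ind <- fit_indices(fit, rooted = rooted)
  list(
    n = fit$N,
    chi_square = ind$chi_square, dof = ind$dof,
    baseline_chi_square = ind$baseline_chi_square,
    baseline_dof = ind$baseline_dof,
    fml = fit$fml_min,
    converged = fit$converged,
    heywood = fit$heywood,
    indices = list(cfi = ind$cfi, tli = ind$tli,
                   rmsea = ind$rmsea, srmr = ind$srmr),
    thresholds = list(cfi = "> 0.90", tli = "> 0.90",
                      rmsea = "< 0.01 / 0.05 / 0.08", srmr = "< 0.08"),
    labels = as.list(assess_fit(ind)),
    srmr_reading = if (rooted) "rooted" else "literal"
  )
}
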