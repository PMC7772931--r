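# Descriptive layer: correlation matrices among indicators and Mann-Whitney
# comparisons of feature distributions between outcome groups.

#' Pearson correlation matrix of feature columns
#'
#' @param features Data frame (e.g. a per-user feature matrix).
#' @param columns Character vector of columns to correlate (default: all
#'   numeric columns).
#' @return Symmetric correlation matrix with unit diagonal. Constant columns
#'   yield `NA` entries and a warning naming them.
#' @export
correlation_matrix <- function(features, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, TRUE)]
  }
  miss <- setdiff(columns, names(features))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, columns, drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 rows for a correlation matrix")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant column(s), correlations undefined: ",
            paste(columns[sds == 0], collapse = ", "))
  }
  suppressWarnings(stats::cor(X))
}

# Internal: U statistic for group a against pooled midranks.
.u_stat <- function(a, b) {
  ranks <- rank(c(a, b))
  sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test
#'
#' U is computed by rank summation with midrank ties. `method = "exact"`
#' enumerates the permutation null over all assignments of the pooled values
#' to the two groups (feasible for small samples; required below 17 pooled
#' observations without ties to get exact tail probabilities).
#' `method = "normal"` uses the tie-corrected normal approximation with a
#' continuity correction. Two-sided throughout.
#'
#' @param sample_a,sample_b Numeric vectors (non-empty).
#' @param method `"exact"` or `"normal"`; the default `"auto"` picks exact
#'   when the pooled size is at most 16.
#' @return List with `u` (U of the first sample), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0L || nb == 0L) stop("both samples must be non-empty")
  if (method == "auto") method <- if (na + nb <= 16L) "exact" else "normal"
  u_obs <- .u_stat(sample_a, sample_b)
  mu <- na * nb / 2

  if (method == "exact") {
    pooled <- c(sample_a, sample_b)
    n <- na + nb
    if (choose(n, na) > 5e5) {
      stop("exact enumeration infeasible for ", n, " pooled observations")
    }
    ranks <- rank(pooled)
    sets <- utils::combn(n, na)
    us <- colSums(matrix(ranks[sets], nrow = na)) - na * (na + 1) / 2
    # two-sided: as-or-more-extreme deviation of U from its null mean
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    pooled <- c(sample_a, sample_b)
    n <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(u = u_obs, p = 1, method = method))
    # continuity correction toward the mean
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(u = u_obs, p = p, method = method)
}

#' Group comparison table for a feature matrix
#'
#' For each feature column: group means, sample standard deviations (divisor
#' `n - 1`), the Mann-Whitney U statistic and two-sided p value, and the
#' coarsest satisfied display bound from `bounds` (the "p <" convention of
#' published comparison tables). No multiple-testing correction is applied
#' by default; `adjust` passes a method to [stats::p.adjust()].
#'
#' @param features Data frame with the feature columns and a binary outcome
#'   column.
#' @param outcome_column Name of the 0/1 outcome column; group "a" is
#'   outcome 1.
#' @param columns Feature columns (default: all numeric columns except the
#'   outcome).
#' @param bounds Display bounds, coarsest to finest (default
#'   `c(0.05, 0.01, 0.005)`).
#' @param method Passed to [mann_whitney_u()].
#' @param adjust Multiple-testing adjustment method for the displayed bound
#'   (default `"none"`, mirroring uncorrected reporting).
#' @return Data frame, one row per feature: `category`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `u_statistic`, `p_value`, `p_bound` (`NA` when no
#'   bound is satisfied).
#' @export
group_comparison_table <- function(features, outcome_column,
                                   columns = NULL,
                                   bounds = c(0.05, 0.01, 0.005),
                                   method = "auto", adjust = "none") {
  stopifnot(outcome_column %in% names(features))
  y <- features[[outcome_column]]
  if (!all(y %in% c(0, 1))) stop("outcome column must be binary 0/1")
  if (is.null(columns)) {
    columns <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                       outcome_column)
  }
  ga <- y == 1; gb <- y == 0
  if (!any(ga) || !any(gb)) stop("one outcome group is empty")
  rows <- lapply(columns, function(cl) {
    a <- features[[cl]][ga]; b <- features[[cl]][gb]
    mw <- mann_whitney_u(a, b, method = method)
    data.frame(category = cl,
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               u_statistic = mw$u, p_value = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p_disp <- stats::p.adjust(out$p_value, method = adjust)
  bounds <- sort(bounds, decreasing = TRUE)
  out$p_bound <- vapply(p_disp, function(p) {
    sat <- bounds[p < bounds]
    if (length(sat)) min(sat) else NA_real_
  }, 0)
  out
}

#' Write a square matrix as CSV with variable names on both dimensions
#'
#' @param M Square matrix (e.g. a covariance or correlation matrix).
#' @param path Output path.
#' @param upper_triangle If `TRUE`, blank out the lower triangle (the
#'   upper-triangle layout of published correlation tables).
#' @param digits Rounding for display (default no rounding).
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(M, path, upper_triangle = FALSE, digits = NULL) {
  stopifnot(nrow(M) == ncol(M))
  out <- M
  if (!is.null(digits)) out <- round(out, digits)
  out <- as.data.frame(out)
  if (upper_triangle) {
    out[lower.tri(out)] <- NA
  }
  utils::write.csv(out, path, row.names = TRUE, na = "")
  invisible(path)
}
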