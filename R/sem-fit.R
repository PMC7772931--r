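# Maximum-likelihood covariance-structure estimation over a reticular (RAM)
# parameterization: one directed-path matrix A over the combined
# observed+latent variable set, one symmetric (co)variance matrix S0, and a
# filter F selecting the observed rows. The implied covariance is
#   Sigma(theta) = F (I - A)^-1 S0 (I - A)^-T F'.

# ---- internal parameter bookkeeping -----------------------------------------

.spec_vars <- function(spec) c(spec$observed_vars, spec$latent_vars)

.is_variance_row <- function(ptable) ptable$op == "~~" & ptable$lhs == ptable$rhs

# Build A and S0 for a full parameter assignment (fixed values + theta).
.ram_matrices <- function(spec, theta) {
  vars <- .spec_vars(spec)
  t_ <- length(vars)
  idx <- stats::setNames(seq_len(t_), vars)
  pt <- spec$ptable
  est <- pt$value
  est[pt$free] <- theta
  A <- matrix(0, t_, t_, dimnames = list(vars, vars))
  S0 <- matrix(0, t_, t_, dimnames = list(vars, vars))
  for (r in seq_len(nrow(pt))) {
    i <- switch(pt$op[r], "=~" = idx[[pt$rhs[r]]], idx[[pt$lhs[r]]])
    j <- switch(pt$op[r], "=~" = idx[[pt$lhs[r]]], idx[[pt$rhs[r]]])
    if (pt$op[r] == "~~") {
      S0[i, j] <- S0[j, i] <- est[r]
    } else {
      A[i, j] <- est[r]
    }
  }
  list(A = A, S0 = S0, idx = idx)
}

# Free-parameter (row, col) indices into A / S0, precomputed once per fit.
.param_index <- function(spec) {
  vars <- .spec_vars(spec)
  idx <- stats::setNames(seq_along(vars), vars)
  pt <- spec$ptable
  free <- which(pt$free)
  data.frame(
    row = vapply(free, function(r) {
      if (pt$op[r] == "=~") idx[[pt$rhs[r]]] else idx[[pt$lhs[r]]]
    }, 0L),
    col = vapply(free, function(r) {
      if (pt$op[r] == "=~") idx[[pt$lhs[r]]] else idx[[pt$rhs[r]]]
    }, 0L),
    in_S = pt$op[free] == "~~",
    is_var = .is_variance_row(pt)[free]
  )
}

# Implied covariance pieces; returns NULL when (I - A) is singular.
.implied_pieces <- function(spec, theta) {
  m <- .ram_matrices(spec, theta)
  t_ <- nrow(m$A)
  IA <- diag(t_) - m$A
  E <- tryCatch(solve(IA), error = function(e) NULL)
  if (is.null(E)) return(NULL)
  W <- E %*% m$S0 %*% t(E)                    # full-variable implied covariance
  obs <- seq_along(spec$observed_vars)        # observed come first in vars
  Sigma <- W[obs, obs, drop = FALSE]
  Sigma <- (Sigma + t(Sigma)) / 2
  list(Sigma = Sigma, W = W, E = E, obs = obs)
}

#' Model-implied covariance matrix
#'
#' @param spec A [sem_spec].
#' @param theta Numeric vector of free-parameter values (ptable order).
#' @param full If `TRUE`, return the implied covariance over all variables
#'   (observed and latent) instead of the observed block.
#' @return A symmetric matrix with variable names on both dimensions.
#' @export
implied_covariance <- function(spec, theta, full = FALSE) {
  stopifnot(inherits(spec, "sem_spec"), length(theta) == sum(spec$ptable$free))
  pieces <- .implied_pieces(spec, theta)
  if (is.null(pieces)) {
    stop("(I - A) is singular: the model contains a cyclic/non-recursive path structure")
  }
  if (full) (pieces$W + t(pieces$W)) / 2 else pieces$Sigma
}

# ---- the ML discrepancy ------------------------------------------------------

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' `F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p`. Zero exactly when
#' `Sigma = S`; positive otherwise (both matrices positive-definite).
#'
#' @param S Sample covariance matrix.
#' @param sigma Model-implied covariance matrix of the same order.
#' @return Nonnegative scalar discrepancy.
#' @export
fml <- function(S, sigma) {
  p <- nrow(S)
  stopifnot(nrow(sigma) == p, ncol(S) == p, ncol(sigma) == p)
  chS <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS)) stop("sample covariance S is not positive-definite")
  chSig <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(chSig)) stop("implied covariance Sigma is not positive-definite")
  logdetS <- 2 * sum(log(diag(chS)))
  logdetSig <- 2 * sum(log(diag(chSig)))
  Sig_inv <- chol2inv(chSig)
  logdetSig + sum(S * Sig_inv) - logdetS - p
}

# Objective + analytic gradient in the *raw* free-parameter space.
# Returns list(f, grad) or list(f = big, grad = 0) when Sigma is not PD.
.fml_fn_grad <- function(theta, spec, S, pidx, want_grad = TRUE) {
  big <- 1e10
  if (any(!is.finite(theta))) return(list(f = big, grad = rep(0, length(theta))))
  pieces <- .implied_pieces(spec, theta)
  if (is.null(pieces) || any(!is.finite(pieces$Sigma))) {
    return(list(f = big, grad = rep(0, length(theta))))
  }
  Sigma <- pieces$Sigma
  ch <- tryCatch(suppressWarnings(chol(Sigma)), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-10)) {
    return(list(f = big, grad = rep(0, length(theta))))
  }
  Sig_inv <- chol2inv(ch)
  chS <- attr(S, "chol")
  logdetS <- if (is.null(chS)) {
    2 * sum(log(diag(chol(S))))
  } else 2 * sum(log(diag(chS)))
  f <- 2 * sum(log(diag(ch))) + sum(S * Sig_inv) - logdetS - nrow(S)
  if (!want_grad) return(list(f = f, grad = NULL))

  # d fml / d Sigma = Sigma^-1 - Sigma^-1 S Sigma^-1
  D <- Sig_inv - Sig_inv %*% S %*% Sig_inv
  E <- pieces$E; W <- pieces$W; obs <- pieces$obs
  G <- E[obs, , drop = FALSE]                 # F (I-A)^-1, p x t
  M <- W[, obs, drop = FALSE]                 # W F', t x p
  GD <- crossprod(G, D)                       # t x p
  TA <- GD %*% t(M)                           # grad wrt A[i,j] = 2 * TA[i,j]
  TS <- GD %*% G                              # grad wrt S0[i,j]
  g <- numeric(length(theta))
  for (k in seq_along(theta)) {
    i <- pidx$row[k]; j <- pidx$col[k]
    g[k] <- if (pidx$in_S[k]) {
      if (i == j) TS[i, i] else 2 * TS[i, j]
    } else {
      2 * TA[i, j]
    }
  }
  list(f = f, grad = g)
}

# ---- fitting -----------------------------------------------------------------

.start_values <- function(spec, S) {
  pt <- spec$ptable
  free <- which(pt$free)
  start <- numeric(length(free))
  is_var <- .is_variance_row(pt)[free]
  first_indicator <- stats::setNames(character(length(spec$latent_vars)),
                                     spec$latent_vars)
  for (r in seq_len(nrow(pt))) {
    if (pt$op[r] == "=~" && !nzchar(first_indicator[[pt$lhs[r]]])) {
      first_indicator[[pt$lhs[r]]] <- pt$rhs[r]
    }
  }
  for (k in seq_along(free)) {
    r <- free[k]
    start[k] <- switch(pt$op[r],
      # scale-aware loading start: ratio of indicator SDs puts the loading
      # at the right order of magnitude when indicators differ in scale
      "=~" = sqrt(S[pt$rhs[r], pt$rhs[r]] /
                  S[first_indicator[[pt$lhs[r]]], first_indicator[[pt$lhs[r]]]]),
      "~"  = 0.0,
      "~~" = {
        if (pt$lhs[r] != pt$rhs[r]) 0.0
        else if (pt$lhs[r] %in% spec$latent_vars) {
          0.5 * S[first_indicator[[pt$lhs[r]]], first_indicator[[pt$lhs[r]]]]
        } else 0.5 * S[pt$lhs[r], pt$lhs[r]]
      })
  }
  start
}

.to_opt <- function(theta, is_var) { x <- theta; x[is_var] <- log(theta[is_var]); x }
.from_opt <- function(x, is_var) { th <- x; th[is_var] <- exp(x[is_var]); th }

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy [fml()] between the sample covariance and the
#' model-implied covariance over the free parameters. Variance parameters are
#' optimized on the log scale (so they stay positive); BFGS is followed by a
#' Newton polish until the gradient infinity-norm drops below `grad_tol`.
#'
#' @param data_or_S Either a data frame / matrix of observations (rows =
#'   units, columns named as in the model), or a named covariance matrix (in
#'   which case `N` is required). A covariance computed from data uses the
#'   divisor `N` (the ML convention; the chi-square statistic is
#'   `(N-1) * F_ML`).
#' @param spec A [sem_spec].
#' @param N Sample size (required when `data_or_S` is a covariance matrix).
#' @param grad_tol Convergence tolerance on the gradient infinity norm
#'   (default `1e-8`).
#' @param max_iter Maximum optimizer iterations (default 500).
#' @param se Compute asymptotic standard errors (default `TRUE`).
#' @return An object of class `sem_fit`: the estimated parameter table,
#'   `theta_hat`, `fml_min`, `implied_cov`, `dof`, `converged`, sample
#'   moments, and (if requested) standard errors, z and p values plus the
#'   standardized solution.
#' @export
fit_sem <- function(data_or_S, spec, N = NULL, grad_tol = 1e-8,
                    max_iter = 500L, se = TRUE) {
  stopifnot(inherits(spec, "sem_spec"))
  x <- data_or_S
  if (is.data.frame(x)) {
    miss <- setdiff(spec$observed_vars, colnames(x))
    if (length(miss)) stop("data missing model variable(s): ",
                           paste(miss, collapse = ", "))
    x <- as.matrix(x[, spec$observed_vars, drop = FALSE])
  }
  is_cov <- is.matrix(x) && nrow(x) == ncol(x) &&
    isSymmetric(unname(x), tol = 1e-8) && !is.null(rownames(x)) &&
    setequal(rownames(x), colnames(x)) &&
    all(spec$observed_vars %in% rownames(x))
  if (is_cov) {
    if (is.null(N)) stop("N must be supplied with a covariance matrix")
    S <- x[spec$observed_vars, spec$observed_vars]
  } else {
    miss <- setdiff(spec$observed_vars, colnames(x))
    if (length(miss)) stop("data missing model variable(s): ",
                           paste(miss, collapse = ", "))
    x <- x[, spec$observed_vars, drop = FALSE]
    if (is.null(N)) N <- nrow(x)
    S <- stats::cov(x) * (nrow(x) - 1) / nrow(x)   # ML divisor N
    # binary endogenous variables are treated as continuous under
    # normal-theory ML; make that visible
    endo <- unique(spec$ptable$lhs[spec$ptable$op == "~"])
    endo <- intersect(endo, colnames(x))
    for (v in endo) {
      if (all(x[, v] %in% c(0, 1))) {
        message("note: binary outcome '", v,
                "' treated as continuous under normal-theory ML")
      }
    }
  }
  p <- length(spec$observed_vars)
  dof <- degrees_of_freedom(spec)
  if (dof < 0L) {
    stop("model is under-identified: ", sum(spec$ptable$free),
         " free parameters exceed the ", p * (p + 1) / 2, " sample moments")
  }
  chS0 <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(chS0)) stop("sample covariance is not positive-definite")

  # optimize on the unit-diagonal rescaling of S (the discrepancy is scale
  # invariant); parameters map back by ratios of the scale factors, keeping
  # the optimizer well conditioned when indicators differ wildly in scale
  vars <- .spec_vars(spec)
  d_obs <- sqrt(diag(S))
  pt <- spec$ptable
  first_ind <- character()
  for (r in seq_len(nrow(pt))) {
    if (pt$op[r] == "=~" && !(pt$lhs[r] %in% names(first_ind))) {
      first_ind[pt$lhs[r]] <- pt$rhs[r]
    }
  }
  d_all <- stats::setNames(numeric(length(vars)), vars)
  d_all[spec$observed_vars] <- d_obs[spec$observed_vars]
  for (l in spec$latent_vars) d_all[l] <- d_all[first_ind[[l]]]
  S_std <- diag(1 / d_obs) %*% S %*% diag(1 / d_obs)
  dimnames(S_std) <- dimnames(S)
  attr(S_std, "chol") <- chol(S_std)
  attr(S, "chol") <- chS0

  pidx <- .param_index(spec)
  is_var <- pidx$is_var
  # per-parameter back-transform factor: std-scale estimate * scale_k = raw
  scale_k <- ifelse(pidx$in_S,
                    d_all[pidx$row] * d_all[pidx$col],
                    d_all[pidx$row] / d_all[pidx$col])
  start <- .start_values(spec, S_std)

  fn <- function(par) {
    .fml_fn_grad(.from_opt(par, is_var), spec, S_std, pidx, want_grad = FALSE)$f
  }
  gr <- function(par) {
    th <- .from_opt(par, is_var)
    g <- .fml_fn_grad(th, spec, S_std, pidx)$grad
    g[is_var] <- g[is_var] * th[is_var]   # chain rule for log-variances
    g
  }

  opt <- stats::optim(.to_opt(start, is_var), fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  par <- opt$par
  # Newton polish to drive the gradient norm to grad_tol
  last_gnorm <- Inf
  for (it in 1:30) {
    g <- gr(par)
    last_gnorm <- max(abs(g))
    if (last_gnorm < grad_tol) break
    H <- tryCatch(stats::optimHess(par, fn, gr), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H + diag(1e-10, length(par)), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    f0 <- fn(par)
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      if (fn(cand) <= f0 + 1e-12) { par <- cand; break }
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
  }
  g <- gr(par)
  last_gnorm <- max(abs(g))
  converged <- last_gnorm < grad_tol
  if (!converged && opt$convergence != 0) {
    warning("optimizer did not converge: final gradient norm ",
            format(last_gnorm, digits = 3))
  }

  theta_std <- .from_opt(par, is_var)
  theta_hat <- theta_std * scale_k   # back to the raw scale
  names(theta_hat) <- spec$ptable$label[spec$ptable$free]
  fml_min <- max(.fml_fn_grad(theta_hat, spec, S, pidx, want_grad = FALSE)$f, 0)
  pieces <- .implied_pieces(spec, theta_hat)
  # variance estimates pinned at the positivity boundary (on the scale-free
  # standardized problem) signal a Heywood-type solution
  heywood <- any(theta_std[is_var] < 1e-5)
  if (heywood) {
    warning("variance estimate at the positivity boundary (Heywood-type solution)")
  }

  fit <- structure(list(
    spec = spec, theta_hat = theta_hat, fml_min = fml_min,
    implied_cov = pieces$Sigma, implied_full = (pieces$W + t(pieces$W)) / 2,
    S = S, N = N, dof = dof, converged = converged,
    grad_norm = last_gnorm, heywood = heywood,
    se = NULL, z = NULL, p_value = NULL, standardized = NULL
  ), class = "sem_fit")
  fit$standardized <- standardize_estimates(fit)
  if (se) {
    errs <- standard_errors(fit)
    fit$se <- errs$se; fit$z <- errs$z; fit$p_value <- errs$p
  }
  fit
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit> F_ML =", format(x$fml_min, digits = 6),
      " df =", x$dof, " N =", x$N,
      if (x$converged) " (converged)" else " (NOT converged)", "\n")
  invisible(x)
}

#' Asymptotic standard errors, z and p values
#'
#' The asymptotic covariance of the free parameters is `(2/(N-1)) H^-1`,
#' with `H` the Hessian of the ML discrepancy at the solution (finite
#' differences of the analytic gradient, raw parameter scale). p values are
#' two-sided from the normal reference. Fixed parameters carry no standard
#' error.
#'
#' @param fit A `sem_fit`.
#' @param N Sample size (defaults to the fit's).
#' @return List with `se`, `z`, `p` (free-parameter order); all `NA` with a
#'   warning when the Hessian is singular.
#' @export
standard_errors <- function(fit, N = fit$N) {
  stopifnot(inherits(fit, "sem_fit"))
  spec <- fit$spec
  pidx <- .param_index(spec)
  theta <- fit$theta_hat
  S <- fit$S
  grad_raw <- function(th) .fml_fn_grad(th, spec, S, pidx)$grad
  k <- length(theta)
  H <- matrix(0, k, k)
  h <- pmax(1e-6, 1e-6 * abs(theta))
  for (j in seq_len(k)) {
    up <- theta; up[j] <- up[j] + h[j]
    dn <- theta; dn[j] <- dn[j] - h[j]
    H[, j] <- (grad_raw(up) - grad_raw(dn)) / (2 * h[j])
  }
  H <- (H + t(H)) / 2
  acov <- tryCatch(solve(H) * 2 / (N - 1), error = function(e) NULL)
  dvar <- if (is.null(acov)) NULL else diag(acov)
  if (is.null(dvar) || any(!is.finite(dvar)) || any(dvar < 0)) {
    warning("singular or indefinite Hessian: standard errors undefined")
    na <- stats::setNames(rep(NA_real_, k), names(theta))
    return(list(se = na, z = na, p = na))
  }
  se <- stats::setNames(sqrt(dvar), names(theta))
  z <- theta / se
  p <- 2 * stats::pnorm(-abs(z))
  list(se = se, z = z, p = p)
}

#' Standardized solution
#'
#' Loadings and paths are rescaled by the implied standard deviation of the
#' predictor over that of the outcome; covariances become implied
#' correlations, variances become proportions of implied variance.
#' Standardized variances of exogenous latent variables equal 1.
#'
#' @param fit A `sem_fit`.
#' @return Named numeric vector over all parameters (ptable order).
#' @export
standardize_estimates <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  spec <- fit$spec
  pt <- spec$ptable
  est <- pt$value
  est[pt$free] <- fit$theta_hat
  V <- fit$implied_full
  vars <- .spec_vars(spec)
  v_ii <- stats::setNames(diag(V), vars)
  if (any(v_ii <= 0)) {
    warning("zero or negative implied variance: standardized solution undefined for some parameters")
  }
  sdv <- sqrt(pmax(v_ii, 0))
  out <- numeric(nrow(pt))
  for (r in seq_len(nrow(pt))) {
    lhs <- pt$lhs[r]; rhs <- pt$rhs[r]
    out[r] <- switch(pt$op[r],
      "=~" = est[r] * sdv[[lhs]] / sdv[[rhs]],   # latent -> indicator
      "~"  = est[r] * sdv[[rhs]] / sdv[[lhs]],
      "~~" = if (lhs == rhs) est[r] / v_ii[[lhs]]
             else est[r] / (sdv[[lhs]] * sdv[[rhs]]))
  }
  stats::setNames(out, pt$label)
}

#' Parameter table of a fitted model
#'
#' One row per parameter with estimate, standardized estimate, standard
#' error, z and p value; fixed parameters (e.g. the scale-setting first
#' loadings) carry `NA` in the inferential columns.
#'
#' @param fit A `sem_fit`.
#' @return Data frame with columns `lhs`, `op`, `rhs`, `estimate`,
#'   `standardized`, `se`, `z`, `p`.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  pt <- fit$spec$ptable
  est <- pt$value
  est[pt$free] <- fit$theta_hat
  se <- z <- pv <- rep(NA_real_, nrow(pt))
  if (!is.null(fit$se)) {
    se[pt$free] <- fit$se
    z[pt$free] <- fit$z
    pv[pt$free] <- fit$p_value
  }
  data.frame(lhs = pt$lhs, op = pt$op, rhs = pt$rhs,
             estimate = est, standardized = unname(fit$standardized),
             se = se, z = z, p = pv, stringsAsFactors = FALSE)
}
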