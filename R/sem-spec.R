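#' @title SEM model specification
#' @description
#' A `sem_spec` holds the parameter table of a structural equation model:
#' measurement loadings (`latent =~ ind1 + ind2 + ...`), structural
#' regressions (`outcome ~ predictor + ...`) and (co)variances (`a ~~ b`).
#' The first listed indicator of every latent has its loading fixed to 1 to
#' set the latent's scale; every variable receives a free variance; all other
#' covariances must be listed explicitly.
#' @name sem_spec
NULL

# Internal constructor; ptable columns: lhs, op, rhs, free, value
new_sem_spec <- function(ptable, observed_vars, latent_vars) {
  rownames(ptable) <- NULL
  ptable$label <- paste(ptable$lhs, ptable$op, ptable$rhs)
  structure(list(ptable = ptable,
                 observed_vars = observed_vars,
                 latent_vars = latent_vars),
            class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  cat("<sem_spec> ", length(x$observed_vars), " observed, ",
      length(x$latent_vars), " latent, ",
      sum(x$ptable$free), " free parameters, df = ",
      degrees_of_freedom(x), "\n", sep = "")
  invisible(x)
}

.valid_varname <- function(x) grepl("^[A-Za-z][A-Za-z0-9_.]*$", x)

#' Parse a model specification from text
#'
#' One relation per line; `#` starts a comment. Operators: `=~` defines a
#' latent by its indicators, `~` a regression, `~~` a covariance (or a
#' variance when both sides coincide; variances are added automatically for
#' every variable, so explicit variance lines are rarely needed).
#'
#' @param text The model text (single string, possibly multi-line, or a
#'   character vector of lines).
#' @return A [sem_spec].
#' @export
parse_model <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  keep <- which(nzchar(lines))

  meas <- list(); regs <- list(); covs <- list()
  for (k in keep) {
    ln <- lines[k]
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
          else if (grepl("~~", ln, fixed = TRUE)) "~~"
          else if (grepl("~", ln, fixed = TRUE)) "~"
          else stop("line ", k, ": no operator (=~, ~, ~~) found: '", ln, "'")
    parts <- strsplit(ln, op, fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("line ", k, ": malformed relation: '", ln, "'")
    lhs <- trimws(parts[1L])
    rhs <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1L]])
    if (!.valid_varname(lhs) || any(!.valid_varname(rhs))) {
      stop("line ", k, ": invalid variable name in '", ln, "'")
    }
    for (r in rhs) {
      if (op == "~" && r == lhs) {
        stop("line ", k, ": a variable cannot regress on itself ('",
             lhs, " ~ ", r, "')")
      }
      entry <- list(lhs = lhs, rhs = r)
      switch(op,
             "=~" = { meas[[length(meas) + 1L]] <- entry },
             "~"  = { regs[[length(regs) + 1L]] <- entry },
             "~~" = { covs[[length(covs) + 1L]] <- entry })
    }
  }
  if (length(meas) + length(regs) + length(covs) == 0L) {
    stop("empty model specification")
  }

  latent_vars <- unique(vapply(meas, `[[`, "", "lhs"))

  # duplicate-definition checks (covariances are symmetric)
  key_dir <- c(vapply(meas, function(e) paste0("=~:", e$lhs, ":", e$rhs), ""),
               vapply(regs, function(e) paste0("~:", e$lhs, ":", e$rhs), ""))
  key_cov <- vapply(covs, function(e) {
    v <- sort(c(e$lhs, e$rhs)); paste0("~~:", v[1L], ":", v[2L])
  }, "")
  dup <- c(key_dir, key_cov)[duplicated(c(key_dir, key_cov))]
  if (length(dup)) stop("duplicate parameter definition: ", paste(dup, collapse = ", "))

  # observed variables in order of first appearance
  mentioned <- c(unlist(lapply(meas, function(e) e$rhs)),
                 unlist(lapply(regs, function(e) c(e$lhs, e$rhs))),
                 unlist(lapply(covs, function(e) c(e$lhs, e$rhs))))
  observed_vars <- setdiff(unique(mentioned), latent_vars)
  if (length(observed_vars) == 0L) stop("model mentions no observed variables")

  rows <- list()
  add <- function(lhs, op, rhs, free, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      lhs = lhs, op = op, rhs = rhs, free = free, value = value,
      stringsAsFactors = FALSE)
  }
  # measurement: first listed indicator per latent fixed to 1
  seen_first <- character()
  for (e in meas) {
    if (e$rhs %in% latent_vars) {
      stop("indicator '", e$rhs, "' is itself a latent variable")
    }
    first <- !(e$lhs %in% seen_first)
    if (first) seen_first <- c(seen_first, e$lhs)
    add(e$lhs, "=~", e$rhs, free = !first, value = if (first) 1 else NA_real_)
  }
  for (e in regs) add(e$lhs, "~", e$rhs, free = TRUE, value = NA_real_)
  user_var <- character()
  for (e in covs) {
    if (e$lhs == e$rhs) {
      user_var <- c(user_var, e$lhs)
      add(e$lhs, "~~", e$rhs, free = TRUE, value = NA_real_)
    } else {
      add(e$lhs, "~~", e$rhs, free = TRUE, value = NA_real_)
    }
  }
  # automatic free variances for every variable not given one explicitly
  for (v in c(observed_vars, latent_vars)) {
    if (!(v %in% user_var)) add(v, "~~", v, free = TRUE, value = NA_real_)
  }

  new_sem_spec(do.call(rbind, rows), observed_vars, latent_vars)
}

#' Model degrees of freedom
#'
#' `p(p+1)/2` distinct sample moments minus the number of free parameters;
#' negative values mean the model is under-identified, zero just-identified.
#'
#' @param spec A [sem_spec].
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  p <- length(spec$observed_vars)
  as.integer(p * (p + 1L) / 2L - sum(spec$ptable$free))
}

#' Baseline (independence) model for a set of observed variables
#'
#' All variables keep a free variance but none are allowed to covary; its
#' degrees of freedom are `p(p-1)/2`. Used as the reference model for the
#' incremental fit indices.
#'
#' @param observed_vars Character vector of variable names (length >= 2).
#' @return A [sem_spec].
#' @export
baseline_model <- function(observed_vars) {
  stopifnot(length(observed_vars) >= 2L)
  ptable <- data.frame(lhs = observed_vars, op = "~~", rhs = observed_vars,
                       free = TRUE, value = NA_real_, stringsAsFactors = FALSE)
  new_sem_spec(ptable, observed_vars, character())
}
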