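# Orchestration: posts -> features -> cohort -> SEM fit -> evaluation ->
# report, for the five bundled analysis modes (configuration presets over one
# engine; the modes differ only in indicator sets, transformations and
# outcome).

.pipeline_modes <- c("withdrawal_liwc", "withdrawal_empath",
                     "recovery_activity", "relapse_liwc", "relapse_empath")

#' Bundled model specification for an analysis mode
#'
#' @param mode One of `withdrawal_liwc`, `withdrawal_empath`,
#'   `recovery_activity`, `relapse_liwc`, `relapse_empath`.
#' @return A [sem_spec].
#' @export
bundled_model <- function(mode) {
  mode <- match.arg(mode, .pipeline_modes)
  path <- system.file("extdata", "models", paste0(mode, ".txt"),
                      package = "recoverysem", mustWork = TRUE)
  parse_model(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Build a pipeline run configuration
#'
#' Inputs may be in-memory objects or file paths (posts CSV, lexicon `.dic`
#' or plain dictionary, forum-set text files, model DSL file). A YAML file
#' with these fields can be loaded with [read_run_config()].
#'
#' @param mode Analysis mode, see [bundled_model()].
#' @param posts Post table or CSV path.
#' @param lex A `lexicon`, a dictionary path, or `"mini"` for the bundled
#'   miniature lexicon.
#' @param sets A `forum_sets` or `list(rdu = path, dar = path)`.
#' @param model A [sem_spec], a model DSL path, or `NULL` for the mode's
#'   bundled model.
#' @param aggregation Feature aggregation mode (see
#'   [aggregate_user_features()]); relapse modes always score per post (the
#'   day-scaling is a per-post transformation).
#' @param srmr_reading `"rooted"` (correlation-scale residuals) or
#'   `"literal"` (unrooted denominator), see [srmr()].
#' @param seed Integer seed recorded and applied at the start of the run.
#' @param out_dir Output directory for run artifacts, or `NULL` to skip
#'   writing.
#' @param extra_columns Optional per-user data frame (keyed by `user_id`)
#'   of externally supplied indicator columns (e.g. a summary score computed
#'   outside the lexicon).
#' @param min_posts,min_consecutive_dar Cohort filter settings.
#' @return A `run_config` list.
#' @export
run_config <- function(mode, posts, lex = "mini", sets = example_forum_sets(),
                       model = NULL, aggregation = "pooled",
                       srmr_reading = c("rooted", "literal"),
                       seed = 1L, out_dir = NULL, extra_columns = NULL,
                       min_posts = 5L, min_consecutive_dar = 5L) {
  structure(list(mode = mode, posts = posts, lex = lex, sets = sets,
                 model = model, aggregation = aggregation,
                 srmr_reading = match.arg(srmr_reading),
                 seed = as.integer(seed), out_dir = out_dir,
                 extra_columns = extra_columns,
                 min_posts = as.integer(min_posts),
                 min_consecutive_dar = as.integer(min_consecutive_dar)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Fields mirror [run_config()]; path fields are resolved relative to the
#' YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.character(p) && !file.exists(p) &&
                         file.exists(file.path(base, p))) file.path(base, p) else p
  run_config(mode = y$mode, posts = rel(y$posts),
             lex = if (is.null(y$lexicon)) "mini" else rel(y$lexicon),
             sets = if (is.null(y$rdu_forums)) example_forum_sets()
                    else list(rdu = rel(y$rdu_forums), dar = rel(y$dar_forums)),
             model = rel(y$model),
             aggregation = if (is.null(y$aggregation)) "pooled" else y$aggregation,
             srmr_reading = if (is.null(y$srmr_reading)) "rooted" else y$srmr_reading,
             seed = if (is.null(y$seed)) 1L else y$seed,
             out_dir = y$out_dir,
             min_posts = if (is.null(y$min_posts)) 5L else y$min_posts,
             min_consecutive_dar = if (is.null(y$min_consecutive_dar)) 5L
                                   else y$min_consecutive_dar)
}

# Internal: resolve possibly-path inputs into objects.
.resolve_inputs <- function(config) {
  posts <- config$posts
  if (is.character(posts)) posts <- read_posts(posts)
  lex <- config$lex
  if (identical(lex, "mini")) lex <- mini_lexicon()
  else if (is.character(lex)) {
    lex <- if (endsWith(lex, ".dic")) read_liwc_dic(lex) else read_lexicon(lex)
  }
  sets <- config$sets
  if (is.list(sets) && !inherits(sets, "forum_sets")) {
    sets <- read_forum_sets(sets$rdu, sets$dar)
  }
  model <- config$model
  if (is.null(model)) model <- bundled_model(config$mode)
  else if (is.character(model)) {
    model <- parse_model(paste(readLines(model, warn = FALSE), collapse = "\n"))
  }
  list(posts = posts, lex = lex, sets = sets, model = model)
}

# Internal: lexicon categories a mode's model needs, with the prime suffix
# stripped for relapse modes. Returns list(categories, negate).
.model_categories <- function(mode, model) {
  outcome <- if (startsWith(mode, "relapse")) "relapse" else "recovery"
  vars <- setdiff(model$observed_vars, outcome)
  if (startsWith(mode, "relapse")) {
    if (any(!endsWith(vars, "_prime"))) {
      # non-negated observed variables are not expected in the bundled
      # relapse models, but custom models may mix; treat them as plain
    }
    negate <- endsWith(vars, "_prime")
    list(vars = vars, categories = ifelse(negate, sub("_prime$", "", vars), vars),
         negate = negate, outcome = outcome)
  } else {
    list(vars = vars, categories = vars, negate = rep(FALSE, length(vars)),
         outcome = outcome)
  }
}

#' Validate a run configuration without computing
#'
#' Reports missing files, variables named by the model but absent from the
#' lexicon (or the externally supplied columns), and mode/input mismatches.
#'
#' @param config A `run_config`.
#' @return Character vector of diagnostics (empty when the config is clean).
#' @export
validate_config <- function(config) {
  diags <- character()
  if (!config$mode %in% .pipeline_modes) {
    return(paste0("unknown mode '", config$mode, "'"))
  }
  for (f in c("posts", "lex", "model")) {
    v <- config[[f]]
    if (is.character(v) && !identical(v, "mini") && !file.exists(v)) {
      diags <- c(diags, paste0(f, " file not found: ", v))
    }
  }
  if (length(diags)) return(diags)   # do not try to read missing files
  resolved <- tryCatch(suppressWarnings(.resolve_inputs(config)),
                       error = function(e) e)
  if (inherits(resolved, "error")) {
    return(paste("input error:", conditionMessage(resolved)))
  }
  posts <- resolved$posts
  if (startsWith(config$mode, "relapse")) {
    if (!"timestamp" %in% names(posts) || anyNA(posts$timestamp)) {
      diags <- c(diags, "relapse modes require parseable post timestamps")
    }
  }
  if (config$mode != "recovery_activity") {
    mc <- .model_categories(config$mode, resolved$model)
    known <- names(resolved$lex$categories)
    if (!is.null(config$extra_columns)) {
      known <- c(known, setdiff(names(config$extra_columns), "user_id"))
    }
    miss <- setdiff(mc$categories, known)
    if (length(miss)) {
      diags <- c(diags, paste0("model variable(s) with no lexicon category ",
                               "or external column: ",
                               paste(miss, collapse = ", ")))
    }
  }
  diags
}

# Internal: per-user relapse-mode features — per-post scoring, day scaling
# to the event, negation of prime indicators, then per-post averaging.
.relapse_features <- function(posts, lex, cohort, mc) {
  keep <- cohort[cohort$relapse_status %in% c("relapsed", "continued"), ]
  rows <- list()
  for (i in seq_len(nrow(keep))) {
    uid <- keep$user_id[i]
    tl <- .sort_timeline(posts[posts$user_id == uid, , drop = FALSE])
    tl <- tl[nzchar(trimws(tl$text)), , drop = FALSE]
    if (nrow(tl) == 0L) next
    event <- if (!is.na(keep$relapse_time[i])) keep$relapse_time[i]
             else max(tl$timestamp)
    tl <- tl[tl$timestamp <= event, , drop = FALSE]
    if (nrow(tl) == 0L) next
    per_post <- matrix(0, nrow(tl), length(mc$categories))
    for (j in seq_len(nrow(tl))) {
      sc <- score_categories(tokenize(tl$text[j]), lex)[mc$categories]
      sc <- scale_by_days_to_event(sc, tl$timestamp[j], event)
      sc[mc$negate] <- negate_category(sc[mc$negate])
      per_post[j, ] <- sc
    }
    rows[[uid]] <- colMeans(per_post)
  }
  if (length(rows) == 0L) stop("no labelable users with nonempty posts")
  mat <- do.call(rbind, rows)
  colnames(mat) <- mc$vars
  out <- data.frame(user_id = names(rows), mat, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$relapse <- as.integer(
    keep$relapse_status[match(out$user_id, keep$user_id)] == "relapsed")
  out
}

#' Run the full analysis pipeline
#'
#' Executes the mode's stage sequence: cohort filtering and labeling,
#' feature extraction (lexicon proportions, negation and day-scaling for
#' relapse modes, normalized forum activity for the activity mode), model
#' fitting and fit evaluation. Artifacts (feature matrix, cohort labels,
#' parameter table, fit report, run log) are written when `out_dir` is set;
#' reruns with an identical config and seed are identical.
#'
#' @param config A `run_config`.
#' @return List (invisible): `features`, `cohort`, `fit`, `report`,
#'   `indices`, `parameter_table`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  diags <- validate_config(config)
  if (length(diags)) {
    stop("invalid configuration:\n  - ", paste(diags, collapse = "\n  - "))
  }
  resolved <- .resolve_inputs(config)
  posts <- resolved$posts; lex <- resolved$lex
  sets <- resolved$sets; model <- resolved$model
  set.seed(config$seed)
  log_lines <- c(paste0("mode: ", config$mode),
                 paste0("seed: ", config$seed),
                 paste0("posts: ", nrow(posts), " from ",
                        length(unique(posts$user_id)), " users"))

  retained <- filter_active_users(posts, sets, config$min_posts)
  cohort <- label_cohort(posts, sets, config$min_posts,
                         config$min_consecutive_dar)
  log_lines <- c(log_lines,
                 paste0("retained users: ", nrow(cohort)),
                 paste0("relapse labels: ",
                        paste(names(table(cohort$relapse_status)),
                              table(cohort$relapse_status),
                              sep = "=", collapse = ", ")))

  mc <- .model_categories(config$mode, model)
  if (config$mode == "recovery_activity") {
    forums <- sub("^act_", "", mc$vars)
    features <- subreddit_activity_features(retained, forums)
    features$recovery <- cohort$recovery[match(features$user_id,
                                               cohort$user_id)]
  } else if (startsWith(config$mode, "relapse")) {
    features <- .relapse_features(retained, lex, cohort, mc)
    log_lines <- c(log_lines,
                   paste0("model fitted on ", nrow(features),
                          " relapsed/continued users (excluded dropped)"))
  } else {
    lex_cats <- intersect(mc$categories, names(lex$categories))
    fm <- user_feature_matrix(retained, lex, config$aggregation)
    features <- fm[, c("user_id", lex_cats), drop = FALSE]
    if (!is.null(config$extra_columns)) {
      extra <- config$extra_columns
      features <- merge(features, extra, by = "user_id", all.x = TRUE,
                        sort = FALSE)
    }
    features$recovery <- cohort$recovery[match(features$user_id,
                                               cohort$user_id)]
  }
  features <- features[stats::complete.cases(features), , drop = FALSE]

  fit <- withCallingHandlers(
    fit_sem(features[, c(mc$vars, mc$outcome), drop = FALSE], model),
    warning = function(w) {
      log_lines <<- c(log_lines, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  report <- fit_report(fit, rooted = config$srmr_reading == "rooted")
  indices <- fit_indices(fit, rooted = config$srmr_reading == "rooted")
  ptab <- parameter_table(fit)
  log_lines <- c(log_lines,
                 sprintf("fit: chi^2 = %.3f (df %d), CFI %.3f, TLI %.3f, RMSEA %.3f, SRMR %.3f",
                         indices$chi_square, indices$dof, indices$cfi,
                         indices$tli, indices$rmsea, indices$srmr))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    utils::write.csv(features, file.path(od, "features.csv"), row.names = FALSE)
    utils::write.csv(cohort, file.path(od, "cohort.csv"), row.names = FALSE)
    utils::write.table(ptab, file.path(od, "parameter_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_matrix_csv(fit$S, file.path(od, "sample_covariance.csv"))
    write_matrix_csv(fit$implied_cov, file.path(od, "implied_covariance.csv"))
    jsonlite::write_json(report, file.path(od, "fit_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_echo <- list(mode = config$mode, seed = config$seed,
                     aggregation = config$aggregation,
                     srmr_reading = config$srmr_reading,
                     min_posts = config$min_posts,
                     min_consecutive_dar = config$min_consecutive_dar)
    yaml::write_yaml(cfg_echo, file.path(od, "run_config.yaml"))
    writeLines(log_lines, file.path(od, "run_log.txt"))
  }
  invisible(list(features = features, cohort = cohort, fit = fit,
                 report = report, indices = indices,
                 parameter_table = ptab, config = config,
                 log = log_lines))
}
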