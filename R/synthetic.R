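# Seeded generators for every input the pipeline consumes: factor-structured
# per-user feature matrices, category-bearing post text, and event-structured
# user timelines, each with ground truth stored alongside.

#' Configuration for the synthetic factor-model generator
#'
#' Defaults emulate the study conditions of the recovery analyses: two
#' correlated latent factors (emotional distress, physical pain) measured by
#' bounded category proportions, positive structural paths into a binary
#' recovery outcome with prevalence 0.38, and a relapsed fraction of 0.62
#' among event-labelable users.
#'
#' @param n_users Number of users (default 2000).
#' @param true_loadings Named list: per latent, a named vector of loadings on
#'   indicator categories.
#' @param latent_covariance PD covariance matrix of the latent factors.
#' @param residual_variances Named vector of indicator residual variances;
#'   defaults to `1 - loading^2` so indicators have unit model variance and
#'   the loadings are the standardized loadings.
#' @param structural_paths Named vector of latent -> outcome coefficients.
#' @param outcome_link Only `"linear_threshold"`: the binary outcome is the
#'   structural linear predictor plus Gaussian noise, thresholded at the
#'   quantile giving `outcome_prevalence`.
#' @param outcome_prevalence Expected fraction of outcome-positive users.
#' @param relapse_fraction Fraction relapsed among event-labelable users.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_users = 2000L,
                             true_loadings = list(
                               emotional_distress = c(negative_emotion = 0.9,
                                                      sad = 0.7, anger = 0.8,
                                                      anxiety = 0.6),
                               physical_pain = c(health = 0.8, body = 0.7,
                                                 pain = 0.6)),
                             latent_covariance = matrix(c(1, 0.4, 0.4, 1), 2,
                               dimnames = list(names(true_loadings),
                                               names(true_loadings))),
                             residual_variances = NULL,
                             structural_paths = c(emotional_distress = 0.5,
                                                  physical_pain = 0.3),
                             outcome_link = "linear_threshold",
                             outcome_prevalence = 0.38,
                             relapse_fraction = 0.62,
                             seed = 1L) {
  stopifnot(is.list(true_loadings), length(true_loadings) >= 1L)
  lat <- names(true_loadings)
  if (!identical(dim(latent_covariance), c(length(lat), length(lat)))) {
    stop("latent_covariance must be square over the latent factors")
  }
  ev <- eigen(latent_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("latent_covariance must be positive-definite")
  cats <- unlist(lapply(true_loadings, names), use.names = FALSE)
  if (anyDuplicated(cats)) stop("each indicator may load on one latent only")
  if (is.null(residual_variances)) {
    lam <- unlist(true_loadings, use.names = FALSE)
    psi <- diag(latent_covariance)[rep(seq_along(lat), lengths(true_loadings))]
    residual_variances <- stats::setNames(pmax(1 - lam^2 * psi, 0.05), cats)
  }
  if (any(residual_variances <= 0)) stop("residual variances must be positive")
  stopifnot(outcome_link == "linear_threshold",
            outcome_prevalence > 0, outcome_prevalence < 1,
            relapse_fraction >= 0, relapse_fraction <= 1)
  if (!all(names(structural_paths) %in% lat)) {
    stop("structural paths must start at declared latent factors")
  }
  structure(list(n_users = as.integer(n_users),
                 true_loadings = true_loadings,
                 latent_covariance = latent_covariance,
                 residual_variances = residual_variances,
                 structural_paths = structural_paths,
                 outcome_link = outcome_link,
                 outcome_prevalence = outcome_prevalence,
                 relapse_fraction = relapse_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Internal: draw latent scores for a config.
.draw_latents <- function(config) {
  lat <- names(config$true_loadings)
  eta <- MASS::mvrnorm(config$n_users, rep(0, length(lat)),
                       config$latent_covariance)
  eta <- matrix(eta, nrow = config$n_users,
                dimnames = list(NULL, lat))
  eta
}

# Internal: structural linear predictor and thresholded binary outcome.
.draw_outcome <- function(config, eta) {
  gamma <- config$structural_paths
  lp <- as.vector(eta[, names(gamma), drop = FALSE] %*% gamma)
  v_lp <- as.vector(t(gamma) %*%
    config$latent_covariance[names(gamma), names(gamma)] %*% gamma)
  noise_sd <- sqrt(max(1 - v_lp, 0.05))
  z <- lp + stats::rnorm(length(lp), 0, noise_sd)
  thr <- stats::qnorm(1 - config$outcome_prevalence,
                      sd = sqrt(v_lp + noise_sd^2))
  list(outcome = as.integer(z > thr), lp = lp)
}

#' Sample a factor-structured feature matrix
#'
#' Latent scores are drawn from a zero-mean Gaussian with the configured
#' covariance; each indicator is `loading * latent + residual`, affinely
#' squashed into \[0, 1\] (`0.5 + 0.1 * x / sd(x)`, clipped at the
#' boundaries; the clipping rate is recorded). The binary outcome thresholds
#' the structural linear predictor plus noise.
#'
#' @param config A [generator_config()].
#' @return List: `features` (data frame, `user_id`, one column per indicator,
#'   `recovery`), and `truth` (latent scores, linear predictor, standardized
#'   loadings, clipping rate, the config).
#' @export
sample_factor_model <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  eta <- .draw_latents(config)
  lat <- names(config$true_loadings)
  cats <- unlist(lapply(config$true_loadings, names), use.names = FALSE)
  n <- config$n_users
  raw <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  std_load <- stats::setNames(numeric(length(cats)), cats)
  for (l in lat) {
    lam <- config$true_loadings[[l]]
    psi <- config$latent_covariance[l, l]
    for (cat in names(lam)) {
      theta <- config$residual_variances[[cat]]
      raw[, cat] <- lam[[cat]] * eta[, l] +
        stats::rnorm(n, 0, sqrt(theta))
      std_load[[cat]] <- lam[[cat]] * sqrt(psi) /
        sqrt(lam[[cat]]^2 * psi + theta)
    }
  }
  # affine squash into [0,1]; proportions bounded like word-count features
  v <- apply(raw, 2, function(x) sqrt(mean(x^2)))
  squashed <- sweep(raw, 2, v, "/") * 0.1 + 0.5
  clipped <- squashed < 0 | squashed > 1
  squashed <- pmin(pmax(squashed, 0), 1)
  out <- .draw_outcome(config, eta)
  features <- data.frame(user_id = sprintf("u%05d", seq_len(n)),
                         squashed, recovery = out$outcome,
                         check.names = FALSE, stringsAsFactors = FALSE)
  list(features = features,
       truth = list(eta = eta, lp = out$lp,
                    standardized_loadings = std_load,
                    clip_rate = mean(clipped),
                    config = config))
}

#' Simulate observations from a model specification
#'
#' Draws multivariate-normal data whose population covariance is the
#' model-implied covariance of `spec` at `theta` — the generative
#' counterpart of the structural equations, used for parameter-recovery
#' simulation and as a Monte-Carlo oracle for the implied covariance.
#'
#' @param spec A [sem_spec].
#' @param theta Free-parameter values (ptable order).
#' @param n Number of observations.
#' @return Data frame of observed variables.
#' @export
simulate_from_spec <- function(spec, theta, n) {
  Sigma <- implied_covariance(spec, theta)
  X <- MASS::mvrnorm(n, rep(0, nrow(Sigma)), Sigma)
  colnames(X) <- spec$observed_vars
  as.data.frame(X)
}

#' Deterministic true-parameter instantiation of a model topology
#'
#' Assigns a fixed, reproducible set of generating values to the free
#' parameters of a specification: free loadings cycle over
#' (0.9, 0.7, 0.5, 0.8, 0.6), structural paths over (0.4, 0.3, 0.2, 0.35),
#' latent covariances 0.3, latent-observed covariances 0.1, residual
#' covariances 0.05, latent variances 1 and observed residual variances 0.5
#' (diagonally dominant, hence positive-definite, for the bundled covariance
#' patterns). The implied covariance is verified positive-definite.
#'
#' @param spec A [sem_spec].
#' @return Named numeric vector of free-parameter values.
#' @export
default_true_parameters <- function(spec) {
  stopifnot(inherits(spec, "sem_spec"))
  pt <- spec$ptable
  free <- which(pt$free)
  load_cycle <- c(0.9, 0.7, 0.5, 0.8, 0.6)
  path_cycle <- c(0.4, 0.3, 0.2, 0.35)
  n_load <- 0L; n_path <- 0L
  theta <- numeric(length(free))
  for (k in seq_along(free)) {
    r <- free[k]
    lhs <- pt$lhs[r]; rhs <- pt$rhs[r]
    both_lat <- c(lhs, rhs) %in% spec$latent_vars
    theta[k] <- switch(pt$op[r],
      "=~" = { n_load <- n_load + 1L
               load_cycle[(n_load - 1L) %% length(load_cycle) + 1L] },
      "~"  = { n_path <- n_path + 1L
               path_cycle[(n_path - 1L) %% length(path_cycle) + 1L] },
      "~~" = if (lhs == rhs) {
               if (lhs %in% spec$latent_vars) 1 else 0.5
             } else if (all(both_lat)) 0.3
             else if (any(both_lat)) 0.1
             else 0.05)
  }
  names(theta) <- pt$label[free]
  Sigma <- implied_covariance(spec, theta)
  if (inherits(tryCatch(chol(Sigma), error = function(e) e), "error")) {
    stop("default true parameters give a non-PD implied covariance for this topology")
  }
  theta
}

# Internal: per category, exact tokens that match that category and no other
# in the lexicon (so generated token draws carry a clean one-category signal).
.unique_category_tokens <- function(lex, categories) {
  out <- list()
  for (cat in categories) {
    cands <- unique(sub("\\*$", "", lex$categories[[cat]]))
    keep <- vapply(cands, function(tok) {
      s <- score_categories(tok, lex)
      s[[cat]] > 0 && sum(s > 0) == 1L
    }, TRUE)
    if (!any(keep)) {
      stop("category '", cat, "' has no tokens unique to it in the lexicon")
    }
    out[[cat]] <- cands[keep]
  }
  out
}

#' Generate synthetic posts carrying a latent factor structure
#'
#' Each user's posts draw tokens from a mixture of category vocabularies and
#' neutral filler; a category's mixture weight increases linearly in the
#' user's score on the latent that the category indicates (slope
#' proportional to the configured loading), so that scoring and per-user
#' aggregation approximately recover the factor structure. Users with a
#' positive recovery outcome receive trailing posts in a recovery (DAR)
#' forum; all users post enough in drug-related forums to pass the activity
#' filter.
#'
#' @param config A [generator_config()].
#' @param lex A `lexicon` containing all configured categories.
#' @param sets A `forum_sets` (default [example_forum_sets()]).
#' @param posts_per_user,tokens_per_post Corpus shape (defaults 20 and 60).
#' @param base_rate Baseline per-token probability of each category
#'   (default 0.05).
#' @param slope Signal slope on the latent score (default 0.35).
#' @return List: `posts` (post table), `truth` (latent scores, outcome,
#'   config).
#' @export
generate_synthetic_posts <- function(config, lex, sets = example_forum_sets(),
                                     posts_per_user = 20L,
                                     tokens_per_post = 60L,
                                     base_rate = 0.05, slope = 0.35) {
  stopifnot(inherits(config, "generator_config"), inherits(lex, "lexicon"))
  cats <- unlist(lapply(config$true_loadings, names), use.names = FALSE)
  miss <- setdiff(cats, names(lex$categories))
  if (length(miss)) stop("lexicon lacks configured categories: ",
                         paste(miss, collapse = ", "))
  vocab <- .unique_category_tokens(lex, cats)
  filler <- c("the", "and", "to", "of", "it", "is", "was", "that", "on",
              "for", "with", "this", "at", "be", "have", "so", "but", "am")
  if (any(vapply(filler, function(tok) any(score_categories(tok, lex) > 0), TRUE))) {
    stop("filler tokens collide with lexicon categories")
  }
  set.seed(config$seed)
  eta <- .draw_latents(config)
  out <- .draw_outcome(config, eta)
  lat_of <- rep(names(config$true_loadings), lengths(config$true_loadings))
  lam <- unlist(config$true_loadings, use.names = FALSE)
  n <- config$n_users
  uid <- sprintf("u%05d", seq_len(n))
  posts <- vector("list", n)
  for (i in seq_len(n)) {
    w <- base_rate * pmax(1 + slope * lam * eta[i, lat_of], 0.05)
    probs <- c(w, max(1 - sum(w), 0.05))
    counts <- stats::rmultinom(posts_per_user, tokens_per_post, probs)
    texts <- character(posts_per_user)
    for (j in seq_len(posts_per_user)) {
      toks <- c(unlist(lapply(seq_along(cats), function(k) {
        sample(vocab[[cats[k]]], counts[k, j], replace = TRUE)
      }), use.names = FALSE),
      sample(filler, counts[length(probs), j], replace = TRUE))
      texts[j] <- paste(sample(toks), collapse = " ")
    }
    forum <- sample(sets$rdu, posts_per_user, replace = TRUE)
    if (out$outcome[i] == 1L) {
      forum[(posts_per_user - 1L):posts_per_user] <-
        sample(sets$dar, 2L, replace = TRUE)
    }
    posts[[i]] <- data.frame(
      user_id = uid[i], forum = forum,
      timestamp = as.Date("2020-01-01") + seq_len(posts_per_user),
      text = texts, stringsAsFactors = FALSE)
  }
  list(posts = do.call(rbind, posts),
       truth = list(eta = eta, recovery = out$outcome, lp = out$lp,
                    config = config))
}

#' Generate user timelines with controlled relapse structure
#'
#' Relapsing users receive a run of at least `min_run` consecutive
#' recovery-forum (DAR) posts followed by a recreational (RDU) post;
#' continued-recovery users a DAR run with no subsequent RDU post. A
#' configurable fraction of decoys violate the consecutive-run filter (short
#' DAR run before RDU, or too few DAR posts) and should be excluded by the
#' labeling rules. Posts to unrelated forums are sprinkled in and must not
#' break runs.
#'
#' @param n_users Number of users.
#' @param relapse_fraction Fraction relapsed among non-decoy users.
#' @param sets A `forum_sets`.
#' @param seed Integer seed.
#' @param decoy_fraction Fraction of decoy users (default 0.2).
#' @param min_run Qualifying DAR run length (default 5).
#' @param lex Optional `lexicon`: when supplied, post texts carry tokens
#'   from `categories` at per-user random rates (so relapse-mode features
#'   are non-degenerate); otherwise texts are plain filler.
#' @param categories Categories to seed text with (default: the categories
#'   used by the bundled relapse models that exist in `lex`).
#' @param tokens_per_post Tokens per generated post (default 40).
#' @return List: `posts` (post table) and `truth` (data frame `user_id`,
#'   `status` in relapsed/continued/excluded).
#' @export
generate_timelines <- function(n_users, relapse_fraction, sets, seed = 1L,
                               decoy_fraction = 0.2, min_run = 5L,
                               lex = NULL, categories = NULL,
                               tokens_per_post = 40L) {
  stopifnot(inherits(sets, "forum_sets"),
            relapse_fraction >= 0, relapse_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction < 1)
  vocab <- NULL
  if (!is.null(lex)) {
    if (is.null(categories)) {
      categories <- intersect(
        c("friend", "we", "shehe", "you", "male", "female", "motion",
          "religion", "tone", "joy", "zest", "cheerfulness",
          "positive_emotion", "white_collar_job", "blue_collar_job",
          "office", "urban"),
        names(lex$categories))
    }
    vocab <- .unique_category_tokens(lex, categories)
  }
  filler <- c("update", "day", "check", "in", "still", "here",
              "ok", "week", "month", "today")
  set.seed(seed)
  n_decoy <- round(n_users * decoy_fraction)
  n_main <- n_users - n_decoy
  n_rel <- round(n_main * relapse_fraction)
  status <- c(rep("relapsed", n_rel), rep("continued", n_main - n_rel),
              rep("excluded", n_decoy))
  status <- sample(status)
  other_forums <- c("askreddit", "movies", "cooking", "gaming")
  uid <- sprintf("t%05d", seq_len(n_users))
  posts <- vector("list", n_users)
  for (i in seq_len(n_users)) {
    forums <- switch(status[i],
      relapsed = c(sample(sets$rdu, sample(0:2, 1), replace = TRUE),
                   sample(sets$dar, min_run + sample(0:3, 1), replace = TRUE),
                   sample(sets$rdu, sample(1:2, 1), replace = TRUE)),
      continued = c(sample(sets$rdu, sample(0:2, 1), replace = TRUE),
                    sample(sets$dar, min_run + sample(0:3, 1), replace = TRUE)),
      excluded = if (stats::runif(1) < 0.5) {
        # short DAR run before the RDU return
        c(sample(sets$rdu, 2, replace = TRUE),
          sample(sets$dar, max(min_run - 2L, 0L), replace = TRUE),
          sample(sets$rdu, sample(1:2, 1), replace = TRUE))
      } else {
        # too few DAR posts, no RDU after
        c(sample(sets$rdu, 3, replace = TRUE),
          sample(sets$dar, max(min_run - 2L, 0L), replace = TRUE))
      })
    # unrelated-forum posts interleaved at random positions
    n_noise <- sample(0:3, 1)
    if (n_noise > 0) {
      pos <- sort(sample(length(forums) + n_noise, n_noise))
      all_forums <- character(length(forums) + n_noise)
      all_forums[pos] <- sample(other_forums, n_noise, replace = TRUE)
      all_forums[-pos] <- forums
      forums <- all_forums
    }
    k <- length(forums)
    texts <- if (is.null(vocab)) {
      paste("update day", seq_len(k))
    } else {
      # per-user random category rates give non-degenerate text features
      w <- 0.04 * pmax(1 + 0.4 * stats::rnorm(length(categories)), 0.05)
      probs <- c(w, max(1 - sum(w), 0.1))
      counts <- stats::rmultinom(k, tokens_per_post, probs)
      vapply(seq_len(k), function(j) {
        toks <- c(unlist(lapply(seq_along(categories), function(m) {
          sample(vocab[[categories[m]]], counts[m, j], replace = TRUE)
        }), use.names = FALSE),
        sample(filler, counts[length(probs), j], replace = TRUE))
        paste(sample(toks), collapse = " ")
      }, "")
    }
    posts[[i]] <- data.frame(
      user_id = uid[i], forum = forums,
      timestamp = as.Date("2020-01-01") + cumsum(sample(1:3, k, replace = TRUE)),
      text = texts, stringsAsFactors = FALSE)
  }
  list(posts = do.call(rbind, posts),
       truth = data.frame(user_id = uid, status = status,
                          stringsAsFactors = FALSE))
}
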