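#' Forum sets: recreational-drug-use and recovery communities
#'
#' @param rdu Character vector of recreational drug use (RDU) forum names.
#' @param dar Character vector of drug addiction recovery (DAR) forum names.
#' @return An object of class `forum_sets`.
#' @export
forum_sets <- function(rdu, dar) {
  rdu <- unique(as.character(rdu))
  dar <- unique(as.character(dar))
  if (length(rdu) == 0L || length(dar) == 0L) {
    stop("both forum sets must be non-empty")
  }
  overlap <- intersect(rdu, dar)
  if (length(overlap)) {
    stop("RDU and DAR sets must be disjoint; shared: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(rdu = rdu, dar = dar), class = "forum_sets")
}

#' @export
print.forum_sets <- function(x, ...) {
  cat("<forum_sets>", length(x$rdu), "RDU /", length(x$dar), "DAR forums\n")
  invisible(x)
}

#' Read forum sets from plain-text files (one forum name per line)
#' @param rdu_path,dar_path Paths to the RDU and DAR lists.
#' @return A `forum_sets`.
#' @export
read_forum_sets <- function(rdu_path, dar_path) {
  rd <- function(p) {
    x <- trimws(readLines(p, warn = FALSE))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  forum_sets(rd(rdu_path), rd(dar_path))
}

#' Bundled example forum sets
#'
#' A small synthetic stand-in for curated RDU/DAR community lists (the real
#' lists are inputs supplied by the analyst).
#' @return A `forum_sets`.
#' @export
example_forum_sets <- function() {
  forum_sets(
    rdu = c("opiates", "benzodiazepines", "trees", "stims", "cocaine",
            "drugs", "researchchemicals"),
    dar = c("opiatesrecovery", "leaves", "redditorsinrecovery",
            "stopdrinking", "addiction", "quittingkratom")
  )
}

# Internal: order a user's posts by timestamp, stable in input order for ties.
.sort_timeline <- function(posts) {
  posts[order(posts$timestamp), , drop = FALSE]
}

#' Filter to users active in drug-related forums
#'
#' Retains users with at least `min_posts` nonempty posts in the union of the
#' RDU and DAR forums.
#'
#' @param posts Data frame with columns `user_id`, `forum`, `text`.
#' @param sets A `forum_sets`.
#' @param min_posts Minimum number of nonempty drug-forum posts (default 5).
#' @return The posts of retained users (all their posts, not only the
#'   qualifying ones).
#' @export
filter_active_users <- function(posts, sets, min_posts = 5L) {
  stopifnot(inherits(sets, "forum_sets"), min_posts >= 1L)
  relevant <- posts$forum %in% c(sets$rdu, sets$dar) & nzchar(trimws(posts$text))
  counts <- table(posts$user_id[relevant])
  keep <- names(counts)[counts >= min_posts]
  posts[posts$user_id %in% keep, , drop = FALSE]
}

#' Label recovery for one user
#'
#' Recovery is 1 iff the user ever posted in a DAR forum.
#'
#' @param forums Character vector of the forums of one user's posts.
#' @param sets A `forum_sets`.
#' @return 0 or 1.
#' @export
label_recovery <- function(forums, sets) {
  stopifnot(inherits(sets, "forum_sets"))
  as.integer(any(forums %in% sets$dar))
}

#' Label relapse for one user's timeline
#'
#' Within the user's subsequence of RDU/DAR posts (posts to unrelated forums
#' do not break a run), the user is:
#' \itemize{
#'   \item `relapsed` if some RDU post follows a DAR post and at least
#'     `min_consecutive_dar` consecutive DAR posts precede the first such RDU
#'     post (`relapse_time` is that post's timestamp);
#'   \item `continued` if the user never posts in RDU after DAR and has at
#'     least `min_consecutive_dar` DAR posts;
#'   \item `excluded` otherwise.
#' }
#'
#' @param timeline Data frame with columns `forum`, `timestamp`, sorted
#'   ascending by timestamp (sorted here defensively).
#' @param sets A `forum_sets`.
#' @param min_consecutive_dar Minimum run of DAR posts qualifying a user
#'   (default 5).
#' @return List with `status` (one of "relapsed", "continued", "excluded")
#'   and `relapse_time` (a `Date`, or `NA` unless relapsed).
#' @export
label_relapse <- function(timeline, sets, min_consecutive_dar = 5L) {
  stopifnot(inherits(sets, "forum_sets"), min_consecutive_dar >= 1L)
  timeline <- .sort_timeline(timeline)
  in_rdu <- timeline$forum %in% sets$rdu
  in_dar <- timeline$forum %in% sets$dar
  sub <- which(in_rdu | in_dar)
  kind <- ifelse(in_dar[sub], "DAR", "RDU")
  ts <- timeline$timestamp[sub]
  na_time <- as.Date(NA)
  if (length(sub) == 0L) {
    return(list(status = "excluded", relapse_time = na_time))
  }
  dar_seen <- cumsum(kind == "DAR") > 0
  first_rdu_after_dar <- which(kind == "RDU" & dar_seen)[1L]
  if (!is.na(first_rdu_after_dar)) {
    # prefix before the first DAR->RDU transition is RDU* DAR*, so the DAR
    # posts before it form one consecutive run
    n_dar_before <- sum(kind[seq_len(first_rdu_after_dar - 1L)] == "DAR")
    if (n_dar_before >= min_consecutive_dar) {
      return(list(status = "relapsed",
                  relapse_time = ts[first_rdu_after_dar]))
    }
    return(list(status = "excluded", relapse_time = na_time))
  }
  if (sum(kind == "DAR") >= min_consecutive_dar) {
    return(list(status = "continued", relapse_time = na_time))
  }
  list(status = "excluded", relapse_time = na_time)
}

#' Label a whole cohort
#'
#' Applies the activity filter, then the recovery and relapse labeling rules,
#' per user.
#'
#' @param posts Post table (`user_id`, `forum`, `timestamp`, `text`).
#' @param sets A `forum_sets`.
#' @param min_posts Activity filter threshold (default 5 nonempty drug-forum
#'   posts).
#' @param min_consecutive_dar Relapse qualification run length (default 5).
#' @return Data frame: `user_id`, `recovery` (0/1), `relapse_status`,
#'   `relapse_time`.
#' @export
label_cohort <- function(posts, sets, min_posts = 5L, min_consecutive_dar = 5L) {
  posts <- filter_active_users(posts, sets, min_posts)
  uids <- unique(posts$user_id)
  rec <- integer(length(uids))
  status <- character(length(uids))
  rtime <- as.Date(rep(NA, length(uids)))
  for (i in seq_along(uids)) {
    tl <- posts[posts$user_id == uids[i], , drop = FALSE]
    rec[i] <- label_recovery(tl$forum, sets)
    lab <- label_relapse(tl, sets, min_consecutive_dar)
    status[i] <- lab$status
    rtime[i] <- lab$relapse_time
  }
  data.frame(user_id = uids, recovery = rec, relapse_status = status,
             relapse_time = rtime, stringsAsFactors = FALSE)
}

#' Per-user normalized forum-activity features
#'
#' For each target forum, the user's post count in that forum divided by the
#' user's total retrieved posts (all forums). With ~1000 posts per user this
#' yields the small normalized activity magnitudes used as indicators in the
#' forum-activity recovery model.
#'
#' @param posts Post table (`user_id`, `forum`).
#' @param target_forums Character vector of forums to featurize.
#' @param prefix Column-name prefix for the activity columns (default
#'   `"act_"`, keeping forum indicators distinct from latent names).
#' @return Data frame: `user_id` plus one column per target forum.
#' @export
subreddit_activity_features <- function(posts, target_forums, prefix = "act_") {
  stopifnot(length(target_forums) > 0L)
  uids <- unique(posts$user_id)
  total <- table(posts$user_id)
  out <- matrix(0, nrow = length(uids), ncol = length(target_forums),
                dimnames = list(uids, paste0(prefix, target_forums)))
  for (j in seq_along(target_forums)) {
    cnt <- table(posts$user_id[posts$forum == target_forums[j]])
    out[names(cnt), j] <- as.numeric(cnt)
  }
  out <- out / as.numeric(total[uids])
  data.frame(user_id = uids, out, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}
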