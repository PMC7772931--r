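#' Construct a category lexicon
#'
#' A lexicon maps psycholinguistic category names to term patterns. A pattern
#' is either an exact lowercase token ("hate") or a stem wildcard ending in
#' `*` ("pray*") that matches any token with that prefix. Categories are not
#' exclusive: a token may count toward several categories.
#'
#' @param categories Named list; each element a character vector of patterns.
#' @return An object of class `lexicon`.
#' @export
lexicon <- function(categories) {
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    stop("`categories` must be a named list of pattern vectors")
  }
  if (anyDuplicated(names(categories))) {
    stop("category names must be unique")
  }
  for (nm in names(categories)) {
    pats <- categories[[nm]]
    if (!is.character(pats) || length(pats) == 0L || any(!nzchar(pats))) {
      stop("category '", nm, "' must contain at least one non-empty pattern")
    }
    # wildcard marker only allowed in terminal position
    bad <- grepl("\\*", sub("\\*$", "", pats))
    if (any(bad)) {
      stop("category '", nm, "': wildcard '*' only allowed at end of pattern: ",
           paste(pats[bad], collapse = ", "))
    }
  }
  categories <- lapply(categories, tolower)
  structure(list(categories = categories), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", length(x$categories), "categories,",
      sum(lengths(x$categories)), "patterns\n")
  invisible(x)
}

#' Category names of a lexicon
#' @param lex A `lexicon`.
#' @return Character vector of category names, in lexicon order.
#' @export
lexicon_categories <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  names(lex$categories)
}

#' Read a lexicon from a plain-text dictionary file
#'
#' One category per line: `category: term1 term2 ...`. Lines starting with
#' `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return A `lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cats <- list()
  for (ln in lines) {
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0L) stop("malformed lexicon line (no ':'): ", ln)
    nm <- trimws(substr(ln, 1L, colon - 1L))
    terms <- strsplit(trimws(substr(ln, colon + 1L, nchar(ln))), "\\s+")[[1L]]
    cats[[nm]] <- terms
  }
  lexicon(cats)
}

#' Read a LIWC-style .dic dictionary file
#'
#' The .dic layout is a `%`-delimited header mapping numeric category ids to
#' names, followed by `term id id ...` lines.
#'
#' @param path File path.
#' @return A `lexicon`.
#' @export
read_liwc_dic <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  pct <- which(lines == "%")
  if (length(pct) < 2L) stop("not a .dic file: expected a %%-delimited header")
  header <- lines[(pct[1L] + 1L):(pct[2L] - 1L)]
  body <- lines[-seq_len(pct[2L])]
  ids <- character()
  for (ln in header) {
    f <- strsplit(ln, "\\s+")[[1L]]
    if (length(f) != 2L) stop("malformed .dic header line: ", ln)
    ids[f[1L]] <- f[2L]
  }
  cats <- stats::setNames(vector("list", length(ids)), unname(ids))
  for (ln in body) {
    f <- strsplit(ln, "\\s+")[[1L]]
    term <- f[1L]
    for (id in f[-1L]) {
      nm <- ids[[id]]
      if (is.null(nm)) stop("unknown category id '", id, "' for term ", term)
      cats[[nm]] <- c(cats[[nm]], term)
    }
  }
  empty <- lengths(cats) == 0L
  if (any(empty)) cats <- cats[!empty]
  lexicon(cats)
}

#' The bundled miniature lexicon
#'
#' A small open dictionary with the category names used throughout the
#' bundled recovery and relapse models. It is a stand-in interface-compatible
#' with LIWC/Empath-style dictionaries, not a reproduction of them.
#'
#' @return A `lexicon`.
#' @export
mini_lexicon <- function() {
  path <- system.file("extdata", "mini_lexicon.dic", package = "recoverysem",
                      mustWork = TRUE)
  read_liwc_dic(path)
}

#' Tokenize post text
#'
#' Lowercases and splits text into maximal runs of alphanumerics plus
#' apostrophes; all other punctuation separates tokens.
#'
#' @param text A character scalar (or vector; tokens are concatenated in order).
#' @return Character vector of lowercase tokens (empty for empty text).
#' @export
tokenize <- function(text) {
  if (length(text) == 0L) return(character())
  text <- tolower(paste(text, collapse = " "))
  toks <- regmatches(text, gregexpr("[a-z0-9']+", text))[[1L]]
  toks[nzchar(toks)]
}

# Internal: count tokens matching any pattern of one category.
# Works on a token frequency table to keep long posts cheap.
.count_matches <- function(tok_unique, tok_counts, exact, prefixes) {
  hit <- tok_unique %in% exact
  for (pre in prefixes) {
    hit <- hit | startsWith(tok_unique, pre)
  }
  sum(tok_counts[hit])
}

#' Score tokens against a lexicon
#'
#' Each category's score is the proportion of tokens matching any of its
#' patterns (a token may count toward several categories). Proportions live
#' in \[0, 1\], mirroring word-count dictionaries that report the percentage
#' of total words.
#'
#' @param tokens Character vector of tokens (as from [tokenize()]).
#' @param lex A `lexicon`.
#' @return Named numeric vector, one proportion per category, in lexicon
#'   order. If `tokens` is empty all values are 0 and the result carries
#'   `attr(, "empty") = TRUE`.
#' @export
score_categories <- function(tokens, lex) {
  stopifnot(inherits(lex, "lexicon"))
  nms <- names(lex$categories)
  out <- stats::setNames(numeric(length(nms)), nms)
  if (length(tokens) == 0L) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  tab <- table(tokens)
  tok_unique <- names(tab)
  tok_counts <- as.integer(tab)
  total <- length(tokens)
  for (nm in nms) {
    pats <- lex$categories[[nm]]
    wild <- endsWith(pats, "*")
    out[[nm]] <- .count_matches(tok_unique, tok_counts,
                                exact = pats[!wild],
                                prefixes = sub("\\*$", "", pats[wild])) / total
  }
  attr(out, "empty") <- FALSE
  out
}

#' Negate a category proportion
#'
#' Returns `1 - value`: the "prime" transformation that turns presence of a
#' psycholinguistic signal into its absence (e.g. `friends` into `friends'`).
#' Used to build the relapse-model indicators.
#'
#' @param value Proportion(s) in \[0, 1\].
#' @return `1 - value`.
#' @export
negate_category <- function(value) {
  if (any(!is.finite(value)) || any(value < 0) || any(value > 1)) {
    stop("negate_category() expects proportions in [0, 1]; got value outside ",
         "range (scale mismatch upstream?)")
  }
  1 - value
}

#' Scale a category value by days to an event
#'
#' Divides a post's category value by the whole number of days between the
#' post and a later event (e.g. the user's relapse day), flooring the divisor
#' at one day so same-day posts are kept rather than discarded.
#'
#' @param value Proportion in \[0, 1\].
#' @param post_time,event_time `Date`s (or anything `as.Date` accepts);
#'   `event_time` must not precede `post_time`.
#' @return Nonnegative real `value / max(1, days between)`.
#' @export
scale_by_days_to_event <- function(value, post_time, event_time) {
  post_time <- as.Date(post_time)
  event_time <- as.Date(event_time)
  gap <- as.numeric(event_time - post_time, units = "days")
  if (any(gap < 0)) stop("event_time precedes post_time")
  value / pmax(1, gap)
}

#' Aggregate a user's posts into one feature vector
#'
#' `"pooled"` (default) concatenates the tokens of all nonempty posts and
#' scores them once; `"per_post_mean"` scores each nonempty post separately
#' and averages the per-post scores. The two agree when all posts have equal
#' token counts.
#'
#' @param texts Character vector of the user's post texts.
#' @param lex A `lexicon`.
#' @param mode `"pooled"` or `"per_post_mean"`.
#' @return Named numeric vector of category proportions.
#' @export
aggregate_user_features <- function(texts, lex, mode = c("pooled", "per_post_mean")) {
  mode <- match.arg(mode)
  token_lists <- lapply(texts, tokenize)
  token_lists <- token_lists[lengths(token_lists) > 0L]
  if (length(token_lists) == 0L) {
    stop("all posts empty: user must be excluded upstream")
  }
  if (mode == "pooled") {
    score_categories(unlist(token_lists, use.names = FALSE), lex)
  } else {
    scores <- vapply(token_lists, score_categories,
                     numeric(length(lex$categories)), lex = lex)
    scores <- matrix(scores, nrow = length(lex$categories),
                     dimnames = list(names(lex$categories), NULL))
    out <- rowMeans(scores)
    attr(out, "empty") <- FALSE
    out
  }
}

#' Per-user feature matrix from a post table
#'
#' Builds one row per user of category proportions (the per-user feature
#' matrix that downstream models consume), in lexicon category order.
#'
#' @param posts Data frame with columns `user_id` and `text`.
#' @param lex A `lexicon`.
#' @param mode Aggregation mode, see [aggregate_user_features()].
#' @return Data frame: `user_id` plus one column per category. Users whose
#'   posts are all empty are dropped with a warning.
#' @export
user_feature_matrix <- function(posts, lex, mode = c("pooled", "per_post_mean")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(posts), all(c("user_id", "text") %in% names(posts)))
  by_user <- split(posts$text, posts$user_id)
  rows <- list()
  dropped <- character()
  for (uid in names(by_user)) {
    feats <- tryCatch(aggregate_user_features(by_user[[uid]], lex, mode),
                      error = function(e) NULL)
    if (is.null(feats)) dropped <- c(dropped, uid) else rows[[uid]] <- feats
  }
  if (length(dropped)) {
    warning(length(dropped), " user(s) with only empty posts dropped")
  }
  if (length(rows) == 0L) stop("no users with nonempty posts")
  mat <- do.call(rbind, rows)
  data.frame(user_id = names(rows), mat, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a post table
#'
#' CSV with columns `user_id`, `forum`, `timestamp` (ISO-8601 date), `text`.
#'
#' @param path File path.
#' @return Data frame with `timestamp` parsed to `Date`.
#' @export
read_posts <- function(path) {
  posts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("user_id", "forum", "timestamp", "text")
  miss <- setdiff(need, names(posts))
  if (length(miss)) stop("post table missing column(s): ", paste(miss, collapse = ", "))
  posts$timestamp <- as.Date(posts$timestamp)
  if (anyNA(posts$timestamp)) stop("unparseable timestamps in post table")
  posts$text[is.na(posts$text)] <- ""
  posts
}
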