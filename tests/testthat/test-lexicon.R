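test_that("tokenization lowercases and splits on punctuation", {
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("I feel awful, awful!"),
                   c("i", "feel", "awful", "awful"))
  expect_identical(tokenize("3 days clean-ish"),
                   c("3", "days", "clean", "ish"))
  expect_identical(tokenize("don't stop"), c("don't", "stop"))
})

test_that("category scoring counts proportions, non-exclusively", {
  lex <- lexicon(list(anger = "hate", affect = c("hate", "calm")))
  s <- score_categories(c("hate", "hate", "calm", "day"), lex)
  expect_equal(unname(s["anger"]), 0.5)
  expect_equal(unname(s["affect"]), 0.75)

  lex10 <- lexicon(list(anger = c("mad", "rage")))
  toks <- c("mad", "rage", rep("calmword", 8))
  expect_equal(unname(score_categories(toks, lex10)["anger"]), 0.2)

  none <- score_categories(c("blue", "sky"), lex)
  expect_true(all(none == 0))
  expect_false(attr(none, "empty"))

  empty <- score_categories(character(), lex)
  expect_true(all(empty == 0))
  expect_true(attr(empty, "empty"))
})

test_that("wildcard patterns do prefix matching on whole tokens", {
  lex <- lexicon(list(religion = c("god", "pray*")))
  s <- score_categories(c("praying", "prayed", "pray", "spray"), lex)
  expect_equal(unname(s["religion"]), 0.75)   # "spray" must not match
  expect_error(lexicon(list(bad = "pr*ay")), "wildcard")
  expect_error(lexicon(list(bad = character())), "non-empty")
})

test_that("scoring is bounded and invariant under token reordering", {
  lex <- mini_lexicon()
  set.seed(11)
  vocab <- c("hate", "sad", "pain", "happy", "the", "run", "cat", "dog")
  for (i in 1:20) {
    toks <- sample(vocab, sample(1:40, 1), replace = TRUE)
    s <- score_categories(toks, lex)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(score_categories(sample(toks), lex), s)
  }
})

test_that("negation is the exact complement with domain checks", {
  expect_identical(negate_category(0.2), 0.8)
  expect_identical(negate_category(0), 1)
  expect_identical(negate_category(0.5), 0.5)
  x <- seq(0, 1, by = 0.05)
  expect_equal(negate_category(negate_category(x)), x)
  expect_equal(x + negate_category(x), rep(1, length(x)))
  expect_error(negate_category(1.2), "\\[0, 1\\]")
  expect_error(negate_category(-0.1), "\\[0, 1\\]")
})

test_that("day scaling floors the divisor at one day and is monotone", {
  d0 <- as.Date("2021-03-01")
  expect_equal(scale_by_days_to_event(0.4, d0, d0 + 2), 0.2)
  expect_equal(scale_by_days_to_event(0.4, d0, d0 + 1), 0.4)
  expect_equal(scale_by_days_to_event(0.4, d0, d0), 0.4)  # same-day floor
  expect_error(scale_by_days_to_event(0.4, d0, d0 - 1), "precedes")
  vals <- vapply(0:30, function(g) scale_by_days_to_event(0.7, d0, d0 + g), 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("user aggregation: pooled and per-post-mean modes", {
  lex <- lexicon(list(anger = "mad"))
  one <- "mad calm calm calm"
  expect_equal(aggregate_user_features(one, lex),
               score_categories(tokenize(one), lex))

  # equal token counts: the two modes coincide (weighted-mean identity)
  p1 <- "mad mad aa bb cc dd ee ff gg hh"                # 10 tokens, 2 hits
  p2 <- "mad mad mad mad aa bb cc dd ee ff"              # 10 tokens, 4 hits
  pooled <- aggregate_user_features(c(p1, p2), lex, "pooled")
  permean <- aggregate_user_features(c(p1, p2), lex, "per_post_mean")
  expect_equal(unname(pooled["anger"]), 0.3)
  expect_equal(unname(permean["anger"]), 0.3)

  # unequal lengths: 10 tokens / 2 hits and 30 tokens / 3 hits
  p3 <- paste(c(rep("mad", 3), rep("zz", 27)), collapse = " ")
  pooled2 <- aggregate_user_features(c(p1, p3), lex, "pooled")
  permean2 <- aggregate_user_features(c(p1, p3), lex, "per_post_mean")
  expect_equal(unname(pooled2["anger"]), 5 / 40)         # 0.125
  expect_equal(unname(permean2["anger"]), (0.2 + 0.1) / 2)
  expect_false(pooled2[["anger"]] == permean2[["anger"]])

  expect_error(aggregate_user_features(c("", "  "), lex), "excluded")
})

test_that("per-user feature matrix drops all-empty users and keeps order", {
  lex <- lexicon(list(anger = "mad", calm = "zen"))
  posts <- data.frame(
    user_id = c("a", "a", "b", "c"),
    text = c("mad zen", "mad mad", "", "zen zen"),
    stringsAsFactors = FALSE)
  expect_warning(fm <- user_feature_matrix(posts, lex), "empty posts")
  expect_identical(fm$user_id, c("a", "c"))
  expect_identical(names(fm), c("user_id", "anger", "calm"))
  expect_equal(fm$anger, c(0.75, 0))
})

test_that("dictionary readers: .dic layout and plain format agree", {
  dic <- tempfile(fileext = ".dic")
  writeLines(c("%", "1\tanger", "2\taffect", "%",
               "hate\t1\t2", "calm\t2", "rage\t1"), dic)
  lx1 <- read_liwc_dic(dic)
  expect_setequal(lexicon_categories(lx1), c("anger", "affect"))
  expect_setequal(lx1$categories$affect, c("hate", "calm"))

  plain <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "anger: hate rage", "affect: hate calm"), plain)
  lx2 <- read_lexicon(plain)
  expect_equal(lapply(lx1$categories[c("anger", "affect")], sort),
               lapply(lx2$categories[c("anger", "affect")], sort))

  lex <- mini_lexicon()
  expect_s3_class(lex, "lexicon")
  expect_true(all(c("negative_emotion", "health", "friend", "urban") %in%
                  lexicon_categories(lex)))
})

test_that("post reader parses timestamps and flags missing columns", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(user_id = "u", forum = "ru1",
                       timestamp = "2021-05-01", text = "hi"),
            f, row.names = FALSE)
  p <- read_posts(f)
  expect_s3_class(p$timestamp, "Date")
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(user_id = "u", text = "hi"), f2, row.names = FALSE)
  expect_error(read_posts(f2), "missing column")
})
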