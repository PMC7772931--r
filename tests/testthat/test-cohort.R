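test_that("activity filter counts nonempty drug-forum posts", {
  sets <- tiny_sets()
  mk <- function(uid, forums, texts) {
    data.frame(user_id = uid, forum = forums,
               timestamp = as.Date("2021-01-01") + seq_along(forums),
               text = texts, stringsAsFactors = FALSE)
  }
  p1 <- mk("a", rep("ru1", 4), rep("x", 4))                 # 4 nonempty
  p2 <- mk("b", c(rep("ru1", 3), rep("da1", 2)), rep("x", 5))
  p3 <- mk("c", rep("ru1", 6), c("x", "", "x", " ", "x", "x"))  # 4 nonempty
  posts <- rbind(p1, p2, p3)
  kept <- filter_active_users(posts, sets, min_posts = 5)
  expect_setequal(unique(kept$user_id), "b")
})

test_that("recovery label is any DAR post", {
  sets <- tiny_sets()
  expect_identical(label_recovery(rep("ru1", 5), sets), 0L)
  expect_identical(label_recovery(c(rep("ru1", 9), "da2"), sets), 1L)
  expect_identical(label_recovery(c("astro", "movies"), sets), 0L)
})

test_that("relapse labeling follows the consecutive-run rule", {
  sets <- tiny_sets()
  lab <- label_relapse(timeline_from_code("RDDDDDR"), sets)
  expect_identical(lab$status, "relapsed")
  expect_identical(lab$relapse_time, as.Date("2021-01-08"))

  expect_identical(label_relapse(timeline_from_code("RRRDDDDDD"), sets)$status,
                   "continued")
  expect_identical(label_relapse(timeline_from_code("DDDR"), sets)$status,
                   "excluded")
  # unrelated forums do not break a DAR run
  expect_identical(label_relapse(timeline_from_code("RDDXDDDXR"), sets)$status,
                   "relapsed")
})

test_that("hand-built timeline fixture is labeled exactly", {
  sets <- tiny_sets()
  fx <- hand_timelines()
  got <- vapply(fx$timelines, function(tl) label_relapse(tl, sets)$status, "")
  expect_identical(got, fx$truth)
})

test_that("with run length 1, relapse = any DAR followed by RDU (exhaustive)", {
  sets <- tiny_sets()
  # brute-force oracle over every RDU/DAR sequence of length <= 8
  oracle <- function(kinds) {
    any(vapply(seq_along(kinds), function(i) {
      kinds[i] == "R" && any(kinds[seq_len(i - 1)] == "D")
    }, TRUE))
  }
  for (len in 1:8) {
    for (mask in 0:(2^len - 1)) {
      kinds <- ifelse(bitwAnd(mask, 2^(seq_len(len) - 1)) > 0, "D", "R")
      tl <- timeline_from_code(paste(kinds, collapse = ""))
      got <- label_relapse(tl, sets, min_consecutive_dar = 1)$status
      expect_identical(got == "relapsed", oracle(kinds),
                       info = paste(kinds, collapse = ""))
    }
  }
})

test_that("statuses partition users and filters are monotone", {
  sets <- tiny_sets()
  set.seed(4)
  codes <- replicate(200, paste(sample(c("R", "D", "X"), sample(1:12, 1),
                                       replace = TRUE), collapse = ""))
  statuses <- vapply(codes, function(cd) {
    label_relapse(timeline_from_code(cd), sets)$status
  }, "")
  expect_true(all(statuses %in% c("relapsed", "continued", "excluded")))

  # raising the run threshold never enlarges the relapsed set
  rel_by_k <- lapply(1:6, function(k) {
    which(vapply(codes, function(cd) {
      label_relapse(timeline_from_code(cd), sets, k)$status == "relapsed"
    }, TRUE))
  })
  for (k in 2:6) expect_true(all(rel_by_k[[k]] %in% rel_by_k[[k - 1]]))

  # raising min_posts never enlarges the retained set
  posts <- do.call(rbind, lapply(seq_along(codes), function(i) {
    tl <- timeline_from_code(codes[i], user = paste0("u", i)); tl
  }))
  kept_by_m <- lapply(1:6, function(m) {
    unique(filter_active_users(posts, sets, m)$user_id)
  })
  for (m in 2:6) expect_true(all(kept_by_m[[m]] %in% kept_by_m[[m - 1]]))
})

test_that("forum-activity features normalize by total posts", {
  posts <- data.frame(
    user_id = c(rep("a", 100), rep("b", 50)),
    forum = c(rep("other", 98), "yoga", "yoga", rep("gym", 50)),
    stringsAsFactors = FALSE)
  f <- subreddit_activity_features(posts, c("yoga", "gym", "fitness"))
  a <- f[f$user_id == "a", ]
  b <- f[f$user_id == "b", ]
  expect_equal(a$act_yoga, 0.02)
  expect_equal(a$act_fitness, 0)
  expect_equal(b$act_gym, 1)
  expect_equal(b$act_yoga, 0)
})

test_that("forum sets validate and read from files", {
  expect_error(forum_sets("a", character()), "non-empty")
  expect_error(forum_sets(c("a", "b"), c("b", "c")), "disjoint")
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("opiates", "trees", ""), f1)
  writeLines(c("# recovery", "leaves"), f2)
  fs <- read_forum_sets(f1, f2)
  expect_setequal(fs$rdu, c("opiates", "trees"))
  expect_identical(fs$dar, "leaves")
})

test_that("cohort labeling table is consistent with per-user rules", {
  sets <- tiny_sets()
  fx <- hand_timelines()
  posts <- do.call(rbind, fx$timelines)
  lab <- label_cohort(posts, sets, min_posts = 4, min_consecutive_dar = 5)
  expect_true(all(lab$recovery[lab$relapse_status != "excluded"] == 1))
  expect_true(all(!is.na(lab$relapse_time[lab$relapse_status == "relapsed"])))
  expect_true(all(is.na(lab$relapse_time[lab$relapse_status != "relapsed"])))
})
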