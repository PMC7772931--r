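test_that("generator configs validate their inputs", {
  expect_error(generator_config(latent_covariance = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
  expect_error(generator_config(true_loadings = list(
    f1 = c(a = 0.5), f2 = c(a = 0.5)),
    latent_covariance = diag(2)), "one latent only")
  cfg <- generator_config(n_users = 10)
  expect_s3_class(cfg, "generator_config")
  # default residuals give unit indicator variance: loadings are standardized
  expect_equal(unname(cfg$residual_variances["negative_emotion"]),
               1 - 0.9^2, tolerance = 1e-12)
})

test_that("the factor sampler is seed-deterministic and bounded", {
  cfg <- generator_config(n_users = 200, seed = 33)
  s1 <- sample_factor_model(cfg)
  s2 <- sample_factor_model(cfg)
  expect_identical(s1$features, s2$features)
  num <- s1$features[, setdiff(names(s1$features), c("user_id", "recovery"))]
  expect_true(all(num >= 0 & num <= 1))
  expect_true(all(s1$features$recovery %in% 0:1))
  expect_lt(s1$truth$clip_rate, 0.001)
})

test_that("generated features match the generating correlation structure", {
  cfg <- generator_config(n_users = 1e5, seed = 44)
  s <- sample_factor_model(cfg)
  cats <- names(cfg$residual_variances)
  emp <- cor(s$features[, cats])
  # implied correlations: std loadings and the latent correlation
  lam <- s$truth$standardized_loadings
  lat_of <- rep(names(cfg$true_loadings), lengths(cfg$true_loadings))
  names(lat_of) <- cats
  Psi <- cov2cor(cfg$latent_covariance)
  imp <- diag(length(cats)); dimnames(imp) <- list(cats, cats)
  for (a in cats) for (b in cats) if (a != b) {
    imp[a, b] <- lam[[a]] * lam[[b]] * Psi[lat_of[[a]], lat_of[[b]]]
  }
  expect_lt(norm(emp - imp, "F"), 0.05)

  # zero loadings: indicators uncorrelated
  cfg0 <- generator_config(n_users = 2e4, seed = 45,
    true_loadings = list(f = c(negative_emotion = 0, sad = 0, anger = 0)),
    latent_covariance = matrix(1, 1, 1, dimnames = list("f", "f")),
    residual_variances = c(negative_emotion = 1, sad = 1, anger = 1),
    structural_paths = c(f = 0.5))
  s0 <- sample_factor_model(cfg0)
  R0 <- cor(s0$features[, c("negative_emotion", "sad", "anger")])
  expect_lt(max(abs(R0[upper.tri(R0)])), 0.03)
})

test_that("simulating from a spec reproduces its implied covariance", {
  spec <- parse_model("F =~ x1 + x2 + x3\nF ~~ F")
  theta <- default_true_parameters(spec)
  set.seed(46)
  d <- simulate_from_spec(spec, theta, 1e5)
  Sigma <- implied_covariance(spec, theta)
  expect_lt(max(abs(cov(d) - Sigma)), 0.8 * 3 / sqrt(1e5) * max(diag(Sigma)) + 0.02)
})

test_that("default true parameters are PD for every bundled topology", {
  for (m in c("withdrawal_liwc", "withdrawal_empath", "recovery_activity",
              "relapse_liwc", "relapse_empath")) {
    spec <- bundled_model(m)
    theta <- default_true_parameters(spec)
    Sigma <- implied_covariance(spec, theta)
    expect_true(all(eigen(Sigma, symmetric = TRUE,
                          only.values = TRUE)$values > 0), info = m)
  }
})

test_that("synthetic posts carry the latent signal into scored features", {
  cfg <- generator_config(n_users = 300, seed = 55)
  lex <- mini_lexicon()
  corpus <- generate_synthetic_posts(cfg, lex)
  expect_identical(corpus$posts,
                   generate_synthetic_posts(cfg, lex)$posts)  # determinism
  fm <- user_feature_matrix(corpus$posts, lex)
  eta <- corpus$truth$eta[, "emotional_distress"]
  hi <- fm$negative_emotion[eta > quantile(eta, 0.9)]
  lo <- fm$negative_emotion[eta < quantile(eta, 0.1)]
  expect_gt(mean(hi), mean(lo))
  # a category outside the configured mixture never occurs
  expect_true(all(fm$urban == 0))
  # recovery outcome is encoded in the timelines themselves
  lab <- label_cohort(corpus$posts, example_forum_sets())
  m <- merge(lab, data.frame(user_id = sprintf("u%05d", 1:300),
                             truth = corpus$truth$recovery))
  expect_identical(m$recovery, m$truth)
})

test_that("generated timelines are labeled back without error", {
  sets <- example_forum_sets()
  tl <- generate_timelines(400, 0.62, sets, seed = 66)
  expect_identical(tl$posts, generate_timelines(400, 0.62, sets, seed = 66)$posts)
  lab <- label_cohort(tl$posts, sets, min_posts = 3)
  m <- merge(lab, tl$truth, by = "user_id")
  expect_equal(nrow(m), 400)
  expect_identical(m$relapse_status, m$status)

  all_rel <- generate_timelines(50, 1, sets, seed = 67, decoy_fraction = 0)
  lab_rel <- label_cohort(all_rel$posts, sets, min_posts = 3)
  expect_true(all(lab_rel$relapse_status == "relapsed"))
  none_rel <- generate_timelines(50, 0, sets, seed = 68, decoy_fraction = 0)
  lab_non <- label_cohort(none_rel$posts, sets, min_posts = 3)
  expect_true(all(lab_non$relapse_status == "continued"))
})
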