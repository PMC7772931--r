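test_that("implied covariance has the one-factor closed form", {
  spec <- parse_model("F =~ x1 + x2 + x3")
  # free order: F=~x2, F=~x3, then variances x1,x2,x3,F
  theta <- theta_by_name(spec, c("F =~ x2" = 0.8, "F =~ x3" = 0.6,
                                 "x1 ~~ x1" = 0.5, "x2 ~~ x2" = 0.4,
                                 "x3 ~~ x3" = 0.3, "F ~~ F" = 2))
  Sigma <- implied_covariance(spec, theta)
  expect_equal(Sigma["x1", "x1"], 2 + 0.5)
  expect_equal(Sigma["x1", "x2"], 0.8 * 2)
  expect_equal(Sigma["x2", "x3"], 0.8 * 0.6 * 2)
  expect_true(isSymmetric(Sigma))

  # zero loadings: diagonal
  theta0 <- theta_by_name(spec, c("F =~ x2" = 0, "F =~ x3" = 0,
                                  "x1 ~~ x1" = 0.5, "x2 ~~ x2" = 0.4,
                                  "x3 ~~ x3" = 0.3, "F ~~ F" = 0))
  expect_equal(implied_covariance(spec, theta0),
               diag(c(0.5, 0.4, 0.3)), ignore_attr = TRUE)
})

test_that("implied covariance matches Monte-Carlo simulation of the equations", {
  spec <- parse_model("
    F =~ x1 + x2 + x3
    y ~ F
    z ~ y
  ")
  vals <- c("F =~ x2" = 0.8, "F =~ x3" = 0.6, "y ~ F" = 0.7, "z ~ y" = 0.5,
            "x1 ~~ x1" = 0.5, "x2 ~~ x2" = 0.4, "x3 ~~ x3" = 0.3,
            "y ~~ y" = 0.2, "z ~~ z" = 0.3, "F ~~ F" = 1)
  theta <- theta_by_name(spec, vals)
  Sigma <- implied_covariance(spec, theta)

  # independent simulation of the structural equations themselves
  set.seed(99)
  n <- 1e6
  F_ <- rnorm(n, 0, 1)
  x1 <- F_ + rnorm(n, 0, sqrt(0.5))
  x2 <- 0.8 * F_ + rnorm(n, 0, sqrt(0.4))
  x3 <- 0.6 * F_ + rnorm(n, 0, sqrt(0.3))
  y <- 0.7 * F_ + rnorm(n, 0, sqrt(0.2))
  z <- 0.5 * y + rnorm(n, 0, sqrt(0.3))
  emp <- cov(cbind(x1 = x1, x2 = x2, x3 = x3, y = y, z = z))
  expect_lt(max(abs(emp[spec$observed_vars, spec$observed_vars] - Sigma)), 0.01)
})

test_that("cyclic path structures are rejected", {
  spec <- parse_model("a ~ b\nb ~ a\na ~~ b")
  theta <- theta_by_name(spec, c("a ~ b" = 1, "b ~ a" = 1, "a ~~ b" = 0,
                                 "a ~~ a" = 1, "b ~~ b" = 1))
  expect_error(implied_covariance(spec, theta), "singular|cyclic")
})

test_that("the ML discrepancy matches direct evaluation and is nonnegative", {
  S <- matrix(c(2, 0.3, 0.3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(fml(S, S), 0)
  expect_equal(fml(matrix(2, 1, 1), matrix(1, 1, 1)), 1 - log(2))

  # independent direct evaluation via determinants and solve()
  direct <- function(S, Sig) {
    log(det(Sig)) + sum(diag(S %*% solve(Sig))) - log(det(S)) - nrow(S)
  }
  set.seed(21)
  for (i in 1:50) {
    p <- sample(2:6, 1)
    S1 <- random_pd(p); S2 <- random_pd(p)
    expect_equal(fml(S1, S2), direct(S1, S2), tolerance = 1e-10)
    expect_gte(fml(S1, S2), 0)
  }
  expect_error(fml(matrix(-1, 1, 1), matrix(1, 1, 1)), "S is not")
  expect_error(fml(matrix(1, 1, 1), matrix(-1, 1, 1)), "Sigma is not")
})

test_that("just-identified fits reproduce the sample covariance exactly", {
  spec <- parse_model("F =~ x1 + x2 + x3")
  set.seed(5)
  d <- simulate_from_spec(spec, default_true_parameters(spec), 300)
  fit <- fit_sem(d, spec)
  expect_true(fit$converged)
  expect_lt(fit$fml_min, 1e-8)
  S <- cov(d) * (nrow(d) - 1) / nrow(d)
  expect_lt(max(abs(fit$implied_cov - S[spec$observed_vars, spec$observed_vars])),
            1e-6)
  # closed-form covariance-ratio loadings
  lam2 <- S["x2", "x3"] / S["x1", "x3"]
  lam3 <- S["x2", "x3"] / S["x1", "x2"]
  expect_equal(unname(fit$theta_hat["F =~ x2"]), lam2, tolerance = 1e-4)
  expect_equal(unname(fit$theta_hat["F =~ x3"]), lam3, tolerance = 1e-4)
})

test_that("under-identified models are refused", {
  spec <- parse_model("a ~~ b\na ~ b")   # 2 vars: 3 moments, 4 free params
  set.seed(1)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_error(fit_sem(d, spec), "under-identified")
})

test_that("fitting is equivariant under variable permutation", {
  spec1 <- parse_model("F =~ x1 + x2 + x3 + x4")
  set.seed(8)
  d <- simulate_from_spec(spec1, default_true_parameters(spec1), 400)
  fit1 <- fit_sem(d, spec1)
  # same model, indicators listed in another order but same scale anchor
  spec2 <- parse_model("F =~ x1 + x4 + x3 + x2")
  fit2 <- fit_sem(d[, c("x4", "x2", "x1", "x3")], spec2)
  expect_equal(fit1$fml_min, fit2$fml_min, tolerance = 1e-8)
  v <- spec1$observed_vars
  expect_equal(fit2$implied_cov[v, v], fit1$implied_cov[v, v],
               tolerance = 1e-6)
})

test_that("parameters of a two-factor model are recovered from data", {
  spec <- parse_model("
    F1 =~ x1 + x2 + x3
    F2 =~ x4 + x5 + x6
    F1 ~~ F2
  ")
  theta <- default_true_parameters(spec)
  set.seed(12)
  d <- simulate_from_spec(spec, theta, 5000)
  fit <- fit_sem(d, spec)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta_hat - theta)), 0.08)  # ~3 Monte-Carlo SEs
})

test_that("standard errors behave: fixed rows carry none, p matches z", {
  spec <- parse_model("F =~ x1 + x2 + x3\nF ~~ F")
  set.seed(3)
  d <- simulate_from_spec(spec, default_true_parameters(spec), 800)
  fit <- fit_sem(d, spec)
  tab <- parameter_table(fit)
  fixed <- tab[tab$op == "=~" & tab$rhs == "x1", ]
  expect_true(is.na(fixed$se) && is.na(fixed$z) && is.na(fixed$p))
  free <- tab[!is.na(tab$se), ]
  expect_true(all(free$se > 0))
  expect_equal(free$p, 2 * pnorm(-abs(free$z)))
})

test_that("standardized solution is scale invariant and correlation valued", {
  spec <- parse_model("
    F1 =~ x1 + x2 + x3
    F2 =~ x4 + x5 + x6
    F1 ~~ F2
  ")
  set.seed(14)
  d <- simulate_from_spec(spec, default_true_parameters(spec), 1500)
  fit <- fit_sem(d, spec)
  std <- fit$standardized
  # standardized latent variances are 1
  expect_equal(unname(std["F1 ~~ F1"]), 1, tolerance = 1e-8)
  expect_equal(unname(std["F2 ~~ F2"]), 1, tolerance = 1e-8)
  # standardized covariance equals the implied correlation
  V <- fit$implied_full
  expect_equal(unname(std["F1 ~~ F2"]),
               V["F1", "F2"] / sqrt(V["F1", "F1"] * V["F2", "F2"]))
  # refitting on arbitrarily rescaled variables leaves it unchanged
  sc <- c(3, 0.02, 10, 1, 0.5, 7)
  d2 <- sweep(d, 2, sc, "*")
  fit2 <- fit_sem(as.data.frame(d2), spec)
  expect_equal(fit2$standardized, std, tolerance = 1e-6)
})

test_that("boundary variance estimates raise a Heywood-type warning", {
  spec <- parse_model("F =~ x1 + x2 + x3")
  # covariance whose closed-form solution needs a negative residual for x1:
  # psi = s12 s13 / s23 = 1.28 > s11 = 1
  v <- c("x1", "x2", "x3")
  S <- matrix(c(1, 0.8, 0.8,
                0.8, 1, 0.5,
                0.8, 0.5, 1), 3, dimnames = list(v, v))
  expect_warning(fit_sem(S, spec, N = 200, se = FALSE), "Heywood")
})
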