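test_that("variance percentages reproduce printed-table arithmetic", {
  # repertoire-size components as printed: percents recompute to the printed
  # values within the rounding the published table itself carries
  vp <- varpart(c(focal = 0, stimulus = 0.005, year = 37.9,
                  Residual = 215.9))
  expect_equal(vp$percent, c(0, 0.002, 14.93, 85.07), tolerance = 0.02)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)

  vp2 <- varpart(c(focal = 1.798, stimulus = 0.286, year = 0.005,
                   Residual = 1.492))
  expect_equal(vp2$percent, c(50.22, 8.00, 0.13, 41.66), tolerance = 0.02)
  expect_equal(sum(vp2$percent), 100, tolerance = 1e-9)
})

test_that("variance partition handles trivial and degenerate cases", {
  expect_equal(varpart(c(a = 0, Residual = 0.046))$percent, c(0, 100))
  expect_equal(varpart(c(a = 2, Residual = 2))$percent, c(50, 50))
  expect_error(varpart(c(a = 0, Residual = 0)), "zero")
  expect_error(varpart(c(a = -1, Residual = 2)), "negative")
  expect_output(print(varpart(c(a = 1, Residual = 3))), "25.00%")
})

test_that("varpart of a fit sums to 100 and matches the components", {
  dd <- design_87()
  tr <- simulate_traits(dd$design, dd$cfg, seed = 11)
  f <- vcmm(male_formula("trait"), tr)
  vp <- varpart(f)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
  expect_equal(vp$variance, unname(f$varcomp))
})

test_that("parametric bootstrap validates inputs and respects bounds", {
  set.seed(12)
  g <- factor(rep(1:10, each = 5))
  y <- rnorm(10, 0, 1)[g] + rnorm(50)
  f <- vcmm(y ~ 1 + (1 | g), data.frame(y, g))
  expect_error(vc_bootstrap(f, B = 0), "positive")

  # true group variance zero: the CI lower bound must be pinned at zero
  y0 <- rnorm(50)
  y0 <- y0 - ave(y0, g) + mean(y0)
  f0 <- vcmm(y ~ 1 + (1 | g), data.frame(y = y0, g))
  b0 <- vc_bootstrap(f0, B = 100, seed = 1)
  expect_equal(unname(b0$ci_variance[1, "g"]), 0)
  expect_output(print(b0), "Parametric bootstrap")
})

test_that("bootstrap is seed-deterministic and leaves the RNG alone", {
  set.seed(13)
  g <- factor(rep(1:8, each = 6))
  y <- rnorm(8, 0, 1)[g] + rnorm(48)
  f <- vcmm(y ~ 1 + (1 | g), data.frame(y, g))
  set.seed(99); before <- runif(1); set.seed(99)
  b1 <- vc_bootstrap(f, B = 50, seed = 2)
  expect_equal(runif(1), before)
  b2 <- vc_bootstrap(f, B = 50, seed = 2)
  expect_identical(b1$ci_variance, b2$ci_variance)
})

test_that("signed Cramer's V obeys its defining identities", {
  dd <- design_87()
  tr <- simulate_traits(dd$design, dd$cfg, seed = 14)
  f <- vcmm(male_formula("trait"), tr)
  e <- cramers_v(f, "date")
  expect_equal(abs(e$signed_V), sqrt(e$chi2 / (e$n_obs * e$df)))
  expect_equal(sign(e$signed_V), sign(coef(f)["date"]), ignore_attr = TRUE)
  expect_gte(e$chi2, 0)
  expect_true(e$df == 1 && e$signed)
  expect_output(print(e), "Cramer's V")
  expect_error(cramers_v(f, "not_a_term"), "term")
})

test_that("exactly orthogonal term gives chi2 = 0 and V = 0", {
  set.seed(15)
  n <- 100
  x <- rep(c(-1, 1), n / 2)
  e <- rnorm(n)
  # response constructed exactly orthogonal to x and the intercept
  y <- resid(lm(e ~ x))
  f <- vcmm(y ~ x, data.frame(y, x))
  eff <- cramers_v(f, "x")
  expect_equal(eff$chi2, 0, tolerance = 1e-10)
  expect_equal(eff$signed_V, 0, tolerance = 1e-6)
})

test_that("multi-level factor terms are reported unsigned", {
  set.seed(16)
  d <- data.frame(y = rnorm(90), w = factor(rep(1:3, 30)),
                  g = factor(rep(1:9, each = 10)))
  f <- vcmm(y ~ w + (1 | g), d)
  e <- cramers_v(f, "w")
  expect_equal(e$df, 2)
  expect_false(e$signed)
  expect_gte(e$V, 0)
})
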