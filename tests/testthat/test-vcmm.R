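test_that("vcmm matches the closed-form one-way ML oracle", {
  set.seed(1)
  g <- factor(rep(1:10, each = 5))
  for (sb in c(0, 0.2, 1, 4)) {
    y <- rnorm(10, 0, sqrt(sb))[g] + rnorm(50)
    f <- vcmm(y ~ 1 + (1 | g), data.frame(y = y, g = g))
    o <- one_way_ml(y, g, 5)
    expect_equal(unname(f$varcomp), unname(o), tolerance = 1e-6)
  }
})

test_that("vcmm agrees with lme4 ML on a nested three-factor design", {
  skip_if_not_installed("lme4")
  dd <- design_87()
  tr <- simulate_traits(dd$design, dd$cfg, seed = 42)
  f <- vcmm(male_formula("trait"), tr)
  lf <- lme4::lmer(trait ~ date + focal_age + elapsed_min +
                     (1 | focal_male_id) + (1 | stimulus_id:year) +
                     (1 | year), tr, REML = FALSE)
  expect_equal(as.numeric(logLik(f)), as.numeric(logLik(lf)),
               tolerance = 1e-6)
  expect_equal(unname(coef(f)), unname(lme4::fixef(lf)), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(f$varcomp[c("focal_male_id", "stimulus_id:year",
                                  "year", "Residual")]),
               vc$vcov[match(c("focal_male_id", "stimulus_id:year", "year",
                               "Residual"), vc$grp)],
               tolerance = 1e-3)
})

test_that("zero group structure gives a boundary-zero variance", {
  set.seed(3)
  d <- data.frame(y = rnorm(60), g = factor(rep(1:6, each = 10)))
  # remove all group structure exactly
  d$y <- d$y - ave(d$y, d$g) + mean(d$y)
  f <- vcmm(y ~ 1 + (1 | g), d)
  expect_equal(unname(f$varcomp["g"]), 0)
})

test_that("fitted log-likelihood beats random candidate parameters", {
  set.seed(4)
  g <- factor(rep(1:12, each = 4))
  h <- factor(rep(1:8, 6))
  y <- rnorm(12, 0, 1)[g] + rnorm(8, 0, 0.6)[h] + rnorm(48)
  f <- vcmm(y ~ 1 + (1 | g) + (1 | h), data.frame(y, g, h))
  cache <- songvar:::.vc_cache(f$pre)
  for (i in 1:25) {
    th <- runif(2, 0, 5)
    dev <- songvar:::.vc_devgrad_cpp(cache, th, f$y)$deviance
    expect_gte(dev, f$deviance - 1e-7)
  }
})

test_that("vcmm is deterministic and supports the standard methods", {
  dd <- design_87()
  tr <- simulate_traits(dd$design, dd$cfg, seed = 7)
  f1 <- vcmm(male_formula("trait"), tr)
  f2 <- vcmm(male_formula("trait"), tr)
  expect_identical(f1$varcomp, f2$varcomp)
  expect_identical(coef(f1), coef(f2))

  expect_s3_class(f1, "vcmm")
  expect_output(print(f1), "Variance components")
  expect_output(print(summary(f1)), "Fixed effects")
  expect_length(residuals(f1), f1$n)
  expect_equal(fitted(f1) + residuals(f1), f1$y, ignore_attr = TRUE)
  expect_named(ranef(f1), c("focal_male_id", "stimulus_id:year", "year"))

  p_full <- predict(f1)
  expect_equal(p_full, fitted(f1))
  p_fix <- predict(f1, newdata = tr, re.form = NA)
  expect_false(isTRUE(all.equal(p_full, p_fix)))

  s <- simulate(f1, nsim = 3, seed = 9)
  expect_equal(dim(s), c(f1$n, 3L))
  s2 <- simulate(f1, nsim = 3, seed = 9)
  expect_equal(s, s2)

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f1))
})

test_that("degenerate inputs are rejected", {
  set.seed(5)
  d <- data.frame(y = rnorm(20), x = rnorm(20),
                  g = factor(rep(1:4, each = 5)))
  d$x2 <- d$x
  expect_error(vcmm(y ~ x + x2 + (1 | g), d), "singular")
  d1 <- transform(d, g = factor(rep("a", 20)))
  expect_error(vcmm(y ~ x + (1 | g), d1), "levels")
})

test_that("missing data are dropped listwise with a count", {
  set.seed(6)
  d <- data.frame(y = rnorm(30), x = rnorm(30),
                  g = factor(rep(1:6, each = 5)))
  d$y[c(2, 9)] <- NA
  d$x[15] <- NA
  f <- vcmm(y ~ x + (1 | g), d)
  expect_equal(f$n, 27)
  expect_equal(f$na.dropped, 3)
})

test_that("VIF diagnostics give closed-form answers", {
  set.seed(8)
  n <- 400
  # exact pairwise correlation 0.6 between two predictors
  a <- rnorm(n); b <- rnorm(n)
  a <- (a - mean(a)) / sd(a)
  b <- resid(lm(b ~ a)); b <- (b - mean(b)) / sd(b)
  x1 <- a
  x2 <- 0.6 * a + sqrt(1 - 0.36) * b
  y <- rnorm(n)
  v <- vif_fixed(y ~ x1 + x2, data.frame(y, x1, x2))
  expect_equal(unname(v), c(1.5625, 1.5625), tolerance = 1e-8)

  # orthogonal predictors -> VIF 1
  v1 <- vif_fixed(y ~ a + b, data.frame(y, a, b))
  expect_equal(unname(v1), c(1, 1), tolerance = 1e-8)

  # duplicated predictor -> error
  expect_error(vif_fixed(y ~ x1 + x1b,
                         data.frame(y, x1, x1b = x1)),
               "collinear")
})
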