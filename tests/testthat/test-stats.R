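test_that("pearson_r matches the hand-expanded covariance formula", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # r = cov(x,y) / (sd x sd y), expanded by hand
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_r(x, y)
  expect_equal(got$r, r_hand)

  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_error(pearson_r(c(1, 1, 1), 1:3), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")

  # affine invariance (sign-preserving)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_r(a, b)$r, pearson_r(3 * a + 5, 0.5 * b - 2)$r)
})

test_that("the sigmoid fit recovers exact parameters and beats a grid oracle", {
  x <- seq(0, 3, length.out = 40)
  y <- sigmoid(x, 58.0, 7.7, 1.2, 3.7)
  f <- fit_sigmoid(x, y)
  expect_equal(c(f$a, f$b, f$c, f$d), c(58.0, 7.7, 1.2, 3.7),
               tolerance = 1e-3)
  expect_gte(f$r2, 1 - 1e-9)

  # stored r2 equals 1 - SSE/SST recomputed from the fitted values
  yn <- y + c(0.5, -0.5)
  fn <- fit_sigmoid(x, yn)
  r2_re <- 1 - sum((yn - fn$fitted)^2) / sum((yn - mean(yn))^2)
  expect_equal(fn$r2, r2_re, tolerance = 1e-9)

  # x-shift invariance with compensating midpoint shift
  fs <- fit_sigmoid(x + 10, yn)
  expect_equal(fs$c, fn$c + 10, tolerance = 1e-4)
  expect_equal(fs$r2, fn$r2, tolerance = 1e-6)

  # multi-start SSE is no worse than a coarse 4-D grid search
  for (s in 1:5) {
    set.seed(600 + s)
    pars <- c(a = runif(1, 20, 80), b = runif(1, 2, 12),
              c = runif(1, 0.5, 2), d = runif(1, 0, 10))
    xs <- sort(runif(25, 0, 3))
    ys <- sigmoid(xs, pars["a"], pars["b"], pars["c"], pars["d"]) + rnorm(25, 0, 2)
    fit <- fit_sigmoid(xs, ys)
    grid <- expand.grid(a = seq(10, 90, 20), b = seq(1, 13, 3),
                        c = seq(0.4, 2.2, 0.3), d = seq(-5, 15, 5))
    g_sse <- min(apply(grid, 1, function(p)
      sum((ys - sigmoid(xs, p[1], p[2], p[3], p[4]))^2)))
    expect_lte(fit$sse, g_sse + 1e-9)
  }
})

test_that("the normality gate routes to t or Mann-Whitney correctly", {
  set.seed(11)
  a <- rnorm(50); b <- rnorm(50, 1)
  r <- two_sample(a, b)
  expect_identical(r$method, "t")
  expect_lt(r$p, 1e-4)

  same <- rnorm(30)
  r2 <- two_sample(same, same)
  expect_gte(r2$p, 0.99)

  ex1 <- rexp(60); ex2 <- rexp(60)
  r3 <- two_sample(ex1, ex2)
  expect_identical(r3$method, "mann-whitney")

  # constant sample: gate inapplicable, falls back to Mann-Whitney with warning
  expect_warning(r4 <- two_sample(rep(1, 10), rnorm(10)), "non-normal")
  expect_identical(r4$method, "mann-whitney")
})

test_that("one-sample t matches its closed form", {
  r0 <- one_sample_t(c(1, 2, 3), mu = 2)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r1 <- one_sample_t(c(1, 2, 3), mu = 0)
  expect_equal(r1$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r1$p, 2 * pt(-r1$statistic, df = 2), tolerance = 1e-9)
  expect_error(one_sample_t(rep(2, 5), 0), "constant")
})

test_that("multi-group comparison flags only genuinely shifted groups", {
  set.seed(21)
  g <- list(rnorm(30), rnorm(30), rnorm(30, 0.9))
  r <- multi_group(g)
  expect_lt(r$p, 0.05)
  expect_false(is.null(r$posthoc))
  sig <- r$posthoc$pair[r$posthoc$significant]
  expect_true(all(grepl("3", sig)))  # only pairs involving the shifted group

  ident <- list(rnorm(25), rnorm(25), rnorm(25))
  r2 <- multi_group(ident)
  if (!is.null(r2$posthoc)) expect_false(any(r2$posthoc$significant))

  expect_error(multi_group(list(rnorm(5), rnorm(5))), "at least 3")
  expect_error(multi_group(list(rnorm(5), rnorm(5), 1)), "n >= 2")

  # non-normal groups go through Kruskal-Wallis
  set.seed(22)
  skewed <- list(rexp(40), rexp(40), rexp(40, 0.4))
  r3 <- multi_group(skewed)
  expect_identical(r3$method, "kruskal-wallis")
})

test_that("lilliefors requires n >= 4 and separates normal from uniform", {
  expect_error(lilliefors(c(1, 2, 3)), "n >= 5")
  set.seed(31)
  rej_norm <- mean(replicate(200, lilliefors(rnorm(100))$p < 0.05))
  rej_unif <- mean(replicate(200, lilliefors(runif(200))$p < 0.05))
  expect_lt(rej_norm, 0.12)
  expect_gt(rej_unif, 0.8)
})
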