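test_that("subset enumeration finds the planted perturbed column", {
  set.seed(71)
  W <- matrix(0, 10, 4)
  W[cbind(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1:4, each = 2))] <- runif(8, 0.5, 1)
  # target data generated with column 3 replaced by a differently balanced module
  Wt <- W
  Wt[, 3] <- 0
  Wt[c(5, 6, 9, 10), 3] <- runif(4, 0.5, 1)
  C <- matrix(rgamma(4 * 80, 2), 4, 80)
  D <- Wt %*% C
  res <- enumerate_update_subsets(W, 1, D, config = engine_config(n_reps = 3),
                                  seed = 2)
  expect_identical(res$subset, 3L)

  # n_up = 0 is a single fixed fit with the empty subset
  res0 <- enumerate_update_subsets(W, 0, D, config = engine_config(), seed = 2)
  expect_identical(res0$subset, integer(0))
  expect_length(res0$r2_by_subset, 1)

  # full update nests every smaller subset
  resN <- enumerate_update_subsets(W, 4, D, config = engine_config(n_reps = 3),
                                   seed = 2)
  # slack reflects the solver's convergence resolution, not the exact optima
  expect_gte(resN$fit$r2, res$fit$r2 - 1e-4)
  expect_error(enumerate_update_subsets(W, 5, D), "exceeds")
})

test_that("baselines are tight for a shared generator and monotone in n_up", {
  cs <- make_control_sets(n_ctrl = 4, n_syn = 3, seed = 81, jitter = 0.001)
  b0 <- baseline_r2(cs$sets, 0, engine_config(), seed = 3)
  expect_true(all(is.na(diag(b0$r2))))
  expect_equal(length(b0$values), 12)
  # all subjects share (almost) one generating synergy set: off-diagonal
  # fits agree closely
  expect_lt(diff(range(b0$values)), 0.05)

  b2 <- baseline_r2(cs$sets, 2, engine_config(n_reps = 2), seed = 3)
  expect_true(all(b2$values >= b0$values - 1e-6))

  expect_error(baseline_r2(cs$sets[1], 0), "at least 2")
})

test_that("the similarity criterion is two-sided with a superiority override", {
  set.seed(91)
  base <- rnorm(20, 0.75, 0.05)
  r_same <- criterion_met(base, base)
  expect_true(r_same$met)
  expect_gte(r_same$p, 0.99)

  worse <- base - 0.3
  r_worse <- criterion_met(worse, base)
  expect_false(r_worse$met)
  expect_lt(r_worse$p, 0.05)
  # closed-form equal-variance t as the oracle when both samples are normal
  if (r_worse$test_name == "t") {
    n <- 20
    sp <- sqrt(((n - 1) * var(worse) + (n - 1) * var(base)) / (2 * n - 2))
    t_hand <- (mean(worse) - mean(base)) / (sp * sqrt(2 / n))
    expect_equal(r_worse$p, 2 * pt(-abs(t_hand), 2 * n - 2), tolerance = 1e-9)
  }

  better <- base + 0.2
  r_better <- criterion_met(better, base)
  expect_true(r_better$met)  # superiority passes regardless of p
  expect_error(criterion_met(numeric(0), base), "nonempty")
})

test_that("mean fixed-basis fit behaves like an arithmetic mean of fits", {
  cs <- make_control_sets(n_ctrl = 3, n_syn = 3, seed = 101)
  target <- cs$sets[[1]]$D
  m1 <- mean_fit_r2(cs$sets[1], target)
  expect_equal(m1$mean_r2, m1$r2s[1])
  m3 <- mean_fit_r2(cs$sets, target)
  expect_equal(m3$mean_r2, mean(m3$r2s))
  # the generating subject's own basis dominates
  expect_equal(which.max(m3$r2s), 1L)
  # appending a control with a worse fit cannot raise the mean
  expect_lte(mean_fit_r2(cs$sets, target)$mean_r2,
             max(m3$r2s) + 1e-12)
})

test_that("the search returns (0,0) for a self-consistent target and follows the trail order", {
  cs <- make_control_sets(n_ctrl = 5, n_syn = 3, seed = 111)
  eng <- engine_config(n_reps = 3)
  baselines <- lapply(0:3, function(nu) baseline_r2(cs$sets, nu, eng, seed = 5))
  sr <- search_nup_nadd(cs$sets, cs$sets[[2]]$D, baselines, max_up = 3,
                        config = eng, seed = 6)
  expect_equal(sr$n_up_star, 0)
  expect_equal(sr$n_add_star, 0)
  # trail covers every visited pair in search order; only the last is met
  expect_identical(sr$trail$met, c(rep(FALSE, nrow(sr$trail) - 1), TRUE))
  expect_true(all(diff(sr$trail$n_add) >= 0))

  # a pure-noise target is never accepted at (0,0)
  set.seed(7)
  Dn <- matrix(abs(rnorm(14 * 120)), 14, 120)
  sr_noise <- tryCatch(
    search_nup_nadd(cs$sets, Dn, baselines, max_up = 3, max_add = 2,
                    config = eng, seed = 8),
    error = function(e) e)
  if (inherits(sr_noise, "error")) {
    expect_match(conditionMessage(sr_noise), "never met")
  } else {
    expect_gt(sr_noise$n_add_star + sr_noise$n_up_star, 0)
  }
})
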