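test_that("segment span counts segments with components strictly above 0.1", {
  reg <- muscle_registry()
  w <- setNames(numeric(14), reg$names)
  w["TA"] <- 1
  p <- segment_span(w, reg)
  expect_identical(p$active_muscles, "TA")
  expect_identical(p$segments_hit, "crus")
  expect_equal(p$span, 1)

  # uniform vector: every component 1/sqrt(14) > 0.1, all three segments
  u <- setNames(rep(1, 14), reg$names)
  expect_equal(segment_span(u, reg)$span, 3)

  # component at exactly 0.1 after normalization is excluded (strict rule)
  w2 <- setNames(numeric(14), reg$names)
  w2["VL"] <- 0.8; w2["ES"] <- sqrt(1 - 0.64 - 0.01); w2["TA"] <- 0.1
  expect_equal(sqrt(sum(w2^2)), 1, tolerance = 1e-12)
  p2 <- segment_span(w2, reg)
  expect_false("TA" %in% p2$active_muscles)
  expect_equal(p2$span, 2)

  # span is invariant to scaling of the synergy
  expect_equal(segment_span(17 * w2, reg)$span, p2$span)
  expect_error(segment_span(numeric(14), reg), "zero")
})

test_that("span distributions sum to 100 and reflect planted composition", {
  reg <- muscle_registry()
  one <- lapply(sample(reg$names, 10, replace = TRUE), function(m) {
    w <- setNames(numeric(14), reg$names); w[m] <- 1; w
  })
  d1 <- span_distribution(one, reg)
  expect_equal(unname(d1$by_span), c(100, 0, 0))
  expect_equal(sum(d1$by_span), 100, tolerance = 1e-9)
  expect_equal(sum(d1$by_combo), 100, tolerance = 1e-9)

  three <- replicate(5, setNames(rep(1, 14), reg$names), simplify = FALSE)
  d2 <- span_distribution(c(one[1:5], three), reg)
  expect_equal(unname(d2$by_span), c(50, 0, 50))
})

test_that("pre/post synergy comparison flags only the shifted muscle", {
  reg <- muscle_registry()
  set.seed(13)
  base <- abs(rnorm(14, 0.3, 0.05))
  pre <- sapply(1:20, function(i) {
    v <- pmax(0.01, base + rnorm(14, 0, 0.02)); v / sqrt(sum(v^2))
  })
  rownames(pre) <- reg$names
  post <- pre
  post[reg$names == "ES", ] <- post[reg$names == "ES", ] + 0.3
  cmp <- compare_pre_post(pre, post)
  expect_true(cmp$flag[cmp$muscle == "ES"])
  expect_equal(sum(cmp$flag), 1)

  same <- compare_pre_post(pre, pre)
  expect_false(any(same$flag))

  expect_warning(small <- compare_pre_post(pre[, 1:2], post[, 1:2]),
                 "fewer than 3")
  expect_true(all(is.na(small$p)))
})

test_that("residual profiles recover planted attenuation on envelopes", {
  cfg <- sim_config(n_subjects = 3, n_synergies = 4, cycles = 8,
                    synth_raw = FALSE, seed = 61)
  coh <- make_cohort(cfg)
  ctrl_envs <- lapply(coh$subjects, function(s)
    list(unnormalized_envelope = s$truth$envelope))

  # a subject identical to the control average has fractions at the ceiling
  p0 <- residual_profile(ctrl_envs[[1]], ctrl_envs[1])
  expect_equal(unname(p0$residual_fraction), rep(1, 14))
  expect_equal(p0$unevenness, 0)

  # planted attenuation is recovered
  set.seed(62)
  atten <- runif(14, 0.2, 1)
  att_env <- sweep(coh$subjects[[1]]$truth$envelope, 2, atten, "*")
  p1 <- residual_profile(list(unnormalized_envelope = att_env), ctrl_envs)
  expect_gte(cor(atten, unname(p1$residual_fraction)), 0.9)

  # balanced 0/1 fractions give the maximal variance 0.25
  half <- coh$subjects[[1]]$truth$envelope
  half[, 8:14] <- 0
  suppressWarnings(p2 <- residual_profile(list(unnormalized_envelope = half),
                                          ctrl_envs[1]))
  expect_equal(p2$unevenness, 0.25, tolerance = 1e-9)
})

test_that("the unevenness filter excludes strictly below 0.04", {
  mk <- function(v) structure(list(unevenness = v),
                              class = "ResidualAmplitudeProfile")
  profs <- lapply(c(0.039, 0.04, 0.041, 0.0, 0.25), mk)
  kept <- unevenness_filter(profs)
  expect_identical(unname(attr(kept, "kept")), c(FALSE, TRUE, TRUE, FALSE, TRUE))
  # brute-force equivalence
  expect_identical(attr(kept, "kept"),
                   vapply(profs, function(p) p$unevenness >= 0.04, logical(1)))
})
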