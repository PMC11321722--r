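test_that("reconstruction R2 uses the mean-subtracted SST", {
  # hand-worked case: SSE = (1-2)^2 + (3-2)^2 = 2, SST = same = 2, R2 = 0
  D <- rbind(c(1, 3), c(2, 2))
  W <- diag(2)
  C <- rbind(c(2, 2), c(2, 2))
  expect_equal(reconstruction_r2(D, W, C), 0)

  # exact reconstruction and the mean predictor
  p <- random_nmf_problem(6, 3, 20, seed = 2)
  expect_equal(reconstruction_r2(p$W %*% p$C, p$W, p$C), 1)
  Dm <- p$D
  Cm <- matrix(1, 1, ncol(Dm))
  Wm <- matrix(rowMeans(Dm), ncol = 1)
  expect_equal(reconstruction_r2(Dm, Wm, Cm), 0, tolerance = 1e-12)

  expect_error(reconstruction_r2(matrix(1, 3, 4), matrix(1, 3, 1),
                                 matrix(1, 1, 4)), "SST")
})

test_that("multiplicative updates honour the partition and never increase the objective", {
  p <- random_nmf_problem(10, 4, 50, seed = 7)
  set.seed(8)
  W <- matrix(runif(10 * 4), 10, 4)
  C <- matrix(runif(4 * 50), 4, 50)

  # all columns frozen: W bit-identical, only C moves
  part_frozen <- partition_spec(4)
  st <- nmf_iterate(p$D, W, C, part_frozen)
  expect_identical(st$W, W)
  expect_false(identical(st$C, C))

  # full update: objective monotone non-increasing over 200 iterations
  err <- sum((p$D - W %*% C)^2)
  Wk <- W; Ck <- C
  for (i in 1:200) {
    st <- nmf_iterate(p$D, Wk, Ck, NULL)
    Wk <- st$W; Ck <- st$C
    e2 <- sum((p$D - Wk %*% Ck)^2)
    expect_lte(e2, err * (1 + 1e-10))
    err <- e2
  }

  # partial partition: untouched columns bit-identical after 100 iterations
  part <- partition_spec(3, up_indices = 2)
  set.seed(9)
  W3 <- matrix(runif(10 * 3), 10, 3)
  C3 <- matrix(runif(3 * 50), 3, 50)
  Wk <- W3; Ck <- C3
  for (i in 1:100) {
    st <- nmf_iterate(p$D, Wk, Ck, part)
    Wk <- st$W; Ck <- st$C
  }
  expect_identical(Wk[, c(1, 3)], W3[, c(1, 3)])
  expect_false(identical(Wk[, 2], W3[, 2]))
  expect_true(all(Wk >= 0) && all(Ck >= 0))
})

test_that("extraction recovers planted modules and is seed-deterministic", {
  set.seed(21)
  W <- matrix(0, 8, 3)
  W[cbind(c(1, 2, 4, 5, 7, 8), c(1, 1, 2, 2, 3, 3))] <- runif(6, 0.5, 1)
  C <- matrix(rgamma(3 * 60, 2), 3, 60)
  D <- W %*% C
  f <- extract_synergies(D, 3, engine_config(n_reps = 5), seed = 3)
  expect_gte(f$r2, 0.999)
  m <- match_centroids(W, f$W, threshold = -1)
  expect_gte(min(m$pairs$sp), 0.98)

  # columns are l2-normalized with scale absorbed into C: R2 unchanged
  expect_equal(unname(apply(f$W, 2, function(v) sqrt(sum(v^2)))), rep(1, 3))
  expect_equal(reconstruction_r2(D, f$W, f$C), f$r2, tolerance = 1e-9)

  # rank-1 data at n = 1
  D1 <- W[, 1, drop = FALSE] %*% C[1, , drop = FALSE]
  expect_gte(extract_synergies(D1, 1, engine_config(n_reps = 3), seed = 1)$r2,
             0.999)

  # determinism under a fixed seed
  f2 <- extract_synergies(D, 3, engine_config(n_reps = 5), seed = 3)
  expect_identical(f$W, f2$W)
  expect_identical(f$r2, f2$r2)
})

test_that("the dimensionality rule picks the R2 closest to target, ties to smaller n", {
  # noiseless rank-1 data: R2 = 1 for every n, so the tie-break selects n = 1
  set.seed(31)
  D1 <- matrix(runif(6), 6, 1) %*% matrix(rgamma(40, 2), 1, 40)
  sel1 <- select_dimensionality(D1, engine_config(n_reps = 3), seed = 2,
                                n_range = 1:4)
  expect_equal(sel1$selected_n, 1)

  # selection equals brute-force argmin over the reported R2 map, and the
  # map is non-decreasing (restart tolerance 0.01)
  for (s in 1:10) {
    p <- random_nmf_problem(5, 3, 30, seed = 100 + s)
    sel <- select_dimensionality(p$D, engine_config(n_reps = 3), seed = s,
                                 n_range = 1:5)
    dist <- abs(sel$r2_by_n - 0.80)
    expect_equal(sel$selected_n, as.integer(names(which.min(dist))))
    expect_true(all(diff(sel$r2_by_n) > -0.01))
  }
})

test_that("basis fitting matches free extraction on its own data and flags bad bases", {
  set.seed(41)
  W <- matrix(0, 8, 3)
  W[cbind(c(1, 2, 4, 5, 7, 8), c(1, 1, 2, 2, 3, 3))] <- runif(6, 0.5, 1)
  C <- matrix(rgamma(3 * 80, 2), 3, 80)
  D <- W %*% C + matrix(runif(8 * 80, 0, 0.08), 8, 80)

  free <- extract_synergies(D, 3, engine_config(n_reps = 5), seed = 5)
  fixed <- fit_basis(D, W, partition_spec(3), engine_config(), seed = 6)
  expect_identical(fixed$W[, 1:3], W)  # freeze contract
  expect_gte(fixed$r2, free$r2 - 0.01)

  # a basis with disjoint support fits strictly worse
  Wbad <- W[c(4:8, 1:3), ]
  bad <- fit_basis(D, Wbad, partition_spec(3), engine_config(), seed = 6)
  expect_lt(bad$r2, fixed$r2)
})

test_that("an appended column recovers a planted extra module", {
  set.seed(51)
  W <- matrix(0, 10, 4)
  W[cbind(c(1, 2, 3, 4, 5, 6, 7, 8), rep(1:4, each = 2))] <- runif(8, 0.5, 1)
  C <- matrix(rgamma(4 * 100, 2), 4, 100)
  D <- W %*% C
  basis <- W[, 1:3]
  part <- partition_spec(3, n_add = 1)
  fit <- fit_basis(D, basis, part, engine_config(n_reps = 5), seed = 7)
  full <- extract_synergies(D, 4, engine_config(n_reps = 5), seed = 8)
  expect_gte(fit$r2, full$r2 - 0.02)
  expect_gte(scalar_product(fit$W[, 4], W[, 4]), 0.9)
  expect_identical(fit$W[, 1:3], basis)
})
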