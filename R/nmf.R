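#' Engine configuration for NMF extraction and fitting
#'
#' @param n_reps number of random restarts per extraction (best repetition
#'   kept).
#' @param max_iter iteration cap per run.
#' @param tol convergence tolerance: relative change in Frobenius
#'   reconstruction error below `tol` for `tol_streak` consecutive iterations
#'   stops the run.
#' @param tol_streak consecutive-iteration requirement for convergence.
#' @param r2_target dimensionality selection target (fraction of variance).
#' @param eps epsilon guard in multiplicative-update denominators.
#' @param rep_fixed_basis if `TRUE`, fixed-basis fits (no updated, no added
#'   columns) are also repeated `n_reps` times over coefficient
#'   initializations; by default a single run is used, since the coefficient
#'   subproblem behaves convex-like in practice.
#' @return list of class `engine_config`.
#' @export
engine_config <- function(n_reps = 20L, max_iter = 1000L, tol = 1e-6,
                          tol_streak = 10L, r2_target = 0.80, eps = 1e-12,
                          rep_fixed_basis = FALSE) {
  structure(list(n_reps = as.integer(n_reps), max_iter = as.integer(max_iter),
                 tol = tol, tol_streak = as.integer(tol_streak),
                 r2_target = r2_target, eps = eps,
                 rep_fixed_basis = isTRUE(rep_fixed_basis)),
            class = "engine_config")
}

#' EMG reconstruction R-squared with mean-subtracted SST
#'
#' `R2 = 1 - SSE/SST` where the sum of squares total is taken around each
#' muscle's own mean: `SST = sum over muscles, bins of (d - mean_muscle)^2`.
#' This differs from variance-accounted-for definitions that omit the mean
#' subtraction. The value can be negative for fits worse than the per-muscle
#' mean predictor; it is returned unclamped.
#'
#' @param D data matrix, muscles x bins (the transposed preprocessed
#'   envelope).
#' @param W synergy matrix, muscles x N.
#' @param C coefficient matrix, N x bins.
#' @return scalar R-squared (at most 1, possibly negative).
#' @export
reconstruction_r2 <- function(D, W, C) {
  stopifnot(nrow(W) == nrow(D), ncol(W) == nrow(C), ncol(C) == ncol(D))
  sst <- sum((D - rowMeans(D))^2)
  if (sst == 0) stop("SST is zero (constant data); R2 undefined")
  1 - sum((D - W %*% C)^2) / sst
}

#' Partition specification for a partitioned NMF fit
#'
#' Describes which columns of a supplied basis are frozen, which are updated
#' in place, and how many fresh columns are appended and extracted from the
#' data.
#'
#' @param n_basis number of columns in the supplied basis.
#' @param up_indices integer indices (within the basis) of columns to update.
#' @param n_add number of freshly initialized additional columns.
#' @return list of class `partition_spec` with `n_fixed`, `up_indices`,
#'   `n_add`.
#' @export
partition_spec <- function(n_basis, up_indices = integer(0), n_add = 0L) {
  up_indices <- as.integer(sort(unique(up_indices)))
  if (length(up_indices) && (min(up_indices) < 1 || max(up_indices) > n_basis))
    stop("up_indices out of range")
  if (n_add < 0) stop("n_add must be nonnegative")
  structure(list(n_fixed = n_basis - length(up_indices),
                 up_indices = up_indices, n_add = as.integer(n_add),
                 n_basis = as.integer(n_basis)),
            class = "partition_spec")
}

#' One multiplicative NMF update under a column partition
#'
#' Performs a single Lee-Seung multiplicative update of `C` (all rows) and of
#' the columns of `W` designated updatable (`up_indices` of the basis plus
#' all appended columns); frozen columns are left bit-identical. Denominators
#' are guarded by `eps`. Each half-update is non-increasing in Frobenius
#' reconstruction error.
#'
#' @inheritParams reconstruction_r2
#' @param partition a [partition_spec()]; `NULL` means update everything.
#' @param eps denominator guard.
#' @return list `(W, C)`.
#' @export
nmf_iterate <- function(D, W, C, partition = NULL, eps = 1e-12) {
  upd <- partition_update_cols(partition, ncol(W))
  C <- C * crossprod(W, D) / (crossprod(W) %*% C + eps)
  if (length(upd)) {
    num <- D %*% t(C)
    den <- W %*% tcrossprod(C)
    W[, upd] <- W[, upd] * num[, upd, drop = FALSE] /
      (den[, upd, drop = FALSE] + eps)
  }
  if (anyNA(W) || anyNA(C)) stop("NaN encountered in NMF update")
  list(W = W, C = C)
}

partition_update_cols <- function(partition, n_cols) {
  if (is.null(partition)) return(seq_len(n_cols))
  c(partition$up_indices,
    if (partition$n_add > 0) partition$n_basis + seq_len(partition$n_add))
}

# Core iteration loop. Returns W, C, iterations, converged, final error.
# The Frobenius error is tracked through the Gram identity
#   ||D - WC||^2 = ||D||^2 - 2<W, D C'> + <W'W, C C'>
# so no explicit reconstruction matrix is formed; fixed-basis fits (no
# updatable columns) precompute W'D and W'W once.
nmf_run <- function(D, W, C, partition = NULL, config = engine_config()) {
  upd <- partition_update_cols(partition, ncol(W))
  eps <- config$eps
  sumD2 <- sum(D^2)
  fixed_basis <- length(upd) == 0L
  if (fixed_basis) {
    WtD <- crossprod(W, D)
    WtW <- crossprod(W)
  }
  prev_err <- sqrt(sum((D - W %*% C)^2))
  streak <- 0L
  it <- 0L
  converged <- FALSE
  while (it < config$max_iter) {
    it <- it + 1L
    if (fixed_basis) {
      C <- C * WtD / (WtW %*% C + eps)
      err2 <- sumD2 - 2 * sum(WtD * C) + sum(WtW * tcrossprod(C))
    } else {
      C <- C * crossprod(W, D) / (crossprod(W) %*% C + eps)
      CtC <- tcrossprod(C)
      num <- tcrossprod(D, C)
      den <- W %*% CtC
      W[, upd] <- W[, upd] * num[, upd, drop = FALSE] /
        (den[, upd, drop = FALSE] + eps)
      err2 <- sumD2 - 2 * sum(W * num) + sum(crossprod(W) * CtC)
    }
    err <- sqrt(max(err2, 0))
    rel <- if (prev_err > 0) abs(prev_err - err) / prev_err else 0
    streak <- if (rel < config$tol) streak + 1L else 0L
    prev_err <- err
    if (streak >= config$tol_streak) { converged <- TRUE; break }
  }
  if (anyNA(W) || anyNA(C)) stop("NaN encountered in NMF run")
  list(W = W, C = C, iterations = it, converged = converged, err = prev_err)
}

# l2-normalize the freely extracted columns of W, absorbing the inverse scale
# into C; reconstruction W %*% C is unchanged. Frozen columns are left alone.
normalize_columns <- function(W, C, cols = seq_len(ncol(W))) {
  for (j in cols) {
    s <- sqrt(sum(W[, j]^2))
    if (s > 0) {
      W[, j] <- W[, j] / s
      C[j, ] <- C[j, ] * s
    }
  }
  list(W = W, C = C)
}

#' Extract muscle synergies by NMF with random restarts
#'
#' Factorizes the data matrix into `n` nonnegative synergies and
#' coefficients by multiplicative updates. Extraction is repeated
#' `config$n_reps` times from random initializations uniform on
#' `(0, max(D)]`, and the repetition with the highest reconstruction
#' R-squared (the best repetition) is returned. Synergy columns are
#' l2-normalized at convergence with the scale absorbed into `C`.
#'
#' @param D muscles x bins data matrix (transposed normalized envelope).
#' @param n number of synergies, between 1 and the muscle count.
#' @param config an [engine_config()].
#' @param seed integer seed; the per-repetition seed stream is recorded in
#'   the result.
#' @return A `FitResult`: list with `r2`, `W` (muscles x n), `C` (n x bins),
#'   `iterations`, `converged`, `rep_seeds`, `partition = NULL`.
#' @export
extract_synergies <- function(D, n, config = engine_config(), seed = 1L) {
  if (n < 1 || n > nrow(D)) stop("n must be between 1 and the muscle count")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  best <- NULL
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    mx <- max(D)
    W0 <- matrix(stats::runif(nrow(D) * n, 0, mx), nrow(D), n)
    C0 <- matrix(stats::runif(n * ncol(D), 0, mx), n, ncol(D))
    run <- nmf_run(D, W0, C0, NULL, config)
    r2 <- reconstruction_r2(D, run$W, run$C)
    if (is.null(best) || r2 > best$r2)
      best <- list(r2 = r2, W = run$W, C = run$C, iterations = run$iterations,
                   converged = run$converged)
  }
  nc <- normalize_columns(best$W, best$C)
  structure(list(r2 = best$r2, W = nc$W, C = nc$C,
                 iterations = best$iterations, converged = best$converged,
                 rep_seeds = rep_seeds, partition = NULL),
            class = "FitResult")
}

#' Select synergy dimensionality by the 80-percent-R2 rule
#'
#' Evaluates the best-of-repetitions reconstruction R-squared for each
#' candidate number of synergies and selects the one whose R-squared is
#' closest to the target (default 0.80); ties are broken toward the smaller
#' dimensionality.
#'
#' @inheritParams extract_synergies
#' @param n_range candidate dimensionalities (default 1 to muscle count).
#' @return An `ExtractionResult`: list with `selected_n`, `r2_by_n` (named
#'   numeric), `fits` (per-n `FitResult`), `target`.
#' @export
select_dimensionality <- function(D, config = engine_config(), seed = 1L,
                                  n_range = seq_len(nrow(D))) {
  set.seed(seed)
  n_seeds <- sample.int(.Machine$integer.max - 1L, length(n_range))
  fits <- vector("list", length(n_range))
  r2 <- numeric(length(n_range))
  for (i in seq_along(n_range)) {
    fits[[i]] <- extract_synergies(D, n_range[i], config, n_seeds[i])
    r2[i] <- fits[[i]]$r2
  }
  names(r2) <- n_range
  dist <- abs(r2 - config$r2_target)
  # distances within numerical fuzz of the minimum are ties, broken toward
  # the smaller dimensionality
  sel <- n_range[which(dist <= min(dist) + 1e-9)[1]]
  structure(list(selected_n = sel, r2_by_n = r2, fits = fits,
                 target = config$r2_target, n_range = n_range),
            class = "ExtractionResult")
}

#' Fit a synergy basis to data with a column partition
#'
#' Fits a supplied synergy basis to a data matrix by partitioned NMF: frozen
#' columns stay bit-identical to the input, updated columns start at their
#' original values and follow the multiplicative update, and `n_add`
#' appended columns are initialized uniformly on `(0, max(D)]` and extracted
#' freely. When columns are appended, the fit is repeated `config$n_reps`
#' times over their initializations and the best R-squared run is returned;
#' purely fixed/updated fits run once unless `config$rep_fixed_basis`.
#'
#' @param D muscles x bins data matrix.
#' @param W_basis muscles x N nonnegative basis.
#' @param partition a [partition_spec()] for `W_basis` (default: all frozen,
#'   nothing added).
#' @param config an [engine_config()].
#' @param seed integer seed.
#' @return A `FitResult` with `W` of `N + n_add` columns, `r2`, `C`,
#'   `partition`, `iterations`, `converged`.
#' @export
fit_basis <- function(D, W_basis, partition = partition_spec(ncol(W_basis)),
                      config = engine_config(), seed = 1L) {
  if (nrow(W_basis) != nrow(D)) stop("basis rows must match muscle count")
  if (partition$n_basis != ncol(W_basis))
    stop("partition does not match basis column count")
  if (any(W_basis < 0)) stop("basis must be nonnegative")
  mx <- max(D)
  n_add <- partition$n_add
  # multiplicative updates cannot move an entry off an exact zero, so
  # updatable columns are floored at a small fraction of their maximum
  # before iteration begins; frozen columns are left untouched
  W_init <- W_basis
  for (j in partition$up_indices)
    W_init[, j] <- pmax(W_init[, j], 0.01 * max(W_init[, j]))
  reps <- if (n_add > 0 || config$rep_fixed_basis) config$n_reps else 1L
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  best <- NULL
  for (r in seq_len(reps)) {
    set.seed(rep_seeds[r])
    W0 <- cbind(W_init,
                if (n_add > 0)
                  matrix(stats::runif(nrow(D) * n_add, 0, mx), nrow(D), n_add))
    C0 <- matrix(stats::runif(ncol(W0) * ncol(D), 0, mx), ncol(W0), ncol(D))
    run <- nmf_run(D, W0, C0, partition, config)
    r2 <- reconstruction_r2(D, run$W, run$C)
    if (is.null(best) || r2 > best$r2)
      best <- list(r2 = r2, W = run$W, C = run$C, iterations = run$iterations,
                   converged = run$converged)
  }
  free_cols <- partition_update_cols(partition, ncol(best$W))
  nc <- normalize_columns(best$W, best$C, free_cols)
  structure(list(r2 = best$r2, W = nc$W, C = nc$C, partition = partition,
                 iterations = best$iterations, converged = best$converged,
                 rep_seeds = rep_seeds),
            class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult: R2 = %.4f, %d synergies, %d iterations%s\n",
              x$r2, ncol(x$W), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
print.ExtractionResult <- function(x, ...) {
  cat("ExtractionResult: selected n =", x$selected_n, "\n")
  print(round(x$r2_by_n, 4))
  invisible(x)
}

#' Transpose a preprocessed envelope into the NMF data matrix
#'
#' @param env a `PreprocessedEmg` (or a bins x muscles matrix).
#' @param normalized use the unit-variance envelope (`TRUE`, default) or the
#'   unnormalized one.
#' @return muscles x bins matrix.
#' @export
nmf_data_matrix <- function(env, normalized = TRUE) {
  m <- if (inherits(env, "PreprocessedEmg")) {
    if (normalized) env$envelope else env$unnormalized_envelope
  } else env
  t(m)
}
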