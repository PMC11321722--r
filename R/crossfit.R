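#' Enumerate update subsets and keep the best partitioned fit
#'
#' For a given number of updated synergies, fits the basis to the target
#' with every possible choice of which basis columns to update
#' (`choose(N, n_up)` subsets), and returns the subset with the highest
#' reconstruction R-squared. Ties break lexicographically (first subset in
#' combination order wins).
#'
#' @param W_basis muscles x N nonnegative synergy basis.
#' @param n_up number of columns to update (0 to N).
#' @param D_target muscles x bins data matrix to fit.
#' @param n_add number of additional freshly extracted columns.
#' @param config an [engine_config()].
#' @param seed integer seed.
#' @param max_subset_fits guard rail on the number of subset fits.
#' @return list with `subset` (integer indices, possibly empty), `fit`
#'   (the best `FitResult`), `r2_by_subset`.
#' @export
enumerate_update_subsets <- function(W_basis, n_up, D_target, n_add = 0L,
                                     config = engine_config(), seed = 1L,
                                     max_subset_fits = 500L) {
  N <- ncol(W_basis)
  if (n_up > N) stop("n_up exceeds the number of basis synergies")
  subsets <- if (n_up == 0) list(integer(0)) else
    apply(utils::combn(N, n_up), 2, identity, simplify = FALSE)
  if (length(subsets) > max_subset_fits)
    stop("subset enumeration too large (", length(subsets), " fits); ",
         "raise max_subset_fits deliberately if this is intended")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(subsets))
  best <- NULL
  r2s <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    part <- partition_spec(N, subsets[[i]], n_add)
    fit <- fit_basis(D_target, W_basis, part, config, sub_seeds[i])
    r2s[i] <- fit$r2
    if (is.null(best) || fit$r2 > best$fit$r2)
      best <- list(subset = subsets[[i]], fit = fit)
  }
  list(subset = best$subset, fit = best$fit, r2_by_subset = r2s)
}

#' Control-to-control baseline R-squared matrix
#'
#' Fits the synergies of each control subject to the envelope of every other
#' control (ordered pairs, diagonal excluded) with `n_up` updated columns
#' (best subset per pair) and no additional columns, yielding the baseline
#' distribution of R-squared values that reflects within-control synergy
#' variability.
#'
#' @param controls list of controls, each a list with `W` (muscles x N
#'   synergy basis) and `D` (muscles x bins data matrix).
#' @param n_up number of updated columns in every fit.
#' @param config an [engine_config()].
#' @param seed integer seed.
#' @return A `BaselineMatrix`: list with `r2` (n x n matrix, `NA` diagonal),
#'   `n_up`, `values` (the off-diagonal entries as a vector).
#' @export
baseline_r2 <- function(controls, n_up = 0L, config = engine_config(),
                        seed = 1L) {
  n <- length(controls)
  if (n < 2) stop("need at least 2 controls for a baseline")
  set.seed(seed)
  pair_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n * n), n, n)
  r2 <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r2[i, j] <- enumerate_update_subsets(controls[[i]]$W, n_up,
                                         controls[[j]]$D, n_add = 0L,
                                         config, pair_seeds[i, j])$fit$r2
  }
  structure(list(r2 = r2, n_up = n_up, values = r2[!is.na(r2)]),
            class = "BaselineMatrix")
}

#' Statistical criterion for R-squared similarity
#'
#' Decides whether a sample of cross-fit R-squared values is not smaller
#' than the baseline sample: the criterion holds when a normality-gated
#' two-tailed test (t if both samples Lilliefors-normal, Mann-Whitney
#' otherwise) gives `p >= alpha`, or when the cross sample's central
#' tendency (mean under t, median under Mann-Whitney) is at least the
#' baseline's, so a superior fit never fails.
#'
#' @param cross_r2s,baseline_r2s numeric samples of R-squared values.
#' @param alpha similarity significance level (default 0.05).
#' @return list with `met`, `p`, `test_name`, `cross_center`,
#'   `baseline_center`.
#' @export
criterion_met <- function(cross_r2s, baseline_r2s, alpha = 0.05) {
  if (!length(cross_r2s) || !length(baseline_r2s))
    stop("both samples must be nonempty")
  if (length(cross_r2s) < 4 || length(baseline_r2s) < 4)
    warning("fewer than 4 values in a sample; the similarity test has low power")
  tr <- suppressWarnings(two_sample(cross_r2s, baseline_r2s))
  center <- if (tr$method == "t") mean else stats::median
  cc <- center(cross_r2s); bc <- center(baseline_r2s)
  list(met = tr$p >= alpha || cc >= bc, p = tr$p, test_name = tr$method,
       cross_center = cc, baseline_center = bc)
}

#' Mean fixed-basis fit R-squared of a cohort to one target
#'
#' Fits each control's synergies to the target envelope with everything
#' frozen (no updated, no additional columns) and averages the R-squared
#' values: the summary measure of how well normative synergies describe one
#' subject's data.
#'
#' @param controls list of controls with `W` components.
#' @param D_target muscles x bins data matrix.
#' @param config an [engine_config()].
#' @param seed integer seed.
#' @return list with `mean_r2` and `r2s` (per control).
#' @export
mean_fit_r2 <- function(controls, D_target, config = engine_config(),
                        seed = 1L) {
  if (!length(controls)) stop("need at least 1 control")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(controls))
  r2s <- vapply(seq_along(controls), function(i)
    fit_basis(D_target, controls[[i]]$W,
              partition_spec(ncol(controls[[i]]$W)), config, seeds[i])$r2,
    numeric(1))
  list(mean_r2 = mean(r2s), r2s = r2s)
}

#' Search for the smallest numbers of updated and additional synergies
#'
#' Systematically searches the smallest `(n_add, n_up)` pair — outer loop
#' over the number of additional synergies starting at 0, inner loop over
#' the number of updated synergies from 0 to `max_up` — such that the
#' control-to-target R-squared sample is statistically similar to (or above)
#' the control-to-control baseline at the same `n_up`. Every control-target
#' fit enumerates the update subsets and keeps the best; fits with added
#' columns repeat over their random initializations.
#'
#' @param controls list of controls with `W` and `D` components.
#' @param D_target muscles x bins data matrix of the target subject.
#' @param baselines_by_nup list of `BaselineMatrix` objects for
#'   `n_up = 0..max_up` (see [baseline_r2()]); element `i` holds `n_up = i-1`.
#' @param max_up largest number of updated synergies tried (default 5).
#' @param max_add largest number of additional synergies tried (default:
#'   muscle count).
#' @param config an [engine_config()].
#' @param seed integer seed.
#' @param alpha similarity significance level.
#' @return A `SearchResult`: list with `n_up_star`, `n_add_star`,
#'   `chosen_subsets` (per control at the accepted pair), `cross_r2s`,
#'   `mean_r2`, `trail` (data frame of every visited pair with p and test).
#' @export
search_nup_nadd <- function(controls, D_target, baselines_by_nup,
                            max_up = 5L, max_add = NULL,
                            config = engine_config(), seed = 1L,
                            alpha = 0.05) {
  if (is.null(max_add)) max_add <- nrow(D_target)
  if (length(baselines_by_nup) < max_up + 1)
    stop("need baselines for every n_up in 0..max_up")
  set.seed(seed)
  seed_pool <- matrix(sample.int(.Machine$integer.max - 1L,
                                 (max_add + 1L) * (max_up + 1L)),
                      max_add + 1L, max_up + 1L)
  trail <- data.frame(n_add = integer(0), n_up = integer(0), p = numeric(0),
                      test = character(0), met = logical(0))
  for (n_add in 0:max_add) {
    max_up_eff <- min(max_up, min(vapply(controls, function(s) ncol(s$W), 1L)))
    for (n_up in 0:max_up_eff) {
      set.seed(seed_pool[n_add + 1L, n_up + 1L])
      fit_seeds <- sample.int(.Machine$integer.max - 1L, length(controls))
      fits <- lapply(seq_along(controls), function(i)
        enumerate_update_subsets(controls[[i]]$W, n_up, D_target, n_add,
                                 config, fit_seeds[i]))
      cross <- vapply(fits, function(f) f$fit$r2, numeric(1))
      base <- baselines_by_nup[[n_up + 1L]]$values
      crit <- suppressWarnings(criterion_met(cross, base, alpha))
      trail <- rbind(trail, data.frame(n_add = n_add, n_up = n_up,
                                       p = crit$p, test = crit$test_name,
                                       met = crit$met))
      if (crit$met) {
        return(structure(list(
          n_up_star = n_up, n_add_star = n_add,
          chosen_subsets = lapply(fits, `[[`, "subset"),
          cross_r2s = cross, mean_r2 = mean(cross),
          fits = fits, trail = trail), class = "SearchResult"))
      }
    }
  }
  stop("similarity criterion never met up to n_add = ", max_add,
       "; trail:\n", paste(utils::capture.output(print(trail)), collapse = "\n"))
}

#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf("SearchResult: n_up* = %d, n_add* = %d, mean R2 = %.4f (%d fits)\n",
              x$n_up_star, x$n_add_star, x$mean_r2, length(x$cross_r2s)))
  invisible(x)
}
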