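#' Pearson correlation with t-test significance
#'
#' @param x,y numeric vectors, length >= 3, finite, nonconstant.
#' @return list with `r` and two-tailed `p` (t distribution, n - 2 df).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Lilliefors test of composite normality
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' SD estimated from the sample, with the Lilliefors correction of the
#' p-value.
#'
#' @param x numeric sample, n >= 5.
#' @return list with `statistic` and `p`.
#' @export
lilliefors <- function(x) {
  if (length(x) < 5) stop("Lilliefors test requires n >= 5")
  if (stats::sd(x) == 0) stop("Lilliefors test undefined for a constant sample")
  lt <- nortest::lillie.test(x)
  list(statistic = unname(lt$statistic), p = lt$p.value)
}

# returns TRUE when the sample passes the Lilliefors normality gate at alpha;
# constant or too-short samples fail the gate (with a warning where noted)
passes_normality <- function(x, alpha = 0.05, warn = TRUE) {
  if (length(x) < 5 || stats::sd(x) == 0) {
    if (warn) warning("normality gate inapplicable (n < 5 or constant sample); ",
                      "treating sample as non-normal")
    return(list(normal = FALSE, p = NA_real_))
  }
  p <- lilliefors(x)$p
  list(normal = p >= alpha, p = p)
}

#' Normality-gated two-sample comparison
#'
#' Tests each sample for normality with the Lilliefors test at
#' `alpha_norm`; if both pass, an equal-variance two-sample t test is used,
#' otherwise the Mann-Whitney (Wilcoxon rank-sum) test. Two-tailed.
#'
#' @param a,b numeric samples.
#' @param alpha_norm significance level of the normality gate.
#' @return A `TestResult`: list with `statistic`, `p`, `method`
#'   (`"t"` or `"mann-whitney"`), `normality_p` (length 2).
#' @export
two_sample <- function(a, b, alpha_norm = 0.05) {
  ga <- passes_normality(a, alpha_norm)
  gb <- passes_normality(b, alpha_norm)
  if (ga$normal && gb$normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(statistic = unname(tt$statistic), p = tt$p.value, method = "t")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    res <- list(statistic = unname(wt$statistic), p = wt$p.value,
                method = "mann-whitney")
  }
  res$normality_p <- c(ga$p, gb$p)
  structure(res, class = "TestResult")
}

#' One-sample t test
#'
#' @param x numeric sample, n >= 2, nonconstant.
#' @param mu null-hypothesis mean.
#' @return A `TestResult` with `statistic`, `p`, `method = "one-sample t"`.
#' @export
one_sample_t <- function(x, mu) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0) stop("one-sample t undefined for a constant sample")
  tt <- stats::t.test(x, mu = mu)
  structure(list(statistic = unname(tt$statistic), p = tt$p.value,
                 method = "one-sample t", normality_p = NA_real_),
            class = "TestResult")
}

#' Normality-gated multi-group comparison with post hoc pairs
#'
#' If every group passes the Lilliefors gate, a one-way ANOVA is used;
#' otherwise the Kruskal-Wallis test. When the omnibus p is below 0.05 a
#' Tukey-Kramer post hoc comparison identifies significantly different
#' pairs (run on rank-transformed data after a Kruskal-Wallis omnibus).
#'
#' @param groups list of numeric samples (>= 3 groups, each n >= 2).
#' @param alpha_norm significance level of the normality gate.
#' @return A `TestResult` with `statistic`, `p`, `method` (`"anova"` or
#'   `"kruskal-wallis"`), `normality_p`, and `posthoc` (data frame of pairs
#'   with adjusted p; `NULL` when the omnibus is not significant).
#' @export
multi_group <- function(groups, alpha_norm = 0.05) {
  if (length(groups) < 3) stop("need at least 3 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("every group needs n >= 2")
  gates <- lapply(groups, passes_normality, alpha = alpha_norm)
  normal <- all(vapply(gates, `[[`, TRUE, "normal"))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (normal) {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    res <- list(statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                method = "anova")
  } else {
    kw <- stats::kruskal.test(y, g)
    res <- list(statistic = unname(kw$statistic), p = kw$p.value,
                method = "kruskal-wallis")
  }
  res$normality_p <- vapply(gates, `[[`, 0, "p")
  res$posthoc <- NULL
  if (res$p < 0.05) {
    yy <- if (res$method == "kruskal-wallis") rank(y) else y
    hsd <- stats::TukeyHSD(stats::aov(yy ~ g))$g
    res$posthoc <- data.frame(pair = rownames(hsd),
                              diff = hsd[, "diff"],
                              p_adj = hsd[, "p adj"],
                              significant = hsd[, "p adj"] < 0.05,
                              row.names = NULL)
  }
  structure(res, class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("TestResult [%s]: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p))
  if (!is.null(x$posthoc)) {
    cat("post hoc (Tukey-Kramer):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Fit a four-parameter sigmoid by multi-start nonlinear least squares
#'
#' Fits `y = a / (1 + exp(-b (x - c))) + d` by Levenberg-Marquardt
#' (trust-region-flavoured) least squares from a small multi-start grid
#' (`d = min(y)`, `a = range of y`, `c = median(x)`, `b in {1, 5, 10}` and
#' their negatives) and returns the solution with the lowest SSE. The
#' coefficient of determination uses the mean-of-y SST.
#'
#' @param x,y numeric vectors, n >= 5, `x` nonconstant.
#' @return A `SigmoidFit`: list with `a`, `b`, `c`, `d`, `r2`, `sse`,
#'   `fitted`, `starts_tried`.
#' @export
fit_sigmoid <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("x has no spread")
  starts <- expand.grid(b = c(1, 5, 10, -1, -5, -10))
  best <- NULL
  trail <- character(0)
  for (b0 in starts$b) {
    st <- list(a = diff(range(y)), b = b0, c = stats::median(x), d = min(y))
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ a / (1 + exp(-b * (x - c))) + d, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500))), silent = TRUE)
    if (inherits(f, "try-error")) {
      trail <- c(trail, sprintf("b0=%g: failed", b0))
      next
    }
    sse <- sum(stats::resid(f)^2)
    trail <- c(trail, sprintf("b0=%g: SSE=%.6g", b0, sse))
    if (is.null(best) || sse < best$sse) best <- list(fit = f, sse = sse)
  }
  if (is.null(best))
    stop("sigmoid fit failed from every start:\n", paste(trail, collapse = "\n"))
  cf <- stats::coef(best$fit)
  # canonicalize the mirrored parameterization: (a,b,c,d) and (-a,-b,c,d+a)
  # describe the same curve; report the rising-limb (b > 0) form
  if (cf["b"] < 0)
    cf <- c(a = -cf[["a"]], b = -cf[["b"]], c = cf[["c"]],
            d = cf[["d"]] + cf[["a"]])
  r2 <- 1 - best$sse / sum((y - mean(y))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["c"]), d = unname(cf["d"]),
                 r2 = r2, sse = best$sse,
                 fitted = stats::fitted(best$fit), starts_tried = trail),
            class = "SigmoidFit")
}

#' Evaluate the four-parameter sigmoid
#'
#' @param x numeric input.
#' @param a,b,c,d sigmoid parameters: amplitude, steepness, midpoint, offset.
#' @return `a / (1 + exp(-b (x - c))) + d`.
#' @export
sigmoid <- function(x, a, b, c, d) a / (1 + exp(-b * (x - c))) + d

#' @export
print.SigmoidFit <- function(x, ...) {
  cat(sprintf("SigmoidFit: y = %.3g/(1+exp(-%.3g(x-%.3g))) + %.3g, R2 = %.4f\n",
              x$a, x$b, x$c, x$d, x$r2))
  invisible(x)
}
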