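#' Segment span of a synergy vector
#'
#' l2-normalizes the synergy vector and calls a muscle active when its
#' component strictly exceeds the threshold (default 0.1); the span is the
#' number of limb/body segments (crus, thigh, trunk) containing at least one
#' active muscle.
#'
#' @param w nonzero synergy vector over the registry muscles (named, or in
#'   registry order).
#' @param registry a [muscle_registry()].
#' @param threshold activation threshold on the normalized component
#'   (strict).
#' @return A `SegmentProfile`: list with `active_muscles`, `segments_hit`,
#'   `span`.
#' @export
segment_span <- function(w, registry = muscle_registry(), threshold = 0.1) {
  if (all(w == 0)) stop("segment span undefined for a zero synergy vector")
  nm <- names(w) %||% registry$names[seq_along(w)]
  wn <- w / sqrt(sum(w^2))
  active <- nm[wn > threshold]
  segs <- sort(unique(unname(registry$segment_map[active])))
  structure(list(active_muscles = active, segments_hit = segs,
                 span = length(segs)), class = "SegmentProfile")
}

#' Span distribution over a set of synergies
#'
#' @param W matrix (muscles x n) or list of synergy vectors.
#' @param registry a [muscle_registry()].
#' @param threshold activation threshold, as in [segment_span()].
#' @return list with `by_span` (percentages over span 1-3, summing to 100)
#'   and `by_combo` (percentages over the 7 nonempty segment combinations).
#' @export
span_distribution <- function(W, registry = muscle_registry(), threshold = 0.1) {
  if (is.matrix(W)) W <- lapply(seq_len(ncol(W)), function(j) {
    v <- W[, j]; names(v) <- rownames(W) %||% registry$names[seq_len(nrow(W))]; v
  })
  if (!length(W)) stop("need at least one synergy")
  profs <- lapply(W, segment_span, registry = registry, threshold = threshold)
  spans <- vapply(profs, `[[`, 1L, "span")
  combos <- vapply(profs, function(p) paste(p$segments_hit, collapse = "+"),
                   character(1))
  by_span <- 100 * vapply(1:3, function(s) mean(spans == s), numeric(1))
  names(by_span) <- as.character(1:3)
  combo_levels <- c("crus", "thigh", "trunk", "crus+thigh", "crus+trunk",
                    "thigh+trunk", "crus+thigh+trunk")
  by_combo <- 100 * vapply(combo_levels, function(cb) mean(combos == cb),
                           numeric(1))
  list(by_span = by_span, by_combo = by_combo, spans = spans)
}

#' Per-muscle comparison of synergies before and after updating
#'
#' Compares, muscle by muscle, the components of a cluster of synergy
#' vectors before and after updating with the normality-gated two-sample
#' test, flagging muscles at `p < alpha` (default 0.01).
#'
#' @param pre,post matrices of l2-normalized synergy vectors (muscles x n).
#' @param alpha flagging level (default 0.01).
#' @return data frame with one row per muscle: `muscle`, `p`, `method`,
#'   `flag`.
#' @export
compare_pre_post <- function(pre, post, alpha = 0.01) {
  if (nrow(pre) != nrow(post)) stop("muscle counts differ")
  nm <- rownames(pre) %||% muscle_registry()$names[seq_len(nrow(pre))]
  small <- ncol(pre) < 3 || ncol(post) < 3
  if (small)
    warning("fewer than 3 synergies on one side; p-values reported as missing")
  out <- data.frame(muscle = nm, p = NA_real_, method = NA_character_,
                    flag = FALSE, stringsAsFactors = FALSE)
  if (small) return(out)
  for (i in seq_len(nrow(pre))) {
    a <- pre[i, ]; b <- post[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b)))) {
      out$p[i] <- 1; out$method[i] <- "identical"; next
    }
    tr <- suppressWarnings(two_sample(a, b))
    out$p[i] <- tr$p
    out$method[i] <- tr$method
    out$flag[i] <- tr$p < alpha
  }
  out
}

#' Residual-amplitude profile: the motoneuron-loss proxy
#'
#' For each muscle, takes the 99th-percentile amplitude of the subject's
#' unnormalized envelope, divides it by the mean of the same muscle's peaks
#' across control limbs, and caps the fraction at 1 (a muscle cannot be
#' "more than fully" innervated under this proxy). The across-muscle
#' population variance of the fractions (`unevenness`, range 0-0.25)
#' quantifies how uneven the loss is.
#'
#' @param subject_env `PreprocessedEmg` of the subject (unnormalized
#'   envelope is used).
#' @param control_envs list of control `PreprocessedEmg` objects.
#' @return A `ResidualAmplitudeProfile`: list with `peak_by_muscle`,
#'   `control_mean_peak`, `residual_fraction`, `unevenness`.
#' @export
residual_profile <- function(subject_env, control_envs) {
  get_env <- function(e) {
    if (is.list(e) && !is.null(e$unnormalized_envelope))
      e$unnormalized_envelope else e
  }
  peak99 <- function(m) apply(m, 2, stats::quantile, probs = 0.99, names = FALSE)
  subj <- peak99(get_env(subject_env))
  ctrl <- rowMeans(vapply(control_envs, function(e) peak99(get_env(e)),
                          numeric(length(subj))))
  if (any(ctrl == 0))
    stop("control mean peak is zero in muscle(s): ",
         paste(names(subj)[ctrl == 0], collapse = ", "))
  frac <- pmin(subj / ctrl, 1)
  structure(list(peak_by_muscle = subj, control_mean_peak = ctrl,
                 residual_fraction = frac,
                 unevenness = mean((frac - mean(frac))^2)),
            class = "ResidualAmplitudeProfile")
}

#' Filter residual profiles by unevenness
#'
#' Keeps profiles whose across-muscle variance of residual fractions is at
#' least `min_variance` (strictly smaller values are excluded); limbs with
#' nearly even profiles carry no information about uneven loss.
#'
#' @param profiles list of `ResidualAmplitudeProfile`s.
#' @param min_variance exclusion threshold (default 0.04).
#' @return the retained sublist, with attribute `kept` (logical vector).
#' @export
unevenness_filter <- function(profiles, min_variance = 0.04) {
  kept <- vapply(profiles, function(p) p$unevenness >= min_variance, logical(1))
  structure(profiles[kept], kept = kept)
}

#' @export
print.ResidualAmplitudeProfile <- function(x, ...) {
  cat(sprintf("ResidualAmplitudeProfile: unevenness = %.4f\n", x$unevenness))
  print(round(x$residual_fraction, 3))
  invisible(x)
}
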