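#' Window-based FIR filter with group-delay compensation
#'
#' Designs a 50th-order window-based (Hamming) FIR filter and applies it with
#' reflection padding and group-delay compensation, so the output is aligned
#' with the input and has the same length. This approximates zero-phase
#' filtering without doubling the effective order.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency (Hz), must be below `fs/2`.
#' @param kind `"highpass"` or `"lowpass"`.
#' @param order filter order (default 50 taps-order).
#' @return filtered signal, same length as `x`.
#' @export
fir_filter <- function(x, fs, cutoff_hz, kind = c("highpass", "lowpass"),
                       order = 50L) {
  kind <- match.arg(kind)
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (length(x) <= 3L * order)
    stop("signal too short for FIR order ", order,
         "; need more than ", 3L * order, " samples")
  h <- design_fir(fs, cutoff_hz, kind, order)
  npad <- order
  n <- length(x)
  # odd (antisymmetric) reflection keeps level and slope continuous at edges
  left <- 2 * x[1] - x[seq(npad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - npad)]
  xp <- c(left, x, right)
  y <- stats::filter(xp, h, method = "convolution", sides = 1L)
  delay <- order / 2
  y <- as.numeric(y[(npad + delay + 1):(npad + delay + n)])
  y
}

#' Magnitude response of the designed FIR filter
#'
#' Evaluates |H(f)| of the same filter [fir_filter()] applies, for use as an
#' independent check of attenuation at a given frequency.
#' @inheritParams fir_filter
#' @param f_hz frequency (Hz) at which to evaluate the response.
#' @return magnitude of the transfer function at `f_hz`.
#' @export
fir_response <- function(f_hz, fs, cutoff_hz, kind = c("highpass", "lowpass"),
                         order = 50L) {
  kind <- match.arg(kind)
  h <- design_fir(fs, cutoff_hz, kind, order)
  k <- seq_along(h) - 1
  Mod(sum(h * exp(-2i * pi * f_hz * k / fs)))
}

# Hamming-window FIR taps. At this order the windowed high-pass design
# leaks a few percent at DC (the transition band is wide at a 0.05
# normalized cutoff), so its taps are shifted to place an exact null at DC;
# the uniform shift is ~1e-3 per tap and negligible in the passband.
design_fir <- function(fs, cutoff_hz, kind, order) {
  h <- signal::fir1(order, cutoff_hz / (fs / 2),
                    type = if (kind == "highpass") "high" else "low")
  h <- as.numeric(h)
  if (kind == "highpass") h <- h - sum(h) / length(h)
  h
}

#' De-spike an envelope by robust thresholding and spline interpolation
#'
#' Flags bins whose value exceeds `median + z_thresh * MAD-SD` per muscle and
#' replaces them by cubic-spline interpolation over the neighbouring bins.
#' Intended for the occasional high-amplitude noise spikes that survive
#' filtering; a muscle where more than 10 percent of bins are flagged raises
#' a warning because that is no longer "occasional".
#'
#' @param envelope nonnegative bins x muscles matrix.
#' @param z_thresh robust z-score threshold (default 8).
#' @param max_run longest run of consecutive above-threshold bins still
#'   treated as a spike (default 2); longer excursions are physiological
#'   bursts — a burst-like envelope has a small MAD relative to its bursts,
#'   and without this guard the de-spiker would interpolate the signal away.
#' @return matrix of the same shape with attribute `n_replaced` (per-muscle
#'   count of interpolated bins).
#' @export
despike_spline <- function(envelope, z_thresh = 8, max_run = 2L) {
  if (any(envelope < 0)) stop("envelope must be nonnegative")
  out <- envelope
  n_replaced <- integer(ncol(envelope))
  for (j in seq_len(ncol(envelope))) {
    v <- envelope[, j]
    med <- stats::median(v)
    rsd <- stats::mad(v)  # MAD scaled to SD-consistency
    if (rsd == 0) next
    over <- v > med + z_thresh * rsd
    if (!any(over)) next
    runs <- rle(over)
    runs$values <- runs$values & runs$lengths <= max_run
    bad <- which(inverse.rle(runs))
    n_replaced[j] <- length(bad)
    if (!length(bad)) next
    if (length(bad) > 0.1 * length(v))
      warning(sprintf("muscle %s: %d of %d bins flagged as spikes (>10%%)",
                      colnames(envelope)[j] %||% j, length(bad), length(v)))
    good <- setdiff(seq_along(v), bad)
    out[bad, j] <- pmax(0, stats::spline(good, v[good], xout = bad)$y)
  }
  attr(out, "n_replaced") <- n_replaced
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a raw EMG recording to the analysis envelope
#'
#' Applies the fixed preprocessing pipeline, in order: 50 Hz high-pass FIR
#' (50th order) -> per-channel mean subtraction (DC-offset correction) ->
#' full-wave rectification -> 20 Hz low-pass FIR -> clamping of residual
#' negative ringing to 0 -> mean over consecutive non-overlapping 20-ms bins
#' -> robust spline de-spiking -> per-muscle unit-variance normalization.
#' Both the normalized envelope (the data matrix fed to NMF) and the
#' unnormalized envelope (needed by the residual-amplitude motoneuron proxy)
#' are retained.
#'
#' @param rec an `EmgRecording`.
#' @param highpass_hz,lowpass_hz FIR cutoffs (Hz).
#' @param fir_order FIR order for both filters.
#' @param bin_ms integration bin width in milliseconds.
#' @param despike_z de-spiking robust z threshold.
#' @return A `PreprocessedEmg`: list with `envelope` (normalized, bins x
#'   muscles), `unnormalized_envelope`, `scale_factors` (per-muscle
#'   population SD used for scaling), `bin_ms`, `fs`, `muscles`, `side`,
#'   `behavior`, `subject_id`.
#' @export
make_envelope <- function(rec, highpass_hz = 50, lowpass_hz = 20,
                          fir_order = 50L, bin_ms = 20, despike_z = 8) {
  m <- rec$matrix
  fs <- rec$fs
  bin_n <- as.integer(round(fs * bin_ms / 1000))
  n_bins <- floor(nrow(m) / bin_n)
  if (n_bins < 2) stop("record too short to form envelope bins")
  env <- matrix(0, n_bins, ncol(m), dimnames = list(NULL, colnames(m)))
  for (j in seq_len(ncol(m))) {
    x <- fir_filter(m[, j], fs, highpass_hz, "highpass", fir_order)
    x <- x - mean(x)
    x <- abs(x)
    x <- fir_filter(x, fs, lowpass_hz, "lowpass", fir_order)
    x <- pmax(x, 0)
    env[, j] <- colMeans(matrix(x[seq_len(n_bins * bin_n)], nrow = bin_n))
  }
  env <- despike_spline(env, despike_z)
  sds <- apply(env, 2, pop_sd)
  zero <- which(sds == 0)
  if (length(zero))
    stop("zero variance after binning in muscle(s): ",
         paste(colnames(m)[zero], collapse = ", "),
         " (unit-variance normalization undefined)")
  norm_env <- sweep(env, 2, sds, "/")
  structure(list(envelope = norm_env,
                 unnormalized_envelope = `attr<-`(env, "n_replaced", NULL),
                 scale_factors = sds,
                 bin_ms = bin_ms, fs = fs, muscles = colnames(m),
                 side = rec$side, behavior = rec$behavior,
                 subject_id = rec$subject_id),
            class = "PreprocessedEmg")
}

# population (divide-by-n) standard deviation: variance over the whole record
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.PreprocessedEmg <- function(x, ...) {
  cat(sprintf("PreprocessedEmg '%s' (%s, %s): %d bins x %d muscles, %g-ms bins\n",
              x$subject_id, x$side, x$behavior,
              nrow(x$envelope), ncol(x$envelope), x$bin_ms))
  invisible(x)
}
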