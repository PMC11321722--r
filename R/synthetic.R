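#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the structure of a pediatric locomotor-EMG study:
#' 13 control subjects, 6 sparse synergies over 14 muscles, at least 22 step
#' cycles per record, 2 kHz sampling, proportional per-subject jitter of the
#' template components, and signal-proportional envelope noise with
#' per-subject signal-to-noise ratios calibrated so that the
#' best-of-repetitions reconstruction R-squared at the true dimensionality
#' sits near the 80-percent operating point of the dimensionality rule and
#' the control-to-control baseline sits slightly below it, as in healthy
#' locomotor cohorts.
#'
#' @param n_subjects number of subjects.
#' @param n_synergies number of generating synergies per subject.
#' @param n_muscles number of muscles (14, the canonical registry).
#' @param cycles step cycles per record (>= 22).
#' @param cycle_s cycle duration in seconds.
#' @param fs sampling rate (Hz) for raw-EMG synthesis.
#' @param noise_snr envelope signal-to-noise variance ratio; a scalar, or a
#'   length-2 range from which each subject's SNR is drawn uniformly
#'   (emulating varying recording quality across subjects).
#' @param subject_jitter relative SD of the multiplicative Gaussian jitter
#'   (truncated at 0, then renormalized) applied to template components per
#'   subject; variability scales with the component itself.
#' @param amp_cv coefficient of variation of per-cycle bump amplitudes.
#' @param bump_sd temporal width (fraction of a cycle) of each synergy's
#'   activation bump.
#' @param bin_ms envelope bin width (ms).
#' @param synth_raw also synthesize raw EMG (envelope-modulated broadband
#'   noise) at `fs`; disable to generate envelopes only.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 13L, n_synergies = 6L, n_muscles = 14L,
                       cycles = 22L, cycle_s = 1.1, fs = 2000,
                       noise_snr = c(3, 6), subject_jitter = 0.15,
                       amp_cv = 0.2, bump_sd = 0.07, bin_ms = 20,
                       synth_raw = TRUE, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_subjects >= 1, n_synergies >= 1, n_muscles >= 1,
            cycles >= 1, cycle_s > 0, fs > 0, noise_snr > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_synergies = as.integer(n_synergies),
                 n_muscles = as.integer(n_muscles),
                 cycles = as.integer(cycles), cycle_s = cycle_s, fs = fs,
                 noise_snr = noise_snr, subject_jitter = subject_jitter,
                 amp_cv = amp_cv, bump_sd = bump_sd, bin_ms = bin_ms,
                 synth_raw = isTRUE(synth_raw), seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate sparse synergy templates
#'
#' Draws `n` nonnegative template synergies, each dominated by 2-4 muscles
#' within one or two (adjacent) limb/body segments, rejecting draws until
#' all pairwise scalar products are at most 0.5 so the templates are
#' well-separated.
#'
#' @param n number of templates (at most the muscle count).
#' @param registry a [muscle_registry()].
#' @param seed integer seed.
#' @param max_sp pairwise scalar-product bound (default 0.5).
#' @param max_tries rejection-sampling cap per template.
#' @return muscles x n nonnegative matrix with l2-normalized columns and
#'   muscle rownames.
#' @export
make_templates <- function(n, registry = muscle_registry(), seed = 1L,
                           max_sp = 0.5, max_tries = 500L) {
  muscles <- registry$names
  if (n > length(muscles)) stop("cannot make more templates than muscles")
  seg_of <- registry$segment_map[muscles]
  adjacency <- list(crus = c("crus", "thigh"), thigh = c("crus", "thigh", "trunk"),
                    trunk = c("thigh", "trunk"))
  set.seed(seed)
  W <- matrix(0, length(muscles), 0)
  for (j in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      seg1 <- sample(c("crus", "thigh", "trunk"), 1)
      segs <- if (stats::runif(1) < 0.5) seg1 else
        unique(c(seg1, sample(adjacency[[seg1]], 1)))
      pool <- muscles[seg_of %in% segs]
      k <- sample(2:min(4, length(pool)), 1)
      picked <- sample(pool, k)
      # small nonzero background on every muscle: recorded synergies are
      # dominated by a few muscles but never exactly zero elsewhere, and a
      # muscle silent in every synergy would have no variance to normalize
      w <- stats::setNames(stats::runif(length(muscles), 0.01, 0.04), muscles)
      w[picked] <- stats::runif(k, 0.5, 1)
      w <- w / sqrt(sum(w^2))
      if (ncol(W) == 0 ||
          all(apply(W, 2, function(v) scalar_product(v, w)) <= max_sp)) {
        W <- cbind(W, w)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not satisfy the pairwise scalar-product constraint ",
                  "for template ", j)
  }
  rownames(W) <- muscles
  colnames(W) <- paste0("T", seq_len(n))
  W
}

# gait-cycle-locked coefficient traces: one Gaussian bump per synergy per
# cycle at a synergy-fixed phase, with amplitude jitter
make_coefficients <- function(n_synergies, cycles, bins_per_cycle,
                              amp_cv = 0.2, bump_sd = 0.08) {
  n_bins <- cycles * bins_per_cycle
  C <- matrix(0, n_synergies, n_bins)
  phases <- ((seq_len(n_synergies) - 0.5) / n_synergies +
               stats::runif(n_synergies, -0.04, 0.04)) %% 1
  tgrid <- (seq_len(n_bins) - 0.5) / bins_per_cycle  # time in cycles
  for (j in seq_len(n_synergies)) {
    for (cy in seq_len(cycles)) {
      center <- (cy - 1) + phases[j]
      amp <- max(0.1, stats::rnorm(1, 1, amp_cv))
      C[j, ] <- C[j, ] + amp * exp(-(tgrid - center)^2 / (2 * bump_sd^2))
    }
  }
  C
}

# raw EMG as broadband (50-450 Hz) noise amplitude-modulated by the envelope,
# plus a small white instrumentation-noise floor so quiescent channels still
# carry sensor noise as real recordings do
synth_raw_emg <- function(envelope, fs, bin_ms, sensor_noise = 0.02) {
  bin_n <- as.integer(round(fs * bin_ms / 1000))
  n_samp <- nrow(envelope) * bin_n
  centers <- (seq_len(nrow(envelope)) - 0.5) * bin_n
  b <- as.numeric(signal::fir1(100, c(50, min(450, 0.45 * fs)) / (fs / 2),
                               type = "pass"))
  b <- b / sqrt(sum(b^2))  # unit-variance carrier from unit white noise
  floor_sd <- sensor_noise * mean(envelope)
  raw <- matrix(0, n_samp, ncol(envelope),
                dimnames = list(NULL, colnames(envelope)))
  for (j in seq_len(ncol(envelope))) {
    wn <- stats::rnorm(n_samp + length(b))
    carrier <- as.numeric(stats::filter(wn, b, method = "convolution",
                                        sides = 1L))[-seq_along(b)]
    carrier <- carrier[seq_len(n_samp)]
    env_up <- stats::approx(centers, envelope[, j], xout = seq_len(n_samp),
                            rule = 2)$y
    raw[, j] <- carrier * env_up + stats::rnorm(n_samp, 0, floor_sd)
  }
  raw
}

make_subject <- function(W_true, config, registry, amp_scale = NULL) {
  bins_per_cycle <- as.integer(round(config$cycle_s * 1000 / config$bin_ms))
  C_true <- make_coefficients(ncol(W_true), config$cycles, bins_per_cycle,
                              config$amp_cv, config$bump_sd)
  if (!is.null(amp_scale)) C_true <- C_true * amp_scale
  E <- W_true %*% C_true
  # signal-proportional (multiplicative gamma, mean 1) envelope noise: the
  # amplitude variability of an EMG envelope scales with activation, and
  # zero-activity bins stay at zero. The gamma shape is set so the total
  # noise variance is var(E)/snr; a two-element noise_snr gives each
  # subject an SNR drawn from that range (recording quality varies across
  # subjects, which is what spreads the cross-fit baseline).
  snr <- if (length(config$noise_snr) == 2)
    stats::runif(1, config$noise_snr[1], config$noise_snr[2]) else
    config$noise_snr
  k <- snr * mean(E^2) / stats::var(as.numeric(E))
  E_noisy <- E * matrix(stats::rgamma(length(E), shape = k, rate = k), nrow(E))
  rownames(E_noisy) <- rownames(W_true)
  sds <- apply(E_noisy, 1, pop_sd)
  sds[sds == 0] <- 1  # muscles outside every synergy's support stay at zero
  D <- E_noisy / sds
  list(W_true = W_true, C_true = C_true, envelope = t(E_noisy), D = D)
}

# multiplicative jitter: each component is scaled by 1 + N(0, jitter_sd),
# truncated at zero. Inter-subject variability in synergy balance scales
# with the component itself, so low-activity muscles keep their relative
# structure across subjects (as normalized recordings do).
jitter_templates <- function(templates, jitter_sd) {
  W <- apply(templates, 2, function(w) {
    v <- pmax(0, w * (1 + stats::rnorm(length(w), 0, jitter_sd)))
    if (all(v == 0)) v <- w
    v / sqrt(sum(v^2))
  })
  rownames(W) <- rownames(templates)
  W
}

#' Generate a synthetic control cohort
#'
#' Per subject: the group templates are jittered (Gaussian, truncated at 0,
#' then renormalized) to emulate inter-subject synergy variability;
#' cycle-locked coefficient traces are drawn; the envelope is the synergy
#' reconstruction plus nonnegative noise at the configured
#' signal-to-noise ratio; and, optionally, raw EMG is synthesized by
#' amplitude-modulating band-limited broadband noise with the envelope.
#'
#' @param config a [sim_config()].
#' @param registry a [muscle_registry()].
#' @return A `SyntheticCohort`: list with `templates` (muscles x n) and
#'   `subjects`, each subject a list with `rec` (an `EmgRecording`, or
#'   `NULL` when raw synthesis is off), and `truth` holding `W_true`,
#'   `C_true`, `envelope` (bins x muscles, noisy, unnormalized), `D`
#'   (muscles x bins, unit-variance rows, ready for NMF).
#' @export
make_cohort <- function(config, registry = muscle_registry()) {
  set.seed(config$seed)
  template_seed <- sample.int(.Machine$integer.max - 1L, 1)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)
  templates <- make_templates(config$n_synergies, registry, template_seed)
  templates <- templates[seq_len(config$n_muscles), , drop = FALSE]
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[s])
    W_s <- jitter_templates(templates, config$subject_jitter)
    truth <- make_subject(W_s, config, registry)
    rec <- NULL
    if (config$synth_raw) {
      raw <- synth_raw_emg(truth$envelope, config$fs, config$bin_ms)
      rec <- emg_recording(raw, fs = config$fs, side = "left",
                           behavior = "walking",
                           subject_id = sprintf("sim%02d", s),
                           registry = registry)
    }
    subjects[[s]] <- list(rec = rec, truth = truth,
                          subject_id = sprintf("sim%02d", s))
  }
  structure(list(templates = templates, subjects = subjects, config = config),
            class = "SyntheticCohort")
}

# a merged (unfractionated-precursor-like) module: active on the union of the
# supports of two templates whose dominant muscles sit in different segments,
# but with its own muscle balance (weights redrawn, not summed). A plain sum
# of two basis synergies lies inside their nonnegative cone and is therefore
# invisible to reconstruction-based fitting; a precursor with its own balance
# is not.
merge_modules <- function(templates, registry, j = NULL) {
  seg_dom <- apply(templates, 2, function(w) {
    segs <- registry$segment_map[rownames(templates)]
    names(which.max(tapply(w, segs, sum)))
  })
  if (is.null(j)) j <- sample(ncol(templates), 1)
  partners <- which(seg_dom != seg_dom[j])
  if (!length(partners)) partners <- setdiff(seq_len(ncol(templates)), j)
  l <- if (length(partners) == 1) partners else sample(partners, 1)
  # support = union of the two parents' dominant muscles, weights redrawn:
  # the precursor coactivates the muscles of both descendants with its own
  # balance. Restricting the support to already-active muscles keeps the
  # per-muscle variance profile (and hence the unit-variance scaling)
  # commensurate with normative records; rejection sampling keeps the
  # precursor's balance clearly distinct from every normative synergy.
  support <- which(templates[, j] > 0.25 | templates[, l] > 0.25)
  for (try in 1:200) {
    w <- templates[, j] * 0  # keep names, zero values
    w[support] <- stats::runif(length(support), 0.3, 1)
    w <- w / sqrt(sum(w^2))
    if (max(apply(templates, 2, function(v) scalar_product(v, w))) <= 0.7)
      return(list(w = w, j = j, l = l))
  }
  list(w = w, j = j, l = l)
}

# a novel multi-segment module, rejection-sampled to be dissimilar
# (scalar product <= max_sp) from every template
novel_module <- function(templates, registry, max_sp = 0.6,
                         max_tries = 200L) {
  muscles <- rownames(templates)
  seg_of <- registry$segment_map[muscles]
  # draw support from muscles already dominant in some template (novel
  # cross-segment combination, not novel muscle territory): pathology
  # recombines existing drive rather than awakening silent channels, and
  # this keeps the record's per-muscle variance profile near normative
  active <- muscles[apply(templates, 1, max) > 0.25]
  for (try in seq_len(max_tries)) {
    segs <- sample(c("crus", "thigh", "trunk"), 2)
    pool <- intersect(active, muscles[seg_of %in% segs])
    if (length(pool) < 3) next
    k <- sample(3:min(5, length(pool)), 1)
    picked <- sample(pool, k)
    if (length(unique(seg_of[picked])) < 2) next
    w <- stats::setNames(numeric(length(muscles)), muscles)
    w[picked] <- stats::runif(length(picked), 0.5, 1)
    w <- w / sqrt(sum(w^2))
    if (all(apply(templates, 2, function(v) scalar_product(v, w)) <= max_sp))
      return(w)
  }
  stop("could not draw a novel module dissimilar from all templates")
}

#' Generate a synthetic SMA-like cohort with planted pathology
#'
#' Builds subjects from the same normative templates as [make_cohort()]
#' under `base_config`, then plants pathology with known ground truth:
#' `n_modified` synergies are replaced by merged multi-segment modules
#' (emulating unfractionated precursors of two normative synergies from
#' different segments), `n_added` novel multi-segment modules (scalar
#' product at most 0.8 against every template) are appended, per-muscle
#' amplitude attenuation is applied to the envelope (and hence to any
#' synthesized raw EMG), and a motor score is generated from the sigmoidal
#' onset-age model `58.0/(1+exp(-7.7(x-1.2)))+3.7` plus noise, clipped to
#' `[0, 72]`.
#'
#' @param base_config a [sim_config()]; its seed fixes the normative
#'   templates shared with the matching control cohort.
#' @param n_modified number of merged (modified) synergies.
#' @param n_added number of novel additional synergies.
#' @param attenuation_spec per-muscle attenuation fractions in `[0, 1]`
#'   (length = muscle count), or `NULL` to draw uniformly from `[0.2, 1]`.
#' @param onset_ages per-subject onset ages (years), or `NULL` to draw
#'   uniformly from `[0.08, 2]`.
#' @param seed integer seed for the pathology draws.
#' @param added_modules optional muscles x `n_added` matrix of added modules
#'   to plant instead of drawing them; rejected if any matches a template at
#'   scalar product above 0.8.
#' @param pathology_gain activation-amplitude multiplier applied to the
#'   planted (modified and added) modules relative to the preserved
#'   normative modules; a gross precursor-like module dominates the motor
#'   output it drives.
#' @param registry a [muscle_registry()].
#' @return A `SyntheticCohort` whose subject `truth` additionally holds
#'   `modified_indices`, `merged_from`, `added_modules`, `attenuation`,
#'   `onset_age`, `rhs`.
#' @export
make_sma_cohort <- function(base_config, n_modified = 1L, n_added = 1L,
                            attenuation_spec = NULL, onset_ages = NULL,
                            seed = 1L, registry = muscle_registry(),
                            added_modules = NULL, pathology_gain = 1.6) {
  if (n_modified > base_config$n_synergies)
    stop("cannot modify more synergies than exist")
  set.seed(base_config$seed)
  template_seed <- sample.int(.Machine$integer.max - 1L, 1)
  templates <- make_templates(base_config$n_synergies, registry, template_seed)
  templates <- templates[seq_len(base_config$n_muscles), , drop = FALSE]
  if (!is.null(added_modules)) {
    sp <- apply(added_modules, 2, function(w)
      max(apply(templates, 2, function(v) scalar_product(v, w))))
    if (any(sp > 0.8))
      stop("supplied added module(s) too similar to a template (SP > 0.8)")
  }
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, base_config$n_subjects)
  subjects <- vector("list", base_config$n_subjects)
  for (s in seq_len(base_config$n_subjects)) {
    set.seed(subject_seeds[s])
    onset <- if (!is.null(onset_ages)) onset_ages[s] else
      stats::runif(1, 0.08, 2)
    atten <- if (!is.null(attenuation_spec)) attenuation_spec else
      stats::runif(nrow(templates), 0.2, 1)
    W_s <- jitter_templates(templates, base_config$subject_jitter)
    modified <- if (n_modified > 0)
      sample(ncol(W_s), n_modified) else integer(0)
    merged_from <- list()
    for (j in modified) {
      mm <- merge_modules(templates, registry, j)
      W_s[, j] <- mm$w
      merged_from[[as.character(j)]] <- c(mm$j, mm$l)
    }
    added <- if (!is.null(added_modules)) added_modules else if (n_added > 0)
      vapply(seq_len(n_added), function(i) {
        # the novel module must be distinct from the normative templates and
        # from any planted precursor module, or the two pathologies collapse
        # into one spatial direction
        for (try in 1:50) {
          w <- novel_module(templates, registry)
          others <- W_s[, modified, drop = FALSE]
          if (!length(modified) ||
              max(apply(others, 2, function(v) scalar_product(v, w))) <= 0.5)
            return(w)
        }
        w
      }, numeric(nrow(templates))) else
      matrix(0, nrow(templates), 0)
    if (n_added > 0) W_s <- cbind(W_s, added)
    # pathological modules drive movement dominantly: their activations are
    # scaled up relative to the preserved normative modules
    amp_scale <- rep(1, ncol(W_s))
    amp_scale[modified] <- pathology_gain
    if (n_added > 0) amp_scale[ncol(W_s) - seq_len(n_added) + 1L] <- pathology_gain
    truth <- make_subject(W_s, base_config, registry, amp_scale)
    # per-muscle attenuation acts on the signal amplitude, i.e. envelope rows
    env_att <- sweep(truth$envelope, 2, atten, "*")
    sds <- apply(env_att, 2, pop_sd)
    sds[sds == 0] <- 1
    truth$envelope <- env_att
    truth$D <- t(env_att) / sds
    truth$modified_indices <- modified
    truth$merged_from <- merged_from
    truth$added_modules <- added
    truth$attenuation <- stats::setNames(atten, rownames(templates))
    truth$onset_age <- onset
    truth$rhs <- min(72, max(0, sigmoid(onset, 58.0, 7.7, 1.2, 3.7) +
                               stats::rnorm(1, 0, 3)))
    rec <- NULL
    if (base_config$synth_raw) {
      raw <- synth_raw_emg(truth$envelope, base_config$fs, base_config$bin_ms)
      rec <- emg_recording(raw, fs = base_config$fs, side = "left",
                           behavior = "AAM",
                           subject_id = sprintf("sma%02d", s),
                           registry = registry)
    }
    subjects[[s]] <- list(rec = rec, truth = truth,
                          subject_id = sprintf("sma%02d", s))
  }
  structure(list(templates = templates, subjects = subjects,
                 config = base_config), class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d subjects, %d templates x %d muscles\n",
              length(x$subjects), ncol(x$templates), nrow(x$templates)))
  invisible(x)
}
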