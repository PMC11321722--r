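# Small in-code fixtures shared across test files.

# write a canonical 14-column EMG text file and return its path
write_emg_fixture <- function(n = 40, seed = 1, shuffle = FALSE, sep = ",") {
  set.seed(seed)
  reg <- muscle_registry()
  m <- matrix(abs(rnorm(n * 14)), n, 14, dimnames = list(NULL, reg$names))
  if (shuffle) m <- m[, sample(14)]
  path <- tempfile(fileext = ".csv")
  write.table(m, path, sep = sep, row.names = FALSE, quote = FALSE)
  list(path = path, matrix = m)
}

# the 14 (onset age, RHS) pairs of the packaged clinical table, read fresh
clinical_pairs <- function() {
  tab <- read_subject_table(system.file("extdata", "sma_clinical_table.csv",
                                        package = "emgsynergy"))
  has <- !is.na(tab$rhs_left)
  list(onset = tab$onset_age[has], left = tab$rhs_left[has],
       right = tab$rhs_right[has], table = tab)
}

# quick random nonnegative factorization problem
random_nmf_problem <- function(m = 6, k = 3, t = 20, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(m * k), m, k)
  C <- matrix(runif(k * t), k, t)
  D <- W %*% C + matrix(runif(m * t, 0, 0.05), m, t)
  list(D = D, W = W, C = C)
}

# tiny control sets (synergies + data) for crossfit tests
make_control_sets <- function(n_ctrl = 4, n_syn = 3, seed = 11, jitter = 0.06,
                              cycles = 8, n_reps = 5) {
  cfg <- sim_config(n_subjects = n_ctrl, n_synergies = n_syn, cycles = cycles,
                    synth_raw = FALSE, subject_jitter = jitter, seed = seed)
  coh <- make_cohort(cfg)
  sets <- lapply(coh$subjects, function(s) {
    f <- extract_synergies(s$truth$D, n_syn, engine_config(n_reps = n_reps),
                           seed = 5)
    list(W = f$W, D = s$truth$D)
  })
  list(cfg = cfg, cohort = coh, sets = sets)
}
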