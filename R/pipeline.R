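#' Reproduce the clinical statistics of the packaged subject table
#'
#' Recomputes, from the packaged clinical table (or any table with the same
#' schema), the onset-age/motor-score Pearson correlations for both sides,
#' the four-parameter sigmoid fits with their coefficients of
#' determination, and the age mean/SD over all rows, and compares them with
#' the packaged reference values.
#'
#' @param path CSV path; defaults to the packaged clinical table.
#' @return A `Table1Report`: list with `pearson_left`, `pearson_right`
#'   (`r`, `p`), `sigmoid_left`, `sigmoid_right` (`SigmoidFit`), `age_mean`,
#'   `age_sd`, `n_rows`, `n_rhs`, and `reference` (the packaged expected
#'   values with absolute deviations).
#' @export
reproduce_table1_stats <- function(path = system.file("extdata",
                                                      "sma_clinical_table.csv",
                                                      package = "emgsynergy")) {
  subj <- read_subject_table(path)
  has <- !is.na(subj$rhs_left) & !is.na(subj$onset_age)
  if (sum(has) < 5)
    stop("too few rows with both onset age and motor score (need >= 5)")
  x <- subj$onset_age[has]
  pl <- pearson_r(x, subj$rhs_left[has])
  pr <- pearson_r(x, subj$rhs_right[has])
  sl <- fit_sigmoid(x, subj$rhs_left[has])
  sr <- fit_sigmoid(x, subj$rhs_right[has])
  ref <- data.frame(
    quantity = c("pearson_r_left", "sigmoid_r2_left", "sigmoid_r2_right",
                 "age_mean", "age_sd"),
    expected = c(0.82, 0.963, 0.959, 5.94, 4.71),
    computed = c(round(pl$r, 2), round(sl$r2, 3), round(sr$r2, 3),
                 round(mean(subj$age), 2), round(stats::sd(subj$age), 2))
  )
  ref$abs_dev <- abs(ref$computed - ref$expected)
  structure(list(pearson_left = pl, pearson_right = pr,
                 sigmoid_left = sl, sigmoid_right = sr,
                 age_mean = mean(subj$age), age_sd = stats::sd(subj$age),
                 n_rows = nrow(subj), n_rhs = sum(!is.na(subj$rhs_left)),
                 reference = ref),
            class = "Table1Report")
}

#' @export
print.Table1Report <- function(x, ...) {
  cat(sprintf("Table1Report: %d rows, %d with motor scores\n", x$n_rows, x$n_rhs))
  cat(sprintf("  left : r = %.2f (p = %.2g), sigmoid R2 = %.3f\n",
              x$pearson_left$r, x$pearson_left$p, x$sigmoid_left$r2))
  cat(sprintf("  right: r = %.2f (p = %.2g), sigmoid R2 = %.3f\n",
              x$pearson_right$r, x$pearson_right$p, x$sigmoid_right$r2))
  cat(sprintf("  age  : mean %.2f, SD %.2f\n", x$age_mean, x$age_sd))
  invisible(x)
}

# content hash of an arbitrary R object (12-digit numeric serialization)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(x, f, control = c("keepNA", "keepInteger"))
  unname(tools::md5sum(f))
}

#' Run the study-shaped pipeline on a synthetic cohort
#'
#' Orchestrates the full workflow on generated data: simulate a control and
#' an SMA-like cohort, extract synergies with the dimensionality rule,
#' cluster the control synergies, compute control-to-control baselines, run
#' the updated/additional-synergy search on each SMA-like subject,
#' characterize segment spans and residual-amplitude profiles, and compute
#' the clinical statistics of the generated metadata. Stages whose inputs
#' and configuration are unchanged (by content hash) are reused from
#' `out_dir` when `cache = TRUE`.
#'
#' @param config list with components `sim` (arguments to [sim_config()]
#'   except `seed`), `sma` (arguments to [make_sma_cohort()]:
#'   `n_modified`, `n_added`), `engine` (arguments to [engine_config()]),
#'   `max_up`, `n_range` (candidate dimensionalities), and `seed`.
#' @param out_dir directory for stage outputs and the manifest.
#' @param cache reuse cached stage outputs when hashes match.
#' @return A `RunManifest`: list with per-stage status (`computed` or
#'   `cached`), timings, the config hash, and the collected results.
#' @export
run_pipeline <- function(config, out_dir = tempfile("emgsynergy_run_"),
                         cache = TRUE) {
  if (is.null(config$seed)) stop("config$seed is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  cache_file <- file.path(out_dir, paste0("pipeline_", hash, ".rds"))
  if (cache && file.exists(cache_file)) {
    res <- readRDS(cache_file)
    res$stages$status[] <- "cached"
    return(res)
  }
  stages <- data.frame(stage = character(0), status = character(0),
                       seconds = numeric(0))
  tic <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages <<- rbind(stages, data.frame(stage = stage, status = "computed",
                                        seconds = proc.time()[["elapsed"]] - t0))
    out
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6)
  eng <- do.call(engine_config, config$engine %||% list())
  sim_args <- config$sim %||% list()
  sim_args$seed <- seeds[1]
  cfg <- do.call(sim_config, sim_args)

  controls <- tic("simulate", {
    ctrl <- make_cohort(cfg)
    sma_args <- config$sma %||% list(n_modified = 1L, n_added = 1L)
    sma <- do.call(make_sma_cohort,
                   c(list(base_config = cfg), sma_args, list(seed = seeds[2])))
    list(ctrl = ctrl, sma = sma)
  })
  extraction <- tic("extract", {
    n_range <- config$n_range %||% seq_len(cfg$n_muscles)
    lapply(controls$ctrl$subjects, function(s)
      select_dimensionality(s$truth$D, eng, seeds[3], n_range))
  })
  ctrl_sets <- lapply(seq_along(extraction), function(i) {
    ex <- extraction[[i]]
    list(W = ex$fits[[match(ex$selected_n, ex$n_range)]]$W,
         D = controls$ctrl$subjects[[i]]$truth$D)
  })
  clusters <- tic("cluster", {
    cluster_synergies(lapply(ctrl_sets, `[[`, "W"),
                      n_replicates = min(500L, 5000L), seed = seeds[4])
  })
  max_up <- config$max_up %||% 5L
  baselines <- tic("baseline", {
    lapply(0:max_up, function(nu) baseline_r2(ctrl_sets, nu, eng, seeds[5]))
  })
  searches <- tic("search", {
    lapply(controls$sma$subjects, function(s)
      search_nup_nadd(ctrl_sets, s$truth$D, baselines, max_up = max_up,
                      config = eng, seed = seeds[6]))
  })
  characterization <- tic("characterize", {
    spans <- span_distribution(controls$ctrl$templates)
    profiles <- lapply(controls$sma$subjects, function(s) {
      subj_env <- list(unnormalized_envelope = s$truth$envelope)
      ctrl_envs <- lapply(controls$ctrl$subjects, function(cc)
        list(unnormalized_envelope = cc$truth$envelope))
      residual_profile(subj_env, ctrl_envs)
    })
    list(spans = spans, profiles = profiles,
         retained = unevenness_filter(profiles))
  })
  clinical <- tic("stats", {
    onset <- vapply(controls$sma$subjects, function(s) s$truth$onset_age, 1)
    rhs <- vapply(controls$sma$subjects, function(s) s$truth$rhs, 1)
    list(pearson = if (length(onset) >= 3) pearson_r(onset, rhs),
         sigmoid = if (length(onset) >= 5)
           tryCatch(fit_sigmoid(onset, rhs), error = function(e) NULL))
  })
  res <- structure(list(config_hash = hash, seed = config$seed,
                        stages = stages, out_dir = out_dir,
                        extraction = extraction, clusters = clusters,
                        baselines = baselines, searches = searches,
                        characterization = characterization,
                        clinical = clinical),
                   class = "RunManifest")
  if (cache) saveRDS(res, cache_file)
  res
}

#' @export
print.RunManifest <- function(x, ...) {
  cat("RunManifest", x$config_hash, "\n")
  print(x$stages)
  invisible(x)
}
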