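#' Read a delimited EMG matrix
#'
#' Reads a plain-text EMG table (comma- or tab-delimited, auto-detected) with
#' one mandatory header row of muscle labels, validates the labels against
#' the canonical registry, and returns the columns reordered into registry
#' order regardless of the order on disk.
#'
#' @param path file path.
#' @param fs sampling rate in Hz (must be positive).
#' @param side `"left"` or `"right"`.
#' @param behavior `"walking"` or `"AAM"` (active-assisted motion).
#' @param subject_id subject identifier string.
#' @param registry a [muscle_registry()].
#' @return An `EmgRecording`: list with `matrix` (samples x muscles, columns
#'   named in canonical order), `fs`, `muscles`, `side`, `behavior`,
#'   `subject_id`.
#' @export
read_emg_table <- function(path, fs, side = c("left", "right"),
                           behavior = c("walking", "AAM"),
                           subject_id = "unknown",
                           registry = muscle_registry()) {
  side <- match.arg(side)
  behavior <- match.arg(behavior)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate in Hz")
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  labs <- resolve_muscles(colnames(df), registry)
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(toupper(trimws(df[[j]])) %in% c("NA", "NAN", "")))
    if (length(bad))
      stop("non-numeric cell in column '", colnames(df)[j], "', row ", bad[1],
           call. = FALSE)
    m[, j] <- v
  }
  colnames(m) <- labs
  # rows with any NA are rejected at ingest
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warning(sum(!keep), " rows with missing values dropped at ingest")
    m <- m[keep, , drop = FALSE]
  }
  ord <- intersect(registry$names, labs)
  m <- m[, ord, drop = FALSE]
  emg_recording(m, fs = fs, side = side, behavior = behavior,
                subject_id = subject_id, registry = registry)
}

#' Construct an EmgRecording in memory
#'
#' @param matrix numeric samples x muscles matrix with canonical column names.
#' @inheritParams read_emg_table
#' @return An `EmgRecording` object.
#' @export
emg_recording <- function(matrix, fs, side = "left", behavior = "walking",
                          subject_id = "unknown", registry = muscle_registry()) {
  if (is.null(colnames(matrix)))
    stop("EMG matrix must carry muscle labels as column names")
  labs <- resolve_muscles(colnames(matrix), registry)
  colnames(matrix) <- labs
  ord <- intersect(registry$names, labs)
  matrix <- matrix[, ord, drop = FALSE]
  if (anyNA(matrix)) stop("EMG matrix contains NA after ingest")
  structure(list(matrix = matrix, fs = fs, muscles = colnames(matrix),
                 side = side, behavior = behavior, subject_id = subject_id),
            class = "EmgRecording")
}

#' @export
print.EmgRecording <- function(x, ...) {
  cat(sprintf("EmgRecording '%s' (%s, %s): %d samples x %d muscles @ %g Hz\n",
              x$subject_id, x$side, x$behavior,
              nrow(x$matrix), ncol(x$matrix), x$fs))
  invisible(x)
}

#' Write an EMG matrix to delimited text
#'
#' @param rec an `EmgRecording`.
#' @param path output path; tab-delimited with a muscle-label header.
#' @export
write_emg_table <- function(rec, path) {
  utils::write.table(rec$matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a subject metadata table
#'
#' Parses a clinical subject table with one row per recording session. The
#' motor-score column (`rhs`, Revised Hammersmith Scale, 0-72) accepts three
#' layouts: `"NA"` (missing), a single value `"48"` applying to both sides,
#' or `"40.75 (41)"` giving left and (right) separately. Missing values
#' anywhere are the literal `NA`.
#'
#' @param path CSV/TSV path with columns `subject_id`, `age`, `onset_age`,
#'   `rhs`, `tasks` (subset of `W`/`A`, comma-separated) and optionally
#'   `group`, `smn1_ex7`, `smn1_ex8`, `smn2_ex7`, `smn2_ex8`.
#' @return A data frame of `SubjectRecord`s: one row per input row with
#'   numeric `rhs_left`/`rhs_right` and integer gene copy-number columns.
#' @export
read_subject_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                          check.names = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "onset_age", "rhs", "tasks")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("subject table lacks required columns: ", paste(miss, collapse = ", "))
  rhs <- parse_rhs(as.character(df$rhs))
  out <- data.frame(
    subject_id = as.character(df$subject_id),
    group = if ("group" %in% colnames(df)) as.character(df$group) else "SMA",
    age = as.numeric(df$age),
    onset_age = as.numeric(df$onset_age),
    rhs_left = rhs$left,
    rhs_right = rhs$right,
    stringsAsFactors = FALSE
  )
  for (g in c("smn1_ex7", "smn1_ex8", "smn2_ex7", "smn2_ex8"))
    out[[g]] <- if (g %in% colnames(df)) as.integer(df[[g]]) else NA_integer_
  out$tasks <- as.character(df$tasks)
  bad <- which(stats::complete.cases(out[, c("onset_age", "age")]) &
                 out$onset_age > out$age)
  if (length(bad))
    stop("onset_age exceeds age for subject(s): ",
         paste(out$subject_id[bad], collapse = ", "))
  out
}

parse_rhs <- function(x) {
  left <- right <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (is.na(s) || s == "" || toupper(s) == "NA") next
    m <- regmatches(s, regexec("^([0-9.]+)\\s*\\(([0-9.]+)\\)$", s))[[1]]
    if (length(m) == 3) {
      left[i] <- as.numeric(m[2]); right[i] <- as.numeric(m[3])
    } else if (grepl("^[0-9.]+$", s)) {
      left[i] <- right[i] <- as.numeric(s)
    } else {
      stop("cannot parse RHS entry '", s, "'", call. = FALSE)
    }
  }
  ok <- is.na(left) | (left >= 0 & left <= 72 & right >= 0 & right <= 72)
  if (!all(ok))
    stop("RHS outside [0, 72] in row(s): ", paste(which(!ok), collapse = ", "))
  list(left = left, right = right)
}

#' Write / read a synergy set
#'
#' A synergy set is a nonnegative muscles x N matrix `W`. It is stored as a
#' CSV with muscles as rows plus a JSON side-car (`<path>.json`) holding the
#' provenance metadata and a content hash so identical content always hashes
#' identically.
#'
#' @param W nonnegative numeric matrix, muscles x N, rownames = muscle labels.
#' @param meta named list of provenance fields (subject, side, behavior, ...).
#' @param path CSV output path.
#' @return `write_synergy_set` returns `path` invisibly; `read_synergy_set`
#'   returns a list with `W`, `meta` and `hash`.
#' @export
write_synergy_set <- function(W, meta = list(), path) {
  if (any(W < 0)) stop("synergy matrix has negative entries")
  if (any(colSums(W) == 0)) warning("synergy set contains a zero column")
  if (is.null(rownames(W))) rownames(W) <- muscle_registry()$names[seq_len(nrow(W))]
  df <- data.frame(muscle = rownames(W), W, check.names = FALSE)
  colnames(df) <- c("muscle", paste0("syn", seq_len(ncol(W))))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  meta$content_hash <- synergy_content_hash(W)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synergy_set
#' @export
read_synergy_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$muscle
  if (any(W < 0)) stop("synergy matrix has negative entries")
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE) else list()
  list(W = W, meta = meta, hash = synergy_content_hash(W))
}

#' Content hash of a synergy matrix
#'
#' MD5 of the matrix serialized at 12 decimal digits, so the hash is stable
#' across writes of identical content and across platforms.
#' @param W numeric matrix.
#' @return character MD5 string.
#' @export
synergy_content_hash <- function(W) {
  txt <- paste(c(dim(W), sprintf("%.12g", W)), collapse = ",")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
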