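test_that("EMG tables round-trip and are returned in canonical muscle order", {
  fx <- write_emg_fixture(n = 10)
  rec <- read_emg_table(fx$path, fs = 2000, side = "left",
                        behavior = "walking", subject_id = "s1")
  expect_s3_class(rec, "EmgRecording")
  expect_equal(dim(rec$matrix), c(10, 14))
  expect_identical(colnames(rec$matrix), muscle_registry()$names)

  # shuffled columns on disk come back in registry order with identical values
  fx2 <- write_emg_fixture(n = 25, seed = 3, shuffle = TRUE, sep = "\t")
  rec2 <- read_emg_table(fx2$path, fs = 1000, side = "right", behavior = "AAM")
  expect_identical(colnames(rec2$matrix), muscle_registry()$names)
  expect_equal(rec2$matrix[, colnames(fx2$matrix)], fx2$matrix,
               ignore_attr = TRUE)

  # write-then-read is the identity
  out <- tempfile(fileext = ".txt")
  write_emg_table(rec2, out)
  rec3 <- read_emg_table(out, fs = 1000, side = "right", behavior = "AAM")
  expect_equal(rec3$matrix, rec2$matrix)
})

test_that("unknown muscle labels and malformed cells are rejected with context", {
  fx <- write_emg_fixture(n = 5)
  lines <- readLines(fx$path)
  lines[1] <- sub("^TA", "TibAnt", lines[1])  # registered alias: accepted
  writeLines(lines, fx$path)
  expect_silent(rec <- read_emg_table(fx$path, fs = 100))
  expect_identical(colnames(rec$matrix)[1], "TA")

  lines[1] <- sub("^TibAnt", "Tibialis_Foo", lines[1])
  writeLines(lines, fx$path)
  expect_error(read_emg_table(fx$path, fs = 100), "Tibialis_Foo")
  expect_error(read_emg_table(fx$path, fs = 100), "aliases")

  fx2 <- write_emg_fixture(n = 5, seed = 9)
  lines <- readLines(fx2$path)
  lines[3] <- sub("^[0-9.]+", "oops", lines[3])
  writeLines(lines, fx2$path)
  expect_error(read_emg_table(fx2$path, fs = 100), "non-numeric")
})

test_that("muscle registry partitions 14 muscles into crus/thigh/trunk", {
  reg <- muscle_registry()
  expect_length(reg$names, 14)
  expect_false(anyDuplicated(reg$names) > 0)
  segs <- split(names(reg$segment_map), reg$segment_map)
  expect_setequal(segs$crus, c("TA", "MG", "LG", "Sol"))
  expect_setequal(segs$trunk, c("ES", "ExtO", "LatDor"))
  expect_length(segs$thigh, 7)
  reg2 <- muscle_registry(segment_overrides = c(GM = "trunk"))
  expect_identical(unname(reg2$segment_map[["GM"]]), "trunk")
  expect_error(muscle_registry(segment_overrides = c(XX = "crus")), "unknown")
})

test_that("the packaged clinical table parses to the published structure", {
  cp <- clinical_pairs()
  tab <- cp$table
  expect_equal(nrow(tab), 18)
  expect_equal(sum(!is.na(tab$rhs_left)), 14)
  expect_true(all(tab$onset_age >= 0.08 & tab$onset_age <= 2))
  # two-sided entry "40.75 (41)" and single entries applying to both sides
  s1711 <- tab[tab$subject_id == "1711", ]
  expect_equal(s1711$rhs_left, 40.75)
  expect_equal(s1711$rhs_right, 41)
  s1712 <- tab[tab$subject_id == "1712", ]
  expect_equal(s1712$onset_age, 1.33)
  expect_equal(s1712$rhs_left, 48)
  expect_equal(s1712$rhs_right, 48)
  expect_equal(s1712$smn2_ex7, 2L)
  # rows with missing scores are retained
  expect_true(is.na(tab$rhs_left[tab$subject_id == "1605"]))
})

test_that("subject tables reject out-of-range motor scores", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,onset_age,rhs,tasks",
               "x1,5,1,80,W"), path)
  expect_error(read_subject_table(path), "\\[0, 72\\]")
  writeLines(c("subject_id,age,onset_age,rhs,tasks",
               "x1,0.5,1,40,W"), path)
  expect_error(read_subject_table(path), "onset_age exceeds age")
})

test_that("synergy sets round-trip losslessly with a stable content hash", {
  set.seed(4)
  W <- matrix(runif(14 * 6), 14, 6,
              dimnames = list(muscle_registry()$names, NULL))
  path <- tempfile(fileext = ".csv")
  write_synergy_set(W, meta = list(subject = "s1", side = "left"), path)
  got <- read_synergy_set(path)
  expect_equal(unname(got$W), unname(W), tolerance = 1e-12)
  expect_identical(got$meta$subject, "s1")
  expect_identical(got$meta$content_hash, got$hash)

  # identical content always hashes identically
  path2 <- tempfile(fileext = ".csv")
  write_synergy_set(W, meta = list(subject = "s1"), path2)
  expect_identical(read_synergy_set(path2)$hash, got$hash)

  expect_error(write_synergy_set(-W, path = tempfile()), "negative")
  Wz <- W; Wz[, 2] <- 0
  expect_warning(write_synergy_set(Wz, path = tempfile(fileext = ".csv")),
                 "zero column")
})
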