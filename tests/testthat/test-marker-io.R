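# Trajectory I/O, validation, gap filling and filtering.

test_that("TSV round trip is lossless and preserves missing samples", {
  tpl <- default_template()
  st <- generate_static_trial(tpl, duration_s = 0.1, noise_sd = 0.3,
                              seed = 11)
  st$positions[3, , "ST"] <- NA            # knock out one sample
  path <- tempfile(fileext = ".tsv")
  write_markers_tsv(st, path)
  back <- read_markers_tsv(path, side = "right", rate = st$rate,
                           trial_kind = "static")
  expect_identical(back$labels, st$labels)
  expect_lt(max(abs(back$positions - st$positions), na.rm = TRUE), 1e-6)
  expect_true(all(is.na(back$positions[3, , "ST"])))
  expect_false(anyNA(back$positions[2, , ]))
})

test_that("left-side series mirror on ingest and round-trip through disk", {
  tpl <- default_template()
  right <- generate_static_trial(tpl, duration_s = 0.05)
  left <- generate_static_trial(tpl, duration_s = 0.05, side = "left")
  # internal representation of a mirrored left foot equals the right foot
  expect_equal(left$positions, right$positions, tolerance = 1e-12)
  path <- tempfile(fileext = ".tsv")
  write_markers_tsv(left, path)
  back <- read_markers_tsv(path, side = "left", rate = 100,
                           trial_kind = "static")
  expect_equal(back$positions, left$positions, tolerance = 1e-12)
  # the file itself holds true (un-mirrored) lab coordinates
  raw <- read_markers_tsv(path, side = "right", rate = 100,
                          trial_kind = "static")
  expect_equal(raw$positions[1, "z", "CA"],
               -right$positions[1, "z", "CA"], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("TSV reader enforces its schema", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("frame\tCA_x\tCA_y\tCA_z\tCA_x", "1\t0\t100\t0\t0"), p)
  expect_error(read_markers_tsv(p), "not triplets|duplicated")
  writeLines(c("frame\tCA_x\tCA_y", "1\t0\t100"), p)
  expect_error(read_markers_tsv(p), "triplets")
  writeLines(c("frame\tCA_x\tCA_y\tCA_z", "2\t0\t100\t0", "1\t0\t100\t0"), p)
  expect_error(read_markers_tsv(p), "increasing")
  writeLines(c("frame\tCA_x\tCA_y\tCA_z", "1\t0\t100\t5"), p)
  s <- read_markers_tsv(p)
  expect_equal(unname(s$positions[1, , "CA"]), c(0, 100, 5))
  expect_error(write_markers_tsv(marker_series(
    array(numeric(0), c(0, 3, 1), list(NULL, NULL, "CA")), rate = 100)),
    "empty")
})

test_that("marker-set validation is report-only and flags the HL rule", {
  tpl <- default_template()
  st <- generate_static_trial(tpl, duration_s = 0.05)
  expect_true(validate_marker_set(st)$pass)

  no_hl <- st
  keep <- setdiff(st$labels, "HL")
  no_hl <- marker_series(st$positions[, , keep, drop = FALSE], rate = 100,
                         trial_kind = "static")
  rep1 <- validate_marker_set(no_hl)
  expect_false(rep1$pass)
  expect_true(any(grepl("HL", rep1$messages)))
  # the same marker set passes as a walking trial
  no_hl$trial_kind <- "walking"
  expect_true(validate_marker_set(no_hl)$pass)
  # present but never observed fails
  st2 <- st
  st2$positions[, , "ST"] <- NA
  expect_false(validate_marker_set(st2)$pass)
  # purity: validation does not mutate
  before <- st$positions
  invisible(validate_marker_set(st))
  expect_identical(st$positions, before)
})

test_that("gap filling reproduces polynomial trajectories and respects limits", {
  n <- 60
  tt <- seq_len(n)
  cubic <- 0.5 + 0.3 * tt - 0.02 * tt^2 + 1e-3 * tt^3
  arr <- array(NA_real_, c(n, 3, 1), list(NULL, NULL, "CA"))
  arr[, 1, 1] <- cubic; arr[, 2, 1] <- 100 + tt; arr[, 3, 1] <- 5
  s <- marker_series(arr, rate = 100)
  s$positions[20:25, , "CA"] <- NA                  # 6-frame interior gap
  filled <- fill_gaps(s, max_gap_frames = 10)
  expect_lt(max(abs(filled$positions[, 1, "CA"] - cubic)), 1e-6)
  # long gaps stay missing
  s2 <- s
  s2$positions[30:45, , "CA"] <- NA
  filled2 <- fill_gaps(s2, max_gap_frames = 10)
  expect_true(all(is.na(filled2$positions[30:45, 1, "CA"])))
  # leading-edge gaps are never extrapolated
  s3 <- marker_series(arr, rate = 100)
  s3$positions[1:3, , "CA"] <- NA
  filled3 <- fill_gaps(s3, max_gap_frames = 10)
  expect_true(all(is.na(filled3$positions[1:3, 1, "CA"])))
})

test_that("low-pass filter passes DC exactly and kills high frequencies", {
  n <- 500
  arr <- array(0, c(n, 3, 2), list(NULL, NULL, c("CA", "ST")))
  arr[, 1, "CA"] <- 42.5
  arr[, 2, "CA"] <- 100
  arr[, 3, "CA"] <- -7
  tt <- (seq_len(n) - 1) / 100
  arr[, 1, "ST"] <- sin(2 * pi * 40 * tt)          # 40 Hz tone
  arr[, 2, "ST"] <- 50
  arr[, 3, "ST"] <- 0
  s <- marker_series(arr, rate = 100)
  f <- lowpass_filter(s, cutoff_hz = 6)
  expect_lt(max(abs(f$positions[, 1, "CA"] - 42.5)), 1e-9)
  core <- 100:400                                   # away from the edges
  atten <- max(abs(f$positions[core, 1, "ST"]))
  expect_lt(atten, 0.01)                            # > 99 % attenuation
  expect_error(lowpass_filter(s, cutoff_hz = 60), "Nyquist")
  expect_error(lowpass_filter(s, cutoff_hz = 0), "Nyquist")
})
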