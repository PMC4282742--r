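# The forward-kinematics generator: template construction, rigidity,
# determinism, forward-inverse consistency.

test_that("template parameters are validated and realized exactly", {
  expect_error(foot_template(foot_length = 0), "foot_length")
  expect_error(foot_template(mla_static = 400), "mla_static")
  tpl <- foot_template(hindfoot_tilt = 5, mla_static = 190)
  s <- generate_static_trial(tpl, duration_s = 0.05)
  expect_equal(compute_hindfoot_frontal_offset(s), 5, tolerance = 1e-6)
  calib <- compute_static_reference(s)
  expect_equal(calib$static_angles[["MLA"]], 190, tolerance = 1e-6)
})

test_that("an arch height exists at which the arch is exactly flat", {
  tpl <- foot_template(mla_static = 180)
  s <- generate_static_trial(tpl, duration_s = 0.05)
  calib <- compute_static_reference(s)
  expect_equal(calib$static_angles[["MLA"]], 180, tolerance = 1e-6)
})

test_that("within-segment marker distances are rigid during walking", {
  tr <- default_walk()
  pos <- tr$series$positions
  segs <- list(c("CA", "PT", "ST"), c("TN", "C"),
               c("FMB", "SMB", "VMB", "FMH", "SMH", "VMH"),
               c("HF", "TT", "LM", "MM"))
  for (seg in segs) {
    for (i in seq_along(seg)) {
      for (j in seq_len(i - 1)) {
        d <- sqrt(rowSums((pos[, , seg[i]] - pos[, , seg[j]])^2))
        expect_lt(diff(range(d)), 1e-9)
      }
    }
  }
})

test_that("the same seed reproduces a trial bit for bit", {
  tpl <- default_template()
  sp <- sim_spec(n_cycles = 2, noise_sd = 0.8, seed = 99)
  a <- generate_walking_trial(tpl, sp)
  b <- generate_walking_trial(tpl, sp)
  expect_identical(a$series$positions, b$series$positions)
  st1 <- generate_static_trial(tpl, noise_sd = 0.5, seed = 7)
  st2 <- generate_static_trial(tpl, noise_sd = 0.5, seed = 7)
  expect_identical(st1$positions, st2$positions)
})

test_that("all-zero curves reduce walking to rigid whole-leg transport", {
  tpl <- default_template()
  cv <- default_joint_curves()
  for (j in names(cv)) for (c in names(cv[[j]])) {
    cv[[j]][[c]] <- list(amp = 0, phase = 0)
  }
  sp <- sim_spec(n_cycles = 2, curves = cv)
  tr <- generate_walking_trial(tpl, sp)
  calib <- default_calib()
  js <- compute_joint_series(tr$series, calib)
  # Sha-Cal is rigidly prescribed: identical to its static value throughout
  for (comp in c("dopl", "eveinv", "abdadd")) {
    expect_lt(max(abs(js$joints[["Sha-Cal"]][[comp]] -
                        calib$static_angles[[paste0("Sha-Cal:", comp)]])),
              1e-9)
  }
})

test_that("prescribed dorsiflexion sinusoids are recovered exactly", {
  tpl <- default_template()
  cv <- default_joint_curves()
  for (j in names(cv)) for (c in names(cv[[j]])) {
    cv[[j]][[c]] <- list(amp = 0, phase = 0)
  }
  cv[["Sha-Cal"]]$dopl <- list(amp = 15, phase = 0)
  sp <- sim_spec(n_cycles = 3, curves = cv)
  tr <- generate_walking_trial(tpl, sp)
  calib <- default_calib()
  js <- compute_joint_series(tr$series, calib)
  presc <- calib$static_angles[["Sha-Cal:dopl"]] +
    15 * sin(2 * pi * tr$truth$phase)
  rec <- js$joints[["Sha-Cal"]]$dopl
  expect_lt(sqrt(mean((rec - presc)^2)), 0.1)
  amp <- (max(rec) - min(rec)) / 2
  expect_equal(amp, 15, tolerance = 0.1)
})

test_that("infeasible prescriptions raise parameter errors", {
  expect_error(sim_spec(curves = list("Sha-Cal" = list(
    dopl = list(amp = 70, phase = 0)))), "60 deg")
  # a huge Chopart sagittal swing folds the chain so far that the authored
  # heel/forefoot targets leave its reachable annulus
  tpl <- default_template()
  cv <- default_joint_curves()
  cv[["Cal-Mid"]]$dopl <- list(amp = 55, phase = 0)
  sp <- sim_spec(n_cycles = 1, curves = cv)
  expect_error(generate_walking_trial(tpl, sp), "not reachable")
})

test_that("a one-participant cohort writes the expected file tree", {
  out <- file.path(tempdir(), "cohort1")
  unlink(out, recursive = TRUE)
  co <- generate_cohort(n_participants = 1, out_dir = out, seed = 5,
                        spec_args = list(n_cycles = 1))
  files <- list.files(out)
  expect_length(grep("_static\\.tsv$", files), 2)     # one per side
  expect_length(grep("_walk\\d\\.tsv$", files), 6)    # three per side
  expect_true("manifest.json" %in% files)
  # fixed seed reproduces the dataset
  out2 <- file.path(tempdir(), "cohort2")
  unlink(out2, recursive = TRUE)
  co2 <- generate_cohort(n_participants = 1, out_dir = out2, seed = 5,
                         spec_args = list(n_cycles = 1))
  f1 <- file.path(out, "P01_r_walk1.tsv")
  f2 <- file.path(out2, "P01_r_walk1.tsv")
  expect_identical(readLines(f1), readLines(f2))
})
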