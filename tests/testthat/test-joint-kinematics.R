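# Grood-Suntay decomposition, planar angles and the arch angle.

test_that("JCS decomposition handles identity and single-axis rotations", {
  I <- diag(3)
  expect_equal(unname(jcs_decompose(I, I)), c(0, 0, 0), tolerance = 1e-12)
  a <- jcs_decompose(I, jcs_compose(30, 0, 0))
  expect_equal(unname(a), c(30, 0, 0), tolerance = 1e-9)
  b <- jcs_decompose(I, jcs_compose(0, 0, -12.5))
  expect_equal(b[["eveinv"]], -12.5, tolerance = 1e-9)
  c <- jcs_decompose(I, jcs_compose(0, 7.25, 0))
  expect_equal(c[["abdadd"]], 7.25, tolerance = 1e-9)
})

test_that("decompose inverts compose on the sub-90-degree open set", {
  set.seed(13)
  for (rep in 1:200) {
    th <- runif(3, -85, 85)
    R <- jcs_compose(th[1], th[3], th[2])   # (dopl, abdadd, eveinv)
    out <- jcs_decompose(diag(3), R)
    expect_equal(unname(out), th, tolerance = 1e-9)
  }
})

test_that("decomposition matches the brute-force numerical inversion", {
  set.seed(17)
  for (rep in 1:40) {
    th <- runif(3, -45, 45)
    R <- jcs_compose(th[1], th[2], th[3])
    ora <- oracle_jcs(R)
    dec <- jcs_decompose(diag(3), R)
    expect_lt(max(abs(ora - dec[c("dopl", "abdadd", "eveinv")])), 1e-6)
  }
})

test_that("gimbal proximity warns but still returns angles", {
  R <- jcs_compose(10, 90, 5)
  expect_warning(out <- jcs_decompose(diag(3), R), "gimbal")
  expect_true(all(is.finite(out)))
})

test_that("static trial input gives constant angles equal to the statics", {
  calib <- default_calib()
  st <- generate_static_trial(default_template(), duration_s = 0.3)
  js <- compute_joint_series(st, calib)
  for (j in setdiff(names(js$joints), "Met-Hal")) {
    for (comp in c("dopl", "eveinv", "abdadd")) {
      v <- js$joints[[j]][[comp]]
      expect_lt(diff(range(v)), 1e-9)
      expect_equal(v[1], calib$static_angles[[paste0(j, ":", comp)]],
                   tolerance = 1e-9)
    }
  }
  pl <- compute_planar_angles(st, calib)
  for (a in names(pl$angles)) {
    expect_equal(pl$angles[[a]]$value_deg[1], calib$static_angles[[a]],
                 tolerance = 1e-9)
  }
})

test_that("joint angles are invariant to global rigid motion", {
  calib <- default_calib()
  walk <- default_walk()$series
  set.seed(19)
  R <- rotation_about(rnorm(3), 18)
  moved <- transform_series(walk, R, c(500, 120, -300))
  a <- compute_joint_series(walk, calib)
  b <- compute_joint_series(moved, calib)
  for (j in names(a$joints)) {
    expect_lt(max(abs(as.matrix(a$joints[[j]][, 3:5]) -
                        as.matrix(b$joints[[j]][, 3:5]))), 1e-9)
  }
})

test_that("planar metatarsal angles match constructed geometry", {
  # a 10-degree pitched first metatarsal in an otherwise flat foot
  tpl <- default_template()
  mk <- tpl$markers
  mk[, "FMB"] <- c(115, 30, -30)
  len <- 60
  mk[, "FMH"] <- mk[, "FMB"] + c(len * cos(10 * pi / 180),
                                 len * sin(10 * pi / 180), 0)
  s <- constant_series(setNames(lapply(colnames(mk), function(l) mk[, l]),
                                colnames(mk)))
  calib <- default_calib()
  pl <- compute_planar_angles(s, calib)
  # foot heading is not exactly +X, so allow the azimuth cosine correction
  expect_equal(pl$angles$F2G$value_deg[1], 10, tolerance = 0.2)

  # metatarsal parallel to the ground line -> zero pitch
  mk2 <- tpl$markers
  mk2[, "FMB"] <- c(115, 30, -30)
  mk2[, "FMH"] <- c(175, 30, -30)
  s2 <- constant_series(setNames(lapply(colnames(mk2),
                                        function(l) mk2[, l]),
                                 colnames(mk2)))
  pl2 <- compute_planar_angles(s2, calib)
  expect_equal(pl2$angles$F2G$value_deg[1], 0, tolerance = 1e-9)

  # first and second metatarsals parallel in the ground plane -> S2F = 0
  mk3 <- tpl$markers
  mk3[, "FMB"] <- mk3[, "SMB"] + c(0, -3, -25)
  mk3[, "FMH"] <- mk3[, "SMH"] + c(0, -3, -25)
  s3 <- constant_series(setNames(lapply(colnames(mk3),
                                        function(l) mk3[, l]),
                                 colnames(mk3)))
  pl3 <- compute_planar_angles(s3, calib)
  expect_equal(pl3$angles$S2F$value_deg[1], 0, tolerance = 1e-9)
  # medially deviated first ray reads positive
  mk3[, "FMH"] <- mk3[, "FMH"] + c(0, 0, -15)
  s4 <- constant_series(setNames(lapply(colnames(mk3),
                                        function(l) mk3[, l]),
                                 colnames(mk3)))
  pl4 <- compute_planar_angles(s4, calib)
  expect_gt(pl4$angles$S2F$value_deg[1], 0)
})

test_that("the arch angle reproduces the worked planar cases", {
  heading <- c(1, 0, 0)
  expect_equal(footkin:::mla_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                   heading), 180)
  expect_equal(footkin:::mla_angle(c(-60, 0, 0), c(0, 30, 0), c(60, 0, 0),
                                   heading), 126.8699, tolerance = 1e-4)
  expect_equal(footkin:::mla_angle(c(-60, 0, 0), c(0, -30, 0), c(60, 0, 0),
                                   heading), 233.1301, tolerance = 1e-4)
})

test_that("the arch angle decreases strictly as ST is raised", {
  tpl <- default_template()
  mk <- tpl$markers
  calib <- default_calib()
  heights <- seq(-15, 35, length.out = 50)
  vals <- vapply(heights, function(h) {
    st <- mk[, "ST"]; st[2] <- h
    foot <- build_foot_frame(mk[, "CA"], mk[, "FMH"], mk[, "VMH"])
    cap <- c(mk[1, "CA"], 0, mk[3, "CA"])
    footkin:::mla_angle(cap, st, mk[, "FMH"],
                        footkin:::foot_heading(foot))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ground-referenced planar angles are invariant to vertical-axis
           rotation and horizontal translation", {
  calib <- default_calib()
  walk <- default_walk()$series
  R <- rotation_about(c(0, 1, 0), 37)
  moved <- transform_series(walk, R, c(250, 0, -400))
  a <- compute_planar_angles(walk, calib)
  b <- compute_planar_angles(moved, calib)
  for (nm in names(a$angles)) {
    expect_lt(max(abs(a$angles[[nm]]$value_deg - b$angles[[nm]]$value_deg),
                  na.rm = TRUE), 1e-9)
  }
})

test_that("a mirrored left-side trial yields identical kinematics", {
  tpl <- default_template()
  calib <- default_calib()
  spec <- sim_spec(n_cycles = 2)
  r <- generate_walking_trial(tpl, spec, side = "right")$series
  l <- generate_walking_trial(tpl, spec, side = "left")$series
  ar <- compute_joint_series(r, calib)
  al <- compute_joint_series(l, calib)
  for (j in names(ar$joints)) {
    expect_lt(max(abs(as.matrix(ar$joints[[j]][, 3:5]) -
                        as.matrix(al$joints[[j]][, 3:5]))), 1e-9)
  }
  pr <- compute_planar_angles(r, calib)
  pl <- compute_planar_angles(l, calib)
  for (nm in names(pr$angles)) {
    expect_lt(max(abs(pr$angles[[nm]]$value_deg -
                        pl$angles[[nm]]$value_deg), na.rm = TRUE), 1e-9)
  }
})
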