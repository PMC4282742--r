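# Forward-kinematics generator: marker trajectories (static and walking)
# with exact ground truth for joint angles, gait events, the hindfoot
# frontal offset and the virtual heel ground-point. It is the oracle for
# every inverse computation in the package.
#
# Design: the kinematic chain is rooted at the calcaneus. Heel (CA) and
# forefoot (SMH) trajectories are authored in closed form -- raised-cosine
# velocity bumps concentrated in swing plus a small, sharp "impact dip" at
# foot strike (CA) and toe off (SMH) so that each event is a unique, curved
# local minimum of the vertical trajectory with a genuine forward-velocity
# zero crossing. The root pitch and a sagittal midfoot "elbow" correction
# are then solved per frame by exact two-link inverse kinematics, so every
# marker of every segment moves rigidly (inter-marker distances constant to
# machine precision) while both authored trajectories are honoured exactly.
# Joint-angle curves for Sha-Cal, Cal-Mid, Mid-Met and Met-Hal are sums of
# 2-3 harmonics with amplitudes shaped to resemble barefoot-walking
# patterns; they are configurable, not digitized from any reference data.

SEGMENT_MARKERS <- list(
  Shank = c("HF", "TT", "LM", "MM"),
  Calcaneus = c("CA", "HL", "PT", "ST"),
  Midfoot = c("TN", "C"),
  Metatarsus = c("FMB", "SMB", "VMB", "FMH", "SMH", "VMH"),
  Phalanx = c("PM")
)

#' Synthetic foot template
#'
#' Builds the neutral (up-right double-leg stance) geometry of one foot and
#' lower shank: 17 marker positions, joint centers of the
#' calcaneus-midfoot-metatarsus-phalanx chain plus the ankle, and the
#' neutral anatomical frames. The shank markers are laid out so that the
#' shank anatomical frame is exactly the identity, which makes the
#' constructed hindfoot tilt appear in the frontal-plane offset without
#' approximation. The sustentaculum-tali (ST) marker height is solved from
#' the requested static arch angle (the locus of ST seeing the CAp-FMH
#' chord at a fixed angle is monotone in its height), so the template's
#' static MLA is known in closed form.
#'
#' @param foot_length Heel-to-phalanx length scale in mm (default 240).
#' @param hindfoot_tilt Constructed frontal-plane tilt of the calcaneus in
#'   degrees, eversion/valgus positive; becomes the ground-truth hindfoot
#'   frontal offset.
#' @param mla_static Target static medial-longitudinal-arch angle (deg);
#'   values above 180 describe a dropped arch.
#' @param hl_offset Anterior/vertical perturbation (mm, length 2) of the HL
#'   marker placement on the heel, reflecting the acknowledged uncertainty
#'   of that landmark.
#' @return A list of class `foot_template` with `markers` (3 x 17),
#'   `joints`, `segments`, `neutral_frames`, `hindfoot_tilt`, `mla_static`.
#' @export
foot_template <- function(foot_length = 240, hindfoot_tilt = 0,
                          mla_static = 183, hl_offset = c(0, 0)) {
  if (foot_length <= 0) stop("parameter error: foot_length must be > 0",
                             call. = FALSE)
  s <- foot_length / 240
  mk <- cbind(
    CA = c(0, 55, 2), HL = c(6 + hl_offset[1], 22 + hl_offset[2], 2),
    PT = c(28, 30, 25), ST = c(35, 28, -18),
    TN = c(85, 45, -22), C = c(80, 35, 28),
    FMB = c(115, 35, -30), SMB = c(120, 38, -5), VMB = c(110, 30, 35),
    FMH = c(175, 28, -32), SMH = c(180, 25, -2), VMH = c(165, 22, 38),
    PM = c(215, 22, -28),
    LM = c(6, 62, 38), MM = c(6, 70, -32),
    TT = c(40, 370, 10), HF = c(-28, 362, -4)
  ) * s
  joints <- cbind(
    ankle = c(10, 65, 3), chopart = c(70, 32, 0),
    lisfranc = c(115, 20, 0), mpj = c(175, 25, -28)
  ) * s

  # frontal-plane tilt: rotate the calcaneus cluster about the X axis
  # through ST (so the arch landmark stays put)
  if (hindfoot_tilt != 0) {
    Rt <- rot_x(hindfoot_tilt)
    pivot <- mk[, "ST"]
    for (l in SEGMENT_MARKERS$Calcaneus) {
      mk[, l] <- pivot + Rt %*% (mk[, l] - pivot)
    }
  }

  # solve ST height for the requested static arch angle
  mk[, "ST"] <- solve_st_height(mk, mla_static)

  neutral <- segment_frames_at(mk)
  tpl <- structure(
    list(markers = mk, joints = joints, segments = SEGMENT_MARKERS,
         neutral_frames = neutral, hindfoot_tilt = hindfoot_tilt,
         mla_static = mla_static, foot_length = foot_length),
    class = "foot_template"
  )
  tpl
}

# ST height from a target MLA, all other template geometry fixed. MLA is
# strictly decreasing in the ST height, so 1-D root finding is safe.
solve_st_height <- function(mk, mla_target) {
  if (!is.finite(mla_target) || mla_target <= 60 || mla_target >= 300) {
    stop("parameter error: mla_static must lie in (60, 300) deg",
         call. = FALSE)
  }
  st <- mk[, "ST"]
  mla_of <- function(y) {
    p <- st; p[2] <- y
    foot <- build_foot_frame(mk[, "CA"], mk[, "FMH"], mk[, "VMH"])
    cap <- c(mk[1, "CA"], 0, mk[3, "CA"])
    mla_angle(cap, p, mk[, "FMH"], foot_heading(foot))
  }
  lo <- -60; hi <- 120
  f_lo <- mla_of(lo) - mla_target
  f_hi <- mla_of(hi) - mla_target
  if (sign(f_lo) == sign(f_hi)) {
    stop("parameter error: mla_static unreachable for this geometry",
         call. = FALSE)
  }
  y <- stats::uniroot(function(v) mla_of(v) - mla_target, c(lo, hi),
                      tol = 1e-12)$root
  st[2] <- y
  st
}

#' Harmonic joint-angle curve set
#'
#' Default per-joint curves over the gait cycle: each component is a sum of
#' 2-3 sinusoidal harmonics of the cycle phase (`sum(amp * sin(2*pi*k*phase
#' + phase_k))`). Amplitudes are in degrees and stay well below the 60-deg
#' validity bound of the composition.
#'
#' @return Nested list `curves[[joint]][[component]] = list(amp, phase)`.
#' @export
default_joint_curves <- function() {
  h <- function(amp, phase) list(amp = amp, phase = phase)
  list(
    "Sha-Cal" = list(
      dopl = h(c(6, 3), c(3.6, 0.8)),
      eveinv = h(c(3, 1.5), c(2.0, 0.0)),
      abdadd = h(c(2), c(1.0))
    ),
    "Cal-Mid" = list(
      dopl = h(c(4, 2), c(3.2, 1.1)),
      eveinv = h(c(2), c(2.4)),
      abdadd = h(c(1.5), c(0.6))
    ),
    "Mid-Met" = list(
      dopl = h(c(3), c(3.9)),
      eveinv = h(c(1.5), c(1.3)),
      abdadd = h(c(1), c(2.2))
    ),
    "Met-Hal" = list(
      dopl = h(c(8, 6), c(4.5, 1.2)),
      eveinv = h(c(1), c(0.5)),
      abdadd = h(c(2), c(2.8))
    )
  )
}

eval_curve <- function(cv, phase) {
  out <- numeric(length(phase))
  for (k in seq_along(cv$amp)) {
    out <- out + cv$amp[k] * sin(2 * pi * k * phase + cv$phase[k])
  }
  out
}

#' Walking simulation specification
#'
#' @param cadence_hz Gait-cycle frequency (cycles/s); self-selected walking
#'   is near 0.8-1.2 Hz.
#' @param n_cycles Number of complete gait cycles.
#' @param stride_mm Stride length (mm per cycle).
#' @param rate Sampling rate in Hz.
#' @param noise_sd Isotropic Gaussian marker noise SD (mm); 0 = exact.
#' @param first_strike_s Time of the first foot strike (s).
#' @param tail_s Extra recording after the last strike (s).
#' @param toe_off_phase Toe-off position within the cycle (fraction).
#' @param curves Joint-angle curves, see [default_joint_curves()].
#' @param seed Optional RNG seed (noise only); same seed, same series.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(cadence_hz = 1.0, n_cycles = 3, stride_mm = 1150,
                     rate = 100, noise_sd = 0, first_strike_s = 0.35,
                     tail_s = 0.3, toe_off_phase = 0.6,
                     curves = default_joint_curves(), seed = NULL) {
  stopifnot(cadence_hz > 0, n_cycles >= 1, rate > 0, noise_sd >= 0,
            toe_off_phase > 0.3, toe_off_phase < 0.9)
  for (j in names(curves)) {
    for (comp in names(curves[[j]])) {
      if (sum(abs(curves[[j]][[comp]]$amp)) >= 60) {
        stop("parameter error: curve amplitude bound (60 deg) violated for ",
             j, " ", comp, call. = FALSE)
      }
    }
  }
  structure(list(cadence_hz = cadence_hz, n_cycles = n_cycles,
                 stride_mm = stride_mm, rate = rate, noise_sd = noise_sd,
                 first_strike_s = first_strike_s, tail_s = tail_s,
                 toe_off_phase = toe_off_phase, curves = curves,
                 seed = seed),
            class = "sim_spec")
}

# Periodic raised-cosine bump of unit peak, center c, full width w (cycle
# fractions), and its running integral from phase 0 (exact, piecewise).
bump <- function(phase, c, w) {
  d <- (phase - c) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  ifelse(abs(d) < w / 2, 0.5 * (1 + cos(2 * pi * d / w)), 0)
}

bump_integral <- function(phase, c, w) {
  # integral of bump over [0, phase] for arbitrary real phase >= (or <) 0
  piece <- function(t1, t2, k) {
    lo <- pmax(t1, k + c - w / 2); hi <- pmin(t2, k + c + w / 2)
    len <- pmax(0, hi - lo)
    ifelse(len > 0,
           0.5 * (len + (w / (2 * pi)) *
                    (sin(2 * pi * (hi - k - c) / w) -
                       sin(2 * pi * (lo - k - c) / w))),
           0)
  }
  out <- numeric(length(phase))
  kr <- floor(min(0, phase, na.rm = TRUE)) - 1
  ks <- seq(kr, ceiling(max(0, phase, na.rm = TRUE)) + 1)
  for (k in ks) {
    out <- out + ifelse(phase >= 0, piece(0, phase, k), -piece(phase, 0, k))
  }
  out
}

# Authored event-signal trajectories of the heel (CA) and forefoot (SMH)
# markers, as closed-form functions of the cycle phase. The heel is fully
# authored (advance concentrated in swing, a small sharp "impact dip" at
# strike giving a unique curved vertical minimum and a forward-velocity
# zero crossing); the forefoot height is authored the same way around toe
# off, and the forefoot advance is derived from a near-constant sagittal
# heel-forefoot chord (the foot pitches rather than stretches), which keeps
# the targets inside the reach of the two-link chain while still producing
# the negative-to-positive forefoot velocity crossing at toe off.
event_profiles <- function(tpl, spec) {
  to <- spec$toe_off_phase
  S <- spec$stride_mm
  y_ca0 <- tpl$markers[2, "CA"]
  y_sm0 <- tpl$markers[2, "SMH"]
  L0 <- sqrt((tpl$markers[1, "SMH"] - tpl$markers[1, "CA"])^2 +
               (y_sm0 - y_ca0)^2)
  b_dip <- 0.217; w_dip <- 0.04
  a_ca <- (1 + b_dip * w_dip / 2) / (0.38 / 2)
  ca_x <- function(ph) S * (a_ca * bump_integral(ph, 0.80, 0.38) -
                              b_dip * bump_integral(ph, 0, w_dip))
  ca_y <- function(ph) y_ca0 + 55 * bump(ph, 0.78, 0.40) -
    4 * bump(ph, 0, 0.07)
  smh_y <- function(ph) y_sm0 + 70 * bump(ph, to + 0.215, 0.43) -
    8 * bump(ph, to, 0.07)
  chord <- function(ph) L0 - 2 * bump(ph, 0.68, 0.55)   # mild arch loading
  list(
    ca_x = ca_x, ca_y = ca_y,
    ca_z = function(ph) tpl$markers[3, "CA"] + 10 * sin(2 * pi * ph),
    smh_y = smh_y,
    smh_x = function(ph) {
      dy <- ca_y(ph) - smh_y(ph)
      ca_x(ph) + (sqrt(pmax(0, chord(ph)^2 - dy^2)) -
                    (tpl$markers[1, "SMH"] - tpl$markers[1, "CA"]))
    }
  )
}

#' Generate one synthetic walking trial
#'
#' Produces marker trajectories at the requested rate together with the
#' exact ground truth: per-frame joint angles of all six joints (as defined
#' by the model's marker-based frames, evaluated on the noise-free
#' trajectories), foot-strike and toe-off frames, and the tracked CAp
#' position. Optional isotropic Gaussian noise is added per marker
#' coordinate after the exact trajectories are built.
#'
#' @param tpl A [foot_template()].
#' @param spec A [sim_spec()].
#' @param side `"right"` or `"left"`; left trials are emitted mirrored.
#' @param include_hl Keep the static-only HL marker in the output.
#' @return List with `series` (a [marker_series()]) and `truth` (list:
#'   `joints`, `foot_strikes`, `toe_offs`, `cap`, `phase`).
#' @export
generate_walking_trial <- function(tpl, spec = sim_spec(), side = "right",
                                   include_hl = FALSE) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rate <- spec$rate
  f <- spec$cadence_hz
  t_end <- spec$first_strike_s + spec$n_cycles / f + spec$tail_s
  nf <- floor(t_end * rate) + 1
  t <- (seq_len(nf) - 1) / rate
  phase <- (t - spec$first_strike_s) * f

  prof <- event_profiles(tpl, spec)
  exact <- pose_chain(tpl, spec, phase, prof)

  labels <- colnames(tpl$markers)
  if (!include_hl) labels <- setdiff(labels, "HL")
  pos <- exact$positions[, , labels, drop = FALSE]
  if (spec$noise_sd > 0) {
    pos <- pos + array(rnorm(length(pos), sd = spec$noise_sd), dim(pos))
  }
  if (side == "left") pos[, 3, ] <- -pos[, 3, ]
  series <- marker_series(pos, rate = rate, side = side,
                          trial_kind = "walking", labels = labels)

  strikes <- round(spec$first_strike_s * rate +
                     (0:spec$n_cycles) / f * rate) + 1
  to_star <- toe_off_phase_star(tpl, spec)
  toe_offs <- round((spec$first_strike_s + (0:(spec$n_cycles - 1) + to_star) / f) *
                      rate) + 1
  truth <- list(joints = exact$joints, foot_strikes = strikes,
                toe_offs = toe_offs, cap = exact$cap, phase = phase)
  list(series = series, truth = truth)
}

# continuous phase of the true toe-off (argmin of the authored forefoot
# vertical trajectory near the nominal toe-off phase)
toe_off_phase_star <- function(tpl, spec) {
  prof <- event_profiles(tpl, spec)
  stats::optimize(prof$smh_y, spec$toe_off_phase + c(-0.06, 0.06))$minimum
}

# Forward kinematics of the whole chain for a vector of phases. Returns the
# exact marker array, per-frame joint-angle truth and CAp truth.
pose_chain <- function(tpl, spec, phase, prof) {
  mk <- tpl$markers
  labels <- colnames(mk)
  nf <- length(phase)
  A <- lapply(tpl$neutral_frames, `[[`, "axes")
  jc <- tpl$joints
  ca0 <- mk[, "CA"]
  cap0 <- c(ca0[1], 0, ca0[3])

  # static JCS offsets of the prescribed joints
  th0 <- list(
    "Sha-Cal" = jcs_decompose(A$Shank, A$Calcaneus),
    "Cal-Mid" = jcs_decompose(A$Calcaneus, A$Midfoot),
    "Mid-Met" = jcs_decompose(A$Midfoot, A$Metatarsus),
    "Met-Hal" = jcs_decompose(A$Metatarsus, A$Phalanx)
  )
  curve_at <- function(joint, ph) {
    cvs <- spec$curves[[joint]]
    base <- th0[[joint]]
    rbind(dopl = base[["dopl"]] + eval_curve(cvs$dopl, ph),
          eveinv = base[["eveinv"]] + eval_curve(cvs$eveinv, ph),
          abdadd = base[["abdadd"]] + eval_curve(cvs$abdadd, ph))
  }
  th_shacal <- curve_at("Sha-Cal", phase)
  th_calmid <- curve_at("Cal-Mid", phase)
  th_midmet <- curve_at("Mid-Met", phase)
  th_methal <- curve_at("Met-Hal", phase)

  ca_t <- cbind(prof$ca_x(phase) + ca0[1], prof$ca_y(phase),
                prof$ca_z(phase))
  smh_t <- cbind(prof$smh_x(phase) + mk[1, "SMH"], prof$smh_y(phase))

  positions <- array(NA_real_, c(nf, 3, length(labels)),
                     dimnames = list(NULL, c("x", "y", "z"), labels))
  cap <- matrix(NA_real_, nf, 3)
  joints_truth <- lapply(JOINT_NAMES, function(j)
    matrix(NA_real_, nf, 3, dimnames = list(NULL,
                                            c("dopl", "eveinv", "abdadd"))))
  names(joints_truth) <- JOINT_NAMES

  prev_delta <- 0
  prev_frames <- NULL
  for (i in seq_len(nf)) {
    Q_cm <- jcs_compose(th_calmid[1, i], th_calmid[3, i], th_calmid[2, i])
    Q_mm <- jcs_compose(th_midmet[1, i], th_midmet[3, i], th_midmet[2, i])
    Q_mh <- jcs_compose(th_methal[1, i], th_methal[3, i], th_methal[2, i])
    Q_sc <- jcs_compose(th_shacal[1, i], th_shacal[3, i], th_shacal[2, i])

    M1 <- A$Calcaneus %*% Q_cm %*% t(A$Midfoot)        # W_mid for rho = 0
    M2 <- M1 %*% A$Midfoot %*% Q_mm %*% t(A$Metatarsus)

    u <- (jc[, "chopart"] - ca0) + M1 %*% (jc[, "lisfranc"] - jc[, "chopart"])
    w <- M2 %*% (mk[, "SMH"] - jc[, "lisfranc"])
    s2 <- smh_t[i, ] - ca_t[i, 1:2]
    u2 <- u[1:2]; w2 <- w[1:2]
    K <- (sum(s2^2) - sum(u2^2) - sum(w2^2)) / 2
    Aq <- sum(u2 * w2)
    Bq <- u2[1] * w2[2] - u2[2] * w2[1]
    Ramp <- sqrt(Aq^2 + Bq^2)
    if (abs(K) > Ramp + 1e-9) {
      stop("parameter error: authored heel/forefoot trajectories are not ",
           "reachable by the kinematic chain (frame ", i, ")", call. = FALSE)
    }
    base_ang <- atan2(Bq, Aq)
    acosv <- acos(clamp1(K / Ramp))
    cand <- c(acosv - base_ang, -acosv - base_ang)
    cand <- (cand + pi) %% (2 * pi) - pi
    delta <- cand[which.min(abs(cand - prev_delta))]
    prev_delta <- delta
    Rd <- rot_z(rad2deg(delta))
    q <- u2 + c(cos(delta) * w2[1] - sin(delta) * w2[2],
                sin(delta) * w2[1] + cos(delta) * w2[2])
    rho <- atan2(s2[2], s2[1]) - atan2(q[2], q[1])
    Rr <- rot_z(rad2deg(rho))

    W_cal <- Rr
    W_mid <- Rr %*% M1
    W_met <- Rr %*% Rd %*% M2
    D_cal <- W_cal %*% A$Calcaneus
    D_met <- W_met %*% A$Metatarsus
    D_phal <- D_met %*% Q_mh
    W_phal <- D_phal %*% t(A$Phalanx)
    D_shank <- D_cal %*% t(Q_sc)
    W_shank <- D_shank %*% t(A$Shank)

    Tr <- ca_t[i, ]
    p_ankle <- Tr + W_cal %*% (jc[, "ankle"] - ca0)
    p_c1 <- Tr + W_cal %*% (jc[, "chopart"] - ca0)
    p_c2 <- p_c1 + W_mid %*% (jc[, "lisfranc"] - jc[, "chopart"])
    p_c3 <- p_c2 + W_met %*% (jc[, "mpj"] - jc[, "lisfranc"])

    place <- function(seg, W, origin_lab, origin0) {
      for (l in tpl$segments[[seg]]) {
        positions[i, , l] <<- origin_lab + W %*% (mk[, l] - origin0)
      }
    }
    place("Calcaneus", W_cal, Tr, ca0)
    place("Midfoot", W_mid, p_c1, jc[, "chopart"])
    place("Metatarsus", W_met, p_c2, jc[, "lisfranc"])
    place("Phalanx", W_phal, p_c3, jc[, "mpj"])
    place("Shank", W_shank, p_ankle, jc[, "ankle"])
    cap[i, ] <- Tr + W_cal %*% (cap0 - ca0)

    # ground-truth joint angles: the model defines its frames from markers
    # (two of them mix segments), so truth is the JCS of the frames built
    # from the exact marker positions
    frames <- segment_frames_at(
      matrix(positions[i, , ], nrow = 3,
             dimnames = list(c("x", "y", "z"), labels)),
      prev = prev_frames)
    prev_frames <- frames
    for (j in JOINT_NAMES) {
      pr <- JOINT_PAIRS[[j]]
      joints_truth[[j]][i, ] <- jcs_decompose(frames[[pr[1]]],
                                              frames[[pr[2]]])
    }
  }
  list(positions = positions, cap = cap, joints = joints_truth)
}

#' Generate a synthetic static (up-right stance) trial
#'
#' The neutral template pose repeated for `duration_s`, with optional
#' marker noise; includes the static-only HL marker.
#'
#' @param tpl A [foot_template()].
#' @param duration_s Length of the trial in seconds.
#' @param rate Sampling rate (Hz).
#' @param noise_sd Marker noise SD (mm).
#' @param side `"right"` or `"left"`.
#' @param seed Optional RNG seed.
#' @return A static [marker_series()].
#' @export
generate_static_trial <- function(tpl, duration_s = 2, rate = 100,
                                  noise_sd = 0, side = "right",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nf <- max(1L, as.integer(round(duration_s * rate)))
  labels <- colnames(tpl$markers)
  pos <- array(rep(as.vector(tpl$markers), each = nf),
               c(nf, 3, length(labels)),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  if (noise_sd > 0) {
    pos <- pos + array(rnorm(length(pos), sd = noise_sd), dim(pos))
  }
  if (side == "left") pos[, 3, ] <- -pos[, 3, ]
  marker_series(pos, rate = rate, side = side, trial_kind = "static",
                labels = labels)
}

#' Generate a synthetic cohort dataset
#'
#' One static and `n_walking` walking trials per foot, for
#' `n_participants` participants with both feet, with per-foot hindfoot
#' tilts and static arch angles either supplied or drawn. Trials are
#' written as TSV files under `out_dir` together with a JSON manifest of
#' the ground truth; the trials are also returned in memory.
#'
#' @param n_participants Number of participants (2 feet each).
#' @param out_dir Optional output directory; NULL = in-memory only.
#' @param tilts Optional numeric vector (length `2 * n_participants`) of
#'   hindfoot tilts (deg); drawn from N(0.5, 3^2) when NULL.
#' @param mlas Optional vector of static MLA targets (deg); drawn from
#'   N(183, 16^2) when NULL.
#' @param n_walking Walking trials per foot.
#' @param noise_sd Marker noise SD (mm).
#' @param seed RNG seed for the whole dataset.
#' @param spec_args Extra arguments passed to [sim_spec()].
#' @return List of class `synthetic_cohort`: per-foot entries with
#'   `participant`, `side`, `tilt`, `mla`, `static`, `walking` (list),
#'   `truth` (list), plus `manifest`.
#' @export
generate_cohort <- function(n_participants = 10, out_dir = NULL,
                            tilts = NULL, mlas = NULL, n_walking = 3,
                            noise_sd = 0, seed = 1, spec_args = list()) {
  if (n_participants < 1) stop("parameter error: n_participants >= 1",
                               call. = FALSE)
  set.seed(seed)
  n_feet <- 2 * n_participants
  if (is.null(tilts)) tilts <- rnorm(n_feet, 0.5, 3)
  if (is.null(mlas)) mlas <- rnorm(n_feet, 183, 16)
  stopifnot(length(tilts) == n_feet, length(mlas) == n_feet)

  feet <- list()
  manifest <- list(seed = seed, feet = list())
  idx <- 0
  for (p in seq_len(n_participants)) {
    for (side in c("left", "right")) {
      idx <- idx + 1
      tpl <- foot_template(hindfoot_tilt = tilts[idx],
                           mla_static = mlas[idx])
      static <- generate_static_trial(tpl, noise_sd = noise_sd, side = side,
                                      seed = seed * 1000 + idx)
      walking <- vector("list", n_walking)
      truth <- vector("list", n_walking)
      for (k in seq_len(n_walking)) {
        sp <- do.call(sim_spec, c(list(
          noise_sd = noise_sd,
          cadence_hz = 0.9 + 0.2 * ((idx + k) %% 3) / 2,
          seed = seed * 10000 + idx * 10 + k), spec_args))
        trial <- generate_walking_trial(tpl, sp, side = side)
        walking[[k]] <- trial$series
        truth[[k]] <- trial$truth
      }
      foot_id <- sprintf("P%02d_%s", p, substr(side, 1, 1))
      feet[[foot_id]] <- list(participant = p, side = side,
                              tilt = tilts[idx], mla = mlas[idx],
                              static = static, walking = walking,
                              truth = truth)
      manifest$feet[[foot_id]] <- list(
        participant = p, side = side, hindfoot_tilt = tilts[idx],
        mla_static = mlas[idx],
        foot_strikes = lapply(truth, `[[`, "foot_strikes"),
        toe_offs = lapply(truth, `[[`, "toe_offs"))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(feet)) {
      ft <- feet[[id]]
      write_markers_tsv(ft$static, file.path(out_dir,
                                             paste0(id, "_static.tsv")))
      for (k in seq_along(ft$walking)) {
        write_markers_tsv(ft$walking[[k]],
                          file.path(out_dir, sprintf("%s_walk%d.tsv", id, k)))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(feet = feet, manifest = manifest, seed = seed),
            class = "synthetic_cohort")
}
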