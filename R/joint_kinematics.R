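# Grood-Suntay joint coordinate system decomposition and planar angles.
#
# For foot segments the long (antero-posterior) axis is X, so the JCS is
# anchored on e1 = proximal Z (flexion axis) and e3 = distal X, with the
# floating axis e2 = e3 x e1 carrying ab-/adduction. This is algebraically
# the intrinsic Z-Y'-X'' Euler factorization of the relative rotation
# Rrel = t(R_proximal) %*% R_distal:
#     Rrel = Rz(dopl) %*% Ry(abdadd) %*% Rx(eveinv)
# With the lab conventions (X forward, Y up, Z right, left feet mirrored)
# the standard Euler signs give dorsiflexion +, adduction +, inversion +.

JOINT_NAMES <- c("Sha-Foo", "Sha-Cal", "Cal-Mid", "Mid-Met", "Cal-Met",
                 "Met-Hal")
JOINT_PAIRS <- list(
  "Sha-Foo" = c("Shank", "Foot"),
  "Sha-Cal" = c("Shank", "Calcaneus"),
  "Cal-Mid" = c("Calcaneus", "Midfoot"),
  "Mid-Met" = c("Midfoot", "Metatarsus"),
  "Cal-Met" = c("Calcaneus", "Metatarsus"),
  "Met-Hal" = c("Metatarsus", "Phalanx")
)
PLANAR_NAMES <- c("F2G", "S2G", "V2G", "S2F", "S2V", "F2Ps", "F2Pt", "MLA")
REPORTED_JOINTS <- setdiff(JOINT_NAMES, "Met-Hal")

#' Compose a rotation from joint-coordinate-system angles
#'
#' Forward constructor of the JCS: builds the relative rotation of a distal
#' segment with respect to its proximal segment from dorsi-/plantar-flexion
#' (about the proximal Z axis), ab-/adduction (floating axis) and
#' eversion/inversion (about the distal X axis), all in degrees.
#' [jcs_decompose()] inverts it on the open set where every angle magnitude
#' is below 90 degrees.
#'
#' @param dopl,abdadd,eveinv Angles in degrees (dorsiflexion, adduction and
#'   inversion positive).
#' @return A 3x3 rotation matrix.
#' @export
jcs_compose <- function(dopl, abdadd, eveinv) {
  rot_z(dopl) %*% rot_y(abdadd) %*% rot_x(eveinv)
}

#' Decompose a relative rotation into joint-coordinate-system angles
#'
#' @param R_proximal,R_distal 3x3 orthonormal axis triads (columns X, Y, Z)
#'   of the proximal and distal anatomical frames, or a [segment_pose()].
#' @return Named numeric of length 3: `dopl`, `eveinv`, `abdadd` in degrees.
#'   Near the gimbal lock of the floating axis (|abdadd| within 1e-6 deg of
#'   90) a warning is raised and the angles are still returned.
#' @export
jcs_decompose <- function(R_proximal, R_distal) {
  if (inherits(R_proximal, "segment_pose")) R_proximal <- R_proximal$axes
  if (inherits(R_distal, "segment_pose")) R_distal <- R_distal$axes
  rel <- crossprod(R_proximal, R_distal)
  s <- clamp1(-rel[3, 1])
  abdadd <- asin(s)
  if (90 - abs(rad2deg(abdadd)) < 1e-6) {
    warning("joint angles at gimbal singularity (|abdadd| ~ 90 deg)",
            call. = FALSE)
  }
  dopl <- atan2(rel[2, 1], rel[1, 1])
  eveinv <- atan2(rel[3, 2], rel[3, 3])
  c(dopl = rad2deg(dopl), eveinv = rad2deg(eveinv),
    abdadd = rad2deg(abdadd))
}

#' Three-dimensional joint rotations for one trial
#'
#' Builds the anatomical frames of every segment at each frame (with
#' frame-to-frame sign continuity of the plane normals) and decomposes the
#' six joints of the model: the whole foot and the calcaneus relative to the
#' shank (Sha-Foo, Sha-Cal), the Chopart and Lisfranc joints (Cal-Mid,
#' Mid-Met), the metatarsus relative to the calcaneus (Cal-Met) and the
#' first metatarso-phalangeal joint (Met-Hal). Frames with missing or
#' degenerate markers yield missing samples.
#'
#' @param walking A [marker_series()] (walking or static).
#' @param calib Optional [static_calibration()]; not needed for the raw JCS
#'   curves but accepted for interface symmetry with the planar angles.
#' @return A list of class `joint_angle_series`: for each joint a data frame
#'   with columns `frame`, `time_s`, `dopl`, `eveinv`, `abdadd` (deg).
#' @export
compute_joint_series <- function(walking, calib = NULL) {
  nf <- n_frames(walking)
  out <- lapply(JOINT_NAMES, function(j) {
    data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / walking$rate,
               dopl = NA_real_, eveinv = NA_real_, abdadd = NA_real_)
  })
  names(out) <- JOINT_NAMES
  prev <- NULL
  for (f in seq_len(nf)) {
    frames <- frames_at_or_null(walking, f, prev)
    if (is.null(frames)) next
    prev <- frames
    for (j in JOINT_NAMES) {
      pr <- JOINT_PAIRS[[j]]
      ang <- jcs_decompose(frames[[pr[1]]], frames[[pr[2]]])
      out[[j]][f, c("dopl", "eveinv", "abdadd")] <- ang
    }
  }
  structure(list(joints = out, rate = walking$rate, side = walking$side),
            class = "joint_angle_series")
}

frames_at_or_null <- function(series, f, prev = NULL) {
  pos <- frame_positions(series, f)
  need <- intersect(RFM_MARKERS_WALKING, series$labels)
  if (length(need) < length(RFM_MARKERS_WALKING)) {
    stop("series lacks required markers: ",
         paste(setdiff(RFM_MARKERS_WALKING, series$labels), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(pos[, RFM_MARKERS_WALKING]))) return(NULL)
  tryCatch(segment_frames_at(pos, prev = prev), error = function(e) NULL)
}

# Horizontal heading of the foot sagittal plane at one frame: unit vector of
# the foot X axis with its vertical component removed.
foot_heading <- function(foot_pose) {
  h <- foot_pose$axes[, "X"]
  h[2] <- 0
  if (vnorm(h) < 1e-9) {
    stop("degenerate foot heading: foot X axis is vertical", call. = FALSE)
  }
  vunit(h)
}

# Project a lab point into the foot sagittal plane -> (horizontal, vertical).
sagittal_coords <- function(p, heading) {
  c(sum(p * heading), p[2])
}

#' Planar angles for one trial
#'
#' Computes the eight planar angles of the model per frame:
#' \describe{
#'   \item{F2G, S2G, V2G}{sagittal-plane pitch of the 1st, 2nd and 5th
#'     metatarsal (base-to-head vector projected into the foot sagittal
#'     plane, angle to the ground line, head-up positive);}
#'   \item{S2F, S2V}{transverse-plane angle of the 1st (resp. 5th)
#'     metatarsal to the 2nd, both projected onto the ground plane, positive
#'     when the ray deviates medially from the 2nd;}
#'   \item{F2Ps, F2Pt}{sagittal and transverse components of the first
#'     metatarso-phalangeal joint (Met-Hal dorsiflexion and adduction);}
#'   \item{MLA}{medial longitudinal arch angle, see [compute_mla()].}
#' }
#'
#' @param walking A [marker_series()].
#' @param calib A [static_calibration()] (required for the MLA, which tracks
#'   the virtual heel ground-point).
#' @return A list of class `planar_angle_series`: a data frame per angle with
#'   columns `frame`, `time_s`, `value_deg`.
#' @export
compute_planar_angles <- function(walking, calib) {
  nf <- n_frames(walking)
  vals <- matrix(NA_real_, nf, length(PLANAR_NAMES),
                 dimnames = list(NULL, PLANAR_NAMES))
  cap <- track_cap(walking, calib)
  prev <- NULL
  for (f in seq_len(nf)) {
    frames <- frames_at_or_null(walking, f, prev)
    if (is.null(frames)) next
    prev <- frames
    pos <- frame_positions(walking, f)
    heading <- foot_heading(frames$Foot)
    vals[f, "F2G"] <- met_pitch(pos[, "FMB"], pos[, "FMH"], heading)
    vals[f, "S2G"] <- met_pitch(pos[, "SMB"], pos[, "SMH"], heading)
    vals[f, "V2G"] <- met_pitch(pos[, "VMB"], pos[, "VMH"], heading)
    vals[f, "S2F"] <- transverse_deviation(pos[, "FMB"], pos[, "FMH"],
                                           pos[, "SMB"], pos[, "SMH"])
    vals[f, "S2V"] <- transverse_deviation(pos[, "VMB"], pos[, "VMH"],
                                           pos[, "SMB"], pos[, "SMH"])
    mh <- jcs_decompose(frames$Metatarsus, frames$Phalanx)
    vals[f, "F2Ps"] <- mh[["dopl"]]
    vals[f, "F2Pt"] <- mh[["abdadd"]]
    if (!any(is.na(cap[f, ]))) {
      vals[f, "MLA"] <- mla_angle(cap[f, ], pos[, "ST"], pos[, "FMH"],
                                  heading)
    }
  }
  out <- lapply(PLANAR_NAMES, function(nm) {
    data.frame(frame = seq_len(nf), time_s = (seq_len(nf) - 1) / walking$rate,
               value_deg = vals[, nm])
  })
  names(out) <- PLANAR_NAMES
  structure(list(angles = out, rate = walking$rate, side = walking$side),
            class = "planar_angle_series")
}

# Sagittal pitch of a metatarsal: base-to-head vector projected into the
# foot sagittal plane, signed angle to the ground line (head up positive).
met_pitch <- function(base, head, heading) {
  v <- head - base
  h <- sum(v * heading)
  if (abs(h) < 1e-9 && abs(v[2]) < 1e-9) return(NA_real_)
  rad2deg(atan2(v[2], h))
}

# Transverse-plane deviation of ray a (base->head) from ray b, both
# projected onto the ground plane; positive toward medial (-Z).
transverse_deviation <- function(a_base, a_head, b_base, b_head) {
  a <- a_head - a_base; a[2] <- 0
  b <- b_head - b_base; b[2] <- 0
  if (vnorm(a) < 1e-9 || vnorm(b) < 1e-9) return(NA_real_)
  rad2deg(atan2(vcross(b, a)[2], sum(a * b)))
}

# MLA angle at ST between the rays to CAp and to FMH, all projected into the
# foot sagittal plane. If ST projects on the dorsal side of the CAp-FMH
# chord the interior angle is returned; if it has dropped below the chord
# (collapsed arch) the reflex angle 360 - interior is returned, so flat or
# fallen arches read >= 180 deg.
mla_angle <- function(cap, st, fmh, heading) {
  p_cap <- sagittal_coords(cap, heading)
  p_st <- sagittal_coords(st, heading)
  p_fmh <- sagittal_coords(fmh, heading)
  u <- p_cap - p_st
  v <- p_fmh - p_st
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) return(NA_real_)
  interior <- rad2deg(acos(clamp1(sum(u * v) / (nu * nv))))
  chord <- p_fmh - p_cap
  if (sqrt(sum(chord^2)) < 1e-9) return(NA_real_)
  # 2D cross product > 0 <=> ST above (dorsal to) the CAp->FMH chord,
  # with the chord oriented heel-to-forefoot
  above <- chord[1] * (p_st[2] - p_cap[2]) -
    chord[2] * (p_st[1] - p_cap[1]) > 0
  if (above) interior else 360 - interior
}

#' Medial longitudinal arch angle for one trial
#'
#' The MLA is measured at the sustentaculum tali (ST) between the rays to
#' CAp -- the vertical projection of the heel marker CA on the ground in the
#' static posture, tracked during walking by the calcaneus technical frame --
#' and to the first metatarsal head (FMH), all projected into the sagittal
#' plane of the foot. Values above 180 deg indicate an arch apex dropped
#' below the heel-to-forefoot chord, as in the flat foot.
#'
#' @param walking A [marker_series()].
#' @param calib A [static_calibration()].
#' @return A data frame with columns `frame`, `time_s`, `value_deg`.
#' @export
compute_mla <- function(walking, calib) {
  compute_planar_angles(walking, calib)$angles$MLA
}

#' Tidy export of angle series
#'
#' Flattens joint and/or planar angle series into a long data frame with
#' columns `trial`, `name`, `component`, `frame`, `time_s`, `value_deg`,
#' ready for CSV export.
#'
#' @param joints A `joint_angle_series` from [compute_joint_series()], or
#'   NULL.
#' @param planar A `planar_angle_series` from [compute_planar_angles()], or
#'   NULL.
#' @param trial Trial identifier stored in the `trial` column.
#' @return A long data frame.
#' @export
angles_long <- function(joints = NULL, planar = NULL, trial = "trial") {
  rows <- list()
  if (!is.null(joints)) {
    for (j in names(joints$joints)) {
      d <- joints$joints[[j]]
      for (comp in c("dopl", "eveinv", "abdadd")) {
        rows[[length(rows) + 1]] <- data.frame(
          trial = trial, name = j, component = comp, frame = d$frame,
          time_s = d$time_s, value_deg = d[[comp]])
      }
    }
  }
  if (!is.null(planar)) {
    for (a in names(planar$angles)) {
      d <- planar$angles[[a]]
      rows[[length(rows) + 1]] <- data.frame(
        trial = trial, name = a, component = "planar", frame = d$frame,
        time_s = d$time_s, value_deg = d$value_deg)
    }
  }
  do.call(rbind, rows)
}
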