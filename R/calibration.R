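# Static calibration: products of the up-right double-leg standing trial.
# Three quantities are derived once per foot and reused for every walking
# trial: (1) the hindfoot frontal-plane offset measured from the additional
# heel-base marker HL, (2) the virtual point CAp (vertical projection of CA
# on the ground) with its coordinates in the calcaneus technical frame, and
# (3) the static reference value of every joint and planar angle.

#' Static calibration container
#'
#' @param hindfoot_frontal_offset Frontal-plane offset of the calcaneus
#'   relative to the shank, degrees, eversion/valgus positive.
#' @param cap_local CAp expressed in the calcaneus technical frame (mm).
#' @param static_angles Named numeric: the 15 joint components (5 joints x
#'   dopl/eveinv/abdadd) and 8 planar angles in the static posture (deg).
#' @param side `"left"` or `"right"`.
#' @return An object of class `static_calibration`.
#' @export
static_calibration <- function(hindfoot_frontal_offset, cap_local,
                               static_angles, side = "right") {
  stopifnot(is.numeric(hindfoot_frontal_offset),
            length(cap_local) == 3,
            is.numeric(static_angles))
  structure(
    list(hindfoot_frontal_offset = unname(hindfoot_frontal_offset),
         cap_local = unname(as.numeric(cap_local)),
         static_angles = static_angles,
         side = side),
    class = "static_calibration"
  )
}

#' @export
print.static_calibration <- function(x, ...) {
  cat("<static_calibration>", x$side, "foot\n")
  cat(sprintf("  hindfoot frontal offset: %+.2f deg (%s)\n",
              x$hindfoot_frontal_offset,
              classify_hindfoot(x$hindfoot_frontal_offset)))
  cat(sprintf("  static MLA: %.1f deg\n", x$static_angles[["MLA"]]))
  cat(sprintf("  CAp (calcaneus technical frame, mm): %s\n",
              paste(round(x$cap_local, 2), collapse = ", ")))
  invisible(x)
}

# Technical (marker-cluster) frame of the calcaneus from CA, PT, ST. The
# raw cross-product orientation is intrinsic to the triad, so virtual
# points expressed in it track any rigid cluster motion exactly.
calcaneus_technical_frame <- function(CA, PT, ST) {
  frame_from_three_points(CA, PT, ST, segment = "Technical", orient = "raw")
}

#' Hindfoot frontal-plane offset from the static trial
#'
#' The heel-base marker HL sits at the most distal point of the Achilles
#' tendon attachment. Per valid static frame, the segment CA-HL is projected
#' into the frontal plane of the shank (spanned by the shank Y and Z axes)
#' and the signed angle between the projection and the shank vertical axis
#' is taken; frames are then time-averaged. A top-of-calcaneus tilt toward
#' lateral (eversion/valgus) is positive. The conventional frame-derived
#' static frontal angle of the hindfoot is biased toward inversion by the
#' usual marker placement (ST higher than PT); this offset replaces it as
#' the clinical alignment value.
#'
#' @param static A static [marker_series()] containing CA, HL and the four
#'   shank markers.
#' @return Offset in degrees (scalar).
#' @export
compute_hindfoot_frontal_offset <- function(static) {
  need <- c("CA", "HL", "HF", "TT", "LM", "MM")
  miss <- setdiff(need, static$labels)
  if (length(miss)) {
    stop("calibration error: static trial lacks marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  vals <- rep(NA_real_, n_frames(static))
  for (f in seq_len(n_frames(static))) {
    pos <- frame_positions(static, f)
    if (any(is.na(pos[, need]))) next
    shank <- build_shank_frame(pos[, "HF"], pos[, "TT"], pos[, "LM"],
                               pos[, "MM"])
    v <- pos[, "CA"] - pos[, "HL"]
    vy <- sum(v * shank$axes[, "Y"])
    vz <- sum(v * shank$axes[, "Z"])
    if (sqrt(vy^2 + vz^2) < 1e-6) {
      stop("degenerate error: CA-HL projects to zero length in the shank ",
           "frontal plane", call. = FALSE)
    }
    vals[f] <- rad2deg(atan2(vz, vy))
  }
  if (all(is.na(vals))) {
    stop("calibration error: no static frame with all of CA, HL and the ",
         "shank markers", call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}

#' Define the virtual heel ground-point CAp
#'
#' CAp is the vertical projection of the CA marker on the ground (Y = 0) in
#' the up-right static posture, averaged over the static frames, together
#' with its coordinates in the calcaneus technical frame (CA, PT, ST) so it
#' can be tracked rigidly during walking.
#'
#' @param static A static [marker_series()] containing CA, PT, ST.
#' @return List with `cap_lab` (mean lab position, mm) and `cap_local`
#'   (coordinates in the calcaneus technical frame, mm).
#' @export
define_cap_point <- function(static) {
  need <- c("CA", "PT", "ST")
  miss <- setdiff(need, static$labels)
  if (length(miss)) {
    stop("calibration error: static trial lacks marker(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  caps <- matrix(NA_real_, n_frames(static), 3)
  locals <- matrix(NA_real_, n_frames(static), 3)
  for (f in seq_len(n_frames(static))) {
    pos <- frame_positions(static, f)
    if (any(is.na(pos[, need]))) next
    ca <- pos[, "CA"]
    if (ca[2] < 0) {
      stop("data error: CA marker below the ground plane (y < 0)",
           call. = FALSE)
    }
    cap <- c(ca[1], 0, ca[3])
    tf <- calcaneus_technical_frame(ca, pos[, "PT"], pos[, "ST"])
    caps[f, ] <- cap
    locals[f, ] <- crossprod(tf$axes, cap - tf$origin)
  }
  if (all(is.na(caps[, 1]))) {
    stop("calibration error: no static frame with CA, PT and ST",
         call. = FALSE)
  }
  list(cap_lab = colMeans(caps, na.rm = TRUE),
       cap_local = colMeans(locals, na.rm = TRUE))
}

#' Track the virtual heel ground-point during walking
#'
#' Rebuilds the calcaneus technical frame (CA, PT, ST) at every frame of a
#' walking trial and maps the calibrated local CAp coordinates back to the
#' laboratory. Tracking is exact under any rigid motion of the calcaneus
#' marker triad; frames with a missing calcaneus marker yield a missing CAp.
#'
#' @param walking A [marker_series()].
#' @param calib A [static_calibration()] (or any list with `cap_local`).
#' @return An `n_frames x 3` matrix of CAp lab positions (mm), NA where
#'   untrackable.
#' @export
track_cap <- function(walking, calib) {
  need <- c("CA", "PT", "ST")
  miss <- setdiff(need, walking$labels)
  if (length(miss)) {
    stop("trial lacks calcaneus marker(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- matrix(NA_real_, n_frames(walking), 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (f in seq_len(n_frames(walking))) {
    pos <- frame_positions(walking, f)
    if (any(is.na(pos[, need]))) next
    tf <- tryCatch(
      calcaneus_technical_frame(pos[, "CA"], pos[, "PT"], pos[, "ST"]),
      error = function(e) NULL)
    if (is.null(tf)) next
    out[f, ] <- tf$origin + tf$axes %*% calib$cap_local
  }
  out
}

#' Full static calibration of one foot
#'
#' Runs the three calibration steps on a static trial: hindfoot frontal
#' offset, CAp definition, and the static reference value of all 15 joint
#' components and 8 planar angles (each computed per frame through the
#' kinematics pipeline and time-averaged).
#'
#' @param static A static [marker_series()] with the full 17-marker set.
#' @return A [static_calibration()].
#' @export
compute_static_reference <- function(static) {
  rep_ok <- validate_marker_set(static)
  if (!rep_ok$pass) {
    stop("calibration error: ", paste(rep_ok$messages, collapse = "; "),
         call. = FALSE)
  }
  offset <- compute_hindfoot_frontal_offset(static)
  cap <- define_cap_point(static)
  partial <- static_calibration(offset, cap$cap_local,
                                c(placeholder = NA_real_),
                                side = static$side)
  joints <- compute_joint_series(static)
  planar <- compute_planar_angles(static, partial)
  static_angles <- numeric()
  for (j in REPORTED_JOINTS) {
    d <- joints$joints[[j]]
    for (comp in c("dopl", "eveinv", "abdadd")) {
      static_angles[paste0(j, ":", comp)] <- mean(d[[comp]], na.rm = TRUE)
    }
  }
  for (a in PLANAR_NAMES) {
    static_angles[a] <- mean(planar$angles[[a]]$value_deg, na.rm = TRUE)
  }
  static_calibration(offset, cap$cap_local, static_angles,
                     side = static$side)
}

#' Save a static calibration to JSON
#'
#' Numbers are written at full double precision so that
#' [read_calibration()] round-trips bit-exactly.
#'
#' @param calib A [static_calibration()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  doc <- list(
    hindfoot_frontal_offset = calib$hindfoot_frontal_offset,
    cap_local = calib$cap_local,
    static_angles = as.list(calib$static_angles),
    side = calib$side
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a static calibration from JSON
#'
#' @param path Path written by [write_calibration()].
#' @return A [static_calibration()].
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  static_calibration(doc$hindfoot_frontal_offset, doc$cap_local,
                     unlist(doc$static_angles), side = doc$side)
}
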