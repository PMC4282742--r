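# Anatomical reference frames for the five foot/leg segments and the whole
# foot, built from skin-marker positions at a single frame. All frames are
# right-handed orthonormal triads with columns X (antero-posterior),
# Y (vertical/dorsal), Z (medio-lateral), expressed in the laboratory frame.

#' Segment pose
#'
#' Container for the pose of one body segment at one frame: an origin and a
#' right-handed orthonormal axis triad.
#'
#' @param segment Segment name, one of `"Shank"`, `"Calcaneus"`, `"Midfoot"`,
#'   `"Metatarsus"`, `"Foot"`, `"Phalanx"` (or `"Technical"` for marker-cluster
#'   technical frames).
#' @param origin Numeric length-3, origin position in mm (lab frame).
#' @param axes 3x3 matrix whose columns are the X, Y, Z unit axes.
#' @return An object of class `segment_pose`.
#' @export
segment_pose <- function(segment, origin, axes) {
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  if (!is_rotation(axes)) {
    stop("axes must be a right-handed orthonormal 3x3 matrix", call. = FALSE)
  }
  dimnames(axes) <- list(NULL, c("X", "Y", "Z"))
  structure(
    list(segment = segment, origin = as.numeric(origin), axes = axes),
    class = "segment_pose"
  )
}

#' @export
print.segment_pose <- function(x, ...) {
  cat("<segment_pose>", x$segment, "\n")
  cat("  origin (mm):", format(round(x$origin, 3)), "\n")
  print(round(x$axes, 6))
  invisible(x)
}

# Triangle-area degeneracy guard (mm^2).
assert_noncollinear <- function(p1, p2, p3, tol = 1e-6) {
  area <- vnorm(vcross(p2 - p1, p3 - p1)) / 2
  if (!is.finite(area) || area < tol) {
    stop("degenerate geometry: markers are (near-)collinear", call. = FALSE)
  }
  invisible(area)
}

#' Build a segment frame from three points
#'
#' Shared construction kernel: X points from `p_origin` to `p_ahead`; Y is the
#' unit normal of the three-point plane with its sign chosen upward (positive
#' lab-Y component); Z completes the right-handed triad (Z = X x Y). When
#' `prev` is supplied, the normal sign is instead matched to the previous
#' pose's Y axis, which keeps frames continuous through extreme poses during
#' walking.
#'
#' @param p_origin,p_ahead,p_third Numeric length-3 marker positions (mm).
#' @param segment Segment name stored in the result.
#' @param prev Optional `segment_pose` from the previous frame for sign
#'   continuity.
#' @param orient `"up"` flips the plane normal to a positive lab-Y
#'   component (anatomical frames, built in near-upright poses);
#'   `"raw"` keeps the cross-product orientation, which depends only on
#'   the marker triad itself and therefore follows the cluster through
#'   arbitrary rigid motion (technical frames).
#' @return A [segment_pose()].
#' @export
frame_from_three_points <- function(p_origin, p_ahead, p_third,
                                    segment = "Technical", prev = NULL,
                                    orient = c("up", "raw")) {
  orient <- match.arg(orient)
  stopifnot(all(is.finite(c(p_origin, p_ahead, p_third))))
  assert_noncollinear(p_origin, p_ahead, p_third)
  x <- vunit(p_ahead - p_origin)
  n <- vunit(vcross(p_ahead - p_origin, p_third - p_origin))
  if (!is.null(prev)) {
    if (sum(n * prev$axes[, "Y"]) < 0) n <- -n
  } else if (orient == "up" && n[2] < 0) {
    n <- -n
  }
  z <- vcross(x, n)
  segment_pose(segment, p_origin, cbind(x, n, z))
}

#' Hallux proximal-phalanx anatomical frame
#'
#' The hallux is modelled as a three-dimensional segment from three markers:
#' PM on the head of the proximal phalanx, FMH on the first metatarsal head
#' and VMH on the fifth metatarsal head. The antero-posterior X axis runs
#' from FMH to PM, the vertical Y axis is the (dorsal) normal of the
#' three-marker plane, and Z = X x Y.
#'
#' @param PM,FMH,VMH Marker positions (mm).
#' @inheritParams frame_from_three_points
#' @return A [segment_pose()] with origin at FMH.
#' @export
build_phalanx_frame <- function(PM, FMH, VMH, prev = NULL) {
  frame_from_three_points(FMH, PM, VMH, segment = "Phalanx", prev = prev)
}

#' Metatarsus anatomical frame
#'
#' Origin at SMB (second metatarsal base); X toward the midpoint of the first
#' and fifth metatarsal heads; Y the up-positive normal of the FMH-VMH-SMB
#' plane; Z = X x Y.
#'
#' @param FMH,VMH,SMB Marker positions (mm).
#' @inheritParams frame_from_three_points
#' @export
build_metatarsus_frame <- function(FMH, VMH, SMB, prev = NULL) {
  frame_from_three_points(SMB, (FMH + VMH) / 2, VMH,
                          segment = "Metatarsus", prev = prev)
}

#' Calcaneus anatomical frame
#'
#' Origin at CA (upper posterior calcaneus); X toward the midpoint of PT
#' (peroneal tubercle) and ST (sustentaculum tali); Y the up-positive normal
#' of the CA-PT-ST plane; Z = X x Y.
#'
#' @param CA,PT,ST Marker positions (mm).
#' @inheritParams frame_from_three_points
#' @export
build_calcaneus_frame <- function(CA, PT, ST, prev = NULL) {
  frame_from_three_points(CA, (PT + ST) / 2, ST,
                          segment = "Calcaneus", prev = prev)
}

#' Midfoot anatomical frame
#'
#' Origin at the midpoint of TN (navicular) and C (cuboid); X toward SMB;
#' Y the up-positive normal of the TN-C-SMB plane; Z = X x Y.
#'
#' @param TN,C,SMB Marker positions (mm).
#' @inheritParams frame_from_three_points
#' @export
build_midfoot_frame <- function(TN, C, SMB, prev = NULL) {
  frame_from_three_points((TN + C) / 2, SMB, C,
                          segment = "Midfoot", prev = prev)
}

#' Whole-foot anatomical frame
#'
#' Origin at CA; X toward the midpoint of the first and fifth metatarsal
#' heads; Y the up-positive plane normal; Z = X x Y. The sagittal plane of
#' the foot used for planar angles is the vertical plane through CA spanned
#' by this X axis and the laboratory vertical.
#'
#' @param CA,FMH,VMH Marker positions (mm).
#' @inheritParams frame_from_three_points
#' @export
build_foot_frame <- function(CA, FMH, VMH, prev = NULL) {
  frame_from_three_points(CA, (FMH + VMH) / 2, VMH,
                          segment = "Foot", prev = prev)
}

#' Shank anatomical frame
#'
#' Origin at the midpoint of the malleoli (LM, MM); Y points proximally
#' toward the midpoint of HF (fibula head) and TT (tibial tuberosity); Z is
#' the malleolar axis MM to LM re-orthogonalized against Y (lateral for a
#' right side); X = Y x Z (forward).
#'
#' @param HF,TT,LM,MM Marker positions (mm).
#' @return A [segment_pose()].
#' @export
build_shank_frame <- function(HF, TT, LM, MM) {
  stopifnot(all(is.finite(c(HF, TT, LM, MM))))
  o <- (LM + MM) / 2
  y_raw <- (HF + TT) / 2 - o
  z_raw <- LM - MM
  if (vnorm(y_raw) < 1e-6 || vnorm(z_raw) < 1e-6) {
    stop("degenerate geometry: shank markers coincide", call. = FALSE)
  }
  y <- vunit(y_raw)
  z_perp <- z_raw - sum(z_raw * y) * y
  if (vnorm(z_perp) < 1e-6) {
    stop("degenerate geometry: malleolar axis parallel to shank axis",
         call. = FALSE)
  }
  z <- vunit(z_perp)
  x <- vcross(y, z)
  segment_pose("Shank", o, cbind(x, y, z))
}

# All six anatomical frames at one frame index of a marker series.
# Returns a named list of segment_pose objects; `prev` (same shape) enables
# frame-to-frame sign continuity.
segment_frames_at <- function(pos, prev = NULL) {
  g <- function(lbl) pos[, lbl]
  p <- function(name) if (is.null(prev)) NULL else prev[[name]]
  list(
    Shank = build_shank_frame(g("HF"), g("TT"), g("LM"), g("MM")),
    Calcaneus = build_calcaneus_frame(g("CA"), g("PT"), g("ST"),
                                      prev = p("Calcaneus")),
    Midfoot = build_midfoot_frame(g("TN"), g("C"), g("SMB"),
                                  prev = p("Midfoot")),
    Metatarsus = build_metatarsus_frame(g("FMH"), g("VMH"), g("SMB"),
                                        prev = p("Metatarsus")),
    Foot = build_foot_frame(g("CA"), g("FMH"), g("VMH"), prev = p("Foot")),
    Phalanx = build_phalanx_frame(g("PM"), g("FMH"), g("VMH"),
                                  prev = p("Phalanx"))
  )
}
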