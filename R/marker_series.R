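# MarkerFrameSeries: labeled 3D marker trajectories with sampling rate,
# body side and trial kind. Positions are stored as an array of dimension
# (n_frames, 3, n_labels) in millimetres; missing samples are NA on all
# three coordinates.

RFM_MARKERS_STATIC <- c("CA", "PT", "ST", "HL", "TN", "C", "FMB", "SMB",
                        "VMB", "FMH", "SMH", "VMH", "PM", "HF", "TT",
                        "LM", "MM")
RFM_MARKERS_WALKING <- setdiff(RFM_MARKERS_STATIC, "HL")

#' Marker trajectory series
#'
#' Construct a labelled marker trajectory series. Positions are given in
#' millimetres in the laboratory frame (X forward, Y vertical up, Z to the
#' subject's right; ground plane Y = 0). Left-side series are mirrored
#' (Z to -Z) on construction so that every downstream sign convention is
#' side-independent; reports un-mirror for display.
#'
#' @param positions Array `(n_frames, 3, n_labels)` or a named list of
#'   `n_frames x 3` matrices. NA marks missing samples.
#' @param rate Sampling frequency in Hz (> 0).
#' @param side `"right"` or `"left"` (or `"R"`/`"L"`).
#' @param trial_kind `"static"` or `"walking"`.
#' @param labels Marker names; taken from `dimnames`/list names if missing.
#' @param mirrored Internal: set when the left-side mirror has already been
#'   applied.
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(positions, rate, side = "right",
                          trial_kind = "walking", labels = NULL,
                          mirrored = FALSE) {
  if (is.list(positions)) {
    labels <- labels %||% names(positions)
    if (is.null(labels)) stop("positions list must be named", call. = FALSE)
    nf <- nrow(positions[[1]])
    arr <- array(NA_real_, c(nf, 3, length(labels)),
                 dimnames = list(NULL, c("x", "y", "z"), labels))
    for (i in seq_along(labels)) {
      m <- as.matrix(positions[[i]])
      if (!identical(dim(m), c(nf, 3L))) {
        stop("all marker matrices must be n_frames x 3", call. = FALSE)
      }
      arr[, , i] <- m
    }
    positions <- arr
  }
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[2] == 3)
  labels <- labels %||% dimnames(positions)[[3]]
  if (is.null(labels)) stop("marker labels are required", call. = FALSE)
  labels <- toupper(labels)
  dimnames(positions) <- list(NULL, c("x", "y", "z"), labels)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("rate must be a positive number (Hz)", call. = FALSE)
  }
  side <- switch(tolower(substr(side, 1, 1)), r = "right", l = "left",
                 stop("side must be 'left' or 'right'", call. = FALSE))
  trial_kind <- match.arg(trial_kind, c("walking", "static"))
  bad <- is.infinite(positions) | is.nan(positions)
  if (any(bad)) stop("coordinates must be finite where not missing",
                     call. = FALSE)
  # harmonize missingness: any NA coordinate marks the whole sample missing
  na_any <- apply(is.na(positions), c(1, 3), any)
  for (k in 1:3) positions[, k, ][na_any] <- NA_real_
  if (side == "left" && !mirrored) {
    positions[, 3, ] <- -positions[, 3, ]
    mirrored <- TRUE
  }
  structure(
    list(labels = labels, positions = positions, rate = rate, side = side,
         trial_kind = trial_kind, mirrored = mirrored),
    class = "marker_series"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %s %s trial: %d frames @ %g Hz, %d markers\n",
              x$side, x$trial_kind, n_frames(x), x$rate, length(x$labels)))
  miss <- round(100 * mean(is.na(x$positions[, 1, , drop = FALSE])), 1)
  cat(sprintf("  markers: %s\n  missing: %g%% of samples\n",
              paste(x$labels, collapse = " "), miss))
  invisible(x)
}

#' Number of frames in a marker series
#' @param series A [marker_series()].
#' @export
n_frames <- function(series) dim(series$positions)[1]

# 3 x n_labels matrix (rows x/y/z) of marker positions at one frame.
frame_positions <- function(series, frame) {
  matrix(series$positions[frame, , ], nrow = 3,
         dimnames = list(c("x", "y", "z"), series$labels))
}

# n_frames x 3 matrix for one marker.
marker_track <- function(series, label) {
  if (!label %in% series$labels) {
    stop(sprintf("marker '%s' not present in series", label), call. = FALSE)
  }
  series$positions[, , label, drop = TRUE]
}

#' Marker set specification
#'
#' The marker roster of the foot model: 17 markers in the static trial
#' (the heel-base marker HL is required only there) and 16 during walking.
#'
#' @return A list with `required_static`, `required_walking` and `lab_axes`.
#' @export
marker_set_spec <- function() {
  list(
    required_static = RFM_MARKERS_STATIC,
    required_walking = RFM_MARKERS_WALKING,
    lab_axes = c(X = "forward (progression)", Y = "vertical up",
                 Z = "subject's right")
  )
}

#' Validate a marker series against the model's marker set
#'
#' Report-only check: lists missing required labels and the fraction of
#' missing samples per label, and gives an overall pass/fail for the trial
#' kind's requirement. Never modifies the series.
#'
#' @param series A [marker_series()].
#' @param spec A [marker_set_spec()].
#' @return A list of class `validation_report` with `pass`, `missing_labels`,
#'   `missing_fraction` and `messages`.
#' @export
validate_marker_set <- function(series, spec = marker_set_spec()) {
  required <- if (series$trial_kind == "static") {
    spec$required_static
  } else {
    spec$required_walking
  }
  missing_labels <- setdiff(required, series$labels)
  present <- intersect(required, series$labels)
  frac <- vapply(present, function(l) {
    mean(is.na(series$positions[, 1, l]))
  }, numeric(1))
  all_missing <- names(frac)[frac >= 1]
  msgs <- character()
  if (length(missing_labels)) {
    msgs <- c(msgs, sprintf("required marker(s) absent: %s",
                            paste(missing_labels, collapse = ", ")))
  }
  if (length(all_missing)) {
    msgs <- c(msgs, sprintf("marker(s) present but never observed: %s",
                            paste(all_missing, collapse = ", ")))
  }
  structure(
    list(pass = length(missing_labels) == 0 && length(all_missing) == 0,
         missing_labels = missing_labels,
         missing_fraction = frac,
         messages = msgs),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$pass) "PASS" else "FAIL", "\n")
  for (m in x$messages) cat("  -", m, "\n")
  worst <- sort(x$missing_fraction, decreasing = TRUE)
  worst <- worst[worst > 0]
  if (length(worst)) {
    cat("  missing samples:",
        paste(sprintf("%s %.1f%%", names(worst), 100 * worst),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fill short gaps by local polynomial interpolation
#'
#' Interior gaps of at most `max_gap_frames` frames are filled per
#' coordinate with the exact polynomial through up to two valid samples on
#' each side (cubic where four support points exist, degrading to quadratic
#' or linear near the edges of the valid span). Longer gaps, and gaps
#' touching the start or end of the trial, are left missing; nothing is ever
#' extrapolated.
#'
#' @param series A [marker_series()].
#' @param max_gap_frames Largest gap length (frames) to fill; `>= 0`.
#' @return The series with short interior gaps filled.
#' @export
fill_gaps <- function(series, max_gap_frames = 10) {
  stopifnot(max_gap_frames >= 0)
  if (max_gap_frames == 0) return(series)
  pos <- series$positions
  for (l in series$labels) {
    miss <- is.na(pos[, 1, l])
    if (!any(miss) || all(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (i in seq_along(runs$values)) {
      if (!runs$values[i]) next
      if (i == 1 || i == length(runs$values)) next     # leading/trailing gap
      if (runs$lengths[i] > max_gap_frames) next
      gap <- starts[i]:ends[i]
      left <- max(1, starts[i] - 2):(starts[i] - 1)
      right <- ends[i] + seq_len(min(2, dim(pos)[1] - ends[i]))
      support <- c(left, right)
      support <- support[!is.na(pos[support, 1, l])]
      if (length(support) < 2) next
      degree <- min(3, length(support) - 1)
      for (k in 1:3) {
        fit <- stats::lm.fit(outer(support, 0:degree, `^`),
                             pos[support, k, l])
        pos[gap, k, l] <- outer(gap, 0:degree, `^`) %*% fit$coefficients
      }
    }
  }
  series$positions <- pos
  series
}

#' Zero-phase low-pass filter
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass
#' filter to every coordinate of every marker. Contiguous valid spans are
#' filtered independently; spans too short for the filter's edge padding are
#' left untouched. Gait-lab marker data are conventionally smoothed near
#' 6 Hz; no single cutoff suits every capture setup, so it is a parameter.
#'
#' @param series A [marker_series()].
#' @param cutoff_hz Cutoff frequency in Hz; must satisfy
#'   `0 < cutoff_hz < rate / 2`.
#' @return The filtered series.
#' @export
lowpass_filter <- function(series, cutoff_hz = 6) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 ||
      cutoff_hz >= series$rate / 2) {
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff_hz / (series$rate / 2), type = "low")
  min_span <- 3 * (length(bf$a) - 1) * 2 + 1
  pos <- series$positions
  for (l in series$labels) {
    valid <- !is.na(pos[, 1, l])
    if (!any(valid)) next
    runs <- rle(valid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (i in seq_along(runs$values)) {
      if (!runs$values[i] || runs$lengths[i] < min_span) next
      span <- starts[i]:ends[i]
      for (k in 1:3) {
        pos[span, k, l] <- filtfilt_padded(bf, pos[span, k, l])
      }
    }
  }
  series$positions <- pos
  series
}

# Zero-phase filtering with odd (reflected) end padding and mean removal,
# so that constants pass through exactly and edge transients are
# suppressed. Two passes of a 2nd-order Butterworth give the conventional
# zero-phase 4th-order response.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  mu <- mean(x)
  x <- x - mu
  np <- min(n - 1, 50)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xp <- c(pre, x, post)
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[np + seq_len(n)] + mu
}
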