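# Gait events from marker motion, cycle segmentation, time normalization
# and ensemble statistics.
#
# Event definitions (coordinate-based, no force plates): a foot strike is a
# local minimum of the heel (CA) vertical trajectory coincident with a zero
# crossing of the heel forward velocity; a toe off is a local minimum of the
# forefoot (SMH) vertical trajectory coincident with a negative-to-positive
# zero crossing of the forefoot forward velocity. Candidate minima are
# refined to the nearest frame by a local quadratic fit, which keeps the
# estimate within one frame under realistic marker noise.

#' Detect gait events from heel and forefoot marker motion
#'
#' @param walking A [marker_series()] containing CA and SMH.
#' @param min_cycle_s Shortest plausible gait cycle (s); controls the local
#'   search windows.
#' @param coincidence_frames Maximal distance (frames) between a vertical
#'   minimum and its forward-velocity zero crossing.
#' @param smooth_hz Cutoff of the internal zero-phase smoothing applied to
#'   the event signals before detection.
#' @param min_prominence_mm Minimal depth of a vertical minimum below the
#'   highest sample of its local window; rejects noise wiggles on flat
#'   (foot-on-ground) spans.
#' @return A list of class `gait_events` with `foot_strikes`, `toe_offs`
#'   (frame indices) and `cycles` (data frame `start`, `toe_off`, `end`).
#' @export
detect_gait_events <- function(walking, min_cycle_s = 0.6,
                               coincidence_frames = 3, smooth_hz = 6,
                               min_prominence_mm = 1.5) {
  for (l in c("CA", "SMH")) {
    if (!l %in% walking$labels) {
      stop("event detection needs marker ", l, call. = FALSE)
    }
  }
  rate <- walking$rate
  ca <- marker_track(walking, "CA")
  smh <- marker_track(walking, "SMH")
  win <- max(3L, as.integer(round(min_cycle_s * rate / 4)))

  strikes <- event_minima(ca[, 2], ca[, 1], rate, win, coincidence_frames,
                          smooth_hz, crossing = "any",
                          prominence = min_prominence_mm)
  toe_offs <- event_minima(smh[, 2], smh[, 1], rate, win,
                           coincidence_frames, smooth_hz,
                           crossing = "up",
                           prominence = min_prominence_mm)
  cycles <- pair_cycles(strikes, toe_offs)
  if (length(strikes) < 2) {
    warning("no complete gait cycle detected", call. = FALSE)
  }
  structure(list(foot_strikes = strikes, toe_offs = toe_offs,
                 cycles = cycles, rate = rate),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d foot strikes, %d toe offs, %d cycles\n",
              length(x$foot_strikes), length(x$toe_offs), nrow(x$cycles)))
  invisible(x)
}

# Local minima of `vert` coincident with a zero crossing of d(fwd)/dt.
event_minima <- function(vert, fwd, rate, win, coincide, smooth_hz,
                         crossing = c("any", "up"), prominence = 1.5) {
  crossing <- match.arg(crossing)
  n <- length(vert)
  ok <- !is.na(vert) & !is.na(fwd)
  if (sum(ok) < 2 * win + 1) return(integer())
  vs <- smooth_signal(vert, rate, smooth_hz)
  fs <- smooth_signal(fwd, rate, smooth_hz)
  vel <- c(NA, diff(fs)) * rate
  # candidate minima: strictly lowest in a +-win window and at least
  # `prominence` below the highest sample on BOTH sides (a one-sided rise,
  # e.g. the edge of a flat foot-on-ground span, is not an event)
  cand <- which(vapply(seq_len(n), function(i) {
    if (is.na(vs[i]) || i <= win || i > n - win) return(FALSE)
    w <- vs[(i - win):(i + win)]
    if (any(is.na(w)) || which.min(w) != win + 1) return(FALSE)
    v0 <- w[win + 1]
    max(w[1:win]) - v0 >= prominence &&
      max(w[(win + 2):(2 * win + 1)]) - v0 >= prominence
  }, logical(1)))
  # velocity zero crossings
  sgn <- sign(vel)
  up <- which(!is.na(sgn[-n]) & !is.na(sgn[-1]) &
                sgn[-n] < 0 & sgn[-1] >= 0)
  down <- which(!is.na(sgn[-n]) & !is.na(sgn[-1]) &
                  sgn[-n] > 0 & sgn[-1] <= 0)
  zc <- if (crossing == "up") up else sort(c(up, down))
  if (!length(cand) || !length(zc)) return(integer())
  keep <- cand[vapply(cand, function(i) min(abs(zc - i)) <= coincide,
                      logical(1))]
  # refine on the unsmoothed signal: the sharp impact minimum carries the
  # timing; smoothing biases it toward the adjacent swing slope
  refined <- vapply(keep, refine_minimum, integer(1), y = vert)
  unique(refined)
}

# Timing refinement of a candidate minimum: recenter to the raw argmin in a
# +-3 frame window, then fit a quadratic over the +-2 frame core of the
# impact dip and round its vertex to the nearest frame. The narrow fit
# avoids bias from the flat foot-on-ground span on one side of the dip.
refine_minimum <- function(i, y, half = 2L) {
  lo <- max(1L, i - 3L); hi <- min(length(y), i + 3L)
  w <- y[lo:hi]
  if (!any(!is.na(w))) return(as.integer(i))
  i <- (lo:hi)[which.min(w)]
  lo <- max(1L, i - half); hi <- min(length(y), i + half)
  idx <- lo:hi
  yy <- y[idx]
  if (any(is.na(yy)) || length(idx) < 2 * half + 1) return(as.integer(i))
  x <- idx - i
  fit <- stats::lm.fit(cbind(1, x, x^2), yy)
  a <- fit$coefficients[3]; b <- fit$coefficients[2]
  if (!is.finite(a) || a <= 0) return(as.integer(i))
  vertex <- -b / (2 * a)
  if (abs(vertex) > half) return(as.integer(i))
  as.integer(round(i + vertex))
}

smooth_signal <- function(x, rate, cutoff_hz) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rate / 2 ||
      sum(!is.na(x)) < 30) {
    return(x)
  }
  bf <- signal::butter(2, cutoff_hz / (rate / 2), type = "low")
  out <- x
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < 30) next
    span <- starts[i]:ends[i]
    out[span] <- filtfilt_padded(bf, x[span])
  }
  out
}

pair_cycles <- function(strikes, toe_offs) {
  rows <- list()
  if (length(strikes) >= 2) {
    for (i in seq_len(length(strikes) - 1)) {
      s0 <- strikes[i]; s1 <- strikes[i + 1]
      to <- toe_offs[toe_offs > s0 & toe_offs < s1]
      rows[[length(rows) + 1]] <- data.frame(
        start = s0, toe_off = if (length(to)) to[1] else NA_integer_,
        end = s1)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), toe_off = integer(), end = integer())
}

#' Time-normalize one gait cycle to 0-100%
#'
#' Linear resampling of the values between two foot strikes onto an evenly
#' spaced percentage grid; the endpoints are preserved exactly.
#'
#' @param values Per-frame values (one trajectory or angle component).
#' @param cycle Either a length-2 vector `c(start, end)` of frame indices or
#'   one row of the `cycles` data frame from [detect_gait_events()].
#' @param n_points Number of grid points (101 = 0..100% in 1% steps).
#' @param max_missing Reject the cycle (return NULL with a warning) when
#'   more than this fraction of its samples is missing.
#' @return Numeric of length `n_points`, or NULL when rejected.
#' @export
normalize_to_cycle <- function(values, cycle, n_points = 101,
                               max_missing = 0.2) {
  if (is.data.frame(cycle)) cycle <- c(cycle$start[1], cycle$end[1])
  start <- cycle[1]; end <- cycle[length(cycle)]
  if (is.na(start) || is.na(end) || start < 1 || end > length(values) ||
      end <= start) {
    stop("cycle out of series bounds", call. = FALSE)
  }
  span <- values[start:end]
  miss <- mean(is.na(span))
  if (miss > max_missing) {
    warning(sprintf("cycle rejected: %.0f%% of samples missing",
                    100 * miss), call. = FALSE)
    return(NULL)
  }
  if (sum(!is.na(span)) < 2) {
    warning("cycle rejected: fewer than 2 valid samples", call. = FALSE)
    return(NULL)
  }
  x <- seq(0, 100, length.out = length(span))
  grid <- seq(0, 100, length.out = n_points)
  out <- stats::approx(x[!is.na(span)], span[!is.na(span)], xout = grid,
                       rule = 1)$y
  # exact endpoint preservation when the endpoints are observed
  if (!is.na(span[1])) out[1] <- span[1]
  if (!is.na(span[length(span)])) out[n_points] <- span[length(span)]
  out
}

#' Pointwise ensemble statistics over normalized cycles
#'
#' @param curves A list of equal-length numeric vectors (normalized cycles),
#'   or a matrix with one curve per row.
#' @param name Curve name carried in the result.
#' @return A list of class `ensemble_curve` with `name`, `percent`, `mean`,
#'   `sd` (sample SD, n-1 denominator; 0 when a single curve) and
#'   `n_curves`.
#' @export
ensemble_stats <- function(curves, name = "curve") {
  if (is.list(curves)) {
    curves <- curves[!vapply(curves, is.null, logical(1))]
    if (!length(curves)) stop("no curves to pool", call. = FALSE)
    len <- unique(vapply(curves, length, integer(1)))
    if (length(len) != 1) {
      stop("schema error: curves have mismatched lengths", call. = FALSE)
    }
    curves <- do.call(rbind, curves)
  }
  if (!is.matrix(curves) || nrow(curves) < 1) {
    stop("curves must be a non-empty list or matrix", call. = FALSE)
  }
  m <- colMeans(curves, na.rm = TRUE)
  s <- if (nrow(curves) == 1) {
    rep(0, ncol(curves))
  } else {
    apply(curves, 2, stats::sd, na.rm = TRUE)
  }
  s[is.na(s)] <- 0
  structure(
    list(name = name,
         percent = seq(0, 100, length.out = ncol(curves)),
         mean = m, sd = s, n_curves = nrow(curves)),
    class = "ensemble_curve"
  )
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve> %s: n = %d, mean range [%.2f, %.2f], mean SD %.2f\n",
              x$name, x$n_curves, min(x$mean), max(x$mean), mean(x$sd)))
  invisible(x)
}

#' Export gait events as a data frame
#'
#' @param events A `gait_events` object.
#' @param trial Trial identifier.
#' @return Data frame with `trial`, `event_type`, `frame`, `time_s`.
#' @export
events_long <- function(events, trial = "trial") {
  data.frame(
    trial = trial,
    event_type = c(rep("foot_strike", length(events$foot_strikes)),
                   rep("toe_off", length(events$toe_offs))),
    frame = c(events$foot_strikes, events$toe_offs),
    time_s = (c(events$foot_strikes, events$toe_offs) - 1) / events$rate
  )
}
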