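# Hindfoot alignment classification, per-foot analysis orchestration,
# cohort summaries and report rendering.

#' Classify hindfoot frontal-plane alignment
#'
#' Clinical alignment categories from the static hindfoot frontal-plane
#' offset (eversion/valgus positive): neutral between -2 and 2 deg
#' (boundaries inclusive), valgus when eversion exceeds 2 deg, varus when
#' inversion exceeds 2 deg.
#'
#' @param offset_deg Offset(s) in degrees.
#' @param bound Neutral half-width in degrees (default 2).
#' @return Character vector: `"neutral"`, `"varus"` or `"valgus"`.
#' @export
classify_hindfoot <- function(offset_deg, bound = 2) {
  if (any(!is.finite(offset_deg))) {
    stop("data error: offset must be finite", call. = FALSE)
  }
  ifelse(abs(offset_deg) <= bound, "neutral",
         ifelse(offset_deg > bound, "valgus", "varus"))
}

#' Analyze one foot: calibration plus walking trials
#'
#' Runs the full pipeline for a single foot: static calibration, then per
#' walking trial the 3D joint and planar angles, gait events, and
#' time-normalized cycles pooled into one ensemble per angle.
#'
#' @param static A static [marker_series()].
#' @param walking A list of walking [marker_series()].
#' @param participant Participant identifier.
#' @param preprocess Apply default cleaning (gap filling) to each trial.
#' @param n_points Normalization grid size.
#' @return A list of class `foot_result`: `participant`, `side`,
#'   `hindfoot_frontal_offset`, `static_mla`, `category`, `calib`,
#'   `ensembles` (list of [ensemble_stats()] outputs keyed by angle name),
#'   `events` (per trial), `n_cycles`.
#' @export
analyze_foot <- function(static, walking, participant = "P01",
                         preprocess = TRUE, n_points = 101) {
  if (preprocess) {
    static <- fill_gaps(static)
    walking <- lapply(walking, fill_gaps)
  }
  calib <- compute_static_reference(static)
  curves <- list()
  events <- list()
  n_cycles <- 0
  for (k in seq_along(walking)) {
    w <- walking[[k]]
    joints <- compute_joint_series(w, calib)
    planar <- compute_planar_angles(w, calib)
    ev <- detect_gait_events(w)
    events[[k]] <- ev
    if (!nrow(ev$cycles)) next
    for (ci in seq_len(nrow(ev$cycles))) {
      cyc <- c(ev$cycles$start[ci], ev$cycles$end[ci])
      n_cycles <- n_cycles + 1
      for (j in REPORTED_JOINTS) {
        d <- joints$joints[[j]]
        for (comp in c("dopl", "eveinv", "abdadd")) {
          nm <- paste0(j, ":", comp)
          curves[[nm]] <- c(curves[[nm]],
                            list(normalize_to_cycle(d[[comp]], cyc,
                                                    n_points)))
        }
      }
      for (a in PLANAR_NAMES) {
        curves[[a]] <- c(curves[[a]],
                         list(normalize_to_cycle(
                           planar$angles[[a]]$value_deg, cyc, n_points)))
      }
    }
  }
  ensembles <- lapply(names(curves), function(nm) {
    ensemble_stats(curves[[nm]], name = nm)
  })
  names(ensembles) <- names(curves)
  structure(
    list(participant = participant, side = static$side,
         hindfoot_frontal_offset = calib$hindfoot_frontal_offset,
         static_mla = calib$static_angles[["MLA"]],
         category = classify_hindfoot(calib$hindfoot_frontal_offset),
         calib = calib, ensembles = ensembles, events = events,
         n_cycles = n_cycles),
    class = "foot_result"
  )
}

#' @export
print.foot_result <- function(x, ...) {
  cat(sprintf("<foot_result> %s %s: offset %+.2f deg (%s), static MLA %.1f deg, %d cycles\n",
              x$participant, x$side, x$hindfoot_frontal_offset, x$category,
              x$static_mla, x$n_cycles))
  invisible(x)
}

#' Summarize a cohort of analyzed feet
#'
#' @param results List of `foot_result` objects (or any list with
#'   `hindfoot_frontal_offset` and `static_mla`).
#' @param bound Neutral classification half-width (deg).
#' @return A list of class `cohort_summary`: `n_feet`, `counts` (neutral /
#'   varus / valgus), `n_neutral_or_valgus`, `mla_mean`, `mla_sd`,
#'   `mla_min`, `mla_max`.
#' @export
summarize_cohort <- function(results, bound = 2) {
  if (!length(results)) stop("data error: empty cohort", call. = FALSE)
  offs <- vapply(results, `[[`, numeric(1), "hindfoot_frontal_offset")
  mlas <- vapply(results, `[[`, numeric(1), "static_mla")
  cats <- classify_hindfoot(offs, bound)
  counts <- c(neutral = sum(cats == "neutral"),
              varus = sum(cats == "varus"),
              valgus = sum(cats == "valgus"))
  structure(
    list(n_feet = length(results), counts = counts,
         n_neutral_or_valgus = unname(counts["neutral"] + counts["valgus"]),
         mla_mean = mean(mlas),
         mla_sd = if (length(mlas) > 1) stats::sd(mlas) else 0,
         mla_n1_flag = length(mlas) == 1,
         mla_min = min(mlas), mla_max = max(mlas)),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d feet: %d neutral, %d varus, %d valgus (%d neutral-or-valgus)\n",
              x$n_feet, x$counts["neutral"], x$counts["varus"],
              x$counts["valgus"], x$n_neutral_or_valgus))
  cat(sprintf("  static MLA: %.1f +/- %.1f deg (range %.1f-%.1f)\n",
              x$mla_mean, x$mla_sd, x$mla_min, x$mla_max))
  invisible(x)
}

#' Render the cohort analysis report
#'
#' Writes per-foot CSVs of ensemble curves, a pooled ensemble CSV, a cohort
#' summary table and figure panels (per joint component and planar angle)
#' showing the ensemble mean with a +/- SD band and the static reference
#' value as a horizontal dashed segment.
#'
#' @param summary A [summarize_cohort()] result.
#' @param results The list of `foot_result` objects.
#' @param out_dir Output directory (created if absent).
#' @param plots Also write figure files (PNG).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(summary, results, out_dir, plots = TRUE) {
  if (!length(results)) stop("data error: empty results", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)
  paths <- character()

  per_foot <- do.call(rbind, lapply(results, function(r) {
    data.frame(participant = r$participant, side = r$side,
               hindfoot_frontal_offset = r$hindfoot_frontal_offset,
               static_mla = r$static_mla, category = r$category,
               n_cycles = r$n_cycles)
  }))
  p <- file.path(out_dir, "feet.csv")
  utils::write.csv(per_foot, p, row.names = FALSE)
  paths <- c(paths, p)

  ens_rows <- list()
  for (r in results) {
    for (nm in names(r$ensembles)) {
      e <- r$ensembles[[nm]]
      ens_rows[[length(ens_rows) + 1]] <- data.frame(
        participant = r$participant, side = r$side, name = nm,
        percent = e$percent, mean = e$mean, sd = e$sd, n = e$n_curves)
    }
  }
  ens <- do.call(rbind, ens_rows)
  p <- file.path(out_dir, "ensembles.csv")
  utils::write.csv(ens, p, row.names = FALSE)
  paths <- c(paths, p)

  summ <- data.frame(
    n_feet = summary$n_feet, n_neutral = summary$counts["neutral"],
    n_varus = summary$counts["varus"], n_valgus = summary$counts["valgus"],
    n_neutral_or_valgus = summary$n_neutral_or_valgus,
    mla_mean = summary$mla_mean, mla_sd = summary$mla_sd,
    mla_min = summary$mla_min, mla_max = summary$mla_max)
  p <- file.path(out_dir, "cohort_summary.csv")
  utils::write.csv(summ, p, row.names = FALSE)
  paths <- c(paths, p)

  if (plots) {
    paths <- c(paths, render_panels(results, out_dir))
  }
  invisible(paths)
}

# Pooled mean +/- SD panels, joints and planar angles on separate sheets.
render_panels <- function(results, out_dir) {
  all_names <- unique(unlist(lapply(results, function(r) names(r$ensembles))))
  pool <- list()
  for (nm in all_names) {
    curves <- list()
    statics <- numeric()
    for (r in results) {
      e <- r$ensembles[[nm]]
      if (!is.null(e)) curves[[length(curves) + 1]] <- e$mean
      sa <- r$calib$static_angles
      if (nm %in% names(sa)) statics <- c(statics, sa[[nm]])
    }
    if (!length(curves)) next
    es <- ensemble_stats(curves, name = nm)
    pool[[nm]] <- data.frame(name = nm, percent = es$percent,
                             mean = es$mean, sd = es$sd,
                             static = mean(statics))
  }
  df <- do.call(rbind, pool)
  paths <- character()
  for (grp in list(joints = REPORTED_JOINTS, planar = PLANAR_NAMES)) {
    sel <- df[sub(":.*", "", df$name) %in% grp, ]
    if (!nrow(sel)) next
    gg <- ggplot2::ggplot(sel, ggplot2::aes(x = .data$percent)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           fill = "grey70") +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$static),
                          linetype = "dashed") +
      ggplot2::facet_wrap(~name, scales = "free_y", ncol = 3) +
      ggplot2::labs(x = "% gait cycle", y = "angle (deg)") +
      ggplot2::theme_bw()
    fn <- file.path(out_dir, paste0("panels_",
                                    if (identical(grp, PLANAR_NAMES))
                                      "planar" else "joints", ".png"))
    grDevices::png(fn, width = 1800, height = 1600, res = 160)
    print(gg)
    grDevices::dev.off()
    paths <- c(paths, fn)
  }
  paths
}
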