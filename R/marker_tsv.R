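# Plain tab-separated trajectory dialect: a header row `frame` followed by
# `<LABEL>_x  <LABEL>_y  <LABEL>_z` triplets, one row per frame, blank cells
# for missing samples, coordinates in millimetres.

#' Read marker trajectories from the TSV dialect
#'
#' @param path Path to a tab-separated trajectory file.
#' @param side `"left"` or `"right"`.
#' @param rate Sampling frequency in Hz (the TSV dialect does not carry it).
#' @param trial_kind `"static"` or `"walking"`.
#' @return A [marker_series()].
#' @export
read_markers_tsv <- function(path, side = "right", rate = 100,
                             trial_kind = "walking") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "numeric", na.strings = c("", "NA"))
  if (ncol(df) < 2 || names(df)[1] != "frame") {
    stop("schema error: first column must be 'frame'", call. = FALSE)
  }
  coord_cols <- names(df)[-1]
  if (length(coord_cols) %% 3 != 0) {
    stop("schema error: coordinate columns are not triplets", call. = FALSE)
  }
  m <- regmatches(coord_cols, regexec("^(.*)_([xyz])$", coord_cols))
  if (any(lengths(m) != 3)) {
    stop("schema error: columns must be named <LABEL>_x/_y/_z", call. = FALSE)
  }
  lab <- toupper(vapply(m, `[`, "", 2))
  axis <- vapply(m, `[`, "", 3)
  if (anyDuplicated(paste0(lab, "_", axis))) {
    stop("schema error: duplicated label columns", call. = FALSE)
  }
  labels <- unique(lab)
  per_label <- split(axis, factor(lab, levels = labels))
  if (!all(vapply(per_label, function(a) setequal(a, c("x", "y", "z")),
                  logical(1)))) {
    stop("schema error: each label needs exactly _x, _y and _z columns",
         call. = FALSE)
  }
  fr <- df$frame
  if (any(diff(fr) <= 0)) {
    stop("schema error: frame index must be strictly increasing",
         call. = FALSE)
  }
  nf <- nrow(df)
  arr <- array(NA_real_, c(nf, 3, length(labels)),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  for (j in seq_along(coord_cols)) {
    k <- match(axis[j], c("x", "y", "z"))
    arr[, k, lab[j]] <- df[[j + 1]]
  }
  marker_series(arr, rate = rate, side = side, trial_kind = trial_kind)
}

#' Write marker trajectories to the TSV dialect
#'
#' Full double precision is preserved (round trips are lossless well below
#' 1e-6 mm). Missing samples become blank cells. Left-side series are
#' written in true laboratory coordinates (the ingest mirroring is undone),
#' so re-reading with `side = "left"` reproduces the series exactly.
#'
#' @param series A [marker_series()] with at least one frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(series, path) {
  if (n_frames(series) == 0) {
    stop("cannot write an empty series", call. = FALSE)
  }
  nf <- n_frames(series)
  pos <- series$positions
  if (series$side == "left" && isTRUE(series$mirrored)) {
    pos[, 3, ] <- -pos[, 3, ]          # restore true lab coordinates
  }
  cols <- vector("list", 1 + 3 * length(series$labels))
  cols[[1]] <- seq_len(nf)
  nms <- "frame"
  i <- 2
  for (l in series$labels) {
    for (k in 1:3) {
      cols[[i]] <- pos[, k, l]
      nms[i] <- paste0(l, "_", c("x", "y", "z")[k])
      i <- i + 1
    }
  }
  df <- as.data.frame(cols, col.names = nms, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nms, collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(x) {
    out <- formatC(x, format = "g", digits = 17)
    out[is.na(x)] <- ""
    out
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}
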