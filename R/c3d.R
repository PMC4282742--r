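# Minimal C3D support for labelled 3D point data (Intel/little-endian
# byte order, integer or floating-point point storage). C3D is the de facto
# standard container for motion-capture trials; no installed R package
# handles it, so a purpose-limited reader/writer is implemented here:
# header + parameter section (POINT group) + 3D point data. Analog
# channels, event records and non-Intel processor types are out of scope.

C3D_BLOCK <- 512L

#' Read 3D point data from a C3D file
#'
#' Reads the 3D point section of a little-endian (Intel) C3D file. Point
#' labels are upper-cased and an optional side prefix (`R_`/`L_`/`R.`/`L.`)
#' is stripped; samples whose residual is negative are marked missing.
#'
#' @param path Path to a C3D file.
#' @param side `"left"` or `"right"`.
#' @param trial_kind `"static"` or `"walking"`.
#' @return A [marker_series()] with the file's point rate.
#' @export
read_c3d <- function(path, side = "right", trial_kind = "walking") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 2 * C3D_BLOCK || raw[2] != as.raw(0x50)) {
    stop("format error: not a C3D file", call. = FALSE)
  }
  hdr <- tryCatch(c3d_read_header(raw), error = function(e) {
    stop("format error: corrupt C3D header: ", conditionMessage(e),
         call. = FALSE)
  })
  prm <- tryCatch(c3d_read_parameters(raw), error = function(e) {
    stop("format error: corrupt C3D parameter section: ",
         conditionMessage(e), call. = FALSE)
  })
  npoints <- prm$used %||% hdr$npoints
  nframes <- hdr$last_frame - hdr$first_frame + 1
  if (!is.null(prm$frames) && is.finite(prm$frames)) {
    nframes <- prm$frames
  }
  if (npoints < 1) stop("format error: no 3D points", call. = FALSE)
  if (nframes < 1) stop("empty trial: no frames of point data", call. = FALSE)
  rate <- prm$rate %||% hdr$rate
  scale <- prm$scale %||% hdr$scale
  data_start <- ((prm$data_start %||% hdr$data_start) - 1) * C3D_BLOCK
  labels <- prm$labels
  if (is.null(labels) || length(labels) < npoints) {
    labels <- c(labels, sprintf("PT%02d", seq_len(npoints)))[seq_len(npoints)]
  }
  labels <- normalize_c3d_labels(labels[seq_len(npoints)])

  vals_per_frame <- 4 * npoints
  is_float <- scale < 0
  bytes_per <- if (is_float) 4L else 2L
  need <- data_start + nframes * vals_per_frame * bytes_per
  if (need > length(raw)) {
    stop("format error: truncated point data section", call. = FALSE)
  }
  con <- rawConnection(raw[(data_start + 1):length(raw)])
  on.exit(close(con))
  if (is_float) {
    vals <- readBin(con, "numeric", n = nframes * vals_per_frame, size = 4,
                    endian = "little")
  } else {
    vals <- readBin(con, "integer", n = nframes * vals_per_frame, size = 2,
                    signed = TRUE, endian = "little")
  }
  dim(vals) <- c(4, npoints, nframes)
  xyz <- vals[1:3, , , drop = FALSE]
  res <- vals[4, , , drop = FALSE]
  if (!is_float) xyz <- xyz * abs(scale)
  arr <- array(NA_real_, c(nframes, 3, npoints),
               dimnames = list(NULL, c("x", "y", "z"), labels))
  for (p in seq_len(npoints)) {
    m <- t(xyz[, p, ])                     # nframes x 3
    m[res[1, p, ] < 0, ] <- NA_real_
    arr[, , p] <- m
  }
  marker_series(arr, rate = rate, side = side, trial_kind = trial_kind)
}

normalize_c3d_labels <- function(labels) {
  labels <- toupper(trimws(labels))
  sub("^[LR][._](?=.)", "", labels, perl = TRUE)
}

c3d_read_header <- function(raw) {
  con <- rawConnection(raw)
  on.exit(close(con))
  param_block <- as.integer(readBin(con, "raw", 1))
  magic <- readBin(con, "raw", 1)
  ints <- readBin(con, "integer", 5, size = 2, signed = TRUE,
                  endian = "little")
  scale <- readBin(con, "numeric", 1, size = 4, endian = "little")
  data_start <- readBin(con, "integer", 1, size = 2, signed = TRUE,
                        endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # analog/frame
  rate <- readBin(con, "numeric", 1, size = 4, endian = "little")
  list(param_block = param_block, npoints = ints[1], nanalog = ints[2],
       first_frame = ints[3], last_frame = ints[4], max_gap = ints[5],
       scale = scale, data_start = data_start, rate = rate)
}

# Parse the parameter section; only the POINT group is interpreted.
c3d_read_parameters <- function(raw) {
  param_block <- as.integer(raw[1])
  base <- (param_block - 1) * C3D_BLOCK
  proc <- as.integer(raw[base + 4])
  if (proc != 84) {
    stop("unsupported processor type ", proc, " (only Intel/84)")
  }
  pos <- base + 5                       # 1-based index of first entry byte
  out <- list()
  group_ids <- integer()                # name -> id map for groups
  repeat {
    if (pos + 1 > length(raw)) break
    nname <- readBin(raw[pos], "integer", size = 1, signed = TRUE)
    gid <- readBin(raw[pos + 1], "integer", size = 1, signed = TRUE)
    nn <- abs(nname)
    if (nn == 0 || gid == 0) break
    name <- rawToChar(raw[(pos + 2):(pos + 1 + nn)])
    off_pos <- pos + 2 + nn
    offset <- readBin(raw[off_pos:(off_pos + 1)], "integer", size = 2,
                      signed = TRUE, endian = "little")
    if (gid < 0) {
      group_ids[toupper(name)] <- -gid
    } else {
      body <- off_pos + 2
      type <- readBin(raw[body], "integer", size = 1, signed = TRUE)
      ndim <- as.integer(raw[body + 1])
      dims <- if (ndim > 0) as.integer(raw[(body + 2):(body + 1 + ndim)])
              else integer()
      dpos <- body + 2 + ndim
      nvals <- prod(c(1, dims))
      val <- switch(as.character(type),
        `-1` = rawToChar(raw[dpos:(dpos + max(nvals, 1) - 1)]),
        `1` = readBin(raw[dpos:(dpos + nvals - 1)], "integer", n = nvals,
                      size = 1, signed = TRUE),
        `2` = readBin(raw[dpos:(dpos + 2 * nvals - 1)], "integer",
                      n = nvals, size = 2, signed = TRUE,
                      endian = "little"),
        `4` = readBin(raw[dpos:(dpos + 4 * nvals - 1)], "numeric",
                      n = nvals, size = 4, endian = "little"),
        stop("unknown parameter type ", type)
      )
      if (type == -1 && length(dims) == 2) {
        val <- substring(val, seq(1, dims[1] * dims[2], dims[1]),
                         seq(dims[1], dims[1] * dims[2], dims[1]))
      }
      out[[paste(gid, toupper(name), sep = ":")]] <- val
    }
    if (offset <= 0) break
    pos <- off_pos + offset
  }
  pid <- if ("POINT" %in% names(group_ids)) group_ids[["POINT"]] else NA
  get <- function(nm) out[[paste(pid, nm, sep = ":")]]
  scalar <- function(x) {
    x <- suppressWarnings(as.numeric(x))[1]
    if (length(x) == 0 || is.na(x)) NULL else x
  }
  list(
    labels = get("LABELS"),
    rate = scalar(get("RATE")),
    scale = scalar(get("SCALE")),
    frames = scalar(get("FRAMES")),
    used = scalar(get("USED")),
    data_start = scalar(get("DATA_START"))
  )
}

#' Write a marker series to a C3D file
#'
#' Writes a little-endian floating-point C3D file with a POINT parameter
#' group (USED, FRAMES, RATE, SCALE, DATA_START, LABELS, UNITS) and the 3D
#' point section. Missing samples are written with residual -1.
#'
#' @param series A [marker_series()] with at least one frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(series, path) {
  nf <- n_frames(series)
  if (nf == 0) stop("cannot write an empty series", call. = FALSE)
  np <- length(series$labels)
  if (nf > 32767) stop("C3D header limits trials to 32767 frames",
                       call. = FALSE)

  # parameter-section length does not depend on the DATA_START value, so
  # build once to size it, then rebuild with the true block number
  n_param_blocks <- c3d_parameter_section(series, 0L)$n_blocks
  data_start_block <- 2L + n_param_blocks
  prm <- c3d_parameter_section(series, data_start_block)

  con <- file(path, "wb")
  on.exit(close(con))
  # --- header block
  writeBin(as.raw(c(2, 0x50)), con)
  writeBin(as.integer(c(np, 0, 1, nf, 0)), con, size = 2, endian = "little")
  writeBin(-1, con, size = 4, endian = "little")            # POINT:SCALE
  writeBin(as.integer(data_start_block), con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")
  writeBin(series$rate, con, size = 4, endian = "little")
  writeBin(raw(C3D_BLOCK - 24), con)
  # --- parameter section, padded to whole blocks
  bytes <- prm$bytes
  writeBin(bytes, con)
  pad <- n_param_blocks * C3D_BLOCK - length(bytes)
  if (pad > 0) writeBin(raw(pad), con)
  # --- point data: x, y, z, residual per point per frame (float32)
  posx <- series$positions
  if (series$side == "left" && isTRUE(series$mirrored)) {
    posx[, 3, ] <- -posx[, 3, ]        # restore true lab coordinates
  }
  vals <- array(0, c(4, np, nf))
  for (p in seq_len(np)) {
    m <- matrix(posx[, , p], ncol = 3)
    miss <- is.na(m[, 1])
    m[miss, ] <- 0
    vals[1:3, p, ] <- t(m)
    vals[4, p, ] <- ifelse(miss, -1, 0)
  }
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

# Build the raw bytes of the parameter section (block header + POINT group).
c3d_parameter_section <- function(series, data_start_block) {
  np <- length(series$labels)
  labw <- max(4L, max(nchar(series$labels)))
  lab_padded <- formatC(series$labels, width = labw, flag = "-")

  entry <- function(name, gid, payload) {
    nm <- charToRaw(name)
    offset <- 2L + length(payload)
    c(as.raw(length(nm)), packInt8(gid), nm,
      packInt16(offset), payload)
  }
  group <- function(name, gid, desc = "") {
    d <- charToRaw(desc)
    entry(name, -gid, c(as.raw(length(d)), d))
  }
  param <- function(name, gid, type, dims, data_raw, desc = "") {
    d <- charToRaw(desc)
    payload <- c(packInt8(type), as.raw(length(dims)), as.raw(dims),
                 data_raw, as.raw(length(d)), d)
    entry(name, gid, payload)
  }
  p_int <- function(name, value) {
    param(name, 1L, 2L, integer(), packInt16(value))
  }
  p_float <- function(name, value) {
    param(name, 1L, 4L, integer(), writeBinRaw(value, 4))
  }
  bytes <- c(
    as.raw(c(2, 0x50)), as.raw(0), as.raw(84),   # nblocks patched below
    group("POINT", 1L, "3D point parameters"),
    p_int("USED", np),
    p_int("FRAMES", n_frames(series)),
    p_int("DATA_START", data_start_block),
    p_float("RATE", series$rate),
    p_float("SCALE", -1),
    param("UNITS", 1L, -1L, c(2L), charToRaw("mm")),
    param("LABELS", 1L, -1L, c(labw, np),
          charToRaw(paste(lab_padded, collapse = "")))
  )
  nb <- ceiling(length(bytes) / C3D_BLOCK)
  bytes[3] <- as.raw(nb)
  list(bytes = bytes, n_blocks = nb)
}

packInt8 <- function(x) {
  writeBinRaw(as.integer(x), 1)
}
packInt16 <- function(x) {
  writeBinRaw(as.integer(x), 2)
}
writeBinRaw <- function(x, size) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(x, con, size = size, endian = "little")
  rawConnectionValue(con)
}
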