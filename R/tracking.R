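#' Centroid trajectory container
#'
#' A trajectory is a per-frame record of the tracked center of mass:
#' timestamps, cm coordinates (origin lower-left, y up) and a validity flag
#' marking tracking dropouts. Stored as a data.frame of class
#' `sa_trajectory` with the frame rate attached as an attribute.
#'
#' @param time_s Strictly increasing timestamps in seconds.
#' @param x_cm,y_cm Centroid coordinates in cm (may be NA on dropout frames).
#' @param valid Logical; `FALSE` marks dropout frames (default all valid).
#' @param fps Nominal frame rate; inferred from the median timestamp spacing
#'   when omitted.
#' @return An `sa_trajectory` data.frame with columns `time_s`, `x_cm`,
#'   `y_cm`, `valid`.
#' @export
trajectory <- function(time_s, x_cm, y_cm, valid = TRUE, fps = NULL) {
  n <- length(time_s)
  valid <- rep_len(valid, n)
  if (n > 1 && any(diff(time_s) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  if (is.null(fps)) {
    fps <- if (n > 1) 1 / stats::median(diff(time_s)) else 20
  }
  out <- data.frame(time_s = time_s, x_cm = x_cm, y_cm = y_cm, valid = valid)
  attr(out, "fps") <- fps
  class(out) <- c("sa_trajectory", "data.frame")
  out
}

traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) {
    dt <- diff(traj$time_s)
    fps <- if (length(dt)) 1 / stats::median(dt) else 20
  }
  fps
}

#' Intensity-weighted centroid of a grayscale frame
#'
#' Threshold segmentation followed by an intensity-weighted center of mass
#' over the above-threshold pixels — the minimal blob tracker the assay
#' needs, assuming the animal is brighter than the background (synthetic
#' convention; invert real frames first if polarity differs). By default the
#' frame is denoised with a 3x3 box mean before thresholding, which
#' suppresses isolated sensor-noise exceedances without biasing the centroid
#' (the kernel is symmetric); set `smooth = FALSE` for raw-pixel semantics.
#' A pixel's coordinate is its matrix index, with the frame oriented
#' `[x, y]` (first index along arena x, second along arena y, y up).
#'
#' @param frame Numeric matrix of intensities.
#' @param threshold Pixels strictly above this value belong to the blob
#'   (applied to the smoothed frame when `smooth = TRUE`).
#' @param smooth Apply the 3x3 box denoising first?
#' @return `c(x, y)` in pixel units, or `NULL` when no pixel clears the
#'   threshold (a tracking dropout, not an error).
#' @export
extract_centroid <- function(frame, threshold, smooth = TRUE) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  if (smooth) frame <- box3_mean(frame)
  mask <- frame > threshold
  if (!any(mask)) return(NULL)
  w <- frame[mask]
  idx <- which(mask, arr.ind = TRUE)
  c(x = sum(idx[, 1] * w) / sum(w), y = sum(idx[, 2] * w) / sum(w))
}

# 3x3 box mean with edge truncation (divide by the in-frame kernel count).
box3_mean <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    acc[ri, rj] <- acc[ri, rj] + f[si, sj, drop = FALSE]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  acc / cnt
}

#' Track a stack of frames into a trajectory
#'
#' Runs [extract_centroid()] on every frame, converts pixel positions to cm
#' via the arena calibration and assembles an [trajectory()]. Dropout frames
#' (no pixel above threshold) are flagged invalid; runs of up to 0.5 s
#' (10 frames at 20 fps) are forward-filled with the last valid position so
#' the closed-loop engine can hold its state, but they keep `valid = FALSE`
#' and are excluded from all analysis denominators.
#'
#' @param frames List of equally-shaped intensity matrices, ordered in time.
#' @param arena An [arena_spec()] with `px_per_cm` set.
#' @param threshold Blob threshold passed to [extract_centroid()].
#' @param smooth Denoise each frame first (see [extract_centroid()]).
#' @return An `sa_trajectory`.
#' @export
track_frames <- function(frames, arena, threshold, smooth = TRUE) {
  if (length(frames) == 0) stop("empty frame stack", call. = FALSE)
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("all frames must share one shape", call. = FALSE)
  n <- length(frames)
  x <- y <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    cen <- extract_centroid(frames[[i]], threshold, smooth = smooth)
    if (!is.null(cen)) {
      cm <- pixel_to_cm(cen[["x"]], cen[["y"]], arena)
      x[i] <- cm$x_cm; y[i] <- cm$y_cm
      valid[i] <- TRUE
    }
  }
  max_fill <- ceiling(0.5 * arena$fps)
  x <- forward_fill(x, valid, max_fill)
  y <- forward_fill(y, valid, max_fill)
  trajectory(time_s = (seq_len(n) - 1) / arena$fps, x_cm = x, y_cm = y,
             valid = valid, fps = arena$fps)
}

# Fill NA runs of length <= max_run with the last preceding valid value.
forward_fill <- function(v, valid, max_run) {
  run <- 0L
  last <- NA_real_
  for (i in seq_along(v)) {
    if (valid[i]) {
      last <- v[i]; run <- 0L
    } else {
      run <- run + 1L
      if (run <= max_run && !is.na(last)) v[i] <- last
    }
  }
  v
}

#' Read and write trajectory CSV files
#'
#' Two dialects are accepted: `time_s, x_cm, y_cm` (optionally `valid`) for
#' calibrated input, and `frame, x_px, y_px` (optionally `valid`) for pixel
#' input, which requires an arena with `px_per_cm`; timestamps are then
#' synthesized from the frame index and frame rate. Writing always emits the
#' cm dialect; a read of a written file reproduces the trajectory to six
#' decimal places.
#'
#' @param path CSV path.
#' @param arena [arena_spec()]; required for the pixel dialect.
#' @return `read_trajectory()` returns an `sa_trajectory`.
#' @export
read_trajectory <- function(path, arena = arena_spec()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- names(df)
  valid <- if ("valid" %in% cols) as.logical(df$valid) else TRUE
  if (all(c("time_s", "x_cm", "y_cm") %in% cols)) {
    traj <- trajectory(df$time_s, df$x_cm, df$y_cm, valid = valid,
                       fps = arena$fps)
  } else if (all(c("frame", "x_px", "y_px") %in% cols)) {
    cm <- pixel_to_cm(df$x_px, df$y_px, arena)
    traj <- trajectory(df$frame / arena$fps, cm$x_cm, cm$y_cm, valid = valid,
                       fps = arena$fps)
  } else {
    stop("unknown trajectory column dialect: expected (time_s, x_cm, y_cm) ",
         "or (frame, x_px, y_px); got (", paste(cols, collapse = ", "), ")",
         call. = FALSE)
  }
  traj
}

#' @rdname read_trajectory
#' @param traj An `sa_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = sprintf("%.6f", traj$time_s),
                   x_cm = ifelse(is.na(traj$x_cm), "",
                                 sprintf("%.6f", traj$x_cm)),
                   y_cm = ifelse(is.na(traj$y_cm), "",
                                 sprintf("%.6f", traj$y_cm)),
                   valid = traj$valid)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
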