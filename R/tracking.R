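#' Percentile background image
#'
#' Computes the per-pixel 95th percentile of intensity over a window of
#' frames. Because the fish is dark and covers any pixel only briefly, the
#' high percentile recovers the sand background.
#'
#' @param frames Array `height x width x n` (n >= 2).
#' @param prob Percentile, default 0.95.
#' @return Matrix `height x width` with attribute `window` (frame count).
#' @export
compute_background <- function(frames, prob = 0.95) {
  if (length(dim(frames)) != 3 || dim(frames)[3] < 2)
    stop("need at least 2 frames")
  d <- dim(frames)
  m <- matrix(frames, nrow = d[1] * d[2], ncol = d[3])
  bg <- matrix(apply(m, 1, quantile, probs = prob, names = FALSE),
               nrow = d[1], ncol = d[2])
  attr(bg, "window") <- d[3]
  bg
}

#' Detect the fish blob in one frame
#'
#' Background subtraction and thresholding: pixels with
#' `|frame - background| > intensity_threshold` are labelled into connected
#' components; the largest component with area `>= min_area` (boundary
#' inclusive) is returned with its intensity-weighted centroid.
#'
#' @param frame,background Matrices of identical dimensions.
#' @param intensity_threshold Absolute-difference threshold.
#' @param min_area Minimum object area in px (inclusive), default 100.
#' @param weighted Use intensity-weighted centroid (default) or binary.
#' @return List `(x, y, area)` or `NULL` when no object qualifies
#'   ("missing" is a value, not an error).
#' @export
detect_blob <- function(frame, background, intensity_threshold = 40,
                        min_area = 100, weighted = TRUE) {
  stopifnot(all(dim(frame) == dim(background)))
  dif <- abs(frame - background)
  mask <- dif > intensity_threshold
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  ok <- which(sizes >= min_area)
  if (!length(ok)) return(NULL)
  best <- ok[which.max(sizes[ok])]
  idx <- which(lab == best, arr.ind = TRUE)
  wgt <- if (weighted) dif[lab == best] else rep(1, nrow(idx))
  list(x = sum(idx[, 2] * wgt) / sum(wgt),
       y = sum(idx[, 1] * wgt) / sum(wgt),
       area = sizes[best])
}

#' Track a frame stack
#'
#' Runs blob detection against a rolling percentile background (recomputed
#' for each window of frames), then linearly interpolates positions across
#' missing frames; leading/trailing missing runs take the nearest detection.
#'
#' @param stack Array `height x width x n` or the list returned by
#'   [render_frames()].
#' @param fps Frames per second of the stack.
#' @param background_window Background window length in frames (<= n).
#' @param intensity_threshold,min_area,weighted Passed to [detect_blob()].
#' @return Trajectory data.frame (`time`, `x`, `y`, `area`, `missing`) with
#'   `fps` attribute; positions in px.
#' @export
track_stack <- function(stack, fps = 10, background_window = NULL,
                        intensity_threshold = 40, min_area = 100,
                        weighted = TRUE) {
  if (is.list(stack)) stack <- stack$frames
  n <- dim(stack)[3]
  if (is.null(background_window)) background_window <- n
  if (background_window > n) stop("background window exceeds stack length")
  x <- y <- area <- rep(NA_real_, n)
  starts <- seq(1, n, by = background_window)
  for (s in starts) {
    e <- min(n, s + background_window - 1)
    if (e - s + 1 < 2) { s2 <- max(1, e - 1); bgw <- s2:e } else bgw <- s:e
    bg <- compute_background(stack[, , bgw, drop = FALSE])
    for (k in s:e) {
      det <- detect_blob(stack[, , k], bg, intensity_threshold, min_area,
                         weighted)
      if (!is.null(det)) { x[k] <- det$x; y[k] <- det$y; area[k] <- det$area }
    }
  }
  missing <- !is.finite(x)
  if (all(missing)) stop("no detections in entire stack")
  time <- (seq_len(n) - 1) / fps
  x <- approx(time[!missing], x[!missing], xout = time, rule = 2)$y
  y <- approx(time[!missing], y[!missing], xout = time, rule = 2)$y
  out <- data.frame(time = time, x = x, y = y, area = area,
                    missing = missing)
  attr(out, "fps") <- fps
  attr(out, "units") <- "px"
  out
}

#' Interpolate missing frames of a trajectory
#'
#' Linear interpolation of `x` and `y` across frames flagged missing;
#' leading/trailing runs are filled with the nearest detection.
#'
#' @param traj Trajectory data.frame with `time`, `x`, `y`, `missing`.
#' @return Trajectory with positions filled in; `missing` flags retained.
#' @export
interpolate_missing <- function(traj) {
  ok <- !traj$missing & is.finite(traj$x) & is.finite(traj$y)
  if (!any(ok)) stop("no detections to interpolate from")
  traj$x <- approx(traj$time[ok], traj$x[ok], xout = traj$time, rule = 2)$y
  traj$y <- approx(traj$time[ok], traj$y[ok], xout = traj$time, rule = 2)$y
  traj
}

#' Remove single-frame tracking spikes
#'
#' Frames whose frame-to-frame displacement exceeds `jump_threshold` px get
#' `x`, `y` replaced by the mean of the surrounding +/- 5 frames (1 s at
#' 10 Hz), excluding every frame flagged in the same pass (a one-frame
#' excursion flags both the outgoing and the returning jump, and the spike
#' itself must not pollute the replacement mean); at sequence edges the
#' mean is taken over the available neighbours. The pass is repeated to a
#' fixed point (or `max_pass`), so consecutive spikes are also resolved.
#'
#' @param traj Trajectory data.frame (>= 11 frames).
#' @param jump_threshold Displacement threshold in px, default 200.
#' @param halfwin Neighbour half-window in frames, default 5.
#' @param max_pass Iteration cap, default 10.
#' @return Despiked trajectory.
#' @export
despike <- function(traj, jump_threshold = 200, halfwin = 5, max_pass = 10) {
  n <- nrow(traj)
  if (n < 2 * halfwin + 1) stop("need at least ", 2 * halfwin + 1, " frames")
  for (pass in seq_len(max_pass)) {
    d <- c(0, sqrt(diff(traj$x)^2 + diff(traj$y)^2))
    bad <- which(d > jump_threshold)
    if (!length(bad)) break
    newx <- traj$x; newy <- traj$y
    for (i in bad) {
      nb <- setdiff(max(1, i - halfwin):min(n, i + halfwin), bad)
      if (!length(nb))
        nb <- setdiff(max(1, i - halfwin):min(n, i + halfwin), i)
      newx[i] <- mean(traj$x[nb]); newy[i] <- mean(traj$y[nb])
    }
    traj$x <- newx; traj$y <- newy
  }
  traj
}

#' Smooth a trajectory with a centred moving average
#'
#' Boxcar smoothing of `x` and `y` over a time window (0.5 s, i.e. 5 frames
#' at 10 Hz, by default); windows shrink symmetrically at the edges.
#'
#' @param traj Trajectory data.frame.
#' @param window Window length in seconds, default 0.5.
#' @param fps Frames per second; taken from the `fps` attribute if absent.
#' @return Smoothed trajectory.
#' @export
smooth_track <- function(traj, window = 0.5, fps = NULL) {
  if (is.null(fps)) fps <- attr(traj, "fps")
  if (is.null(fps)) fps <- 1 / median(diff(traj$time))
  k <- max(1L, round(window * fps))
  if (k %% 2 == 0) k <- k + 1L
  traj$x <- running_mean(traj$x, k)
  traj$y <- running_mean(traj$y, k)
  traj
}

# centred running mean with shrinking edge windows
running_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Calibrate a pixel trajectory to mm
#'
#' @param traj Trajectory in px.
#' @param px_per_mm Pixel scale (> 0); taken from the attribute if absent.
#' @return Trajectory with `x`, `y` in mm (`units` attribute set to "mm").
#' @export
calibrate <- function(traj, px_per_mm = NULL) {
  if (is.null(px_per_mm)) px_per_mm <- attr(traj, "px_per_mm")
  if (is.null(px_per_mm) || px_per_mm <= 0)
    stop("px_per_mm must be positive")
  traj$x <- traj$x / px_per_mm
  traj$y <- traj$y / px_per_mm
  attr(traj, "units") <- "mm"
  attr(traj, "px_per_mm") <- px_per_mm
  traj
}

#' Undo [calibrate()]
#' @param traj Calibrated trajectory (mm).
#' @param px_per_mm Pixel scale; defaults to the stored attribute.
#' @return Trajectory in px.
#' @export
uncalibrate <- function(traj, px_per_mm = NULL) {
  if (is.null(px_per_mm)) px_per_mm <- attr(traj, "px_per_mm")
  traj$x <- traj$x * px_per_mm
  traj$y <- traj$y * px_per_mm
  attr(traj, "units") <- "px"
  traj
}
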