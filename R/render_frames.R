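#' Render grayscale frames from a trajectory
#'
#' Produces a synthetic frame stack for exercising the tracking chain: a dark
#' fish blob (a filled disk of the requested area) on a brighter sand-like
#' background whose texture can drift slowly over time, plus Gaussian pixel
#' noise. The ground-truth centroid of every frame is recorded.
#'
#' @param trajectory Data frame with columns `time` (s), `x`, `y` (px,
#'   image convention, 1-based pixel coordinates).
#' @param arena Frame size in px, `c(width, height)`.
#' @param blob_area Fish blob area, px^2 (disk of radius `sqrt(area/pi)`).
#' @param drift Sand-drift rate, px/hour; translates the background texture.
#' @param seed Integer seed for the pixel noise.
#' @param bg_level,blob_level Background and blob intensities (0-255 scale).
#' @param noise_sd SD of the per-pixel Gaussian noise.
#'
#' @return List with `frames`, an array `height x width x n`, and `truth`, a
#'   data.frame of the rendered centroids.
#' @export
render_frames <- function(trajectory, arena = c(width = 160, height = 120),
                          blob_area = 300, drift = 0, seed = 1,
                          bg_level = 180, blob_level = 60, noise_sd = 3) {
  w <- as.integer(arena[1]); h <- as.integer(arena[2])
  n <- nrow(trajectory)
  r <- sqrt(blob_area / pi)
  if (any(trajectory$x < r | trajectory$x > w - r + 1 |
          trajectory$y < r | trajectory$y > h - r + 1, na.rm = TRUE))
    stop("blob outside arena")
  set.seed(as.integer(seed))
  ph <- runif(4, 0, 2 * pi)
  frames <- array(0, dim = c(h, w, n))
  xs <- seq_len(w); ys <- seq_len(h)
  for (k in seq_len(n)) {
    off <- drift * trajectory$time[k] / 3600
    tex <- 12 * outer(sin(2 * pi * ys / 37 + ph[1]),
                      sin(2 * pi * (xs + off) / 53 + ph[2])) +
      8 * outer(cos(2 * pi * ys / 17 + ph[3]),
                cos(2 * pi * (xs + off) / 23 + ph[4]))
    fr <- bg_level + tex
    cx <- trajectory$x[k]; cy <- trajectory$y[k]
    if (is.finite(cx) && is.finite(cy)) {
      ix <- xs[abs(xs - cx) <= r]
      iy <- ys[abs(ys - cy) <= r]
      if (length(ix) && length(iy)) {
        d2 <- outer((iy - cy)^2, (ix - cx)^2, "+")
        sub <- fr[iy, ix, drop = FALSE]
        sub[d2 <= r^2] <- blob_level
        fr[iy, ix] <- sub
      }
    }
    frames[, , k] <- fr + rnorm(h * w, 0, noise_sd)
  }
  list(frames = frames,
       truth = data.frame(time = trajectory$time,
                          x = trajectory$x, y = trajectory$y))
}
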