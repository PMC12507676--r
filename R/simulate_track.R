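#' Simulate a multi-day behavioural track for one individual
#'
#' Generates a 10 Hz (configurable) position track whose instantaneous speed
#' follows the diel intensity of a [diel_template()] plus multiplicative
#' gamma noise, with contiguous rest bouts produced by a two-state
#' (active/rest) semi-Markov process with phase-dependent entry rates.
#' Optional tracking artifacts (missing-detection gaps and single-frame
#' position spikes) can be injected. Time 0 is local midnight of day 1.
#'
#' @param template A [diel_template()].
#' @param schedule A [make_light_schedule()].
#' @param days Number of whole days to simulate (>= 1).
#' @param fps Frames per second (> 0); the assay records at 10 Hz.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param px_per_mm Pixel scale of the camera (px per mm).
#' @param arena Arena size in px, `c(width, height)`; image convention
#'   (origin top-left, y increases downward).
#' @param gap_rate Missing-detection gaps per hour (mean length 2 s).
#' @param spike_rate Single-frame position spikes (> 200 px) per hour.
#' @param rest_speed_sd SD of the residual speed during rest bouts, mm/s.
#' @param speed_cv Coefficient of variation of active-speed gamma noise.
#'
#' @return A list with `track` — a data.frame with columns `time` (s), `x`,
#'   `y` (px), `area` (px^2) and `missing` — and `truth`, a list holding the
#'   artifact-free positions, per-frame true rest flags, expected speeds and
#'   the bout process realisation. `fps`, `px_per_mm` and the schedule are
#'   attached as attributes of `track`.
#' @export
simulate_track <- function(template, schedule, days = 6, fps = 10,
                           seed = 1, px_per_mm = 2,
                           arena = c(width = 500, height = 900),
                           gap_rate = 0, spike_rate = 0,
                           rest_speed_sd = 2.5, speed_cv = 0.5) {
  stopifnot(days >= 1, fps > 0)
  set.seed(as.integer(seed))
  total_s <- days * 86400
  n <- as.integer(round(total_s * fps))
  time <- (seq_len(n) - 1) / fps

  bouts <- simulate_rest_bouts(template, schedule, total_s)
  rest <- logical(n)
  if (nrow(bouts)) {
    for (b in seq_len(nrow(bouts))) {
      i0 <- floor(bouts$start[b] * fps) + 1
      i1 <- min(n, ceiling(bouts$end[b] * fps))
      if (i0 <= i1) rest[i0:i1] <- TRUE
    }
  }

  exp_speed <- template_speed(template, schedule, time)
  shape <- 1 / speed_cv^2
  speed <- exp_speed * rgamma(n, shape = shape, rate = shape)
  speed[rest] <- abs(rnorm(sum(rest), 0, rest_speed_sd))
  true_rest <- rest | exp_speed == 0

  # random-walk heading; reflective arena boundaries via path folding
  theta <- cumsum(rnorm(n, 0, 0.4))
  step_px <- speed / fps * px_per_mm
  x <- fold_reflect(arena[1] / 2 + cumsum(step_px * cos(theta)), arena[1])
  y <- fold_reflect(arena[2] / 2 + cumsum(step_px * sin(theta)), arena[2])
  x_true <- x
  y_true <- y

  missing <- logical(n)
  if (gap_rate > 0) {
    n_gap <- rpois(1, gap_rate * total_s / 3600)
    if (n_gap > 0) {
      starts <- sample.int(n, n_gap)
      lens <- 1 + rpois(n_gap, 2 * fps)
      for (g in seq_len(n_gap)) {
        idx <- starts[g]:min(n, starts[g] + lens[g] - 1)
        missing[idx] <- TRUE
      }
    }
  }
  if (spike_rate > 0) {
    n_spk <- rpois(1, spike_rate * total_s / 3600)
    if (n_spk > 0) {
      at <- sample(2:(n - 1), min(n_spk, n - 2))
      ang <- runif(length(at), 0, 2 * pi)
      mag <- runif(length(at), 250, 400)
      x[at] <- x[at] + mag * cos(ang)
      y[at] <- y[at] + mag * sin(ang)
    }
  }
  x[missing] <- NA_real_
  y[missing] <- NA_real_

  area <- rnorm(n, 350, 30)
  area[missing] <- NA_real_

  track <- data.frame(time = time, x = x, y = y, area = area,
                      missing = missing)
  attr(track, "fps") <- fps
  attr(track, "px_per_mm") <- px_per_mm
  attr(track, "units") <- "px"
  attr(track, "schedule") <- schedule
  list(track = track,
       truth = list(x = x_true, y = y_true, rest = true_rest,
                    expected_speed = exp_speed, bouts = bouts,
                    arena = arena))
}

# piecewise-constant-hazard semi-Markov rest bout process; exact via
# redrawing the exponential waiting time at each phase boundary
simulate_rest_bouts <- function(template, schedule, total_s) {
  rate_of <- function(t) {
    st <- schedule$state(t)
    r <- template$rest_bout_rate
    unname(ifelse(st == "day", r["day"],
                  ifelse(st == "night", r["night"], r["ramp"]))) / 3600
  }
  boundaries <- function(t) {
    tod <- t %% 86400
    day0 <- t - tod
    pts <- day0 + c(schedule$day_start, schedule$day_start + schedule$ramp_s,
                    schedule$day_end - schedule$ramp_s, schedule$day_end,
                    86400)
    min(pts[pts > t + 1e-9])
  }
  t <- 0
  start <- numeric(0); end <- numeric(0)
  while (t < total_s) {
    # waiting time to next rest bout under the current phase's rate
    repeat {
      r <- rate_of(t)
      b <- boundaries(t)
      w <- if (r > 0) rexp(1, r) else Inf
      if (t + w <= b) { t <- t + w; break }
      t <- b
      if (t >= total_s) break
    }
    if (t >= total_s) break
    d <- rexp(1, 1 / template$rest_bout_mean_duration)
    start <- c(start, t); end <- c(end, min(t + d, total_s))
    t <- t + d
  }
  data.frame(start = start, end = end)
}

# reflect a path into [0, L]
fold_reflect <- function(x, L) {
  m <- x %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}
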