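#' Swimming speed from subsequent positions
#'
#' Euclidean displacement between subsequent `x`, `y` positions divided by
#' the frame interval. The speed is assigned to the later frame of each
#' pair; the first frame gets speed 0 so the series matches the track
#' length.
#'
#' @param track Calibrated trajectory (positions in mm) with `time` in s.
#' @return Data frame `time`, `speed` (mm/s) with the track's attributes.
#' @export
speed_series <- function(track) {
  if (nrow(track) < 2) stop("need at least 2 frames")
  dt <- diff(track$time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  sp <- c(0, sqrt(diff(track$x)^2 + diff(track$y)^2) / dt)
  out <- data.frame(time = track$time, speed = sp)
  attr(out, "fps") <- attr(track, "fps")
  out
}

#' Movement flags from a speed series
#'
#' A frame counts as movement when speed strictly exceeds the threshold
#' (15 mm/s by default); below it, residual speed is mostly tracking noise
#' and fin undulation.
#'
#' @param s Speed series from [speed_series()] (or a numeric vector, mm/s).
#' @param threshold Movement threshold in mm/s (> 0), default 15.
#' @return Logical vector.
#' @export
movement_flags <- function(s, threshold = 15) {
  stopifnot(threshold > 0)
  sp <- if (is.data.frame(s)) s$speed else s
  sp > threshold
}

#' Rest flags from movement flags
#'
#' A time point is at rest when strictly less than `max_frac` of the frames
#' in the centred sliding window (60 s by default) are movement. Edge
#' windows shrink to the available frames.
#'
#' @param m Logical movement flags.
#' @param window Window length in seconds, default 60.
#' @param max_frac Movement fraction bound (strict `<`), default 0.05.
#' @param fps Frames per second of the series.
#' @return Logical rest flags, same length as `m`.
#' @export
rest_flags <- function(m, window = 60, max_frac = 0.05, fps = 10) {
  k <- max(1L, as.integer(round(window * fps)))
  n <- length(m)
  h1 <- (k - 1L) %/% 2L
  h2 <- k - 1L - h1
  cs <- cumsum(c(0, as.numeric(m)))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  frac <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  frac < max_frac
}

#' Average daily total rest
#'
#' Sums rest time within each complete day (midnight to midnight) and
#' averages across days. Days with frame coverage below `min_coverage` of
#' the nominal day length are excluded.
#'
#' @param rest Logical rest flags.
#' @param time Timestamps in s (0 = midnight of day 1).
#' @param fps Frames per second.
#' @param min_coverage Minimum fraction of the day's nominal frames, 0.95.
#' @return Mean hours of rest per day (scalar). Rest and non-rest always sum
#'   to 24 h within each retained day.
#' @export
total_rest <- function(rest, time, fps = 10, min_coverage = 0.95) {
  day <- floor(time / 86400)
  frames_per_day <- 86400 * fps
  cnt <- table(day)
  keep <- as.numeric(names(cnt))[cnt >= min_coverage * frames_per_day]
  if (!length(keep)) stop("no complete day of data")
  per_day <- vapply(keep, function(d) mean(rest[day == d]) * 24, numeric(1))
  mean(per_day)
}

#' Bin a series into midnight-anchored 30-min bins
#'
#' @param time Timestamps in s (0 = midnight of day 1).
#' @param value Numeric series (speed in mm/s, or 0/1 rest flags).
#' @return A `days x 48` matrix of per-bin means (class `binned_day`), with
#'   a `counts` attribute holding per-bin sample counts (0-count bins are
#'   `NA` and thereby flagged).
#' @export
bin30 <- function(time, value) {
  if (diff(range(time)) < 86400 - 1800)
    stop("series must span at least one day")
  day <- floor(time / 86400)
  bin <- floor((time %% 86400) / 1800) + 1
  days <- sort(unique(day))
  mat <- matrix(NA_real_, length(days), 48,
                dimnames = list(day = days, bin = 1:48))
  cnt <- matrix(0L, length(days), 48)
  di <- match(day, days)
  sums <- rowsum(value, group = (di - 1) * 48 + bin)
  ns <- rowsum(rep(1, length(value)), group = (di - 1) * 48 + bin)
  key <- as.integer(rownames(sums))
  mat[cbind((key - 1) %/% 48 + 1, (key - 1) %% 48 + 1)] <- sums / ns
  cnt[cbind((key - 1) %/% 48 + 1, (key - 1) %% 48 + 1)] <- as.integer(ns)
  attr(mat, "counts") <- cnt
  class(mat) <- c("binned_day", "matrix")
  mat
}

#' Species daily profile from per-individual binned days
#'
#' Averages each individual's binned days into a daily 48-bin profile, then
#' averages across individuals. The per-bin SD is taken across individuals'
#' daily means (the across-days SD of the pooled data is also returned).
#'
#' @param binned_list List of `days x 48` matrices, one per individual.
#' @param species Six-letter species code.
#' @return List of class `species_profile`: `species`, `profile` (48-vector),
#'   `sd` (across individuals), `sd_days` (across days, pooled), `n`,
#'   `individual_means` (`n x 48`).
#' @export
daily_profile <- function(binned_list, species = "unknwn") {
  ind <- do.call(rbind, lapply(binned_list, function(m)
    colMeans(unclass(m), na.rm = TRUE)))
  alldays <- do.call(rbind, lapply(binned_list, unclass))
  prof <- colMeans(ind)
  sd_ind <- if (nrow(ind) > 1) apply(ind, 2, sd) else rep(NA_real_, 48)
  structure(
    list(species = species, profile = prof, sd = sd_ind,
         sd_days = apply(alldays, 2, sd, na.rm = TRUE),
         n = length(binned_list), individual_means = ind),
    class = "species_profile")
}

#' Scaled vertical position
#'
#' Scales the vertical position of the fish into `[0, 1]` with 0 the lowest
#' and 1 the highest observed position. Image-convention y (downward) is
#' inverted, so larger values mean higher in the water column.
#'
#' @param track Trajectory with image-convention `y`.
#' @return Numeric vector in `[0, 1]`; constant y gives all 0.5 with a
#'   warning.
#' @export
vertical_scaled <- function(track) {
  y <- track$y
  rng <- range(y, na.rm = TRUE)
  if (diff(rng) == 0) {
    warning("constant vertical position; returning 0.5")
    return(rep(0.5, length(y)))
  }
  (rng[2] - y) / (rng[2] - rng[1])
}

#' Paired test of vertical position during rest vs activity
#'
#' For each species, each individual contributes its mean scaled vertical
#' position during rest and during active (non-rest) frames; a paired
#' t-test compares the two, with Bonferroni correction across species
#' (p multiplied by the number of species tested, capped at 1).
#'
#' @param data List per species: each element a list of individuals, each
#'   with components `vertical` (from [vertical_scaled()]) and `rest`
#'   (logical flags).
#' @return Data frame with one row per species: `species`, `n`, `mean_rest`,
#'   `mean_active`, `t`, `df`, `p`, `p_adj`. Species with a single
#'   individual are skipped (with a message).
#' @export
rest_position_test <- function(data) {
  rows <- lapply(names(data), function(sp) {
    inds <- data[[sp]]
    pr <- vapply(inds, function(i) mean(i$vertical[i$rest]), numeric(1))
    pa <- vapply(inds, function(i) mean(i$vertical[!i$rest]), numeric(1))
    ok <- is.finite(pr) & is.finite(pa)
    pr <- pr[ok]; pa <- pa[ok]
    if (length(pr) < 2) {
      message("species ", sp, " has < 2 usable individuals; skipped")
      return(NULL)
    }
    d <- pr - pa
    if (sd(d) == 0) {
      tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
    } else {
      tt <- t.test(pr, pa, paired = TRUE)
    }
    data.frame(species = sp, n = length(pr),
               mean_rest = mean(pr), mean_active = mean(pa),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adj <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Fisher g-test periodogram
#'
#' Detrends the binned speed series (removes a linear trend), computes the
#' FFT periodogram, and tests the largest ordinate with Fisher's exact
#' g-statistic; further peaks are tested iteratively after removing the
#' ordinates already found, until a peak fails the threshold or `max_peaks`
#' is reached.
#'
#' @param x Binned speed values, equally spaced.
#' @param dt Bin width in seconds, default 1800 (30-min bins).
#' @param threshold Significance threshold on the Fisher p, default 0.05.
#' @param max_peaks Maximum number of peaks reported, default 5.
#' @return Data frame `period_h`, `power`, `p`, `significant`, ordered as
#'   found; the full spectrum is attached as attribute `spectrum`.
#' @export
fisher_periodogram <- function(x, dt = 1800, threshold = 0.05,
                               max_peaks = 5) {
  n <- length(x)
  if (n * dt < 2 * 86400) stop("need at least 2 days of bins")
  tt <- seq_along(x)
  x <- x - fitted(lm(x ~ tt))
  I <- Mod(fft(x))^2 / n
  m <- floor((n - 1) / 2)
  I <- I[2:(m + 1)]
  periods <- n * dt / (1:m) / 3600
  spectrum <- data.frame(period_h = periods, power = I)
  avail <- rep(TRUE, m)
  out <- NULL
  for (i in seq_len(max_peaks)) {
    mm <- sum(avail)
    if (mm < 2) break
    k <- which(avail)[which.max(I[avail])]
    g <- I[k] / sum(I[avail])
    p <- fisher_g_p(g, mm)
    sig <- p < threshold
    out <- rbind(out, data.frame(period_h = periods[k], power = I[k],
                                 p = p, significant = sig))
    if (!sig) break
    avail[k] <- FALSE
  }
  attr(out, "spectrum") <- spectrum
  out
}

# exact tail probability of Fisher's g with m ordinates
fisher_g_p <- function(g, m) {
  jmax <- min(m, floor(1 / g))
  j <- seq_len(jmax)
  p <- sum((-1)^(j - 1) * exp(lchoose(m, j) + (m - 1) * log1p(-j * g)))
  min(1, max(0, p))
}
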