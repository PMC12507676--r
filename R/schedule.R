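#' Build a laboratory light schedule
#'
#' Defines the daily light cycle of the behavioural assay: lights ramp on over
#' `ramp` minutes starting at `day_start`, stay on until `day_end`, and ramp
#' off over the `ramp` minutes preceding `day_end`. The default mirrors a
#' 12:12 light:dark cycle with 30-min dawn/dusk ramps (07:00-19:00).
#'
#' @param day_start,day_end Clock times, `"HH:MM"` strings or hours as
#'   numbers (e.g. `7` or `"07:00"`). `day_start < day_end`.
#' @param ramp Ramp duration in minutes, `>= 0`. `ramp = 0` gives a step
#'   schedule with states `day`/`night` only. The two ramps must not overlap
#'   (`2 * ramp` may not exceed the day length) and must not spill into the
#'   night on either side.
#'
#' @return An object of class `light_schedule` with elements `day_start`,
#'   `day_end`, `ramp_s` (all seconds since midnight), `state(t)` returning
#'   one of `"night"`, `"dawn-ramp"`, `"day"`, `"dusk-ramp"` for times `t` in
#'   seconds (periodic over 24 h), and `light(t)` returning relative light
#'   intensity in `[0, 1]` (linear ramps).
#' @export
#' @examples
#' sch <- make_light_schedule("07:00", "19:00", 30)
#' sch$state(13 * 3600)  # "day"
make_light_schedule <- function(day_start = "07:00", day_end = "19:00",
                                ramp = 30) {
  t0 <- parse_clock(day_start)
  t1 <- parse_clock(day_end)
  if (!(t0 < t1)) stop("day_start must precede day_end")
  if (ramp < 0) stop("ramp must be non-negative")
  ramp_s <- ramp * 60
  day_len <- t1 - t0
  if (2 * ramp_s > day_len) stop("ramps overlap: 2*ramp exceeds day length")

  state <- function(t) {
    tod <- t %% 86400
    out <- rep("night", length(tod))
    if (ramp_s > 0) {
      out[tod >= t0 & tod < t0 + ramp_s] <- "dawn-ramp"
      out[tod >= t0 + ramp_s & tod < t1 - ramp_s] <- "day"
      out[tod >= t1 - ramp_s & tod < t1] <- "dusk-ramp"
    } else {
      out[tod >= t0 & tod < t1] <- "day"
    }
    out
  }
  light <- function(t) {
    tod <- t %% 86400
    l <- numeric(length(tod))
    if (ramp_s > 0) {
      up <- tod >= t0 & tod < t0 + ramp_s
      l[up] <- (tod[up] - t0) / ramp_s
      dn <- tod >= t1 - ramp_s & tod < t1
      l[dn] <- (t1 - tod[dn]) / ramp_s
      l[tod >= t0 + ramp_s & tod < t1 - ramp_s] <- 1
    } else {
      l[tod >= t0 & tod < t1] <- 1
    }
    l
  }
  structure(
    list(day_start = t0, day_end = t1, ramp_s = ramp_s,
         day_length = day_len, state = state, light = light),
    class = "light_schedule")
}

#' @exportS3Method base::print
print.light_schedule <- function(x, ...) {
  cat(sprintf("light schedule: day %s-%s, ramp %d min\n",
              fmt_clock(x$day_start), fmt_clock(x$day_end), x$ramp_s %/% 60))
  invisible(x)
}

# "HH:MM" or numeric hours -> seconds since midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(x * 3600)
  parts <- strsplit(as.character(x), "[:.]")[[1]]
  if (length(parts) == 1) parts <- c(parts, "0")
  as.numeric(parts[1]) * 3600 + as.numeric(parts[2]) * 60
}

fmt_clock <- function(s) sprintf("%02d:%02d", s %/% 3600, (s %% 3600) %/% 60)

#' Midnight-anchored 30-min bin states for a schedule
#'
#' Labels each of the 48 half-hour bins of the day with the light state at
#' its midpoint; used to orient PCA axes and summarise profiles by phase.
#'
#' @param schedule A [make_light_schedule()] object.
#' @return Character vector of length 48.
#' @export
bin_states <- function(schedule) {
  mids <- (seq_len(48) - 0.5) * 1800
  schedule$state(mids)
}
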