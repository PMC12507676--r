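#' Diel activity template for a synthetic species
#'
#' Parametrises the expected instantaneous swim speed over the day as the sum
#' of a day/night square wave convolved with the light ramps and Gaussian
#' bumps at dawn and dusk, plus a two-state (active/rest) semi-Markov bout
#' process with phase-dependent rates. The four archetypes correspond to the
#' classical diel guilds.
#'
#' @param archetype One of `"diurnal"`, `"nocturnal"`, `"crepuscular"`,
#'   `"cathemeral"`.
#' @param base_speed Baseline active swim speed, mm/s.
#' @param day_night_contrast Dimensionless >= 0; relative amplitude of the
#'   day/night modulation (sign set by the archetype). Forced to 0 for
#'   cathemeral templates.
#' @param crepuscular_gain Dimensionless >= 0; amplitude of the dawn/dusk
#'   Gaussian bumps (SD 30 min). Forced to 0 for cathemeral templates.
#' @param rest_bout_rate Named numeric, rest bouts per hour by light phase
#'   (`day`, `night`, `ramp`).
#' @param rest_bout_mean_duration Mean rest bout duration, seconds.
#'
#' @return A `diel_template` object.
#' @export
diel_template <- function(archetype = c("diurnal", "nocturnal",
                                        "crepuscular", "cathemeral"),
                          base_speed = NULL,
                          day_night_contrast = NULL,
                          crepuscular_gain = NULL,
                          rest_bout_rate = NULL,
                          rest_bout_mean_duration = 300) {
  archetype <- match.arg(archetype)
  defaults <- switch(archetype,
    diurnal     = list(bs = 30, dnc = 1.2, cg = 0.4,
                       rr = c(day = 1.5, night = 9, ramp = 3)),
    nocturnal   = list(bs = 30, dnc = 1.2, cg = 0.4,
                       rr = c(day = 9, night = 1.5, ramp = 3)),
    crepuscular = list(bs = 25, dnc = 0.15, cg = 2.5,
                       rr = c(day = 6, night = 6, ramp = 0.5)),
    cathemeral  = list(bs = 28, dnc = 0, cg = 0,
                       rr = c(day = 4.5, night = 4.5, ramp = 4.5)))
  if (is.null(base_speed)) base_speed <- defaults$bs
  if (is.null(day_night_contrast)) day_night_contrast <- defaults$dnc
  if (is.null(crepuscular_gain)) crepuscular_gain <- defaults$cg
  if (is.null(rest_bout_rate)) rest_bout_rate <- defaults$rr
  if (archetype == "cathemeral") {
    day_night_contrast <- 0
    crepuscular_gain <- 0
  }
  stopifnot(base_speed >= 0, day_night_contrast >= 0, crepuscular_gain >= 0,
            all(rest_bout_rate >= 0), rest_bout_mean_duration > 0)
  structure(
    list(archetype = archetype, base_speed = base_speed,
         day_night_contrast = day_night_contrast,
         crepuscular_gain = crepuscular_gain,
         rest_bout_rate = rest_bout_rate,
         rest_bout_mean_duration = rest_bout_mean_duration),
    class = "diel_template")
}

#' Expected active swim speed of a template over the day
#'
#' @param template A [diel_template()].
#' @param schedule A [make_light_schedule()].
#' @param t Times in seconds (since experiment midnight).
#' @return Expected speed, mm/s, always `>= 0`.
#' @export
template_speed <- function(template, schedule, t) {
  l <- schedule$light(t)
  sgn <- switch(template$archetype,
                nocturnal = -1, 1)
  mod <- 1 + sgn * template$day_night_contrast * (l - 0.5)
  # Gaussian crepuscular bumps centred on the ramp midpoints, SD 30 min
  tod <- t %% 86400
  dawn <- schedule$day_start + schedule$ramp_s / 2
  dusk <- schedule$day_end - schedule$ramp_s / 2
  sig <- 1800
  # circular distance so bumps wrap at midnight
  cdist <- function(a, b) pmin(abs(a - b), 86400 - abs(a - b))
  bump <- exp(-cdist(tod, dawn)^2 / (2 * sig^2)) +
    exp(-cdist(tod, dusk)^2 / (2 * sig^2))
  pmax(0, template$base_speed * (mod + template$crepuscular_gain * bump))
}

#' @exportS3Method base::print
print.diel_template <- function(x, ...) {
  cat(sprintf(
    "diel template [%s]: base %.1f mm/s, contrast %.2f, crepuscular gain %.2f\n",
    x$archetype, x$base_speed, x$day_night_contrast, x$crepuscular_gain))
  invisible(x)
}
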