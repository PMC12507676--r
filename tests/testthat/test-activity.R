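test_that("speed is Euclidean displacement over time, assigned to the later frame", {
  tr <- flat_track(20)
  expect_equal(speed_series(tr)$speed, rep(0, 20))
  # 3 mm per 0.1-s frame = 30 mm/s
  tr$x <- seq(0, by = 3, length.out = 20)
  expect_equal(speed_series(tr)$speed, c(0, rep(30, 19)))
  # circular path: speed ~ r * omega
  r <- 40; omega <- 0.8
  tt <- seq(0, 30, by = 0.1)
  circ <- data.frame(time = tt, x = r * cos(omega * tt),
                     y = r * sin(omega * tt))
  sp <- speed_series(circ)$speed[-1]
  expect_equal(mean(sp), r * omega, tolerance = 0.01)
  bad <- flat_track(5); bad$time[3] <- bad$time[2]
  expect_error(speed_series(bad), "increasing")
})

test_that("movement uses a strict greater-than threshold", {
  expect_false(movement_flags(14.9))
  expect_false(movement_flags(15))
  expect_true(movement_flags(15.1))
  expect_equal(movement_flags(rep(0, 100)), rep(FALSE, 100))
})

test_that("rest calls are strict at exactly 5% movement in a window", {
  # every 20th frame moves: every 60-frame window holds exactly 3/60 = 5%
  m <- rep(c(TRUE, rep(FALSE, 19)), 30)
  r <- rest_flags(m, window = 60, max_frac = 0.05, fps = 1)
  expect_false(any(r[30:(length(m) - 30)]))
  # all-still series is all rest
  expect_true(all(rest_flags(rep(FALSE, 500), fps = 10)))
  # just under the bound is rest: 2/60 movement in every interior window
  m2 <- rep(c(TRUE, rep(FALSE, 29)), 20)
  expect_true(all(rest_flags(m2, window = 60, max_frac = 0.05,
                             fps = 1)[30:570]))
})

test_that("rest is monotone in the allowed movement fraction", {
  set.seed(13)
  m <- runif(2000) < 0.06
  r_tight <- rest_flags(m, max_frac = 0.03, fps = 1)
  r_loose <- rest_flags(m, max_frac = 0.10, fps = 1)
  expect_true(all(r_loose[r_tight]))
})

test_that("alternating still/active blocks lose at most one window length per transition", {
  # 10 min active / 10 min still at 1 Hz for 2 h
  m <- rep(rep(c(TRUE, FALSE), each = 600), 6)
  r <- rest_flags(m, window = 60, max_frac = 0.05, fps = 1)
  frac <- mean(r)
  # exactly half the time is still; erosion <= 60 s per transition
  n_trans <- 11
  expect_lte(frac, 0.5)
  expect_gte(frac, 0.5 - n_trans * 60 / length(m))
  # the eroded band at each edge is under 60 s: still-block interiors rest
  interior <- unlist(lapply(seq_len(6), function(b)
    (b - 1) * 1200 + 600 + 61:540))
  expect_true(all(r[interior]))
  # active-block interiors never rest
  act_int <- unlist(lapply(seq_len(6), function(b)
    (b - 1) * 1200 + 61:540))
  expect_false(any(r[act_int]))
})

test_that("total rest averages complete days and complements activity exactly", {
  fps <- 1
  tt <- seq(0, 2 * 86400 - 1)
  expect_equal(total_rest(rep(TRUE, length(tt)), tt, fps), 24)
  expect_equal(total_rest(rep(FALSE, length(tt)), tt, fps), 0)
  rest <- rep(c(TRUE, FALSE), length.out = length(tt))
  expect_equal(total_rest(rest, tt, fps) +
                 total_rest(!rest, tt, fps), 24)
  # partial third day is excluded
  tt3 <- seq(0, 2.3 * 86400)
  rest3 <- tt3 < 2 * 86400   # rest in full days, active in the partial tail
  expect_equal(total_rest(rest3, tt3, fps), 24)
  expect_error(total_rest(TRUE, 0:100, fps), "no complete day")
})

test_that("the two-state bout generator's rest target is recovered", {
  # long bouts keep window-edge erosion small relative to total rest
  tpl <- diel_template("cathemeral", rest_bout_rate = c(day = 2.4, night = 2.4,
                                                        ramp = 2.4),
                       rest_bout_mean_duration = 1200)
  tgt <- dielniche:::rest_target_hours(tpl, sched_12)
  expect_equal(tgt, 24 * (1200 / (1200 + 1500)))
  sim <- simulate_track(tpl, sched_12, days = 6, fps = 1, seed = 31)
  cal <- calibrate(sim$track)
  sp <- speed_series(cal)
  r <- rest_flags(movement_flags(sp), fps = 1)
  expect_equal(total_rest(r, sp$time, fps = 1), tgt, tolerance = 0.5 / tgt)
})

test_that("30-min binning is midnight-anchored with per-bin means and counts", {
  tt <- seq(0, 2 * 86400 - 1)
  b <- bin30(tt, rep(3.5, length(tt)))
  expect_equal(dim(b), c(2, 48))
  expect_true(all(b == 3.5))
  # day-only speed on a 12:12 step schedule: 24 bins of 1, 24 of 0
  sch0 <- make_light_schedule("07:00", "19:00", 0)
  v <- as.numeric(sch0$state(tt) == "day")
  b2 <- bin30(tt, v)
  expect_equal(sum(b2[1, ] == 1), 24)
  expect_equal(sum(b2[1, ] == 0), 24)
  # a missing hour leaves its bins computed from remaining samples, flagged
  keep <- !(tt >= 10 * 3600 & tt < 11 * 3600)
  b3 <- bin30(tt[keep], rep(1, sum(keep)))
  cnt <- attr(b3, "counts")
  expect_true(all(is.na(b3[1, 21:22])))
  expect_equal(cnt[1, 21], 0L)
  expect_equal(cnt[1, 20], 1800L)
  expect_error(bin30(1:100, 1:100), "at least one day")
})

test_that("species profiles average days then individuals, with cross-checked SD", {
  one_day <- matrix(1:48, 1, 48)
  p1 <- daily_profile(list(one_day), species = "aaaaaa")
  expect_equal(unname(p1$profile), as.numeric(1:48))
  # two individuals: mean of their profiles
  p2 <- daily_profile(list(one_day, one_day + 2), species = "bbbbbb")
  expect_equal(unname(p2$profile), as.numeric(1:48) + 1)
  # 3-individual SD against the direct formula
  m <- lapply(c(0, 1, 5), function(o) matrix(rep(1:48 + o, 2), 2, 48,
                                             byrow = TRUE))
  p3 <- daily_profile(m, species = "cccccc")
  expect_equal(unname(p3$sd), rep(sd(c(0, 1, 5)), 48))
  expect_equal(p3$n, 3)
})

test_that("binning then profiling commutes with averaging identical replicates", {
  tt <- seq(0, 2 * 86400 - 1)
  v <- 5 + sin(2 * pi * tt / 86400)
  b <- bin30(tt, v)
  p1 <- daily_profile(list(b), "dddddd")
  p4 <- daily_profile(rep(list(b), 4), "eeeeee")
  expect_equal(p1$profile, p4$profile)
})

test_that("vertical position scales to [0, 1] with image-y inverted", {
  tr <- flat_track(5)
  tr$y <- c(100, 50, 0, 25, 75)   # image y: 100 is lowest in the tank
  v <- vertical_scaled(tr)
  expect_equal(v, c(0, 0.5, 1, 0.75, 0.25))
  # monotone rising fish (decreasing image y) gives a monotone series
  tr$y <- seq(90, 10, length.out = 5)
  expect_true(all(diff(vertical_scaled(tr)) > 0))
  tr$y <- rep(4, 5)
  expect_warning(v2 <- vertical_scaled(tr), "constant")
  expect_equal(v2, rep(0.5, 5))
})

test_that("paired rest-position test matches the textbook formula with Bonferroni", {
  mk_ind <- function(rest_v, act_v) {
    list(vertical = c(rep(rest_v, 50), rep(act_v, 50)),
         rest = rep(c(TRUE, FALSE), each = 50))
  }
  # constructed 5-individual species: rest position 0.1 lower
  rest_v <- c(0.20, 0.25, 0.22, 0.28, 0.24)
  act_v <- rest_v + c(0.09, 0.11, 0.10, 0.12, 0.08)
  sp1 <- lapply(seq_len(5), function(i) mk_ind(rest_v[i], act_v[i]))
  # identical positions: t = 0, p = 1
  sp2 <- lapply(1:3, function(i) mk_ind(0.3, 0.3))
  out <- rest_position_test(list(spone = sp1, sptwo = sp2))
  d <- rest_v - act_v
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(out$t[out$species == "spone"], t_hand)
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(out$p[out$species == "spone"], p_hand)
  expect_equal(out$p_adj[out$species == "spone"], min(1, 2 * p_hand))
  expect_equal(out$t[out$species == "sptwo"], 0)
  expect_equal(out$p[out$species == "sptwo"], 1)
  # single-individual species are skipped
  expect_message(
    out2 <- rest_position_test(list(sp = sp1[1], spone = sp1)),
    "skipped")
  expect_equal(nrow(out2), 1)
})

test_that("Bonferroni correction multiplies by the number of species", {
  # five species with identical moderate effects: p_adj = 5 * p
  mk_sp <- function(seed) {
    set.seed(seed)
    lapply(1:4, function(i)
      list(vertical = runif(100), rest = rep(c(TRUE, FALSE), 50)))
  }
  sps <- setNames(lapply(1:5, mk_sp), paste0("spec0", 1:5))
  out <- rest_position_test(sps)
  expect_equal(out$p_adj, pmin(1, out$p * 5))
})

test_that("the Fisher periodogram finds planted periods", {
  dt <- 1800
  tt <- seq(0, 6 * 86400 - dt, by = dt)
  set.seed(17)
  x24 <- 5 + 2 * sin(2 * pi * tt / 86400) + rnorm(length(tt), 0, 0.3)
  pg <- fisher_periodogram(x24)
  expect_true(pg$significant[1])
  expect_equal(pg$period_h[1], 24)
  # two superposed periods are both detected
  x2 <- 5 + 2 * sin(2 * pi * tt / 86400) +
    1.5 * sin(2 * pi * tt / 43200) + rnorm(length(tt), 0, 0.3)
  pg2 <- fisher_periodogram(x2)
  found <- pg2$period_h[pg2$significant]
  expect_true(all(c(24, 12) %in% found))
  expect_error(fisher_periodogram(rnorm(48)), "2 days")
})

test_that("the Fisher g-test holds its nominal type-I rate on white noise", {
  dt <- 1800
  n <- 4 * 48
  set.seed(23)
  hits <- vapply(seq_len(1000), function(i) {
    pg <- fisher_periodogram(rnorm(n), dt = dt, max_peaks = 1)
    pg$significant[1]
  }, logical(1))
  rate <- mean(hits)
  # binomial 99% CI around 0.05 with 1,000 replicates
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 1000))
})
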