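thr1 <- make_thresholds(1)

test_that("quiet and rotation-free signals yield no events", {
  expect_equal(nrow(detect_movements(make_mag(rep(0, 40), gyro = 0), thr1)), 0)

  # mechanical-swing surrogate: large oscillatory acceleration, zero gyro
  swing <- make_mag(3 * sin(2 * pi * 0.5 * (0:199) / 20), gyro = 0)
  expect_equal(nrow(detect_movements(swing, thr1)), 0)
  expect_equal(nrow(detect_movements_reference(swing, thr1)), 0)
})

test_that("a single biphasic burst is one hand-traceable event", {
  m <- make_mag(c(0.5, 2, -2, 0.5, 0.5), gyro = 1)
  ev <- detect_movements(m, thr1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_index, 2L)
  expect_equal(ev$end_index, 4L)  # down-crossing (2,3) then up-crossing (3,4)
  expect_equal(ev$trigger_side, "positive")
})

test_that("chained oscillations close one movement per direction pair", {
  m <- make_mag(c(0.5, 2, -2, 2, -2, 2, -2, 0.5), gyro = 1)
  ev <- detect_movements(m, thr1)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$start_index, c(2L, 5L))
  expect_equal(ev$end_index, c(4L, 7L))
  expect_equal(ev$trigger_side, c("positive", "negative"))
  expect_identical(as.data.frame(detect_movements_reference(m, thr1)),
                   as.data.frame(ev))
})

test_that("exact zeros inherit the previous sign and do not create crossings", {
  # graze of the baseline between two positive lobes: no crossing occurs,
  # so the first event must wait for the true down/up pair further on
  m <- make_mag(c(0.5, 2, 0, 2, -2, 2, 0.5), gyro = 1)
  ev <- detect_movements(m, thr1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_index, 2L)
  expect_equal(ev$end_index, 6L)
  expect_identical(as.data.frame(detect_movements_reference(m, thr1)),
                   as.data.frame(ev))
})

test_that("an event left open at the end of the recording is discarded", {
  m <- make_mag(c(0.5, 2, -2, -0.5), gyro = 1)  # only one crossing after start
  ev <- detect_movements(m, thr1)
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "diagnostics")$discarded_open_event)
})

test_that("fast detector and literal reference agree on random signals", {
  withr::with_seed(101, {
    for (i in 1:250) {
      n <- sample(30:80, 1)
      x <- cumsum(rnorm(n))
      x <- (x - mean(x)) / max(sd(x), 0.1)
      x[sample(n, size = max(1, n %/% 10))] <- 0  # exercise zero inheritance
      g <- abs(rnorm(n)) * stats::rbinom(n, 1, 0.7)
      m <- make_mag(x, gyro = 1)
      m$gyro_mag <- g
      thr <- make_thresholds(runif(1, 0.3, 1.2))
      a <- detect_movements(m, thr)
      b <- detect_movements_reference(m, thr)
      expect_identical(as.data.frame(a), as.data.frame(b))
      expect_identical(attr(a, "diagnostics"), attr(b, "diagnostics"))
      if (nrow(a) > 1) {
        expect_true(all(diff(a$start_index) > 0))
        expect_true(all(a$start_index[-1] > a$end_index[-nrow(a)]))
      }
      if (nrow(a) > 0) expect_true(all(a$end_index > a$start_index))
    }
  })
})

test_that("detection is deterministic and gates monotonely", {
  sim <- simulate_imu(sim_config(duration = 120), seed = 17)
  mag <- preprocess(sim$left)
  thr <- calibrate(mag)

  expect_identical(as.data.frame(detect_movements(mag, thr)),
                   as.data.frame(detect_movements(mag, thr)))

  n0 <- nrow(detect_movements(mag, thr, gyro_floor = 0))
  for (floor_ in c(0.1, 0.5, 0.9)) {
    nf <- nrow(detect_movements(mag, thr, gyro_floor = floor_))
    expect_lte(nf, n0)
    n0 <- nf
  }

  wider <- thr
  wider$pos_threshold <- thr$pos_threshold * 1.4
  wider$neg_threshold <- thr$neg_threshold * 1.4
  expect_lte(nrow(detect_movements(mag, wider)),
             nrow(detect_movements(mag, thr)))
})

test_that("concatenation across a quiet gap unions the event lists", {
  lobe <- function(a) c(0.01, a, -a, 0.01)
  part_a <- c(rep(0.01, 5), lobe(2), rep(0.01, 5))
  part_b <- c(rep(0.01, 5), lobe(1.5), lobe(2.5), rep(0.01, 5))
  gap <- rep(0.01, 20)
  ev_a <- detect_movements(make_mag(part_a), thr1)
  ev_b <- detect_movements(make_mag(part_b), thr1)
  ev_ab <- detect_movements(make_mag(c(part_a, gap, part_b)), thr1)
  off <- length(part_a) + length(gap)
  expect_equal(ev_ab$start_index, c(ev_a$start_index, ev_b$start_index + off))
  expect_equal(ev_ab$end_index, c(ev_a$end_index, ev_b$end_index + off))
})

test_that("awake time subtracts logged sleep rounded to 10 minutes", {
  ws <- as.POSIXct("2015-03-01 08:00:00", tz = "UTC")
  we <- ws + 10 * 3600

  nap2h <- activity_log(data.frame(start = ws + 4 * 3600, end = ws + 6 * 3600,
                                   state = "asleep"))
  expect_equal(awake_hours(nap2h, ws, we), 8)

  naps83 <- activity_log(data.frame(
    start = c(ws + 3600, ws + 5 * 3600),
    end = c(ws + 3600 + 40 * 60, ws + 5 * 3600 + 43 * 60),
    state = "asleep"
  ))
  expect_equal(awake_hours(naps83, ws, we), (600 - 80) / 60)  # 83 -> 80 min

  expect_equal(awake_hours(NULL, ws, we), 10)

  # sleep outside the wear window does not count
  early <- activity_log(data.frame(start = ws - 2 * 3600, end = ws - 3600,
                                   state = "asleep"))
  expect_equal(awake_hours(early, ws, we), 10)

  expect_error(awake_hours(NULL, we, ws), class = "legmov_validation_error")
})

test_that("summarize_day counts all wear-time events but rates by awake time", {
  sim <- simulate_imu(sim_config(duration = 300,
                                 nap_segments = data.frame(start = 100, end = 200)),
                      seed = 23)
  day <- summarize_day(sim$left, log = sim$log)
  expect_equal(day$n_movements, nrow(day_events(day)))
  expect_equal(day$wear_hours, 300 / 3600)
  # the 100 s nap rounds to 0 min at 10-minute resolution
  expect_equal(day$awake_hours, 300 / 3600)
  expect_equal(day$rate_per_awake_hour, day$n_movements / day$awake_hours)

  quiet <- make_recording(ax = 0, ay = 0,
                          az = 9.81 + c(0, 1.2, 0, -1.2, 0, 2, 0, -2, 0, 2.8,
                                        0, -2.8, rep(0, 28)))
  day0 <- summarize_day(quiet)
  expect_equal(day0$n_movements, 0)  # in-band peaks but no rotation at all
  expect_equal(day0$rate_per_awake_hour, 0)
})

test_that("a fully asleep wear period has no defined rate", {
  ws <- as.POSIXct("2015-03-01 08:00:00", tz = "UTC")
  rec <- simulate_imu(sim_config(duration = 600), seed = 3)$left
  log <- activity_log(data.frame(start = ws, end = ws + 600, state = "asleep"))
  expect_error(summarize_day(rec, log = log),
               class = "legmov_validation_error", regexp = "undefined")
})
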