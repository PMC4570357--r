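test_that("segment scoring applies the over/under/correct bookkeeping", {
  truth <- annotation_set(data.frame(
    segment_start = c(0, 20), segment_end = c(20, 40),
    leg = "left", count = c(3, 2)
  ))
  # 2 events in the first segment (obs 3), 3 in the second (obs 2)
  det <- make_events(c(1, 5, 21, 25, 30))
  rep <- score_segments(det, truth)
  expect_equal(rep$n_correct, 4)
  expect_equal(rep$false_positives, 1)
  expect_equal(rep$false_negatives, 1)
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$n_correct + rep$false_negatives, rep$n_observed)

  perfect <- make_events(c(1, 5, 9, 21, 25))
  rep2 <- score_segments(perfect, truth)
  expect_equal(rep2$false_positives, 0)
  expect_equal(rep2$false_negatives, 0)
  expect_equal(rep2$sensitivity, 1.0)

  # events outside every segment are excluded and reported
  stray <- make_events(c(1, 5, 9, 21, 25, 100))
  rep3 <- score_segments(stray, truth)
  expect_equal(rep3$n_unassigned, 1)
  expect_equal(rep3$n_detected, 5)

  overlapping <- annotation_set(data.frame(
    segment_start = c(0, 10), segment_end = c(20, 30),
    leg = "left", count = c(1, 1)
  ))
  expect_error(score_segments(det, overlapping),
               class = "legmov_validation_error")
})

test_that("segment sensitivity is invariant to segment order", {
  withr::with_seed(41, {
    truth_df <- data.frame(
      segment_start = seq(0, 180, by = 20), segment_end = seq(20, 200, by = 20),
      leg = "left", count = sample(0:5, 10, replace = TRUE)
    )
    det <- make_events(sort(runif(30, 0, 200)))
    s1 <- score_segments(det, annotation_set(truth_df))$sensitivity
    s2 <- score_segments(det, annotation_set(truth_df[sample(10), ]))$sensitivity
    expect_equal(s2, s1)
  })
})

test_that("event-time scoring matches greedily one-to-one within tolerance", {
  truth <- annotation_set(data.frame(time = c(1, 2), leg = "left"),
                          mode = "event_times")
  det <- make_events(1.1)
  rep <- score_events(det, truth, tolerance = 0.25)
  expect_equal(rep$n_correct, 1)
  expect_equal(rep$false_negatives, 1)
  expect_equal(rep$false_positives, 0)

  identical_lists <- make_events(c(1, 2))
  expect_equal(score_events(identical_lists, truth, 0.25)$sensitivity, 1.0)

  spurious <- make_events(c(1, 2, 7))
  rep2 <- score_events(spurious, truth, 0.25)
  expect_equal(rep2$false_positives, 1)
  expect_equal(rep2$sensitivity, 1.0)

  expect_error(score_events(det, truth, tolerance = -1),
               class = "legmov_validation_error")

  # legs are matched separately
  cross <- annotation_set(data.frame(time = 1, leg = "right"),
                          mode = "event_times")
  expect_equal(score_events(make_events(1, leg = "left"), cross)$n_correct, 0)
})

test_that("huge-tolerance event matching reduces to min-count bookkeeping", {
  withr::with_seed(43, {
    truth_times <- sort(runif(12, 0, 100))
    det <- make_events(sort(runif(9, 0, 100)))
    ev_truth <- annotation_set(data.frame(time = truth_times, leg = "left"),
                               mode = "event_times")
    rep_ev <- score_events(det, ev_truth, tolerance = 1e6)
    seg_truth <- annotation_set(data.frame(
      segment_start = 0, segment_end = 100, leg = "left", count = 12
    ))
    rep_seg <- score_segments(det, seg_truth)
    expect_equal(rep_ev$n_correct, rep_seg$n_correct)
    expect_equal(rep_ev$false_positives, rep_seg$false_positives)
    expect_equal(rep_ev$false_negatives, rep_seg$false_negatives)
  })
})

test_that("mean segment rate is total count over total duration, one decimal", {
  video <- annotation_set(data.frame(
    segment_start = 0, segment_end = 460, leg = "left", count = 636
  ))
  expect_equal(mean_rate_over_segments(video), 1.4)

  none <- annotation_set(data.frame(
    segment_start = 0, segment_end = 100, leg = "left", count = 0
  ))
  expect_equal(mean_rate_over_segments(none), 0.0)

  slow <- annotation_set(data.frame(
    segment_start = 0, segment_end = 3600, leg = "left", count = 1000
  ))
  expect_equal(mean_rate_over_segments(slow), 0.3)

  det <- make_events(c(1, 2, 3))
  expect_equal(
    mean_rate_over_segments(det, data.frame(segment_start = 0, segment_end = 10)),
    0.3
  )
  zero_dur <- data.frame(segment_start = 5, segment_end = 5)
  expect_error(mean_rate_over_segments(det, zero_dur),
               class = "legmov_validation_error")
})

test_that("tidy and glance expose the report tables", {
  truth <- annotation_set(data.frame(
    segment_start = 0, segment_end = 20, leg = "left", count = 2
  ))
  rep <- score_segments(make_events(c(1, 5)), truth)
  expect_equal(nrow(tidy(rep)), 1)
  g <- glance(rep)
  expect_equal(g$sensitivity, 1.0)
  expect_equal(g$n_observed, 2)
})

test_that("well-separated simulated movements are recovered almost one-to-one", {
  # a detector start can sit anywhere inside a movement lasting up to 1 s,
  # so the matching window spans one maximum movement duration
  agg_correct <- 0
  agg_truth <- 0
  agg_fp <- 0
  for (s in 1:5) {
    sim <- simulate_imu(sim_config(duration = 300, burst_rate = 4,
                                   direction_changes = 1), seed = s)
    events <- dplyr::bind_rows(lapply(c("left", "right"), function(lg) {
      mag <- preprocess(sim[[lg]])
      detect_movements(mag, calibrate(mag))
    }))
    rep <- score_events(events, sim$truth, tolerance = 1.0)
    agg_correct <- agg_correct + rep$n_correct
    agg_truth <- agg_truth + rep$n_observed
    agg_fp <- agg_fp + rep$false_positives
  }
  expect_gte(agg_correct / agg_truth, 0.95)
  expect_lte(agg_fp, 0.05 * agg_truth)
})
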