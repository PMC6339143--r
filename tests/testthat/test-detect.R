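test_that("a rectangular pulse yields one event with its amplitude and width", {
  rec <- pulse_trace(2, 1e-3,
                     data.frame(start_s = 0.4, dur_s = 0.1, amp_pA = 100))
  ev <- detect_spikes(rec, detection_config(threshold = 50))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_pA, 100)
  expect_equal(ev$polarity, "+")
  expect_equal(ev$width_s, 0.1, tolerance = 1.5e-3)   # within ~1 sample
})

test_that("sub-threshold traces produce no events", {
  rec <- mea_ts(numeric(1000), dt = 1e-3, unit = "current")
  expect_equal(nrow(detect_spikes(rec)), 0)
  rec2 <- mea_ts(rep(c(-40, 40), 500), dt = 1e-3, unit = "current")
  expect_equal(nrow(detect_spikes(rec2)), 0)
})

test_that("same-polarity peaks inside the refractory gap merge", {
  rec <- pulse_trace(1, 1e-3,
                     data.frame(start_s = c(0.400, 0.405),
                                dur_s = c(0.003, 0.003),
                                amp_pA = c(100, 100)))
  ev <- detect_spikes(rec, detection_config(threshold = 50,
                                            refractory = 0.05))
  expect_equal(nrow(ev), 1)
  ev2 <- detect_spikes(rec, detection_config(threshold = 50,
                                             refractory = 0))
  expect_equal(nrow(ev2), 2)
})

test_that("detection rejects bad inputs", {
  expect_error(detect_spikes(mea_ts(c(0, 100, 0, NA, 0), dt = 1e-3)),
               "non-finite")
  v <- mea_ts(rnorm(100), dt = 1e-3, unit = "voltage")
  expect_error(detect_spikes(v), "unit tag")
  expect_error(detection_config(threshold = 0), "positive")
})

test_that("detect_spikes agrees exactly with the per-sample oracle", {
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 8000
    dt <- 1e-3
    x <- 10 * rnorm(n)
    # stamp in smooth spikes of both polarities at random times
    for (k in 1:25) {
      c0 <- runif(1, 0.2, 7.8)
      amp <- sample(c(-1, 1), 1) * runif(1, 40, 300)
      sig <- runif(1, 0.005, 0.05)
      tt <- (0:(n - 1)) * dt
      x <- x + amp * exp(-(tt - c0)^2 / (2 * sig^2))
    }
    rec <- mea_ts(x, dt = dt, unit = "current")
    for (thr in c(50, 120)) {
      for (refr in c(0, 0.04)) {
        got <- detect_spikes(rec, detection_config(threshold = thr,
                                                   refractory = refr))
        want <- brute_detect(x, dt, 0, threshold = thr, refractory = refr)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$peak_time_s, want$peak_time_s, tolerance = 0)
        expect_equal(got$amplitude_pA, want$amplitude_pA, tolerance = 0)
        expect_equal(got$width_s, want$width_s, tolerance = 0)
        expect_equal(got$polarity, want$polarity)
      }
    }
  }
})

test_that("raising the threshold never increases the event count", {
  sim <- simulate_recording(recording_config(120, seed = 21),
                            data.frame(regime = "synchronous",
                                       duration = 120))
  counts <- sapply(seq(30, 200, by = 10), function(thr) {
    nrow(detect_spikes(sim$recording, detection_config(threshold = thr)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("greedy pairing classifies biphasic spikes without double use", {
  cfg <- detection_config(pairing_window = 2)
  ev <- make_events(c(10.0, 10.3), c(150, -150))
  out <- pair_biphasic(ev, cfg)
  expect_equal(out$kind, c("biphasic", "biphasic"))
  expect_equal(out$pair_id, c(1L, 1L))
  expect_equal(diff(out$peak_time_s), 0.3)

  single <- pair_biphasic(make_events(5, 150), cfg)
  expect_equal(single$kind, "unipolar")
  expect_true(is.na(single$pair_id))

  trio <- pair_biphasic(make_events(c(1.0, 1.3, 1.6), c(150, -150, 150)),
                        cfg)
  expect_equal(trio$kind, c("biphasic", "biphasic", "unipolar"))
  expect_equal(sum(!is.na(trio$pair_id)), 2)

  # peaks farther apart than the window stay unipolar
  far <- pair_biphasic(make_events(c(1, 4), c(150, -150)), cfg)
  expect_equal(far$kind, c("unipolar", "unipolar"))
})

test_that("event counts conserve across kinds", {
  sim <- simulate_recording(recording_config(300, seed = 8),
                            data.frame(regime = c("asynchronous",
                                                  "synchronous"),
                                       duration = c(150, 150)))
  ev <- pair_biphasic(detect_spikes(sim$recording))
  n_uni <- sum(ev$kind == "unipolar")
  n_bi <- sum(ev$kind == "biphasic")
  expect_equal(n_uni + n_bi, nrow(ev))
  expect_equal(n_bi %% 2, 0)
})

test_that("detection recovers simulated ground truth", {
  sim <- simulate_recording(recording_config(600, seed = 31),
                            data.frame(regime = "synchronous",
                                       duration = 600))
  ev <- detect_spikes(sim$recording)
  truth <- sim$truth
  matched <- vapply(seq_len(nrow(truth)), function(k) {
    any(abs(ev$peak_time_s - truth$time_s[k]) <= truth$width_s[k] / 2)
  }, logical(1))
  expect_gte(mean(matched), 0.95)

  # no false positives on a medium-only baseline at the 50 pA threshold
  base <- simulate_baseline(recording_config(120, seed = 32))
  expect_equal(nrow(detect_spikes(base)), 0)
})
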