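test_that("baseline traces stay within the configured peak-to-peak span", {
  for (s in 1:3) {
    ts <- simulate_baseline(recording_config(60, seed = s))
    expect_lt(max(ts$values) - min(ts$values), 1)   # under 1 pA span
    expect_lt(max(abs(ts$values)), 0.5)
    expect_equal(mean(ts$values), 0, tolerance = 0.01)
  }
  zero <- simulate_baseline(recording_config(10, seed = 1,
                                             baseline_noise_pp = 0))
  expect_equal(zero$values, numeric(10000))
})

test_that("the generator is reproducible from its seed", {
  cfg <- recording_config(30, seed = 42)
  expect_identical(simulate_baseline(cfg)$values,
                   simulate_baseline(cfg)$values)
  sch <- data.frame(regime = c("asynchronous", "synchronous"),
                    duration = c(15, 15))
  a <- simulate_recording(cfg, sch)
  b <- simulate_recording(cfg, sch)
  expect_identical(a$recording$values, b$recording$values)
  expect_identical(a$truth, b$truth)
})

test_that("biphasic template geometry follows wave speed and electrode size", {
  # a 1 mm diameter disc crossed at 500 um/s: lobes 2 s apart
  w <- wave_params(500, electrode_area = pi / 4)
  expect_equal(w$electrode_diameter, 1)
  tpl <- biphasic_template(w, sampling_rate = 1000)
  tt <- (seq_along(tpl$values) - 1) * tpl$dt
  sep_meas <- tt[which.min(tpl$values)] - tt[which.max(tpl$values)]
  expect_equal(sep_meas, 2, tolerance = 1e-3)
  expect_equal(tpl$separation, 2)

  tpl2 <- biphasic_template(wave_params(1000, electrode_area = pi / 4),
                            sampling_rate = 1000)
  expect_equal(tpl2$separation, 1)   # doubled speed halves the separation

  # default: 0.3 s from the sync parameters when no wave geometry given
  tpl3 <- biphasic_template(sync = sync_params(), sampling_rate = 1000)
  tt3 <- (seq_along(tpl3$values) - 1) * tpl3$dt
  expect_equal(tt3[which.min(tpl3$values)] - tt3[which.max(tpl3$values)],
               0.3, tolerance = 1e-3)

  # charge balance: net area below 1% of a single lobe's area
  lobe_area <- tpl$amplitude * tpl$sigma * sqrt(2 * pi)
  expect_lt(abs(sum(tpl$values) * tpl$dt), 0.01 * lobe_area)
  expect_equal(max(tpl$values), tpl$amplitude, tolerance = 0.02)

  expect_error(biphasic_template(wave_params(1e6, electrode_area = pi / 4),
                                 sampling_rate = 10),
               "2 samples")
})

test_that("event counts match the configured rates", {
  cfg <- recording_config(600, seed = 11)
  sim <- simulate_recording(cfg, data.frame(regime = "asynchronous",
                                            duration = 600),
                            async = async_params(event_rate = 0.05))
  n <- nrow(sim$truth)
  expect_true(all(sim$truth$kind == "unipolar"))
  expect_lt(abs(n - 30), 3 * sqrt(30))

  sim2 <- simulate_recording(recording_config(100, seed = 12),
                             data.frame(regime = "synchronous",
                                        duration = 100))
  pairs <- length(unique(sim2$truth$event_id))
  expect_gt(pairs, 40)
  expect_lt(pairs, 60)
  expect_true(all(sim2$truth$kind == "biphasic"))
  expect_true(all(table(sim2$truth$event_id) == 2))

  expect_error(simulate_recording(cfg, data.frame(regime = character(0),
                                                  duration = numeric(0))),
               "non-empty")
  expect_error(simulate_recording(cfg,
                                  data.frame(regime = "asynchronous",
                                             duration = 10)),
               "sum")
  expect_error(recording_config(0), "positive")
})

test_that("ground truth logs every insertion and amplitudes calibrate", {
  cfg <- recording_config(300, seed = 5, baseline_noise_pp = 0)
  sim <- simulate_recording(cfg, data.frame(regime = "asynchronous",
                                            duration = 300),
                            async = async_params(event_rate = 0.05))
  truth <- sim$truth
  expect_gt(nrow(truth), 0)
  expect_false(is.unsorted(truth$time_s))
  expect_true(all(truth$time_s > 0 & truth$time_s < 300))
  fs <- 1 / sim$recording$dt
  for (k in seq_len(nrow(truth))) {
    i0 <- round(truth$time_s[k] * fs) + 1
    win <- max(1, i0 - 50):min(length(sim$recording$values), i0 + 50)
    seg <- sim$recording$values[win]
    peak <- if (truth$amplitude_pA[k] > 0) max(seg) else min(seg)
    expect_equal(peak, truth$amplitude_pA[k],
                 tolerance = 0.02 + 1e-6)
  }
})

test_that("the inhibition experiment suppresses and restores activity", {
  cfg <- recording_config(2400, seed = 3)
  sim <- simulate_inhibition_experiment(cfg)
  expect_equal(sim$phases$label, c("before", "during", "after"))
  during <- sim$phases[sim$phases$label == "during", ]
  tt <- ts_time(sim$recording)
  blk <- sim$recording$values[tt >= during$start_s & tt < during$end_s]
  expect_lt(max(abs(blk)), 5)    # block-phase magnitude under 5 pA

  # zero residual and zero noise: identically silent block phase
  sim0 <- simulate_inhibition_experiment(
    recording_config(300, seed = 4, baseline_noise_pp = 0),
    inhibition_protocol(100, 100, 100, residual_amplitude = 0))
  tt0 <- ts_time(sim0$recording)
  expect_equal(sim0$recording$values[tt0 >= 100 & tt0 < 200],
               numeric(sum(tt0 >= 100 & tt0 < 200)))

  # pre and post phases share their generating distribution
  rates <- sapply(1:4, function(s) {
    si <- simulate_inhibition_experiment(
      recording_config(1300, seed = s),
      inhibition_protocol(600, 100, 600))
    n_pre <- length(unique(si$truth$event_id[si$truth$time_s < 600]))
    n_post <- length(unique(si$truth$event_id[si$truth$time_s >= 700]))
    n_post / n_pre
  })
  expect_true(all(rates > 0.8 & rates < 1.25))

  expect_error(simulate_inhibition_experiment(recording_config(100),
                                              inhibition_protocol()),
               "sum")
})
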