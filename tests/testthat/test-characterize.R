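test_that("regular trains are labeled synchronous, sparse ones asynchronous", {
  times <- seq(2, 98, by = 2)
  ev <- make_events(times, rep(150, length(times)))
  seg <- segment_regimes(ev, c(0, 100), window = 30, rate_cutoff = 0.25,
                         cv_cutoff = 0.5)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "synchronous")
  expect_equal(seg$spike_count, length(times))

  sparse <- make_events(c(50, 180, 260, 400, 555), rep(120, 5))
  seg2 <- segment_regimes(sparse, c(0, 600))
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$label, "asynchronous")

  empty <- make_events(numeric(0), numeric(0))
  seg3 <- segment_regimes(empty, c(0, 300))
  expect_equal(seg3$label, "asynchronous")
  expect_equal(c(seg3$start_s, seg3$end_s), c(0, 300))
})

test_that("spike statistics bin ISIs, amplitudes and widths per regime", {
  # ten biphasic pairs whose onsets fall 2.x s apart: all ISI mass in [2,3)
  isis <- c(2.1, 2.4, 2.9, 2.2, 2.6, 2.3, 2.8, 2.5, 2.7)
  onsets <- cumsum(c(5, isis))
  times <- as.vector(rbind(onsets, onsets + 0.3))
  amps <- rep(c(150, -150), length(onsets))
  ev <- make_events(times, amps, widths = 0.15, kind = "biphasic",
                    pair_id = rep(seq_along(onsets), each = 2))
  seg <- data.frame(start_s = 0, end_s = 40, label = "synchronous")
  st <- spike_statistics(ev, seg)
  isi_h <- st$synchronous$isi_histogram
  expect_equal(sum(isi_h$count), length(isis))
  expect_equal(isi_h$count[isi_h$lo == 2], length(isis))
  expect_equal(st$synchronous$biphasic_separations,
               rep(0.3, length(onsets)), tolerance = 1e-12)
  amp_h <- st$synchronous$amplitude_histogram
  expect_equal(sum(amp_h$count), nrow(ev))
  expect_equal(amp_h$count[amp_h$lo == 150], nrow(ev))

  # 7 unipolar + 3 biphasic-labeled events: unipolar fraction 0.7
  ev2 <- make_events(seq(10, 100, by = 10), rep(-100, 10),
                     kind = c(rep("unipolar", 7), rep("biphasic", 3)))
  st2 <- spike_statistics(ev2, data.frame(start_s = 0, end_s = 120,
                                          label = "asynchronous"))
  expect_equal(st2$asynchronous$unipolar_fraction, 0.7)

  st3 <- spike_statistics(make_events(numeric(0), numeric(0)),
                          data.frame(start_s = 0, end_s = 10,
                                     label = "asynchronous"))
  expect_true(all(st3$asynchronous$amplitude_histogram$count == 0))
  expect_true(all(st3$asynchronous$isi_histogram$count == 0))
  expect_equal(st3$asynchronous$n_events, 0)
})

test_that("histogram mass is conserved on simulated data", {
  sim <- simulate_recording(recording_config(400, seed = 41),
                            data.frame(regime = c("asynchronous",
                                                  "synchronous"),
                                       duration = c(200, 200)))
  ev <- pair_biphasic(detect_spikes(sim$recording))
  seg <- segment_regimes(ev, c(0, 400))
  st <- spike_statistics(ev, seg)
  total <- 0
  for (lab in names(st)) {
    s <- st[[lab]]
    expect_equal(sum(s$amplitude_histogram$count), s$n_events)
    expect_equal(sum(s$width_histogram$count), s$n_events)
    total <- total + s$n_events
  }
  expect_equal(total, nrow(ev))
})

test_that("wave speed follows diameter over separation", {
  ev <- make_events(c(10, 12), c(150, -150), kind = "biphasic",
                    pair_id = c(1L, 1L))
  ws <- estimate_wave_speed(ev, electrode_diameter = 1)
  expect_equal(ws$median_um_s, 500)          # 1000 um / 2 s

  ev2 <- make_events(c(10, 10.7), c(150, -150), kind = "biphasic",
                     pair_id = c(1L, 1L))
  ws2 <- estimate_wave_speed(ev2, electrode_diameter = 1)
  expect_equal(ws2$median_um_s, 1000 / 0.7, tolerance = 1e-12)

  ws3 <- estimate_wave_speed(ev, electrode_diameter = 2)
  expect_equal(ws3$speeds_um_s, 2 * ws$speeds_um_s)

  expect_warning(out <- estimate_wave_speed(make_events(5, 150),
                                            electrode_diameter = 1),
                 "no complete")
  expect_equal(out$n_pairs, 0)
})

test_that("characterization recovers the generator's parameters", {
  sim <- simulate_recording(recording_config(600, seed = 51),
                            data.frame(regime = "synchronous",
                                       duration = 600))
  ev <- pair_biphasic(detect_spikes(sim$recording))
  seg <- segment_regimes(ev, c(0, 600))
  st <- spike_statistics(ev, seg)
  s <- st$synchronous
  # mean |amplitude| within 10% of the generator's 150 pA
  expect_equal(mean(abs(ev$amplitude_pA)), 150, tolerance = 0.1)
  # event rate within 20% of 1 / mean_isi
  expect_equal(s$mean_rate, 0.5, tolerance = 0.2)
  # modal ISI bin contains the generator's 2 s mean interval
  isi_h <- s$isi_histogram
  modal <- isi_h[which.max(isi_h$count), ]
  expect_true(modal$lo <= 2 && 2 <= modal$hi)
})

test_that("wave-speed recovery across the plausible speed range", {
  for (speed in c(300, 500, 1000)) {
    w <- wave_params(speed)
    sim <- simulate_recording(
      recording_config(600, seed = 60 + speed / 100),
      data.frame(regime = "synchronous", duration = 600),
      sync = sync_params(mean_isi = 8, isi_jitter_sd = 1,
                         isi_clip = c(5, 15)),
      wave = w)
    ev <- pair_biphasic(detect_spikes(sim$recording),
                        detection_config(pairing_window = 5))
    ws <- estimate_wave_speed(ev, w$electrode_diameter)
    expect_gt(ws$n_pairs, 10)
    expect_equal(ws$median_um_s, speed, tolerance = 0.1)
  }
})

test_that("asynchronous-to-synchronous count disparity is reproduced", {
  sim <- simulate_recording(recording_config(1200, seed = 71),
                            data.frame(regime = c("asynchronous",
                                                  "synchronous"),
                                       duration = c(600, 600)))
  ev <- pair_biphasic(detect_spikes(sim$recording))
  seg <- segment_regimes(ev, c(0, 1200))
  st <- spike_statistics(ev, seg)
  ratio <- st$synchronous$n_events / st$asynchronous$n_events
  expect_gt(ratio, 5)     # ~10x disparity within a factor of 2
  expect_lt(ratio, 20)
})
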