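test_that("qc gate applies each rejection rule independently", {
  expect_true(qc_pass(holding_current_pA = 100, rs_before_mohm = 15,
                      rs_after_mohm = 16)$pass)
  # series resistance above 30 MOhm
  r1 <- qc_pass(holding_current_pA = 50, rs_before_mohm = 35,
                rs_after_mohm = 35)
  expect_false(r1$pass)
  expect_match(r1$reasons[[1]], "30 MOhm")
  # 30% drift trips the 20% rule even with both values below 30
  r2 <- qc_pass(holding_current_pA = 50, rs_before_mohm = 20,
                rs_after_mohm = 26)
  expect_false(r2$pass)
  expect_match(r2$reasons[[1]], "changed")
  # holding current rule, either sign
  r3 <- qc_pass(holding_current_pA = -250, rs_before_mohm = 10,
                rs_after_mohm = 10)
  expect_false(r3$pass)
  expect_match(r3$reasons[[1]], "holding")
  # boundary values pass (rules are strict inequalities)
  expect_true(qc_pass(holding_current_pA = 200, rs_before_mohm = 30,
                      rs_after_mohm = 30)$pass)
  expect_true(qc_pass(holding_current_pA = 0, rs_before_mohm = 25,
                      rs_after_mohm = 30)$pass)
  # several violations are all reported
  r4 <- qc_pass(holding_current_pA = 300, rs_before_mohm = 40,
                rs_after_mohm = 10)
  expect_equal(length(r4$reasons[[1]]), 3)
  expect_error(qc_pass(holding_current_pA = 10, rs_before_mohm = NA,
                       rs_after_mohm = 20), "missing")
})

test_that("templates are unit peak with the closed-form biexponential peak time", {
  fs <- 20000
  # decay_mix = 1: peak time has the closed form tr * log(1 + td/tr)
  for (tr in c(0.3, 0.5, 1)) {
    for (td in c(3, 8, 15)) {
      tm <- make_template(tr, td, td, decay_mix = 1, length_ms = 80,
                          sampling_hz = fs)
      t_star <- tr * log(1 + td / tr) / 1000
      expect_lte(abs(tm$peak_time_s - t_star), 1 / fs)
    }
  }
  # equal decay constants collapse the mix
  t1 <- make_template(0.5, 6, 6, decay_mix = 0.2)
  t2 <- make_template(0.5, 6, 6, decay_mix = 0.9)
  expect_equal(t1$waveform, t2$waveform)
  # unit peak for random valid parameter draws
  set.seed(41)
  for (i in 1:20) {
    tr <- runif(1, 0.2, 1.5)
    td1 <- runif(1, 2, 6)
    td2 <- runif(1, 6, 15)
    tm <- make_template(tr, td1, td2, runif(1), length_ms = 120)
    expect_equal(max(abs(tm$waveform)), 1, tolerance = 1e-9)
    expect_lt(abs(tm$waveform[length(tm$waveform)]), 0.01)
  }
  expect_warning(make_template(5, 4, 12, 0.7, length_ms = 200), "slow-rise")
  expect_error(make_template(-1, 4), "tau_rise_ms")
})

test_that("a clean injected event is recovered exactly once with exact scale", {
  fs <- 20000
  tm <- make_template(0.5, 4, 12, 0.7, sampling_hz = fs)
  L <- length(tm$waveform)
  y <- numeric(fs)
  y[5001:(5000 + L)] <- 20 * tm$waveform
  ev <- detect_events(synq_recording(y, fs, "outward"), tm, 5)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$onset_s - 5000 / fs), 1 / fs)
  expect_equal(ev$peak_amplitude_pA, 20, tolerance = 0.1 / 20)
  expect_equal(ev$charge_pC, 20 * sum(tm$waveform) / fs, tolerance = 1e-6)

  # inward polarity: same event with flipped sign
  evn <- detect_events(synq_recording(-y, fs, "inward"), tm, 5)
  expect_equal(nrow(evn), 1)
  expect_equal(evn$peak_amplitude_pA, -20, tolerance = 0.1 / 20)
  expect_equal(evn$charge_pC, -ev$charge_pC, tolerance = 1e-9)

  expect_error(detect_events(synq_recording(numeric(100), fs, "outward"),
                             tm, 5), "shorter")
  expect_error(detect_events(synq_recording(y, fs, "outward"), tm, 0),
               "threshold")
})

test_that("detection is invariant to offsets and positive rescaling", {
  sim <- simulate_mpsc_trace(sim_ephys_config(duration_s = 20, seed = 8))
  tm <- make_template(0.5, 4, 12, 0.7)
  base <- detect_events(sim$recording, tm, 5)
  shifted <- synq_recording(sim$recording$current_pA + 50, 20000, "outward")
  evs <- detect_events(shifted, tm, 5)
  expect_equal(evs$onset_s, base$onset_s)
  expect_equal(evs$peak_amplitude_pA, base$peak_amplitude_pA,
               tolerance = 1e-9)
  # criterion is scale-free: tripling the trace leaves it unchanged
  scaled <- synq_recording(3 * sim$recording$current_pA, 20000, "outward")
  evc <- detect_events(scaled, tm, 5)
  expect_equal(evc$onset_s, base$onset_s)
  expect_equal(evc$criterion_value, base$criterion_value, tolerance = 1e-9)
  expect_equal(evc$peak_amplitude_pA, 3 * base$peak_amplitude_pA,
               tolerance = 1e-9)
})

test_that("pure noise produces essentially no detections at threshold 5", {
  set.seed(77)
  rec <- synq_recording(rnorm(20 * 20000, 0, 2), 20000, "outward")
  ev <- detect_events(rec, make_template(0.5, 4, 12, 0.7), 5)
  expect_lte(nrow(ev), 2)    # well below the 2 Hz signal regime
})

test_that("simulated trains are recovered with high recall and precision", {
  cfg <- sim_ephys_config(duration_s = 60, seed = 15)
  sim <- simulate_mpsc_trace(cfg)
  tm <- make_template(0.5, 4, 12, 0.7)
  ev <- detect_events(sim$recording, tm, 5)
  m <- match_onsets(sim$truth$onsets_s, ev$onset_s)
  expect_gte(m$recall, 0.90)
  expect_gte(m$precision, 0.90)
  # amplitude estimator unbiased within 5% on matched events (comparing
  # against all true events would mix in the sub-threshold selection)
  pair_idx <- vapply(ev$onset_s, function(o) {
    j <- which.min(abs(sim$truth$onsets_s - o))
    if (abs(sim$truth$onsets_s[j] - o) <= 0.002) j else NA_integer_
  }, integer(1))
  ok <- !is.na(pair_idx)
  est <- abs(ev$peak_amplitude_pA[ok])
  tru <- sim$truth$amplitudes_pA[pair_idx[ok]]
  expect_lt(abs(mean(est) - mean(tru)) / mean(tru), 0.05)
  sm <- summarize_events(ev)
  expect_equal(sm$frequency_hz * sim$recording$duration_s, nrow(ev))
  expect_equal(sum(sm$ieis_s[[1]]),
               max(ev$onset_s) - min(ev$onset_s), tolerance = 1e-9)
})

test_that("trace simulation honours its degenerate cases", {
  z <- simulate_mpsc_trace(sim_ephys_config(duration_s = 5, event_rate_hz = 0,
                                            baseline_noise_sd_pA = 1,
                                            seed = 2))
  expect_equal(length(z$truth$onsets_s), 0)
  expect_lt(max(abs(z$recording$current_pA)), 6)
  # a single noise-free event peaks at exactly the drawn amplitude
  one <- simulate_mpsc_trace(sim_ephys_config(duration_s = 5,
                                              event_rate_hz = 0.2,
                                              amplitude_sd_pA = 0,
                                              baseline_noise_sd_pA = 0,
                                              seed = 14))
  if (length(one$truth$onsets_s) > 0) {
    expect_equal(max(abs(one$recording$current_pA)), 20, tolerance = 1e-9)
  }
  expect_error(simulate_mpsc_trace(sim_ephys_config(duration_s = 0.01,
                                                    kernel_ms = 60,
                                                    seed = 1)),
               "kernel")
  # inward polarity deflects negative
  inw <- simulate_mpsc_trace(sim_ephys_config(duration_s = 10,
                                              polarity = "inward",
                                              baseline_noise_sd_pA = 0,
                                              seed = 3))
  expect_lt(min(inw$recording$current_pA), -10)
  expect_lte(max(inw$recording$current_pA), 1e-9)
})

test_that("event counts follow the Poisson rate and summaries are exact", {
  counts <- vapply(1:100, function(s) {
    cfg <- sim_ephys_config(duration_s = 300, seed = s)
    # count only: Poisson draw is the first RNG use
    synaptiq:::with_seed(s, rpois(1, cfg$event_rate_hz * cfg$duration_s))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 600), 4 * sqrt(600) / sqrt(100))

  # empty events give zeros, one rectangular event integrates exactly
  empty <- summarize_events(tibble::tibble(onset_s = numeric(),
                                           peak_amplitude_pA = numeric(),
                                           charge_pC = numeric()),
                            duration_s = 300)
  expect_equal(empty$frequency_hz, 0)
  expect_equal(empty$total_charge_pC, 0)
  expect_equal(charge_transfer(rep(10, 200), 20000), 0.1)  # 10 pA x 10 ms
})
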