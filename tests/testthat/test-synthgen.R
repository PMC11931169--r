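test_that("poisson_train respects rate, refractory and determinism", {
  expect_identical(poisson_train(0, 60, 0.002, seed = 0), numeric(0))
  expect_error(poisson_train(-1, 60), ">= 0")

  counts <- vapply(1:100, function(s)
    length(poisson_train(5, 60, 0.002, seed = s)), numeric(1))
  # Poisson(300) tail bound, slightly shrunk by the refractory period
  expect_true(all(abs(counts - 300) <= 4 * sqrt(300) + 10))
  expect_gt(mean(counts), 300 - 3 * sqrt(300 / 100))

  tr <- poisson_train(200, 10, 0.002, seed = 3)
  expect_true(all(diff(tr) >= 0.002))
  expect_true(all(tr >= 0 & tr < 10))
  expect_false(is.unsorted(tr, strictly = TRUE))
  expect_identical(tr, poisson_train(200, 10, 0.002, seed = 3))
})

test_that("empirical firing rate recovers the configured rate", {
  # refractory correction: effective rate of an exponential-gap + dead-time
  # process is rate / (1 + rate * refractory)
  rate <- 8; refr <- 0.002
  counts <- vapply(1:100, function(s)
    length(poisson_train(rate, 30, refr, seed = 1000 + s)), numeric(1))
  expected <- rate / (1 + rate * refr) * 30
  se <- sqrt(expected) / sqrt(100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("type1 events reproduce the named periodic waveforms", {
  s <- type1_event("sine", freq = 1000, amplitude = 50, noise_sigma = 0,
                   seed = 0, phase = 0)
  expect_length(s, 90)
  expect_equal(max(s), 50, tolerance = 1e-2)
  # 1 kHz over 3 ms: three full cycles (period of 30 samples)
  expect_equal(s[31:60], s[1:30], tolerance = 1e-9)
  expect_equal(sum(abs(diff(sign(s[abs(s) > 1e-6]))) > 0), 5)

  q <- type1_event("square", freq = 500, amplitude = 50, noise_sigma = 0, seed = 0)
  expect_true(all(abs(abs(q) - 50) < 1e-9))

  a <- type1_event("sawtooth", 700, 40, 10, seed = 2)
  b <- type1_event("sawtooth", 700, 40, 10, seed = 2)
  expect_identical(a, b)
  expect_error(type1_event("triangle", 700, 40), "arg")
  expect_error(type1_event("sine", -5, 40), "freq")
})

test_that("type2 events always satisfy the SNR bound", {
  tpl <- spike_template(1, amplitude = 60, width = 0.5, seed = 1)
  seg <- type2_event(tpl, noise_sigma = 30, seed = 1)
  expect_length(seg, 90)
  expect_error(type2_event(tpl, noise_sigma = 0), "noise")

  big <- spike_template(2, amplitude = 250, width = 0.5, seed = 1)
  huge <- big
  huge$waveform <- huge$waveform * 2; huge$amplitude <- 500
  # amplitude 500 must be attenuated below 10 * 30 = 300 before noise
  seg2 <- type2_event(huge, noise_sigma = 30, seed = 2)
  expect_lt(max(abs(seg2)) / 30, 10 + 2)  # noise can add a little

  # exhaustive check: every generated event satisfies snr(seg, sigma) < 10
  set.seed(99)
  snrs <- vapply(1:1000, function(s) {
    tpl_s <- spike_template(s %% 5, amplitude = runif(1, 50, 600),
                            width = 0.5, seed = 1)
    snr(type2_event(tpl_s, noise_sigma = 30, seed = s), 30)
  }, numeric(1))
  expect_true(all(snrs < 10))
})

test_that("labeled_events honors composition, determinism and SNR labels", {
  bank <- tiny_bank()
  ev <- labeled_events(400, bank, seed = 5)
  expect_equal(as.vector(table(ev$labels)), c(360, 20, 20))
  expect_equal(dim(ev$segments), c(400, 90))
  ev2 <- labeled_events(400, bank, seed = 5)
  expect_identical(ev$segments, ev2$segments)
  expect_identical(ev$labels, ev2$labels)

  # segments are peak-aligned: absolute max at sample 46
  peak_ok <- apply(ev$segments, 1, function(z) which.max(abs(z)) == 46)
  expect_true(all(peak_ok))

  # type2 events stay below the linear SNR threshold of 10 against their
  # own 30 uV noise floor; neural peaks reach at least the detection floor
  t2 <- ev$segments[ev$labels == "TYPE2", , drop = FALSE]
  expect_true(all(apply(t2, 1, function(z) snr(z, 30)) < 10))
  nn <- ev$segments[ev$labels == "NEURAL", , drop = FALSE]
  expect_true(all(apply(nn, 1, function(z) max(abs(z))) >= 50))
})

test_that("synthetic units realize the requested composition", {
  bank <- tiny_bank()
  u <- synthetic_unit(100, 0.96, bank, seed = 1)
  expect_s3_class(u, "sorted_unit")
  expect_equal(sum(u$labels == "NEURAL"), 96)
  expect_equal(length(u$times), 100)
  expect_false(is.unsorted(u$times))

  u0 <- synthetic_unit(10, 0, bank, seed = 2)
  expect_equal(sum(u0$labels == "NEURAL"), 0)

  a <- synthetic_unit(200, 0.7, bank, seed = 3)
  b <- synthetic_unit(200, 0.7, bank, seed = 3)
  expect_identical(a$times, b$times)
  expect_identical(a$segments, b$segments)
  expect_error(synthetic_unit(50, 0.5, templates = NULL), "template")
  expect_error(synthetic_unit(50, 1.5, bank), "neural_fraction")
})

test_that("simulated recordings have calibrated noise and consistent labels", {
  cfg <- sim_config(n_channels = 2, duration = 8, n_cells = 3,
                    firing_rate = 4, seed = 9)
  rec <- simulate_recording(cfg)
  expect_s3_class(rec, "labeled_recording")

  # background (event-free) noise std within 5% of the configured 10 uV
  fs <- rec$sampling_rate
  mask <- rep(TRUE, ncol(rec$samples))
  for (t in rec$true_events$time_s) {
    i0 <- max(1, round(t * fs) - 60); i1 <- min(ncol(rec$samples), round(t * fs) + 60)
    mask[i0:i1] <- FALSE
  }
  for (ch in 1:2)
    expect_equal(sd(rec$samples[ch, mask]), 10, tolerance = 0.05)

  # all event times inside the recording; per-unit times strictly increasing
  expect_true(all(rec$true_events$time_s >= 0 &
                  rec$true_events$time_s < cfg$duration))
  for (ut in rec$true_units)
    expect_false(is.unsorted(ut, strictly = TRUE))

  # label/SNR consistency at the recording level: neural peaks reach the
  # threshold, type2 windows stay below it (sigma = configured noise floor)
  for (i in seq_len(nrow(rec$true_events))) {
    e <- rec$true_events[i, ]
    at <- round(e$time_s * fs) + 1
    win <- rec$samples[e$channel, max(1, at - 45):min(ncol(rec$samples), at + 44)]
    if (e$kind == "NEURAL") expect_gte(snr(win, 10), 10)
    if (e$kind == "TYPE2") expect_lt(snr(win, 10), 10)
  }

  # pure-noise configuration
  quiet <- simulate_recording(sim_config(n_channels = 1, duration = 2,
                                         n_cells = 0, type1_rate = 0,
                                         type2_rate = 0, seed = 1))
  expect_equal(nrow(quiet$true_events), 0)
  expect_equal(sd(quiet$samples), 10, tolerance = 0.05)

  # seed determinism
  r2 <- simulate_recording(cfg)
  expect_identical(rec$samples, r2$samples)
  expect_identical(rec$true_events, r2$true_events)
})

test_that("a 60 s default-style recording yields thousands of labeled events", {
  rec <- simulate_recording(sim_config(n_channels = 4, duration = 60,
                                       n_cells = 10, firing_rate = 5, seed = 2))
  expect_gt(nrow(rec$true_events), 2000)
  expect_lt(nrow(rec$true_events), 30000)
})
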