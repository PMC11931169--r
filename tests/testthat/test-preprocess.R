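make_rec <- function(mat, fs = 30000) recording(mat, fs)

test_that("bandpass attenuates out-of-band tones and passes the spike band", {
  fs <- 30000
  t <- seq(0, 1, by = 1 / fs)[-1]
  rms <- function(x) sqrt(mean(x^2))
  hum <- make_rec(matrix(sin(2 * pi * 50 * t), 1))
  out <- bandpass_filter(hum, 300, 6000)
  expect_lt(rms(out$samples), 0.05 * rms(hum$samples))

  tone <- make_rec(matrix(sin(2 * pi * 1000 * t), 1))
  out2 <- bandpass_filter(tone, 300, 6000)
  expect_equal(rms(out2$samples), rms(tone$samples), tolerance = 0.1)

  zero <- make_rec(matrix(0, 1, 5000))
  expect_true(all(bandpass_filter(zero)$samples == 0))

  # DC removal
  dc <- make_rec(matrix(7, 1, 30000))
  expect_lt(max(abs(bandpass_filter(dc)$samples[, 1000:29000])), 1e-6)

  expect_error(bandpass_filter(tone, 6000, 300), "corners")
  expect_error(bandpass_filter(tone, 300, 20000), "corners")
})

test_that("common median reference subtracts the per-sample median", {
  x <- rnorm(1000)
  same <- make_rec(rbind(x, x, x))
  expect_true(all(abs(common_median_reference(same)$samples) < 1e-12))

  two <- make_rec(rbind(x, -x))
  expect_equal(common_median_reference(two)$samples, two$samples)

  a <- rnorm(500); b <- rnorm(500)
  three <- make_rec(rbind(a, a, b))
  out <- common_median_reference(three)
  expect_equal(out$samples[3, ], b - a)
  expect_equal(out$samples[1, ], rep(0, 500))

  expect_warning(common_median_reference(make_rec(matrix(x, 1))), "channels")
})

test_that("noise_sigma is accurate and robust to sparse spikes", {
  set.seed(10)
  ests <- vapply(1:20, function(s) {
    set.seed(s); noise_sigma(rnorm(60000, 0, 10))
  }, numeric(1))
  expect_true(all(ests > 9.5 & ests < 10.5))

  expect_equal(noise_sigma(rep(0, 2000)), 0)
  expect_error(noise_sigma(rnorm(100)), "1000")

  # 1% of samples replaced by large spikes barely moves the estimate
  set.seed(4)
  x <- rnorm(50000, 0, 10)
  idx <- sample(50000, 500)
  x[idx] <- x[idx] - 200
  expect_lt(abs(noise_sigma(x) - 10) / 10, 0.1)
  expect_gt(abs(sd(x) - 10) / 10, 0.5)  # the plain std is badly inflated
})

test_that("normalize_noise calibrates the floor and is idempotent", {
  set.seed(2)
  r <- make_rec(matrix(rnorm(60000, 0, 20), 2))
  out <- normalize_noise(r, 10)
  expect_equal(out$samples, r$samples / 2, tolerance = 0.05)
  again <- normalize_noise(out, 10)
  expect_equal(again$samples, out$samples, tolerance = 0.05)
  expect_error(normalize_noise(make_rec(matrix(0, 1, 2000))), "zero")
})

test_that("detect_events finds inserted spikes and nothing in silence", {
  expect_identical(nrow(detect_events(make_rec(matrix(0, 1, 30000)))), 0L)

  tpl <- spike_template(1, amplitude = 60, width = 0.3, seed = 2)$waveform
  hits <- 0L; singles <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(30000, 0, 10)
    at <- 12000
    x[(at - 45):(at + 44)] <- x[(at - 45):(at + 44)] + tpl
    ev <- detect_events(make_rec(matrix(x, 1)), k_sigma = 5)
    near <- abs(ev$peak_sample - at) <= 6  # within 0.2 ms
    if (sum(near) >= 1) hits <- hits + 1L
    if (nrow(ev) == 1 && sum(near) == 1) singles <- singles + 1L
  }
  expect_gte(hits, 99)
  expect_gte(singles, 99)

  # two spikes 10 ms apart are both found
  set.seed(7)
  x <- rnorm(30000, 0, 10)
  for (at in c(10000, 10300))
    x[(at - 45):(at + 44)] <- x[(at - 45):(at + 44)] + tpl
  ev <- detect_events(make_rec(matrix(x, 1)), k_sigma = 5)
  expect_equal(nrow(ev), 2)
})

test_that("detection recall on high-SNR simulated spikes exceeds 95%", {
  found <- total <- 0L
  for (s in 1:100) {
    rec <- simulate_recording(sim_config(n_channels = 4, duration = 1,
                                         n_cells = 4, firing_rate = 5,
                                         type1_rate = 0, type2_rate = 0,
                                         seed = 4000 + s))
    pp <- suppressWarnings(preprocess_recording(rec))  # edge events skipped
    gtn <- rec$true_events[rec$true_events$kind == "NEURAL", ]
    gtn <- gtn[gtn$time_s > 0.005 & gtn$time_s < 0.995, ]
    hit <- vapply(gtn$time_s, function(t)
      any(abs(pp$events$time_s - t) <= 5e-4), logical(1))
    found <- found + sum(hit); total <- total + nrow(gtn)
  }
  expect_gte(found / total, 0.95)
})

test_that("segments are extracted with the absolute maximum centred", {
  set.seed(5)
  x <- rnorm(6000, 0, 1)
  x[3001] <- -50
  r <- make_rec(matrix(x, 1))
  out <- extract_segments(r, data.frame(peak_sample = 3001, channel = 1))
  expect_equal(dim(out$segments), c(1, 90))
  expect_equal(which.min(out$segments[1, ]), 46)
  expect_equal(out$segments[1, ], x[2956:3045])

  # events too close to the edge are skipped with a warning
  expect_warning(
    out2 <- extract_segments(r, data.frame(peak_sample = c(10, 3001),
                                           channel = c(1, 1))),
    "skipped")
  expect_equal(nrow(out2$segments), 1)

  # repeated extraction is identical (pure function)
  again <- extract_segments(r, data.frame(peak_sample = 3001, channel = 1))
  expect_identical(out$segments, again$segments)
})

test_that("extracted segments recover inserted templates at moderate SNR", {
  # correlation is bounded by the template's energy share of the window:
  # compact tri-phasic spikes at SNR 6 top out around 0.85, so 0.8 is the
  # recovery bar here
  tpl <- spike_template(4, amplitude = 60, width = 0.6, seed = 2)$waveform
  cors <- vapply(1:50, function(s) {
    set.seed(s)
    x <- rnorm(20000, 0, 10)  # SNR 6
    x[(9955):(10044)] <- x[(9955):(10044)] + tpl
    r <- make_rec(matrix(x, 1))
    ev <- detect_events(r, k_sigma = 5)
    ev <- ev[which.min(abs(ev$peak_sample - 10000)), ]
    seg <- extract_segments(r, ev)$segments
    cor(as.numeric(seg), tpl)
  }, numeric(1))
  expect_gt(mean(cors > 0.8), 0.9)
})

test_that("snr is the peak magnitude over sigma", {
  z <- rep(0, 90); z[46] <- -50
  expect_equal(snr(z, 5), 10)
  expect_equal(snr(z, 10), 5)
  expect_equal(snr(rep(0, 90), 3), 0)
  expect_error(snr(z, 0), "sigma")
})

test_that("referencing before detection matters on correlated interference", {
  # a strong shared hum inflates the per-channel noise estimate so much
  # that real spikes are missed; the common median reference cancels the
  # hum and restores detection, so the pipeline order is load-bearing
  set.seed(12)
  fs <- 30000
  t <- seq_len(fs) / fs
  hum <- 80 * sin(2 * pi * 900 * t)
  mat <- do.call(rbind, lapply(1:8, function(i) hum + rnorm(fs, 0, 5)))
  tpl <- spike_template(2, amplitude = 150, width = 0.5, seed = 3)$waveform
  at <- round(seq(2000, 28000, length.out = 10))
  for (a in at) mat[1, (a - 45):(a + 44)] <- mat[1, (a - 45):(a + 44)] + tpl
  r <- make_rec(mat)
  before <- detect_events(r, k_sigma = 5)
  after <- detect_events(common_median_reference(r), k_sigma = 5)
  hits_before <- sum(vapply(at, function(a)
    any(abs(before$peak_sample - a) <= 6), logical(1)))
  hits_after <- sum(vapply(at, function(a)
    any(abs(after$peak_sample - a) <= 6), logical(1)))
  expect_lt(hits_before, 5)
  expect_gte(hits_after, 9)
  expect_false(identical(before, after))
})
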