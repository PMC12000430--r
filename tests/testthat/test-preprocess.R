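# Filtering, epoching, artifact handling, referencing and segmentation.

test_that("notch filter removes line harmonics and preserves the passband", {
  fs <- 500
  t <- seq_len(20 * fs) / fs
  interior <- seq(2 * fs, 18 * fs) # steady state away from record edges
  x <- rbind(
    sin(2 * pi * 50 * t), sin(2 * pi * 20 * t),
    sin(2 * pi * 50 * t) + sin(2 * pi * 100 * t) + sin(2 * pi * 150 * t),
    rnorm(length(t))
  )
  r <- notch_filter(make_recording(x, fs), 50)
  expect_lt(sd(r$data[1, interior]) / sd(x[1, ]), 0.01)
  expect_equal(sd(r$data[2, interior]) / sd(x[2, interior]), 1, tolerance = 0.01)
  # all harmonics below Nyquist attenuated >= 40 dB (periodogram oracle)
  for (f in c(50, 100, 150)) {
    before <- periodogram_power(x[3, interior], fs, f - 0.5, f + 0.5)
    after <- periodogram_power(r$data[3, interior], fs, f - 0.5, f + 0.5)
    expect_gt(10 * log10(before / after), 40)
  }
  expect_error(notch_filter(make_recording(x, fs), 300), "Nyquist")
})

test_that("bandpass filter meets its stopband and passband contracts", {
  fs <- 1000
  t <- seq_len(20 * fs) / fs
  interior <- seq(2 * fs, 18 * fs)
  x <- rbind(rep(5, length(t)), sin(2 * pi * 20 * t), rnorm(length(t)), rnorm(length(t)))
  r <- bandpass_filter(make_recording(x, fs), 3, 150)
  # DC removed
  expect_lt(mean(abs(r$data[1, interior])), 0.05)
  # 20 Hz amplitude preserved within 1%
  expect_equal(sd(r$data[2, interior]) / sd(x[2, interior]), 1, tolerance = 0.01)
  # white noise: >= 40 dB attenuation below lo/2 and above 2*hi
  lo_band <- c(0.5, 1.5)
  hi_band <- c(300, 499)
  for (ch in 3:4) {
    before_lo <- periodogram_power(x[ch, interior], fs, lo_band[1], lo_band[2], "hann")
    after_lo <- periodogram_power(r$data[ch, interior], fs, lo_band[1], lo_band[2], "hann")
    expect_gt(10 * log10(before_lo / after_lo), 40)
    before_hi <- periodogram_power(x[ch, interior], fs, hi_band[1], hi_band[2], "hann")
    after_hi <- periodogram_power(r$data[ch, interior], fs, hi_band[1], hi_band[2], "hann")
    expect_gt(10 * log10(before_hi / after_hi), 40)
  }
  expect_error(bandpass_filter(make_recording(x, fs), 3, 600), "Nyquist")
  # idempotence: applying twice changes band-interior power < 1 dB
  r2 <- bandpass_filter(r, 3, 150)
  p1 <- periodogram_power(r$data[3, interior], fs, 10, 100)
  p2 <- periodogram_power(r2$data[3, interior], fs, 10, 100)
  expect_lt(abs(10 * log10(p2 / p1)), 1)
})

test_that("epoching and resampling have exact sample arithmetic", {
  fs <- 4000
  t <- seq_len(61 * fs) / fs
  x <- matrix(rep(sin(2 * pi * 10 * t), 4), 4, byrow = TRUE)
  ep <- make_epochs(make_recording(x, fs), 2)
  expect_equal(dim(ep$data)[1], 30) # floor(61 / 2)
  expect_equal(ep$epoch_duration, 2)

  ep500 <- resample_epochs(ep, 500)
  expect_equal(dim(ep500$data)[3], 1000)
  ep1000 <- resample_epochs(ep, 1000)
  expect_equal(dim(ep1000$data)[3], 2000)
  # waveform matches the analytic sine after decimation
  tt <- (seq_len(2000) - 1) / 1000 + 1 / fs
  expect_lt(max(abs(ep1000$data[1, 1, ] - sin(2 * pi * 10 * tt))), 1e-3)

  short <- make_recording(matrix(rnorm(4 * 100), 4), fs)
  expect_error(make_epochs(short, 2), "shorter")
})

test_that("artifact-epoch rejection flags constructed outliers only", {
  set.seed(1)
  mats <- lapply(1:30, function(e) matrix(rnorm(4 * 200), 4))
  mats[[7]] <- mats[[7]] * 100
  ep <- make_epochs_from_matrix(mats, 100)
  out <- reject_artifact_epochs(ep, 4)
  expect_identical(which(!out$kept_mask), 7L)

  # identical epochs: zero variance guarded, none rejected
  same <- make_epochs_from_matrix(rep(list(matrix(1:800, 4)), 10), 100)
  expect_true(all(reject_artifact_epochs(same, 4)$kept_mask))

  # infinite threshold keeps everything
  expect_true(all(reject_artifact_epochs(ep, Inf)$kept_mask))
  one <- make_epochs_from_matrix(mats[1], 100)
  expect_error(reject_artifact_epochs(one, 4), "2 epochs")
})

test_that("parrm is a guarded no-op off stimulation and detects absence", {
  set.seed(2)
  fs <- 4000
  x <- matrix(rnorm(2 * fs * 5), 2)
  rec_off <- make_recording(x, fs, condition = "off")
  expect_identical(parrm_remove(rec_off, 130)$data, rec_off$data)

  rec_dbs <- make_recording(x, fs, condition = "dbs")
  out <- parrm_remove(rec_dbs, 130)
  expect_false(out$parrm_log$removed)
  expect_identical(out$data, rec_dbs$data)
})

test_that("parrm removes a pure pulse train almost completely", {
  fs <- 4000
  rec <- add_dbs_artifact(make_recording(matrix(0, 2, fs * 10), fs), 130, 60, 50)
  out <- parrm_remove(rec, 130)
  expect_true(out$parrm_log$removed)
  expect_equal(out$parrm_log$period, fs / 130, tolerance = 1e-5)
  expect_lt(sd(out$data[1, ]) / sd(rec$data[1, ]), 0.05)
})

test_that("parrm suppresses the artifact without distorting oscillations", {
  # independent stimulator clock: slight skew against the sampling clock
  fs <- 4000
  n <- fs * 10
  t <- seq_len(n) / fs
  sig <- rbind(20 * sin(2 * pi * 23.7 * t), 20 * sin(2 * pi * 16.3 * t))
  rec <- add_dbs_artifact(make_recording(sig, fs, condition = "dbs"),
    130 * (1 + 5e-5), 60, 100
  )
  out <- parrm_remove(rec, 130)
  for (ch in 1:2) {
    supp <- 10 * log10(
      periodogram_power(rec$data[ch, ], fs, 129, 131.5) /
        periodogram_power(out$data[ch, ], fs, 129, 131.5)
    )
    expect_gt(supp, 20)
    dist <- 10 * log10(
      periodogram_power(out$data[ch, ], fs, 10, 35) /
        periodogram_power(sig[ch, ], fs, 10, 35)
    )
    expect_lt(abs(dist), 1)
  }
})

test_that("bipolar referencing cancels common mode and counts contacts", {
  fs <- 500
  t <- seq_len(fs * 4) / fs
  common <- sin(2 * pi * 13 * t)
  distinct <- rbind(
    sin(2 * pi * 7 * t), sin(2 * pi * 11 * t), sin(2 * pi * 17 * t),
    sin(2 * pi * 23 * t), sin(2 * pi * 29 * t), sin(2 * pi * 31 * t),
    sin(2 * pi * 37 * t), sin(2 * pi * 41 * t)
  )
  rec <- new_recording(
    distinct + rep(1, 8) %o% common, fs,
    make_channel_info(6, 2)
  )
  bip <- bipolar_reference(rec)
  # 6 cortex contacts -> 5 bipolar; 2 stn -> 1
  expect_equal(sum(bip$channel_info$site == "cortex"), 5)
  expect_equal(sum(bip$channel_info$site == "stn"), 1)
  # analytic difference (common mode cancels exactly)
  expect_equal(bip$data[1, ], distinct[1, ] - distinct[2, ], tolerance = 1e-12)

  # pure common mode nulls out
  rec_cm <- new_recording(
    rep(c(1, 2, 0.5, 3, 1, 2, 1, 1), each = length(t)) * 0 +
      rep(1, 8) %o% common, fs, make_channel_info(6, 2)
  )
  expect_lt(max(abs(bipolar_reference(rec_cm)$data)), 1e-12)

  expect_error(
    bipolar_reference(new_recording(
      matrix(rnorm(3 * 100), 3), fs,
      make_channel_info(2, 1)
    )),
    "fewer than 2"
  )
})

test_that("stim-contact exclusion drops exactly the named channels", {
  rec <- make_recording(matrix(rnorm(10 * 100), 10), 500, n_cortex = 2)
  expect_identical(exclude_stim_contacts(rec, character(0)), rec)
  out <- exclude_stim_contacts(rec, c("LFP_2", "LFP_5"))
  expect_equal(nrow(out$data), 8)
  expect_false(any(c("LFP_2", "LFP_5") %in% out$channel_info$name))
  expect_error(exclude_stim_contacts(rec, "LFP_99"), "LFP_99")
})

test_that("bootstrap segmentation is reproducible and well-formed", {
  mats <- lapply(1:15, function(e) matrix(rnorm(2 * 100), 2))
  ep <- make_epochs_from_matrix(mats, 50)
  s1 <- bootstrap_segments(ep, n_segments = 200, seed = 9)
  s2 <- bootstrap_segments(ep, n_segments = 200, seed = 9)
  expect_identical(s1$segments, s2$segments)
  expect_length(s1$segments, 200)
  expect_true(all(vapply(s1$segments, length, integer(1)) == 30))
  expect_true(all(unlist(s1$segments) %in% 1:15))
  expect_true(s1$coverage > 0 && s1$coverage <= 1)

  s400 <- bootstrap_segments(ep, n_segments = 400, seed = 9)
  expect_length(s400$segments, 400)

  # degenerate: a single kept epoch is repeated 30 times
  ep1 <- ep
  ep1$kept_mask <- c(TRUE, rep(FALSE, 14))
  sd1 <- bootstrap_segments(ep1, n_segments = 5, seed = 1)
  expect_true(all(unlist(sd1$segments) == 1L))
})
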