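# Synthetic recording, connectome and cohort generators.

test_that("sources are deterministic, band-limited and skewed on demand", {
  cfg <- sim_config(
    sampling_rate = 1000, duration = 20, source_band = c(20, 30),
    nongaussianity = 0, seed = 3
  )
  s1 <- simulate_sources(cfg)
  s2 <- simulate_sources(cfg)
  expect_identical(s1, s2)

  # >= 90% of variance inside the widened band (periodogram oracle)
  frac <- periodogram_power(s1[1, ], 1000, 19, 31) /
    periodogram_power(s1[1, ], 1000, 0, 500)
  expect_gt(frac, 0.90)

  # Gaussian source: skewness ~ 0
  expect_lt(abs(skewness_of(s1[1, ])), 0.15)

  # skewed source in a band admitting in-band triples
  cfg_sk <- sim_config(
    sampling_rate = 1000, duration = 20, source_band = c(5, 45),
    nongaussianity = 1, seed = 3
  )
  expect_gt(skewness_of(simulate_sources(cfg_sk)[1, ]), 0.5)

  # band above Nyquist rejected
  expect_error(
    sim_config(sampling_rate = 100, source_band = c(20, 60)),
    "Nyquist"
  )
})

test_that("gaussian sources suppress the bispectrum as epochs accumulate", {
  fs <- 1000
  len <- 2 * fs
  mean_b <- function(n_ep, seed) {
    cfg <- sim_config(
      sampling_rate = fs, duration = 2 * n_ep + 4,
      source_band = c(5, 45), nongaussianity = 0, seed = seed
    )
    s <- simulate_sources(cfg)[1, ]
    mats <- lapply(seq_len(n_ep), function(e) {
      matrix(s[(e - 1) * len + seq_len(len)], 1)
    })
    ep <- make_epochs_from_matrix(mats, fs, n_cortex = 1)
    ep$channel_info <- make_channel_info(1, 0)[1, ]
    co <- fourier_coefficients(ep, 1)
    mean(Mod(cross_bispectrum(co, co)$b))
  }
  b_small <- mean_b(8, 11)
  b_large <- mean_b(64, 12)
  # |B| ~ n^(-1/2): expect a clear decrease by about sqrt(8)
  expect_lt(b_large, b_small / 1.8)
})

test_that("couple_and_mix produces the configured delay and direction", {
  cfg <- sim_config(
    sampling_rate = 1000, duration = 20, source_band = c(5, 45),
    coupling_delay = 25, snr = 30, innovation_sd = 0,
    line_noise_amplitude = 0, n_cortex_channels = 2,
    n_stn_channels = 2, seed = 5
  )
  src <- simulate_sources(cfg)
  out <- couple_and_mix(src, cfg)
  expect_s3_class(out$recording, "stn_recording")
  expect_equal(out$ground_truth$true_delay, 25)
  expect_equal(out$ground_truth$true_direction, "cortex->stn")
  # brute-force cross-correlation oracle between a cortex and an STN channel
  cc <- ccf(out$recording$data[3, ], out$recording$data[1, ],
    lag.max = 60, plot = FALSE
  )
  expect_equal(cc$lag[which.max(abs(cc$acf))], 25)
  # one-way coupling: peak strictly on one side of zero lag
  expect_gt(cc$lag[which.max(abs(cc$acf))], 0)

  # non-integer delay rejected with the finest representable delay named
  cfg_bad <- sim_config(
    sampling_rate = 1000, duration = 5,
    source_band = c(5, 45), coupling_delay = 25.5
  )
  expect_error(couple_and_mix(simulate_sources(cfg_bad), cfg_bad), "1 ms")
})

test_that("zero coupling gain decouples the channel sets", {
  cfg <- sim_config(
    sampling_rate = 500, duration = 60, source_band = c(10, 30),
    coupling_gain = 0, coupling_delay = 24, snr = 20,
    line_noise_amplitude = 0,
    n_cortex_channels = 2, n_stn_channels = 2, seed = 6
  )
  out <- couple_and_mix(simulate_sources(cfg), cfg)
  ep <- make_epochs(out$recording, 2)
  csd <- csd_multitaper(ep, 5)
  ic <- imcoh_grand_average(csd, 1:2, 3:4)
  band <- ic$freqs >= 10 & ic$freqs <= 30
  expect_lt(mean(ic$values[band]), 0.12)
})

test_that("stimulation artifact has the commanded period and clean spectrum", {
  fs <- 4000
  n <- fs * 10
  rec0 <- make_recording(matrix(0, 2, n), fs)
  expect_identical(add_dbs_artifact(rec0, 130, 60, 0), rec0)
  rec <- add_dbs_artifact(rec0, 130, 60, 50)
  expect_equal(rec$dbs_artifact$period_samples, 4000 / 130)
  expect_equal(rec$condition, "dbs")
  x <- rec$data[1, ]
  # power confined to DC and 130 Hz harmonics (aliased); duration chosen so
  # every harmonic falls on the periodogram grid
  pw <- Mod(fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  alias <- function(f) {
    f <- f %% fs
    pmin(f, fs - f)
  }
  harm <- unique(alias(130 * (0:1000)))
  on_harm <- vapply(freqs, function(f) any(abs(alias(f) - harm) < 0.01), logical(1))
  expect_lt(sum(pw[!on_harm]) / sum(pw), 0.01)
  expect_error(add_dbs_artifact(rec0, 2500, 60, 10), "Nyquist")
})

test_that("simulate_var honours stability and known Granger structure", {
  A_bad <- list(matrix(c(1.1, 0, 0, 0.5), 2, 2))
  expect_error(simulate_var(A_bad, diag(2), 100), "spectral radius")

  # decoupled: both cross-correlations flat
  A0 <- list(diag(c(0.5, 0.5)))
  x <- simulate_var(A0, diag(2), 20000, seed = 4)
  cc <- ccf(x[1, ], x[2, ], lag.max = 10, plot = FALSE)
  expect_lt(max(abs(cc$acf)), 0.05)
  # determinism
  expect_identical(x, simulate_var(A0, diag(2), 20000, seed = 4))
})

test_that("fiber atlas realises requested counts exactly (brute-force scan)", {
  geom <- list(
    ecog = rbind(c(40, -10, 60), c(44, -25, 60)),
    stn = rbind(c(12, -13, -7), c(12, -13, 3))
  )
  counts <- matrix(c(7, 0, 2, 4), 2, 2)
  atlas <- simulate_fiber_atlas(geom, counts, seed = 1, n_decoys = 10)
  brute <- function(e, s) {
    sum(vapply(atlas$streamlines, function(ln) {
      min(sqrt(colSums((t(ln) - e)^2))) <= 5 &&
        min(sqrt(colSums((t(ln) - s)^2))) <= 3
    }, logical(1)))
  }
  for (i in 1:2) {
    for (j in 1:2) {
      expect_identical(brute(geom$ecog[i, ], geom$stn[j, ]), as.integer(counts[i, j]))
      expect_identical(
        count_connecting_fibers(atlas, geom$ecog[i, ], geom$stn[j, ]),
        as.integer(counts[i, j])
      )
    }
  }
  # all-zero request: only decoys, nothing qualifies
  atlas0 <- simulate_fiber_atlas(geom, matrix(0, 2, 2), seed = 2, n_decoys = 5)
  expect_identical(count_connecting_fibers(atlas0, geom$ecog[1, ], geom$stn[1, ]), 0L)
  # decoys impossible: every point near the cortex contact is inside the
  # (inflated) STN radius of the coincident contact
  expect_error(
    simulate_fiber_atlas(
      list(ecog = rbind(c(0, 0, 0)), stn = rbind(c(0, 0, 1))),
      matrix(2, 1, 1),
      seed = 3, r_ecog = 5, r_stn = 30
    ),
    "unsatisfiable|decoy"
  )
})

test_that("lme cohort has the configured linear structure", {
  tab0 <- simulate_lme_cohort(
    n_subjects = 6, n_obs_per_subject = 8,
    true_betas = c(1, 4, 0.5),
    random_intercept_sd = 0, residual_sd = 0, seed = 3
  )
  # noiseless limit: exact linear relation
  fit <- lm(response ~ pattern + medication, data = tab0)
  expect_equal(unname(coef(fit)), c(1, 4, 0.5), tolerance = 1e-10)
  expect_identical(tab0, simulate_lme_cohort(
    n_subjects = 6, n_obs_per_subject = 8, true_betas = c(1, 4, 0.5),
    random_intercept_sd = 0, residual_sd = 0, seed = 3
  ))
  expect_error(simulate_lme_cohort(n_subjects = 1), "2 subjects")
})
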