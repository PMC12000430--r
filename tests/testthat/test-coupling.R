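# Cross-spectra, imaginary coherency, MIC, Whittle VAR and TRGC.

lagged_pair_epochs <- function(n_ep = 20, fs = 500, f0 = 20, lag_rad = pi / 2,
                               noise = 0.01, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n_ep), function(e) {
      ph <- runif(1) * 2 * pi
      t <- seq_len(2 * fs) / fs
      rbind(
        sin(2 * pi * f0 * t + ph) + rnorm(2 * fs, sd = noise),
        sin(2 * pi * f0 * t + ph - lag_rad) + rnorm(2 * fs, sd = noise)
      )
    })
    make_epochs_from_matrix(mats, fs, n_cortex = 1)
  })
}

test_that("csd is Hermitian with psd diagonal and unit self-coherency", {
  ep <- lagged_pair_epochs()
  csd <- csd_multitaper(ep, 5)
  for (f in seq(1, length(csd$freqs), by = 50)) {
    S <- csd$matrices[, , f]
    expect_lt(max(Mod(S - Conj(t(S)))), 1e-12)
    expect_true(all(Re(diag(S)) >= 0))
  }
  ps <- multitaper_psd(ep, 5)
  expect_equal(Re(csd$matrices[1, 1, ]), ps$values[1, ], tolerance = 1e-10)

  # identical channels: |coherency| = 1 everywhere
  mats <- lapply(1:10, function(e) {
    x <- rnorm(1000)
    rbind(x, x)
  })
  csd2 <- csd_multitaper(make_epochs_from_matrix(mats, 500, n_cortex = 1), 5)
  coh <- Mod(csd2$matrices[1, 2, ]) /
    sqrt(Re(csd2$matrices[1, 1, ]) * Re(csd2$matrices[2, 2, ]))
  expect_equal(coh, rep(1, length(coh)), tolerance = 1e-9)

  one <- make_epochs_from_matrix(list(matrix(rnorm(100), 1)), 50)
  expect_error(csd_multitaper(one), "two channels")
})

test_that("imaginary coherency sees quadrature and ignores zero lag", {
  ep <- lagged_pair_epochs(lag_rad = pi / 2)
  csd <- csd_multitaper(ep, 5)
  f20 <- which.min(abs(csd$freqs - 20))
  C <- csd$matrices[1, 2, f20] /
    sqrt(Re(csd$matrices[1, 1, f20]) * Re(csd$matrices[2, 2, f20]))
  expect_lt(abs(Re(C)), 0.05) # purely imaginary at 90 degrees
  expect_gt(abs(Im(C)), 0.99)
  ic <- imcoh_grand_average(csd, 1, 2)
  expect_gt(ic$values[f20], 0.99)

  # zero-lag scaled copy: exactly immune (cross-spectrum purely real)
  mats <- lapply(1:10, function(e) {
    x <- rnorm(1000)
    rbind(x, 1.7 * x)
  })
  csd0 <- csd_multitaper(make_epochs_from_matrix(mats, 500, n_cortex = 1), 5)
  ic0 <- imcoh_grand_average(csd0, 1, 2)
  expect_lt(max(ic0$values), 1e-10)
  # real mixing of several shared sources: small everywhere, far below the
  # quadrature case above
  cm <- sin(2 * pi * 7 * seq_len(1000) / 500)
  mats2 <- lapply(1:10, function(e) {
    x <- rnorm(1000)
    rbind(x + cm, 1.7 * x + cm)
  })
  csd2m <- csd_multitaper(make_epochs_from_matrix(mats2, 500, n_cortex = 1), 5)
  ic2m <- imcoh_grand_average(csd2m, 1, 2)
  expect_lt(max(ic2m$values), 0.15)
})

test_that("imaginary coherency matches a hand-computed toy csd", {
  csd <- structure(
    list(
      freqs = c(10), fs = 500, n_samples = 1000,
      matrices = array(c(1 + 0i, 0.3 - 0.4i, 0.3 + 0.4i, 1 + 0i), c(2, 2, 1)),
      channel_info = make_channel_info(1, 1), n_epochs = 1
    ),
    class = "stn_csd"
  )
  ic <- imcoh_grand_average(csd, 1, 2)
  expect_equal(ic$values, 0.4, tolerance = 1e-12)
})

test_that("mic maximises, recovers mixings and respects zero-lag immunity", {
  fs <- 500
  nc <- 5
  ns <- 3
  withr::with_seed(3, {
    mixc <- runif(nc, 0.4, 1.5) * sample(c(-1, 1), nc, TRUE)
    mixs <- runif(ns, 0.4, 1.5) * sample(c(-1, 1), ns, TRUE)
    lag <- 6 # ~90 degrees at 22 Hz
    mats <- lapply(1:40, function(e) {
      t <- seq_len(2 * fs + lag) / fs
      s <- sin(2 * pi * 22 * t + runif(1) * 2 * pi)
      rbind(
        outer(mixc, s[(lag + 1):(lag + 2 * fs)]) + matrix(rnorm(nc * 2 * fs, sd = 0.4), nc),
        outer(mixs, 0.8 * s[seq_len(2 * fs)]) + matrix(rnorm(ns * 2 * fs, sd = 0.4), ns)
      )
    })
  })
  ep <- make_epochs_from_matrix(mats, fs, n_cortex = nc)
  csd <- csd_multitaper(ep, 5)
  m <- mic(csd, 1:nc, nc + 1:ns)
  fpk <- which.min(abs(m$freqs - 22))
  expect_gt(m$values[fpk], 0.9)
  expect_gt(abs(cor(m$seed_patterns_z[, fpk], abs(mixc))), 0.9)
  expect_gt(abs(cor(m$target_patterns_z[, fpk], abs(mixs))), 0.9)
  expect_true(all(m$values >= 0 & m$values <= 1 + 1e-9))

  # maximisation property: MIC >= |Im coherency| of every whitened
  # seed-target component pair at each frequency
  for (f in seq(1, length(m$freqs), by = 25)) {
    S <- csd$matrices[, , f]
    wa <- stncoupling:::inv_sqrt_herm(Re(S[1:nc, 1:nc]))$value
    wb <- stncoupling:::inv_sqrt_herm(Re(S[nc + 1:ns, nc + 1:ns]))$value
    D <- Im(Re(wa) %*% S[1:nc, nc + 1:ns] %*% Re(wb))
    expect_gte(m$values[f] + 1e-10, max(abs(D)))
    expect_gte(m$values[f] + 1e-10, mean(abs(D)))
  }

  # single-channel instantaneous copy: exactly zero
  mats0 <- lapply(1:10, function(e) {
    x <- rnorm(1000)
    rbind(x, 0.5 * x)
  })
  m0 <- mic(
    csd_multitaper(make_epochs_from_matrix(mats0, fs, n_cortex = 1), 5),
    1, 2
  )
  expect_lt(max(m0$values), 1e-10)
})

test_that("whittle recursion recovers a known VAR from its csd", {
  A <- list(matrix(c(0.5, 0, 0.5, 0.3), 2, 2, byrow = TRUE)) # x drives y
  x <- simulate_var(A, diag(2), 200 * 500, seed = 9)
  fs <- 250
  len <- 2 * fs
  n_ep <- ncol(x) %/% len
  mats <- lapply(seq_len(n_ep), function(e) x[, (e - 1) * len + seq_len(len)])
  ep <- make_epochs_from_matrix(mats, fs, n_cortex = 1)
  csd <- csd_multitaper(ep, 5)
  fit <- var_from_csd(csd, order = 10)
  expect_lt(max(abs(fit$A[[1]] - A[[1]])), 0.05 * max(abs(A[[1]])) + 0.02)
  expect_lt(max(abs(fit$Sigma - diag(2))), 0.05)
  # higher lags near zero
  expect_lt(max(abs(fit$A[[5]])), 0.05)

  # white noise: all lag > 0 coefficients vanish
  withr::with_seed(10, {
    matsw <- lapply(1:50, function(e) matrix(rnorm(2 * len), 2))
  })
  csdw <- csd_multitaper(make_epochs_from_matrix(matsw, fs, n_cortex = 1), 5)
  fitw <- var_from_csd(csdw, order = 5)
  expect_lt(max(abs(fitw$A[[1]])), 0.05)
})

test_that("spectral granger matches a closed-form oracle of the true VAR", {
  A1 <- matrix(c(0.5, 0, 0.5, 0.3), 2, 2, byrow = TRUE)
  Sig <- diag(2)
  fs <- 250
  x <- simulate_var(list(A1), Sig, 1600 * 500, seed = 13)
  len <- 2 * fs
  mats <- lapply(seq_len(ncol(x) %/% len), function(e) {
    x[, (e - 1) * len + seq_len(len)]
  })
  csd <- csd_multitaper(make_epochs_from_matrix(mats, fs, n_cortex = 1), 5)
  fit <- var_from_csd(csd, order = 10)
  fit$fs <- fs
  freqs <- csd$freqs
  est <- stncoupling:::spectral_gc_pair(fit, 1, 2, freqs)

  # independent closed-form oracle written out in scalars
  oracle <- vapply(freqs, function(f) {
    z <- exp(-2i * pi * f / fs)
    H <- solve(diag(2) - A1 * z)
    S22 <- Re((H %*% Sig %*% Conj(t(H)))[2, 2])
    sig_x_cond <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
    log(S22 / (S22 - Mod(H[2, 1])^2 * sig_x_cond))
  }, numeric(1))
  expect_lt(max(abs(est$ab - oracle)), 0.02 * max(oracle))
  expect_lt(max(est$ba), 0.01) # no reverse coupling
})

test_that("trgc is antisymmetric, directional and nulls instantaneous mixing", {
  A1 <- matrix(c(0.5, 0, 0.5, 0.3), 2, 2, byrow = TRUE)
  x <- simulate_var(list(A1), diag(2), 100 * 500, seed = 14)
  fs <- 250
  len <- 2 * fs
  mats <- lapply(seq_len(ncol(x) %/% len), function(e) x[, (e - 1) * len + seq_len(len)])
  csd <- csd_multitaper(make_epochs_from_matrix(mats, fs, n_cortex = 1), 5)
  tg <- trgc(csd, 1, 2, order = 10)
  tg_swap <- trgc(csd, 2, 1, order = 10)
  expect_lt(max(abs(tg$values + tg_swap$values)), 1e-10)
  expect_gt(mean(tg$values), 0) # x (seed) drives y

  # instantaneously mixed shared source (asymmetric SNR, which inflates the
  # plain net Granger score): TRGC stays an order of magnitude below the
  # genuinely coupled reference above, and shrinks as data accumulate
  withr::with_seed(15, {
    zero_lag_trgc <- function(n_ep) {
      mats0 <- lapply(seq_len(n_ep), function(e) {
        s <- as.numeric(arima.sim(list(ar = 0.7), len))
        rbind(s + rnorm(len, sd = 0.5), 0.8 * s + rnorm(len, sd = 0.5))
      })
      csd0 <- csd_multitaper(make_epochs_from_matrix(mats0, fs, n_cortex = 1), 5)
      trgc(csd0, 1, 2, order = 10)
    }
    t_small <- zero_lag_trgc(40)
    t_large <- zero_lag_trgc(640)
    expect_lt(max(abs(t_small$values)), max(tg$values) / 5)
    expect_lt(max(abs(t_large$values)), max(abs(t_small$values)))
  })
})

test_that("segment averaging is element-wise with matched grids", {
  ep <- lagged_pair_epochs(n_ep = 10)
  csd <- csd_multitaper(ep, 5)
  ic <- imcoh_grand_average(csd, 1, 2)
  avg <- average_segments(list(ic, ic, ic))
  expect_equal(avg$values, ic$values)
  expect_equal(avg$segment_count, 3)
  ic2 <- ic
  ic2$values <- ic$values + 0.2
  expect_equal(
    average_segments(list(ic, ic2))$values,
    ic$values + 0.1
  )
  ic3 <- ic
  ic3$freqs <- ic$freqs + 1
  expect_error(average_segments(list(ic, ic3)), "mismatched")
  ic4 <- ic
  ic4$method <- "mic"
  expect_error(average_segments(list(ic, ic4)), "mismatched")
})
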