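# Multitaper spectra, normalisation, band averages, rank reduction, SSD.

sine_epochs <- function(freq, fs = 500, n_ep = 10, n_ch = 1, amp = 1,
                        noise = 0, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(n_ep), function(e) {
      ph <- runif(1) * 2 * pi
      t <- seq_len(2 * fs) / fs
      base <- amp * sin(2 * pi * freq * t + ph)
      do.call(rbind, lapply(seq_len(n_ch), function(ch) {
        base + if (noise > 0) rnorm(length(t), sd = noise) else 0
      }))
    })
    make_epochs_from_matrix(mats, fs, n_cortex = n_ch)
  })
}

test_that("multitaper psd satisfies Parseval and the grid contract", {
  ep <- sine_epochs(20, amp = 1)
  ps <- multitaper_psd(ep, 5)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.5) # 1 / duration
  df <- ps$freqs[2] - ps$freqs[1]
  integrated <- sum(ps$values[1, ]) * df
  expect_equal(integrated, 0.5, tolerance = 0.05 * 0.5) # sine variance
  # spectral mass concentrated within 20 +/- 5 Hz
  sel <- ps$freqs >= 15 & ps$freqs <= 25
  expect_gt(sum(ps$values[1, sel]) / sum(ps$values[1, ]), 0.95)
  # incompatible bandwidth errors
  short <- make_epochs_from_matrix(list(matrix(rnorm(50), 1)), 100)
  expect_error(multitaper_psd(short, 0.5), "taper")
})

test_that("white-noise multitaper spectrum is flat", {
  withr::with_seed(4, {
    mats <- lapply(1:40, function(e) matrix(rnorm(1000), 1))
  })
  ps <- multitaper_psd(make_epochs_from_matrix(mats, 500), 5)
  sel <- ps$freqs > 5 & ps$freqs < 245
  fit <- lm(log(ps$values[1, sel]) ~ log(ps$freqs[sel]))
  expect_lt(abs(coef(fit)[2]), 0.1)
})

test_that("percent-total normalisation sums to 100 and is scale invariant", {
  ep <- sine_epochs(20, n_ch = 2, noise = 0.5)
  ps <- multitaper_psd(ep, 5)
  pn <- normalize_percent_total(ps)
  sums <- rowSums(pn$values[, pn$included_bins])
  expect_equal(unname(sums), c(100, 100), tolerance = 1e-9)
  # excluded window not part of the total
  f <- pn$freqs
  expect_true(all(!pn$included_bins[f > 45 & f < 55]))

  ps2 <- ps
  ps2$values <- ps$values * 2
  pn2 <- normalize_percent_total(ps2)
  expect_equal(pn$values, pn2$values, tolerance = 1e-12)

  pn95 <- normalize_percent_total(ps, range = c(5, 95), exclusion = NULL)
  expect_equal(unname(rowSums(pn95$values[, pn95$included_bins])), c(100, 100),
    tolerance = 1e-9
  )
  expect_error(normalize_percent_total(pn), "already")
})

test_that("band averages follow inclusive-endpoint arithmetic", {
  ep <- sine_epochs(20)
  ps <- multitaper_psd(ep, 5)
  # constant spectrum -> the constant
  ps_const <- ps
  ps_const$values[] <- 3.5
  expect_equal(unname(band_average(ps_const, "low_beta")), 3.5)
  # (12, 20) on a 0.5 Hz grid has 17 bins, endpoints included
  sel <- ps$freqs >= 12 & ps$freqs <= 20
  expect_equal(sum(sel), 17)
  expect_equal(
    unname(band_average(ps, c(12, 20))),
    mean(ps$values[1, sel])
  )
  # hand-computed toy: 5 bins
  toy <- ps
  toy$freqs <- c(10, 11, 12, 13, 14)
  toy$values <- matrix(c(1, 2, 3, 4, 10), 1)
  expect_equal(unname(band_average(toy, c(10, 14))), 4)
  expect_error(band_average(toy, c(50, 60)), "no frequency bins")
})

test_that("rank reduction uses the fixed component table and is faithful", {
  withr::with_seed(5, {
    mats <- lapply(1:10, function(e) rbind(
      matrix(rnorm(6 * 500), 6),
      matrix(rnorm(8 * 500), 8)
    ))
  })
  ep <- make_epochs_from_matrix(mats, 250, n_cortex = 6)
  rr_c <- reduce_rank(ep, "cortex", "unipolar")
  expect_equal(dim(rr_c$epochs$data)[2], 5)
  rr_s <- reduce_rank(ep, "stn", "unipolar")
  expect_equal(dim(rr_s$epochs$data)[2], 3)
  ep_bip <- ep
  ep_bip$channel_info$montage <- "bipolar"
  expect_equal(dim(reduce_rank(ep_bip, "cortex", "bipolar")$epochs$data)[2], 4)
  expect_equal(dim(reduce_rank(ep_bip, "stn", "bipolar")$epochs$data)[2], 3)
  expect_error(reduce_rank(make_epochs_from_matrix(
    lapply(1:3, function(e) matrix(rnorm(2 * 100), 2)), 100
  ), "cortex", "unipolar"), "fewer")

  # exact-rank data reconstructs perfectly from its components
  withr::with_seed(55, {
    lift <- matrix(rnorm(6 * 3), 6, 3)
    mats3 <- lapply(1:4, function(e) {
      rbind(lift %*% matrix(rnorm(3 * 500), 3), matrix(rnorm(3 * 500), 3))
    })
  })
  ep3 <- make_epochs_from_matrix(mats3, 250, n_cortex = 6)
  rr3 <- reduce_rank(ep3, "cortex", "unipolar", n = 3)
  recon <- rr3$projection %*% rr3$epochs$data[1, , ]
  orig <- ep3$data[1, 1:6, ]
  orig_c <- orig - rowMeans(ep3$data[, 1:6, ] |> aperm(c(2, 1, 3)) |> matrix(nrow = 6))
  expect_lt(max(abs(recon - orig_c)), 1e-9)
})

test_that("ssd recovers mixings, satisfies contracts and is gain invariant", {
  fs <- 500
  mix <- c(1.5, -0.8, 0.4, 1.0)
  withr::with_seed(6, {
    mats <- lapply(1:40, function(e) {
      t <- seq_len(2 * fs) / fs
      s <- sin(2 * pi * 15 * t + runif(1) * 2 * pi)
      outer(mix, s) + matrix(rnorm(4 * 2 * fs, sd = 0.4), 4)
    })
  })
  ep <- make_epochs_from_matrix(mats, fs)
  sf <- ssd_fit(ep, c(12, 20))
  expect_gt(abs(cor(sf$patterns_z[, 1], abs(mix))), 0.95)
  # z-score contract per component
  expect_equal(colMeans(sf$patterns_z), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(sf$patterns_z, 2, sd), rep(1, 4), tolerance = 1e-12)
  # eigenvalues descending
  expect_true(all(diff(sf$snr_eigenvalues) <= 0))
  # component spectrum peaks inside the band
  cs <- sf$component_spectrum
  expect_true(cs$freqs[which.max(cs$values[1, ])] >= 12 &&
    cs$freqs[which.max(cs$values[1, ])] <= 20)

  # Rayleigh optimality: top eigenvalue beats every channel and 100 random
  # filters on the band / (bandwidth-normalised) flank power ratio
  scl <- sf$channel_scale
  ratio_of <- function(w) {
    num <- den <- 0
    for (m in mats) {
      ms <- m / scl
      band <- stncoupling:::fft_zero_phase(list(
        stncoupling:::resp_bandpass(12, 20, 4)
      ), t(ms), fs) %*% w
      flank <- stncoupling:::fft_zero_phase(list(
        stncoupling:::resp_bandpass(11, 21, 4),
        stncoupling:::resp_bandstop(12, 20, 4)
      ), t(ms), fs) %*% w
      num <- num + sum((band - mean(band))^2)
      den <- den + sum((flank - mean(flank))^2)
    }
    num / den / (8 / 2) # bandwidth normalisation as in the fit
  }
  top <- sf$snr_eigenvalues[1]
  for (ch in 1:4) {
    w <- numeric(4)
    w[ch] <- 1
    expect_gte(top * (1 + 1e-6), ratio_of(w))
  }
  withr::with_seed(7, {
    for (k in 1:100) {
      w <- rnorm(4)
      expect_gte(top * (1 + 1e-6), ratio_of(w / sqrt(sum(w^2))))
    }
  })

  # invariance to rescaling one channel
  mats10 <- lapply(mats, function(m) {
    m[2, ] <- m[2, ] * 10
    m
  })
  sf10 <- ssd_fit(make_epochs_from_matrix(mats10, fs), c(12, 20))
  expect_lt(max(abs(sf$patterns_z - sf10$patterns_z)), 1e-5)
})

test_that("ssd on broadband noise has no spatial SNR structure", {
  withr::with_seed(8, {
    mats <- lapply(1:40, function(e) matrix(rnorm(4 * 1000), 4))
  })
  sf <- ssd_fit(make_epochs_from_matrix(mats, 500), c(12, 20))
  expect_equal(sf$snr_eigenvalues[1], 1, tolerance = 0.25)
})
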