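# Shared fixture builders. All fixtures are generated in code at test time.

make_channel_info <- function(n_cortex = 2, n_stn = 2, montage = "unipolar") {
  data.frame(
    name = c(sprintf("ECOG_%d", seq_len(n_cortex)), sprintf("LFP_%d", seq_len(n_stn))),
    site = c(rep("cortex", n_cortex), rep("stn", n_stn)),
    montage = montage,
    region = c(rep("motor", n_cortex), rep("stn", n_stn)),
    mni_x = c(40 + 10 * seq_len(n_cortex), rep(12, n_stn)),
    mni_y = c(rep(-10, n_cortex), rep(-13, n_stn)),
    mni_z = c(rep(60, n_cortex), -7 + 8 * seq_len(n_stn)),
    is_stim_contact = FALSE,
    stringsAsFactors = FALSE
  )
}

make_recording <- function(data, fs, n_cortex = NULL, condition = "off") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  n <- nrow(data)
  if (is.null(n_cortex)) n_cortex <- ceiling(n / 2)
  new_recording(data, fs, make_channel_info(n_cortex, n - n_cortex),
    condition = condition
  )
}

make_epochs_from_matrix <- function(mat_list, fs, n_cortex = NULL) {
  # mat_list: list of channels x samples matrices (one per epoch)
  n_ep <- length(mat_list)
  n_ch <- nrow(mat_list[[1]])
  len <- ncol(mat_list[[1]])
  arr <- array(0, c(n_ep, n_ch, len))
  for (e in seq_len(n_ep)) arr[e, , ] <- mat_list[[e]]
  if (is.null(n_cortex)) n_cortex <- ceiling(n_ch / 2)
  new_epochs(arr, fs, make_channel_info(n_cortex, n_ch - n_cortex))
}

# Independent band-power oracle: direct periodogram. A Hann window is
# available for stopband measurements, where rectangular-window leakage
# from the passband would otherwise dominate.
periodogram_power <- function(x, fs, lo, hi, window = c("rect", "hann")) {
  window <- match.arg(window)
  n <- length(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    x <- (x - mean(x)) * w / sqrt(mean(w^2))
  }
  pw <- Mod(stats::fft(x))^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- (freqs >= lo & freqs <= hi) | (freqs >= fs - hi & freqs <= fs - lo)
  sum(pw[sel])
}

skewness_of <- function(x) {
  x <- x - mean(x)
  mean(x^3) / mean(x^2)^1.5
}

# Seed/target epoch pair with a known sample delay and per-channel noise.
delayed_pair_epochs <- function(duration = 60, fs = 1000, delay = 25,
                                snr_db = 10, seed = 1, band = c(5, 45)) {
  cfg <- sim_config(
    sampling_rate = fs, duration = duration + 4,
    source_band = band, nongaussianity = 1, seed = seed
  )
  src <- simulate_sources(cfg)[1, ]
  n <- duration * fs
  src <- src[seq_len(n + delay)]
  x0 <- src[delay + seq_len(n)]
  y0 <- src[seq_len(n)]
  ns <- sqrt(10^(-snr_db / 10))
  noise <- withr::with_seed(seed + 1000, matrix(rnorm(2 * n, sd = ns), 2))
  len <- 2 * fs
  n_ep <- n %/% len
  mats <- lapply(seq_len(n_ep), function(e) {
    ix <- (e - 1) * len + seq_len(len)
    rbind(x0[ix] + noise[1, ix], y0[ix] + noise[2, ix])
  })
  make_epochs_from_matrix(mats, fs, n_cortex = 1)
}
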