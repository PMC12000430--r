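# Multitaper power spectra, percent-total normalisation, canonical band
# averages, SVD rank normalisation, and spatio-spectral decomposition.

#' Canonical frequency band definitions
#'
#' @param name One of "mu_alpha", "low_beta", "high_beta", "theta", "gamma".
#' @return List with `name`, `lo`, `hi` (Hz).
#' @export
band_definition <- function(name = c(
                              "mu_alpha", "low_beta", "high_beta",
                              "theta", "gamma"
                            )) {
  name <- match.arg(name)
  edges <- switch(name,
    mu_alpha = c(8, 12), low_beta = c(12, 20), high_beta = c(20, 30),
    theta = c(4, 8), gamma = c(60, 90)
  )
  list(name = name, lo = edges[1], hi = edges[2])
}

as_band <- function(band) {
  if (is.character(band)) band <- band_definition(band)
  if (is.list(band)) {
    return(c(band$lo, band$hi))
  }
  stopifnot(length(band) == 2L, band[2] > band[1])
  band
}

# Tapered Fourier coefficients for every kept epoch and taper:
# array [n_freq, n_tapers, n_epochs, n_channels], one-sided grid.
tapered_fft <- function(epochs, bandwidth) {
  dat <- kept_epoch_data(epochs)
  d <- dim(dat)
  fs <- epochs$sampling_rate
  mp <- multitaper_params(d[3], fs, bandwidth)
  tap <- dpss_tapers(d[3], mp$nw, mp$k)
  nf <- d[3] %/% 2 + 1
  out <- array(0i, dim = c(nf, mp$k, d[1], d[2]))
  for (e in seq_len(d[1])) {
    x <- t(dat[e, , , drop = TRUE])
    if (d[2] == 1L) x <- matrix(dat[e, 1, ], ncol = 1)
    x <- sweep(x, 2, colMeans(x))
    for (j in seq_len(mp$k)) {
      X <- stats::mvfft(x * tap[, j])
      out[, j, e, ] <- X[seq_len(nf), ]
    }
  }
  list(
    coeffs = out, freqs = (seq_len(nf) - 1) * fs / d[3],
    n_tapers = mp$k, fs = fs, n_samples = d[3]
  )
}

#' Multitaper power spectral density
#'
#' Slepian-taper spectral estimates averaged over tapers and kept epochs,
#' one spectrum per channel. The `bandwidth` is the full spectral smoothing
#' bandwidth; the half-bandwidth W is `bandwidth / 2` and
#' `2 * duration * W - 1` tapers are used.
#'
#' @param epochs An epochs object.
#' @param bandwidth Full smoothing bandwidth in Hz (default 5).
#' @return An `stn_power_spectrum` with one-sided PSD in microvolt^2/Hz on a
#'   `1 / epoch_duration` Hz grid.
#' @export
multitaper_psd <- function(epochs, bandwidth = 5) {
  stopifnot(inherits(epochs, "stn_epochs"))
  tf <- tapered_fft(epochs, bandwidth)
  nf <- length(tf$freqs)
  pw <- Mod(tf$coeffs)^2 / tf$fs
  # average tapers and epochs; fold to one-sided density
  vals <- apply(pw, c(1, 4), mean)
  interior <- seq(2, nf - if (tf$n_samples %% 2 == 0) 1 else 0)
  vals[interior, ] <- 2 * vals[interior, , drop = FALSE]
  structure(
    list(
      freqs = tf$freqs, values = t(vals), normalisation = "raw",
      channel_info = epochs$channel_info, bandwidth = bandwidth,
      n_tapers = tf$n_tapers, n_epochs = sum(epochs$kept_mask)
    ),
    class = "stn_power_spectrum"
  )
}

#' Normalise a power spectrum to percent total power
#'
#' Each bin becomes `100 * raw / sum(raw)` over the normalisation range,
#' excluding a line-noise window, per channel. The default mirrors a
#' 5-60 Hz range with a 45-55 Hz exclusion; a broader 5-95 Hz range is
#' available through `range`.
#'
#' @param spectrum A raw `stn_power_spectrum`.
#' @param range Two-element normalisation range in Hz.
#' @param exclusion Two-element excluded window in Hz (`NULL` for none).
#' @return The normalised spectrum; values over included bins sum to 100
#'   per channel.
#' @export
normalize_percent_total <- function(spectrum, range = c(5, 60),
                                    exclusion = c(45, 55)) {
  stopifnot(inherits(spectrum, "stn_power_spectrum"))
  if (spectrum$normalisation != "raw") {
    stop("spectrum is already normalised", call. = FALSE)
  }
  f <- spectrum$freqs
  include <- f >= range[1] & f <= range[2]
  if (!is.null(exclusion)) {
    include <- include & !(f >= exclusion[1] & f <= exclusion[2])
  }
  if (!any(include)) stop("empty normalisation range", call. = FALSE)
  totals <- rowSums(spectrum$values[, include, drop = FALSE])
  if (any(totals <= 0)) stop("zero total power in normalisation range", call. = FALSE)
  spectrum$values <- 100 * spectrum$values / totals
  spectrum$normalisation <- sprintf(
    "pct_%g_%g%s", range[1], range[2],
    if (is.null(exclusion)) "" else sprintf("_excl_%g_%g", exclusion[1], exclusion[2])
  )
  spectrum$included_bins <- include
  spectrum
}

#' Average a spectrum over a canonical band
#'
#' Arithmetic mean over bins with `lo <= f <= hi` (inclusive endpoints).
#'
#' @param spectrum An `stn_power_spectrum`.
#' @param band A band name, [band_definition()], or `c(lo, hi)` in Hz.
#' @return Named numeric vector, one value per channel.
#' @export
band_average <- function(spectrum, band) {
  b <- as_band(band)
  sel <- spectrum$freqs >= b[1] & spectrum$freqs <= b[2]
  if (!any(sel)) stop("band contains no frequency bins", call. = FALSE)
  out <- rowMeans(spectrum$values[, sel, drop = FALSE])
  names(out) <- spectrum$channel_info$name
  out
}

# Fixed component counts used to normalise dimensionality across subjects.
rank_table <- c(
  "bipolar.cortex" = 4L, "bipolar.stn" = 3L,
  "unipolar.cortex" = 5L, "unipolar.stn" = 3L
)

#' Reduce a channel set to a fixed number of principal components
#'
#' Extracts principal components by singular value decomposition of the
#' concatenated epoch data for one site and keeps the first n, where n is
#' fixed per site and montage (bipolar cortex 4, bipolar STN 3, unipolar
#' cortex 5, unipolar STN 3) so dimensionality matches across recordings.
#'
#' @param epochs An epochs object.
#' @param site "cortex" or "stn".
#' @param montage "unipolar" or "bipolar".
#' @param n Override for the component count (defaults to the fixed table).
#' @return List with `epochs` (component "channels"), `projection`
#'   (channels x n, for pattern back-mapping) and `channel_names`.
#' @export
reduce_rank <- function(epochs, site = c("cortex", "stn"),
                        montage = c("bipolar", "unipolar"), n = NULL) {
  site <- match.arg(site)
  montage <- match.arg(montage)
  n <- n %||% rank_table[[paste(montage, site, sep = ".")]]
  idx <- which(epochs$channel_info$site == site &
    epochs$channel_info$montage == montage)
  if (length(idx) < n) {
    stop(sprintf(
      "site %s (%s) has %d channels, fewer than the %d required components",
      site, montage, length(idx), n
    ), call. = FALSE)
  }
  dat <- kept_epoch_data(epochs)[, idx, , drop = FALSE]
  d <- dim(dat)
  flat <- matrix(aperm(dat, c(2, 3, 1)), nrow = d[2]) # channels x (samples*epochs)
  ch_means <- rowMeans(flat)
  flat <- flat - ch_means
  dat <- sweep(dat, 2, ch_means)
  sv <- svd(flat, nu = n, nv = 0)
  U <- sv$u # channels x n
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(n)) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  red <- array(0, dim = c(d[1], n, d[3]))
  for (e in seq_len(d[1])) {
    red[e, , ] <- t(U) %*% dat[e, , ]
  }
  ci <- data.frame(
    name = sprintf("%s_pc%d", site, seq_len(n)),
    site = site, montage = montage,
    region = if (site == "stn") "stn" else "motor",
    mni_x = NA_real_, mni_y = NA_real_, mni_z = NA_real_,
    is_stim_contact = FALSE, stringsAsFactors = FALSE
  )
  list(
    epochs = new_epochs(red, epochs$sampling_rate, ci,
      condition = epochs$condition, subject_id = epochs$subject_id
    ),
    projection = U,
    channel_names = epochs$channel_info$name[idx]
  )
}

# Covariance of band-filtered epoch data (channels x channels).
band_covariance <- function(dat, fs, lo, hi, stop_band = NULL) {
  d <- dim(dat)
  acc <- matrix(0, d[2], d[2])
  filts <- list(resp_bandpass(lo, hi, 4))
  if (!is.null(stop_band)) {
    filts <- c(filts, list(resp_bandstop(stop_band[1], stop_band[2], 4)))
  }
  n_obs <- 0
  for (e in seq_len(d[1])) {
    x <- t(dat[e, , , drop = TRUE])
    if (d[2] == 1L) x <- matrix(dat[e, 1, ], ncol = 1)
    y <- fft_zero_phase(filts, x, fs)
    y <- sweep(y, 2, colMeans(y))
    acc <- acc + crossprod(y)
    n_obs <- n_obs + d[3]
  }
  acc / n_obs
}

#' Spatio-spectral decomposition
#'
#' Finds spatial filters maximising the ratio of band power to
#' flanking-band ("noise") power through a generalised eigendecomposition
#' of the band and flank covariance matrices. Channels are scaled by their
#' flank-band standard deviation beforehand, making the decomposition
#' invariant to per-channel gain. Spatial patterns are computed as
#' `C_signal %*% filters %*% solve(t(filters) %*% C_signal %*% filters)`,
#' absolute values taken, and Z-scored across channels per component.
#'
#' @param epochs An epochs object (typically rank-normalised).
#' @param band Target band (name, [band_definition()] or `c(lo, hi)` Hz).
#' @param flank_width Flanking noise bandwidth in Hz on each side.
#' @param bandwidth Multitaper bandwidth for the component spectrum.
#' @param ridge Relative ridge added to a singular noise covariance.
#' @param projection Optional channels x components projection (from
#'   [reduce_rank()]) used to back-map patterns to the physical contacts
#'   before Z-scoring.
#' @param channel_names Names reported for the pattern rows (defaults to
#'   the epochs' channels, or the projection's row names).
#' @return An `stn_ssd` list: `filters`, `patterns_z`, `snr_eigenvalues`
#'   (descending), `component_spectrum` (multitaper PSD of the strongest
#'   component), `band`, `channel_scale`.
#' @export
ssd_fit <- function(epochs, band, flank_width = 1, bandwidth = 5,
                    ridge = 1e-8, projection = NULL, channel_names = NULL) {
  stopifnot(inherits(epochs, "stn_epochs"))
  b <- as_band(band)
  fs <- epochs$sampling_rate
  if (b[2] + flank_width >= fs / 2) {
    stop("band plus flanks must lie below Nyquist", call. = FALSE)
  }
  dat <- kept_epoch_data(epochs)
  d <- dim(dat)

  # per-channel gain estimate from the out-of-band residual (everything
  # except the band and its flanks); dividing by it makes the decomposition
  # invariant to channel gain without tying the scale to oscillatory content
  resid_sd <- numeric(d[2])
  stop_resp <- list(resp_bandstop(b[1] - flank_width, b[2] + flank_width, 4))
  for (e in seq_len(d[1])) {
    x <- t(dat[e, , , drop = TRUE])
    if (d[2] == 1L) x <- matrix(dat[e, 1, ], ncol = 1)
    y <- fft_zero_phase(stop_resp, x, fs)
    resid_sd <- resid_sd + apply(y, 2, stats::var)
  }
  scale_vec <- sqrt(resid_sd / d[1])
  scale_vec[scale_vec == 0] <- 1
  dat_s <- dat
  for (ch in seq_len(d[2])) dat_s[, ch, ] <- dat[, ch, ] / scale_vec[ch]

  c_sig <- band_covariance(dat_s, fs, lo = b[1], hi = b[2])
  c_noise <- band_covariance(dat_s, fs,
    lo = b[1] - flank_width,
    hi = b[2] + flank_width, stop_band = b
  )
  # bandwidth normalisation: flanks cover 2 * flank_width Hz against the
  # band's (hi - lo) Hz, so spectrally flat data scores an SNR of 1
  c_noise <- c_noise * (b[2] - b[1]) / (2 * flank_width)

  # generalised eigenproblem via noise whitening
  en <- eigen(c_noise, symmetric = TRUE)
  tol <- max(en$values) * 1e-10
  lam <- en$values
  ridged <- FALSE
  if (any(lam < tol)) {
    eps <- ridge * sum(diag(c_noise)) / ncol(c_noise)
    lam <- lam + eps
    ridged <- TRUE
  }
  Wh <- en$vectors %*% diag(1 / sqrt(lam), length(lam))
  M <- t(Wh) %*% c_sig %*% Wh
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  filters <- Wh %*% es$vectors
  # sign convention: largest-magnitude weight positive
  for (j in seq_len(ncol(filters))) {
    if (filters[which.max(abs(filters[, j])), j] < 0) {
      filters[, j] <- -filters[, j]
    }
  }
  patterns <- c_sig %*% filters %*%
    solve(t(filters) %*% c_sig %*% filters)
  if (!is.null(projection)) patterns <- projection %*% patterns
  patterns_z <- apply(abs(patterns), 2, function(p) (p - mean(p)) / stats::sd(p))

  # strongest component time course: band-filter, then apply filter
  comp <- array(0, dim = c(d[1], 1, d[3]))
  for (e in seq_len(d[1])) {
    x <- t(dat_s[e, , , drop = TRUE])
    if (d[2] == 1L) x <- matrix(dat_s[e, 1, ], ncol = 1)
    y <- fft_zero_phase(list(resp_bandpass(b[1], b[2], 4)), x, fs)
    comp[e, 1, ] <- y %*% filters[, 1]
  }
  comp_ci <- data.frame(
    name = "ssd_component_1", site = epochs$channel_info$site[1],
    montage = epochs$channel_info$montage[1],
    region = epochs$channel_info$region[1],
    mni_x = NA_real_, mni_y = NA_real_, mni_z = NA_real_,
    is_stim_contact = FALSE, stringsAsFactors = FALSE
  )
  comp_epochs <- new_epochs(comp, fs, comp_ci,
    condition = epochs$condition, subject_id = epochs$subject_id
  )
  spec <- multitaper_psd(comp_epochs, bandwidth = bandwidth)

  structure(
    list(
      band = b, filters = filters, patterns_z = patterns_z,
      snr_eigenvalues = rev(sort(es$values)),
      component_spectrum = spec, channel_scale = scale_vec,
      ridged = ridged,
      channel_names = channel_names %||%
        (if (is.null(projection)) epochs$channel_info$name else rownames(projection))
    ),
    class = "stn_ssd"
  )
}

#' @export
print.stn_ssd <- function(x, ...) {
  cat(sprintf(
    "<stn_ssd> band %g-%g Hz: %d components, top SNR eigenvalue %.3g\n",
    x$band[1], x$band[2], ncol(x$filters), x$snr_eigenvalues[1]
  ))
  invisible(x)
}
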