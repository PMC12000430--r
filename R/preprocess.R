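# Cleaning and structuring of raw multichannel recordings.

# Analytic zero-phase (forward-backward) Butterworth amplitude responses.
# An order-k Butterworth applied forward and backward has amplitude
# response |H|^2 = 1 / (1 + (f/fc)^(2k)); evaluating it analytically is
# exact at any order and cutoff, unlike transfer-function coefficients
# which degenerate numerically at extreme normalised cutoffs.
resp_lowpass <- function(fc, order = 4) {
  function(f) 1 / (1 + (f / fc)^(2 * order))
}

resp_highpass <- function(fc, order = 4) {
  function(f) {
    r <- numeric(length(f))
    pos <- f > 0
    r[pos] <- 1 / (1 + (fc / f[pos])^(2 * order))
    r
  }
}

resp_bandpass <- function(lo, hi, order = 4) {
  lp <- resp_lowpass(hi, order)
  hp <- resp_highpass(lo, order)
  function(f) lp(f) * hp(f)
}

resp_bandstop <- function(lo, hi, order = 2) {
  f0sq <- lo * hi
  width <- hi - lo
  function(f) {
    x <- (f * width) / (f^2 - f0sq)
    r <- 1 / (1 + x^(2 * order))
    r[!is.finite(x)] <- 0
    r
  }
}

# FIR filtfilt response from the tap vector.
resp_fir <- function(b, fs) {
  j <- seq_along(b) - 1
  function(f) {
    H <- exp(-2i * pi * outer(f / fs, j)) %*% b
    as.numeric(Mod(H)^2)
  }
}

# Zero-phase filtering in the frequency domain: reflection padding, then
# multiplication of the spectrum by the product of the given amplitude
# responses (each a function of frequency in Hz).
fft_zero_phase <- function(responses, x, fs, pad = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (is.null(pad)) pad <- min(n - 1L, 2048L)
  left <- 2 * rep(x[1, ], each = pad) - x[seq(pad + 1, 2), , drop = FALSE]
  right <- 2 * rep(x[n, ], each = pad) - x[seq(n - 1, n - pad), , drop = FALSE]
  xp <- rbind(matrix(left, pad), x, matrix(right, pad))
  nfft <- stats::nextn(nrow(xp), c(2, 3, 5))
  xp <- rbind(xp, matrix(0, nfft - nrow(xp), ncol(xp)))
  fgrid <- (seq_len(nfft) - 1) * fs / nfft
  fgrid <- pmin(fgrid, fs - fgrid) # alias to the physical frequency
  mag <- rep(1, nfft)
  for (r in responses) mag <- mag * r(fgrid)
  Y <- stats::mvfft(stats::mvfft(xp) * mag, inverse = TRUE)
  out <- Re(Y[pad + seq_len(n), , drop = FALSE]) / nfft
  if (vec) as.numeric(out) else out
}

#' Notch filter at a line frequency and all higher harmonics
#'
#' Zero-phase forward-backward Butterworth band-stop at `line_freq` and
#' every harmonic below Nyquist.
#'
#' @param recording A recording.
#' @param line_freq Mains frequency in Hz (< Nyquist).
#' @param width Half-width of each stop band in Hz.
#' @return The filtered recording.
#' @export
notch_filter <- function(recording, line_freq = 50, width = 2) {
  stopifnot(inherits(recording, "stn_recording"))
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (line_freq >= nyq) stop("line frequency must be below Nyquist", call. = FALSE)
  harmonics <- seq(line_freq, nyq - width - 0.5, by = line_freq)
  notches <- lapply(harmonics, function(f) {
    resp_bandstop(f - width, f + width, order = 2)
  })
  recording$data[] <- t(fft_zero_phase(notches, t(recording$data), fs))
  recording
}

#' Band-pass filter a recording
#'
#' Zero-phase cascade of a high-pass and a low-pass Butterworth section,
#' applied forward-backward.
#'
#' @param recording A recording.
#' @param lo,hi Band edges in Hz; `hi` must be below Nyquist.
#' @param order Butterworth order of each section.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(recording, lo = 3, hi = 150, order = 4) {
  stopifnot(inherits(recording, "stn_recording"))
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (hi >= nyq) stop("upper band edge must be below Nyquist", call. = FALSE)
  recording$data[] <- t(fft_zero_phase(
    list(resp_bandpass(lo, hi, order)),
    t(recording$data), fs
  ))
  recording
}

#' Divide a recording into fixed-duration epochs
#'
#' @param recording A recording.
#' @param duration Epoch duration in seconds (default 2 s); the trailing
#'   partial epoch is discarded.
#' @return An [new_epochs()] object.
#' @export
make_epochs <- function(recording, duration = 2) {
  stopifnot(inherits(recording, "stn_recording"))
  fs <- recording$sampling_rate
  len <- as.integer(round(duration * fs))
  n <- ncol(recording$data)
  n_epochs <- n %/% len
  if (n_epochs < 1) {
    stop("recording shorter than one epoch", call. = FALSE)
  }
  arr <- array(0, dim = c(n_epochs, nrow(recording$data), len))
  for (e in seq_len(n_epochs)) {
    arr[e, , ] <- recording$data[, (e - 1) * len + seq_len(len)]
  }
  new_epochs(arr, fs, recording$channel_info,
    condition = recording$condition, subject_id = recording$subject_id
  )
}

#' Resample epochs to a lower rate
#'
#' Applies a zero-phase anti-alias FIR low-pass at 80% of the target
#' Nyquist, then decimates. The source rate must be an integer multiple of
#' the target rate.
#'
#' @param epochs An epochs object.
#' @param target_rate Target rate in Hz (500 for spectral/coupling
#'   analysis, 1000 for delay analysis).
#' @return Resampled epochs with `duration * target_rate` samples each.
#' @export
resample_epochs <- function(epochs, target_rate) {
  stopifnot(inherits(epochs, "stn_epochs"))
  fs <- epochs$sampling_rate
  if (target_rate == fs) {
    return(epochs)
  }
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop("sampling rate must be an integer multiple of the target rate",
      call. = FALSE
    )
  }
  factor <- as.integer(round(factor))
  fir <- signal::fir1(64, 0.8 / factor)
  d <- dim(epochs$data)
  len_out <- d[3] %/% factor
  keep <- seq(1, by = factor, length.out = len_out)
  # filter every epoch/channel trace in one matrix pass
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  flat <- fft_zero_phase(list(resp_fir(unclass(fir), fs)), flat, fs)[keep, , drop = FALSE]
  out <- aperm(array(flat, dim = c(len_out, d[1], d[2])), c(2, 3, 1))
  new_epochs(out, target_rate, epochs$channel_info,
    kept_mask = epochs$kept_mask,
    condition = epochs$condition, subject_id = epochs$subject_id
  )
}

#' Reject epochs containing high-amplitude artifacts
#'
#' Automated surrogate for visual artifact marking: an epoch is rejected
#' when its peak-to-peak amplitude z-score (per channel, across epochs)
#' exceeds `z_thresh` on any channel.
#'
#' @param epochs An epochs object.
#' @param z_thresh Rejection threshold (default 4).
#' @return The epochs with `kept_mask` updated and a `rejection_log`
#'   attribute listing rejected epochs.
#' @export
reject_artifact_epochs <- function(epochs, z_thresh = 4) {
  stopifnot(inherits(epochs, "stn_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 2) stop("need at least 2 epochs", call. = FALSE)
  p2p <- apply(epochs$data, c(1, 2), function(x) max(x) - min(x))
  z <- scale(p2p) # per-channel z-score across epochs
  z[is.nan(z)] <- 0 # zero-variance channels cannot reject
  bad <- apply(abs(z) > z_thresh, 1, any)
  if (all(bad)) {
    stop("all epochs rejected; raise z_thresh", call. = FALSE)
  }
  epochs$kept_mask <- epochs$kept_mask & !bad
  epochs$rejection_log <- list(
    z_thresh = z_thresh, rejected = which(bad),
    n_rejected = sum(bad), n_total = d[1]
  )
  epochs
}

#' Remove periodic stimulation artifacts (period-based reconstruction)
#'
#' Estimates the exact stimulation period by maximising the variance
#' explained by a period-phase template, builds a per-sample artifact
#' template by averaging other samples at similar period-phase within a
#' sliding time window, and subtracts it. Recordings whose condition is not
#' "dbs" are returned unchanged. If no periodic artifact is detected (the
#' template explains less than `detect_threshold` of the variance) the
#' recording is likewise returned unchanged, with the decision logged.
#'
#' @param recording A recording with condition "dbs".
#' @param stim_freq Stimulation frequency in Hz.
#' @param window Sliding-window half-width in seconds.
#' @param phase_tol Period-phase tolerance in samples: samples whose phase
#'   differs by no more than this contribute to a template value.
#' @param detect_threshold Minimum fraction of channel variance the
#'   template must explain for removal to proceed.
#' @return The cleaned recording with a `parrm_log` attribute (estimated
#'   period, per-channel explained variance, removal decision).
#' @export
parrm_remove <- function(recording, stim_freq, window = 2,
                         phase_tol = 0.01, detect_threshold = 0.01) {
  stopifnot(inherits(recording, "stn_recording"))
  if (recording$condition != "dbs") {
    return(recording) # guarded no-op off stimulation
  }
  fs <- recording$sampling_rate
  n <- ncol(recording$data)
  p0 <- fs / stim_freq
  # use the channel with the strongest artifact for period estimation
  ref <- which.max(apply(recording$data, 1, function(x) max(abs(diff(x)))))
  x_ref <- recording$data[ref, ]

  period <- estimate_artifact_period(x_ref, p0)
  score <- parrm_period_score(x_ref, period, bin_width = 0.25)
  if (score < detect_threshold) {
    recording$parrm_log <- list(
      removed = FALSE, period = period,
      explained = score, reason = "no periodic artifact detected"
    )
    return(recording)
  }

  w_samp <- as.integer(round(window * fs))
  cleaned <- recording$data
  explained <- numeric(nrow(cleaned))
  for (ch in seq_len(nrow(cleaned))) {
    tmpl <- parrm_template(cleaned[ch, ], period, w_samp, phase_tol)
    explained[ch] <- stats::var(tmpl) / stats::var(cleaned[ch, ])
    cleaned[ch, ] <- cleaned[ch, ] - tmpl
  }
  recording$data <- cleaned
  recording$parrm_log <- list(
    removed = TRUE, period = period, explained = explained,
    stim_freq = stim_freq, window = window, phase_tol = phase_tol
  )
  recording
}

# Fraction of variance explained by the phase-binned mean at a candidate
# period (coarse bins; used for period search and artifact detection).
parrm_period_score <- function(x, period, bin_width = 0.25) {
  n <- length(x)
  phase <- ((seq_len(n) - 1) %% period)
  bins <- floor(phase / bin_width) + 1L
  mu <- rowsum(x, bins) / as.numeric(table(bins))
  tmpl <- mu[match(bins, sort(unique(bins)))]
  stats::var(tmpl) / stats::var(x)
}

# Three-stage grid search with golden-section refinement around fs/f.
estimate_artifact_period <- function(x, p0) {
  score <- function(p) parrm_period_score(x, p, bin_width = 0.25)
  cand <- p0 * (1 + seq(-0.005, 0.005, length.out = 61))
  s <- vapply(cand, score, numeric(1))
  best <- cand[which.max(s)]
  if (which.max(s) %in% c(1L, length(cand))) {
    stop("artifact period estimate did not converge: best candidate at ",
      "grid edge (p = ", signif(best, 8), "); check stim_freq",
      call. = FALSE
    )
  }
  step <- cand[2] - cand[1]
  cand2 <- seq(best - step, best + step, length.out = 81)
  s2 <- vapply(cand2, score, numeric(1))
  best2 <- cand2[which.max(s2)]
  step2 <- cand2[2] - cand2[1]
  opt <- stats::optimize(score,
    interval = c(best2 - step2, best2 + step2),
    maximum = TRUE, tol = p0 * 1e-9
  )
  opt$maximum
}

# Per-sample artifact template. The recording is split into time blocks of
# the window length; within each block (plus half-block margins) samples
# are averaged on a period-phase grid, the grid being widened from
# phase_tol until bins are adequately populated (sampled phases cluster on
# a slowly drifting lattice whenever the stimulation and amplifier clocks
# are near-commensurate, so a fixed fine tolerance can leave bins empty).
# The template is evaluated at each sample's exact phase by linear
# interpolation between bin centres, and consecutive block templates are
# crossfaded for a continuous estimate.
parrm_template <- function(x, period, w_samp, phase_tol, min_members = 16L) {
  n <- length(x)
  phase <- (seq_len(n) - 1) %% period

  block_template <- function(member_idx) {
    ph <- phase[member_idx]
    v <- x[member_idx]
    bw <- phase_tol
    repeat {
      nb <- max(4L, as.integer(ceiling(period / bw)))
      bwa <- period / nb
      bins <- pmin(as.integer(floor(ph / bwa)) + 1L, nb)
      counts <- tabulate(bins, nbins = nb)
      # widen until (nearly) every sample's own bin is well populated;
      # empty bins are irrelevant (phases cluster on a lattice when the
      # clocks are near-commensurate)
      if (stats::quantile(counts[bins], 0.1) >= min_members ||
        bwa >= period / 4) {
        break
      }
      bw <- bw * 2
    }
    sums <- numeric(nb)
    acc <- rowsum(v, bins)
    sums[as.integer(rownames(acc))] <- acc
    mu <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
    centers <- (seq_len(nb) - 0.5) * bwa
    ok <- !is.na(mu)
    # circular padding so interpolation wraps across the period boundary
    cx <- c(centers[ok] - period, centers[ok], centers[ok] + period)
    cy <- rep(mu[ok], 3)
    function(q) stats::approx(cx, cy, xout = q, rule = 2)$y
  }

  n_blocks <- max(1L, as.integer(ceiling(n / w_samp)))
  centers_t <- (seq_len(n_blocks) - 0.5) * w_samp
  tmpl_funs <- lapply(seq_len(n_blocks), function(b) {
    lo <- max(1L, as.integer((b - 1.5) * w_samp))
    hi <- min(n, as.integer((b + 0.5) * w_samp))
    block_template(lo:hi)
  })
  t_all <- seq_len(n)
  b_left <- pmin(pmax(findInterval(t_all, centers_t), 1L), n_blocks)
  b_right <- pmin(b_left + 1L, n_blocks)
  alpha <- ifelse(b_right > b_left,
    (t_all - centers_t[b_left]) / w_samp, 0
  )
  alpha <- pmin(pmax(alpha, 0), 1)
  tmpl <- numeric(n)
  for (b in seq_len(n_blocks)) {
    sel_l <- which(b_left == b)
    if (length(sel_l)) {
      tmpl[sel_l] <- tmpl[sel_l] +
        (1 - alpha[sel_l]) * tmpl_funs[[b]](phase[sel_l])
    }
    sel_r <- which(b_right == b & b_right != b_left)
    if (length(sel_r)) {
      tmpl[sel_r] <- tmpl[sel_r] +
        alpha[sel_r] * tmpl_funs[[b]](phase[sel_r])
    }
  }
  tmpl
}

#' Re-reference to a bipolar montage
#'
#' Each bipolar channel is the difference of two adjacent physical contacts
#' within a site (contacts are adjacent in channel order). Common-mode
#' components, including the recording reference, cancel exactly.
#'
#' @param recording A unipolar recording with at least 2 contacts per site.
#' @return A bipolar recording; channel metadata records the constituent
#'   contacts, and regions are inherited from the first contact of a pair.
#' @export
bipolar_reference <- function(recording) {
  stopifnot(inherits(recording, "stn_recording"))
  ci <- recording$channel_info
  new_rows <- list()
  new_data <- list()
  for (site in unique(ci$site)) {
    idx <- which(ci$site == site & ci$montage == "unipolar")
    if (length(idx) < 2) {
      stop("site '", site, "' has fewer than 2 unipolar contacts", call. = FALSE)
    }
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]
      b <- idx[k + 1]
      new_data[[length(new_data) + 1L]] <-
        recording$data[a, ] - recording$data[b, ]
      row <- ci[a, ]
      row$name <- paste0(ci$name[a], "-", ci$name[b])
      row$montage <- "bipolar"
      row$mni_x <- mean(c(ci$mni_x[a], ci$mni_x[b]))
      row$mni_y <- mean(c(ci$mni_y[a], ci$mni_y[b]))
      row$mni_z <- mean(c(ci$mni_z[a], ci$mni_z[b]))
      row$is_stim_contact <- ci$is_stim_contact[a] || ci$is_stim_contact[b]
      row$anode <- ci$name[a]
      row$cathode <- ci$name[b]
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  ci_out <- do.call(rbind, new_rows)
  rownames(ci_out) <- NULL
  new_recording(do.call(rbind, new_data), recording$sampling_rate, ci_out,
    condition = recording$condition, subject_id = recording$subject_id
  )
}

#' Drop stimulation contacts from a recording
#'
#' Stimulation contacts carry no usable signal during DBS; for OFF-therapy
#' versus ON-DBS comparisons they are dropped from both recordings of a
#' pair (so information content matches), while OFF versus levodopa
#' comparisons retain them.
#'
#' @param recording A recording.
#' @param stim_contact_names Channel names to drop; empty leaves the
#'   recording unchanged.
#' @return The recording without the named channels.
#' @export
exclude_stim_contacts <- function(recording, stim_contact_names) {
  stopifnot(inherits(recording, "stn_recording"))
  if (length(stim_contact_names) == 0) {
    return(recording)
  }
  unknown <- setdiff(stim_contact_names, recording$channel_info$name)
  if (length(unknown)) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- !(recording$channel_info$name %in% stim_contact_names)
  recording$data <- recording$data[keep, , drop = FALSE]
  recording$channel_info <- recording$channel_info[keep, , drop = FALSE]
  rownames(recording$channel_info) <- NULL
  recording
}

#' Bootstrap epoch segments
#'
#' Standardises data length across recordings by resampling kept epochs
#' with replacement into fixed-size segments (default 30 x 2 s = 60 s).
#'
#' @param epochs An epochs object.
#' @param n_segments Number of segments (200 for coupling analysis, 400 for
#'   the delay analysis).
#' @param epochs_per_segment Epochs per segment (default 30).
#' @param seed Integer seed.
#' @return An `stn_segment_set`: list of epoch-index vectors (indices into
#'   the kept epochs), the seed, and the fraction of kept epochs covered.
#' @export
bootstrap_segments <- function(epochs, n_segments = 200,
                               epochs_per_segment = 30, seed = 1L) {
  stopifnot(inherits(epochs, "stn_epochs"))
  kept <- which(epochs$kept_mask)
  if (length(kept) == 0) stop("no kept epochs to sample", call. = FALSE)
  segs <- with_seed(derive_seed(seed, "segments"), {
    lapply(seq_len(n_segments), function(i) {
      kept[sample.int(length(kept), epochs_per_segment, replace = TRUE)]
    })
  })
  coverage <- length(unique(unlist(segs))) / length(kept)
  structure(
    list(
      segments = segs, n_segments = n_segments,
      epochs_per_segment = epochs_per_segment,
      seed = as.integer(seed), coverage = coverage
    ),
    class = "stn_segment_set"
  )
}
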