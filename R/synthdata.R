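# Synthetic recordings, connectome fixtures and cohort tables with known
# ground truth. These generators define the study conditions under which the
# analysis stages are validated: band-limited non-Gaussian oscillatory
# sources, a delayed unidirectional cortex -> STN interaction, 1/f
# background with 50 Hz line noise, and periodic stimulation artifacts.

#' Simulation configuration
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Recording duration in seconds.
#' @param n_cortex_channels,n_stn_channels Channel counts for the cortical
#'   strip and the DBS lead.
#' @param n_sources Number of independent oscillatory source pairs.
#' @param source_band Two-element (lo, hi) band in Hz occupied by the
#'   sources. For bispectral delay estimation the band must admit in-band
#'   frequency triples (hi > 2 * lo), since the bispectrum is only non-zero
#'   where f1, f2 and f1 + f2 all carry signal.
#' @param coupling_delay Cortex -> STN transmission delay in ms; must be an
#'   integer number of samples at `sampling_rate`.
#' @param coupling_gain Gain of the delayed cortical source in the STN
#'   source; 0 decouples the sites.
#' @param innovation_sd Standard deviation of the band-limited innovation
#'   added to the STN source (relative to the unit-variance seed source).
#' @param snr Per-channel signal-to-background ratio in dB.
#' @param line_noise_amplitude Amplitude (microvolts) of the common-mode
#'   50 Hz mains component.
#' @param dbs Optional list with `frequency` (Hz), `pulse_width` (microseconds)
#'   and `amplitude` (microvolts) describing a stimulation artifact train.
#' @param nongaussianity Skewness-control parameter of the exponential
#'   source transform; 0 leaves sources Gaussian.
#' @param source_scale Root-mean-square amplitude (microvolts) given to the
#'   mixed source signal per channel.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(sampling_rate = 4000, duration = 120,
                       n_cortex_channels = 6, n_stn_channels = 8,
                       n_sources = 1,
                       source_band = c(20, 30),
                       coupling_delay = 25, coupling_gain = 1,
                       innovation_sd = 0.3,
                       snr = 10, line_noise_amplitude = 5,
                       dbs = NULL, nongaussianity = 1,
                       source_scale = 20, seed = 1L) {
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (length(source_band) != 2L || source_band[1] <= 0 ||
    source_band[2] <= source_band[1]) {
    stop("source_band must be (lo, hi) with 0 < lo < hi", call. = FALSE)
  }
  if (sampling_rate <= 2 * source_band[2]) {
    stop("source band outside Nyquist: sampling_rate must exceed twice ",
      "the upper band edge",
      call. = FALSE
    )
  }
  if (coupling_delay < 0) stop("coupling_delay must be >= 0", call. = FALSE)
  if (!is.null(dbs)) {
    stopifnot(all(c("frequency", "pulse_width", "amplitude") %in% names(dbs)))
  }
  structure(
    list(
      sampling_rate = sampling_rate, duration = duration,
      n_cortex_channels = n_cortex_channels,
      n_stn_channels = n_stn_channels, n_sources = n_sources,
      source_band = source_band, coupling_delay = coupling_delay,
      coupling_gain = coupling_gain, innovation_sd = innovation_sd,
      snr = snr, line_noise_amplitude = line_noise_amplitude,
      dbs = dbs, nongaussianity = nongaussianity,
      source_scale = source_scale, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Zero-phase Butterworth band-pass used throughout the generators
# (cascaded high-pass and low-pass sections for numerical stability at
# narrow relative bandwidths).
bandpass_zp <- function(x, fs, lo, hi, order = 8) {
  nyq <- fs / 2
  if (hi >= nyq) stop("band outside Nyquist", call. = FALSE)
  fft_zero_phase(list(resp_bandpass(lo, hi, order)), x, fs)
}

# One realisation of a band-limited, optionally skewed, unit-variance
# source. Filter-edge margins are trimmed before each standardisation so
# edge ringing never leaks into the statistics (the exponential transform
# would amplify any edge excursion enormously).
one_source <- function(n, fs, band, nongaussianity) {
  m <- 2000L
  x <- stats::rnorm(n + 4L * m)
  x <- bandpass_zp(x, fs, band[1], band[2])
  x <- x[(m + 1):(length(x) - m)]
  x <- (x - mean(x)) / stats::sd(x)
  if (nongaussianity > 0) {
    # monotone exponential skewing transform, then re-filter to the band
    y <- exp(nongaussianity * x)
    y <- y - mean(y)
    y <- bandpass_zp(y, fs, band[1], band[2])
    y <- y[(m + 1):(length(y) - m)]
    x <- (y - mean(y)) / stats::sd(y)
  } else {
    x <- x[(m + 1):(length(x) - m)]
    x <- (x - mean(x)) / stats::sd(x)
  }
  x
}

#' Simulate band-limited oscillatory sources
#'
#' Sources are band-filtered Gaussian noise; when `nongaussianity > 0` they
#' are passed through a monotone exponential transform and re-filtered,
#' yielding the skewed (non-zero third-order cumulant) statistics that
#' bispectral delay estimation requires.
#'
#' @param config A [sim_config()].
#' @return Matrix of sources x samples, unit variance per source.
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- round(config$duration * config$sampling_rate)
  with_seed(derive_seed(config$seed, "sources"), {
    t(vapply(
      seq_len(config$n_sources),
      function(i) {
        one_source(
          n, config$sampling_rate, config$source_band,
          config$nongaussianity
        )
      },
      numeric(n)
    ))
  })
}

# 1/f^alpha background noise, unit variance.
pink_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  X <- X / (f^(exponent / 2))
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Couple sources and mix into channels
#'
#' The STN-set source is the coupling-gain-scaled cortical source delayed by
#' `coupling_delay` plus an independent band-limited innovation. Both source
#' sets are mixed into their channel sets through random full-rank mixing
#' matrices, then 1/f background noise and common-mode 50 Hz line noise are
#' added at the configured SNR.
#'
#' @param sources Matrix from [simulate_sources()].
#' @param config The [sim_config()] used to generate them.
#' @return List with elements `recording` (an [new_recording()] object) and
#'   `ground_truth` (mixing matrices, true delay, true direction).
#' @export
couple_and_mix <- function(sources, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.matrix(sources)) sources <- matrix(sources, nrow = 1L)
  fs <- config$sampling_rate
  n <- ncol(sources)
  d_samp <- config$coupling_delay * fs / 1000
  if (abs(d_samp - round(d_samp)) > 1e-9) {
    stop(sprintf(
      "coupling_delay must be an integer number of samples; finest representable delay at %g Hz is %g ms",
      fs, 1000 / fs
    ), call. = FALSE)
  }
  d_samp <- as.integer(round(d_samp))

  with_seed(derive_seed(config$seed, "mix"), {
    n_src <- nrow(sources)
    # delayed copy of each cortical source plus independent innovation
    stn_sources <- matrix(0, n_src, n)
    for (i in seq_len(n_src)) {
      shifted <- c(rep(0, d_samp), sources[i, seq_len(n - d_samp)])
      innov <- if (config$innovation_sd > 0) {
        config$innovation_sd *
          one_source(n, fs, config$source_band, config$nongaussianity)
      } else {
        0
      }
      stn_sources[i, ] <- config$coupling_gain * shifted + innov
    }
    if (config$coupling_gain == 0 && config$innovation_sd > 0) {
      # decoupled condition: STN carries only its own independent source
      for (i in seq_len(n_src)) {
        stn_sources[i, ] <- stn_sources[i, ] / stats::sd(stn_sources[i, ])
      }
    }

    mix_c <- matrix(stats::rnorm(config$n_cortex_channels * n_src),
      config$n_cortex_channels, n_src
    )
    mix_s <- matrix(stats::rnorm(config$n_stn_channels * n_src),
      config$n_stn_channels, n_src
    )
    sig_c <- mix_c %*% sources
    sig_s <- mix_s %*% stn_sources
    sig <- rbind(sig_c, sig_s)
    # one common scale factor (source_scale uV rms averaged over channels)
    # so relative mixing weights -- and bipolar derivations -- survive
    rms <- sqrt(mean(sig^2))
    if (rms == 0) rms <- 1
    sig <- sig / rms * config$source_scale
    mix_c <- mix_c / rms * config$source_scale
    mix_s <- mix_s / rms * config$source_scale

    n_ch <- nrow(sig)
    noise_var <- config$source_scale^2 / (10^(config$snr / 10))
    noise <- t(vapply(
      seq_len(n_ch),
      function(i) sqrt(noise_var) * pink_noise(n),
      numeric(n)
    ))
    tt <- seq_len(n) / fs
    line_phase <- stats::runif(1, 0, 2 * pi)
    line_gain <- 1 + 0.1 * stats::rnorm(n_ch)
    line <- outer(
      line_gain,
      sin(2 * pi * 50 * tt + line_phase)
    ) * config$line_noise_amplitude
    data <- sig + noise + line

    ci <- default_channel_info(
      config$n_cortex_channels,
      config$n_stn_channels
    )
    rec <- new_recording(data, fs, ci,
      condition = if (is.null(config$dbs)) "off" else "dbs",
      subject_id = "sim"
    )
    if (!is.null(config$dbs)) {
      rec <- add_dbs_artifact(
        rec, config$dbs$frequency,
        config$dbs$pulse_width, config$dbs$amplitude
      )
    }
    gt <- list(
      mixing_cortex = mix_c, mixing_stn = mix_s,
      true_delay = config$coupling_delay,
      true_direction = if (config$coupling_gain != 0) "cortex->stn" else "none",
      source_band = config$source_band,
      seed = config$seed
    )
    list(recording = rec, ground_truth = gt)
  })
}

# ECoG strip channels plus DBS lead channels with plausible MNI geometry:
# the strip runs posteriorly over sensorimotor cortex, the lead sits in STN.
default_channel_info <- function(n_cortex, n_stn) {
  regions <- rep(c("prefrontal", "motor", "sensory", "parietal"),
    length.out = n_cortex
  )
  # contacts ordered front to back along the strip
  regions <- sort(factor(regions, levels = c("prefrontal", "motor", "sensory", "parietal")))
  cortex <- data.frame(
    name = sprintf("ECOG_%d", seq_len(n_cortex)),
    site = "cortex", montage = "unipolar",
    region = as.character(regions),
    mni_x = 40 + 2 * seq_len(n_cortex),
    mni_y = seq(-2, -2 - 10 * (n_cortex - 1) / max(1, n_cortex - 1) * 5,
      length.out = n_cortex
    ),
    mni_z = 60,
    is_stim_contact = FALSE,
    stringsAsFactors = FALSE
  )
  stn <- data.frame(
    name = sprintf("LFP_%d", seq_len(n_stn)),
    site = "stn", montage = "unipolar", region = "stn",
    mni_x = 12, mni_y = -13, mni_z = seq(-9, -9 + 1.5 * (n_stn - 1),
      length.out = n_stn
    ),
    is_stim_contact = FALSE,
    stringsAsFactors = FALSE
  )
  rbind(cortex, stn)
}

#' Superimpose a periodic stimulation artifact
#'
#' Adds a charge-balanced biphasic rectangular pulse train at the requested
#' frequency to every channel, with channel-specific log-uniform gains. The
#' exact pulse-onset grid is recorded in the returned recording's
#' `dbs_artifact` attribute for oracle use.
#'
#' @param recording A recording.
#' @param frequency Pulse frequency in Hz.
#' @param pulse_width Pulse phase width in microseconds.
#' @param amplitude Base amplitude in microvolts; 0 leaves the recording
#'   unchanged.
#' @param seed Seed for the channel gains.
#' @return The recording with artifact added and condition set to "dbs".
#' @export
add_dbs_artifact <- function(recording, frequency, pulse_width, amplitude,
                             seed = 1L) {
  stopifnot(inherits(recording, "stn_recording"))
  fs <- recording$sampling_rate
  if (frequency >= fs / 2) {
    stop("stimulation frequency must be below Nyquist", call. = FALSE)
  }
  if (amplitude == 0) {
    return(recording)
  }
  n <- ncol(recording$data)
  period <- fs / frequency # samples, possibly fractional
  # continuous-phase biphasic kernel: the stimulator is periodic in
  # continuous time, so each sample's value is a pure function of its
  # period-phase. Pulses narrower than one sample are smeared to one
  # sample width, as the acquisition anti-alias filtering would do.
  w <- max(pulse_width * 1e-6 * fs, 1)
  phase <- (seq_len(n) - 1) %% period
  train <- ifelse(phase < 2 * w, sin(pi * phase / w), 0)
  with_seed(derive_seed(seed, "dbs_gain"), {
    gains <- exp(stats::runif(nrow(recording$data), log(0.5), log(2)))
  })
  recording$data <- recording$data + amplitude * outer(gains, train)
  recording$condition <- "dbs"
  recording$dbs_artifact <- list(
    frequency = frequency, period_samples = period,
    pulse_width_us = pulse_width, amplitude = amplitude,
    gains = gains, train = train
  )
  recording
}

#' Simulate a stable vector autoregressive process
#'
#' Analytic test bed for the spectral Granger-causality estimators: the
#' generating coefficients admit a closed-form spectrum and Granger scores.
#'
#' @param coefficient_matrices List of m x m lag coefficient matrices
#'   (lag 1 first).
#' @param innovation_covariance m x m positive-definite matrix.
#' @param n_samples Realisation length.
#' @param seed Integer seed.
#' @param burn_in Samples discarded at the start.
#' @return Matrix channels x samples.
#' @export
simulate_var <- function(coefficient_matrices, innovation_covariance,
                         n_samples, seed = 1L, burn_in = 1000L) {
  A <- coefficient_matrices
  m <- nrow(A[[1]])
  p <- length(A)
  if (var_spectral_radius(A) >= 1) {
    stop("unstable VAR: companion-matrix spectral radius >= 1", call. = FALSE)
  }
  L <- t(chol(innovation_covariance))
  with_seed(derive_seed(seed, "var"), {
    ntot <- n_samples + burn_in
    e <- L %*% matrix(stats::rnorm(m * ntot), m, ntot)
    x <- matrix(0, m, ntot)
    for (t in seq(p + 1, ntot)) {
      acc <- e[, t]
      for (k in seq_len(p)) acc <- acc + A[[k]] %*% x[, t - k]
      x[, t] <- acc
    }
    x[, burn_in + seq_len(n_samples), drop = FALSE]
  })
}

var_spectral_radius <- function(A) {
  m <- nrow(A[[1]])
  p <- length(A)
  comp <- matrix(0, m * p, m * p)
  comp[seq_len(m), ] <- do.call(cbind, A)
  if (p > 1) {
    comp[m + seq_len(m * (p - 1)), seq_len(m * (p - 1))] <-
      diag(m * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a streamline atlas with known connection counts
#'
#' Builds a synthetic fiber atlas in which, for each requested
#' (cortex contact, STN contact) pair, exactly the requested number of
#' streamlines pass within 5 mm of the cortex contact and 3 mm of the STN
#' contact, plus decoy streamlines that violate at least one radius.
#'
#' @param contact_geometry List with `ecog` and `stn`: matrices of MNI mm
#'   coordinates (rows = contacts).
#' @param pair_counts Integer matrix (n_ecog x n_stn) of requested counts.
#' @param seed Integer seed.
#' @param n_decoys Number of non-qualifying streamlines added.
#' @param r_ecog,r_stn Inclusion radii in mm.
#' @return A `fiber_atlas`: list of polyline matrices (points x 3), with the
#'   requested counts attached as `ground_truth`.
#' @export
simulate_fiber_atlas <- function(contact_geometry, pair_counts, seed = 1L,
                                 n_decoys = 20L, r_ecog = 5, r_stn = 3) {
  ecog <- as.matrix(contact_geometry$ecog)
  stn <- as.matrix(contact_geometry$stn)
  pair_counts <- as.matrix(pair_counts)
  if (any(pair_counts < 0)) stop("requested counts must be >= 0", call. = FALSE)
  stopifnot(nrow(pair_counts) == nrow(ecog), ncol(pair_counts) == nrow(stn))

  qualifies <- function(line, e_xyz, s_xyz) {
    de <- sqrt(colSums((t(line) - e_xyz)^2))
    ds <- sqrt(colSums((t(line) - s_xyz)^2))
    min(de) <= r_ecog && min(ds) <= r_stn
  }
  qual_matrix <- function(line) {
    outer(
      seq_len(nrow(ecog)), seq_len(nrow(stn)),
      Vectorize(function(i, j) qualifies(line, ecog[i, ], stn[j, ]))
    )
  }

  with_seed(derive_seed(seed, "fibers"), {
    lines <- list()
    for (i in seq_len(nrow(ecog))) {
      for (j in seq_len(nrow(stn))) {
        made <- 0L
        tries <- 0L
        while (made < pair_counts[i, j]) {
          tries <- tries + 1L
          if (tries > 500L) {
            stop("geometrically unsatisfiable fiber request for pair (",
              i, ",", j, ")",
              call. = FALSE
            )
          }
          a <- ecog[i, ] + stats::runif(3, -1, 1) * r_ecog / 2.5
          b <- stn[j, ] + stats::runif(3, -1, 1) * r_stn / 2.5
          npts <- 10L
          w <- seq(0, 1, length.out = npts)
          line <- outer(1 - w, a) + outer(w, b) +
            matrix(stats::rnorm(npts * 3, sd = 0.3), npts, 3)
          line[1, ] <- a
          line[npts, ] <- b
          qm <- qual_matrix(line)
          target <- matrix(FALSE, nrow(ecog), nrow(stn))
          target[i, j] <- TRUE
          # a streamline must qualify for its designated pair and, for any
          # other pair, only via the same contacts' shared proximity
          if (identical(qm, target)) {
            lines[[length(lines) + 1L]] <- line
            made <- made + 1L
          }
        }
      }
    }
    # decoys: pass near one cortex contact but miss every STN contact
    added <- 0L
    tries <- 0L
    while (added < n_decoys) {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop("cannot place decoy streamlines: contacts too close to the ",
          "combined radii",
          call. = FALSE
        )
      }
      i <- sample.int(nrow(ecog), 1)
      a <- ecog[i, ] + stats::runif(3, -1, 1) * r_ecog / 2.5
      b <- a + c(
        stats::runif(1, 10, 30), stats::runif(1, 10, 30),
        stats::runif(1, 10, 30)
      )
      npts <- 8L
      w <- seq(0, 1, length.out = npts)
      line <- outer(1 - w, a) + outer(w, b)
      ds_all <- apply(stn, 1, function(s) {
        min(sqrt(colSums((t(line) - s)^2)))
      })
      if (all(ds_all > r_stn + 0.5)) {
        lines[[length(lines) + 1L]] <- line
        added <- added + 1L
      }
    }
    structure(
      list(
        streamlines = lines,
        ground_truth = list(
          pair_counts = pair_counts, r_ecog = r_ecog,
          r_stn = r_stn, ecog = ecog, stn = stn
        )
      ),
      class = "fiber_atlas"
    )
  })
}

#' @export
print.fiber_atlas <- function(x, ...) {
  cat(sprintf(
    "<fiber_atlas> %d streamlines, %d x %d contact pairs\n",
    length(x$streamlines), nrow(x$ground_truth$pair_counts),
    ncol(x$ground_truth$pair_counts)
  ))
  invisible(x)
}

#' Simulate a multi-subject cohort table with known mixed-model structure
#'
#' Generates observations
#' `response = b0 + b_pattern * pattern + b_medication * medication +
#'  u_subject + noise` with Gaussian random intercepts, for validating the
#' mixed-effects linkage of coupling patterns to connectomic measures.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_obs_per_subject Observations per subject (split over the two
#'   medication states).
#' @param true_betas Numeric vector `c(intercept, pattern, medication)`.
#' @param random_intercept_sd,residual_sd Standard deviations (>= 0).
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `pattern`, `medication`,
#'   `response`; the generating parameters are attached as the
#'   `ground_truth` attribute.
#' @export
simulate_lme_cohort <- function(n_subjects = 18, n_obs_per_subject = 10,
                                true_betas = c(0, 4, 0.5),
                                random_intercept_sd = 1, residual_sd = 1,
                                seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (random_intercept_sd < 0 || residual_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  stopifnot(length(true_betas) == 3L)
  with_seed(derive_seed(seed, "cohort"), {
    u <- stats::rnorm(n_subjects, sd = random_intercept_sd)
    tab <- do.call(rbind, lapply(seq_len(n_subjects), function(s) {
      pattern <- stats::rnorm(n_obs_per_subject)
      medication <- rep_len(c(0, 1), n_obs_per_subject)
      response <- true_betas[1] + true_betas[2] * pattern +
        true_betas[3] * medication + u[s] +
        stats::rnorm(n_obs_per_subject, sd = residual_sd)
      data.frame(
        subject = sprintf("S%02d", s), pattern = pattern,
        medication = medication, response = response,
        stringsAsFactors = FALSE
      )
    }))
    attr(tab, "ground_truth") <- list(
      true_betas = true_betas,
      random_intercept_sd = random_intercept_sd,
      residual_sd = residual_sd, seed = seed
    )
    tab
  })
}
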