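# Frequency-resolved undirected and directed coupling between cortex and
# STN channel sets: multitaper cross-spectra, imaginary coherency (bivariate
# grand average and maximised multivariate with spatial patterns), and
# multivariate time-reversed spectral Granger causality.

#' Multitaper cross-spectral density
#'
#' Taper- and epoch-averaged cross-spectra between all channels, Hermitian
#' per frequency.
#'
#' @param epochs An epochs object (>= 2 channels).
#' @param bandwidth Full multitaper smoothing bandwidth in Hz.
#' @param epoch_indices Optional indices (into the kept epochs) defining a
#'   bootstrap segment; `NULL` uses all kept epochs.
#' @return An `stn_csd`: `freqs` (Hz) and `matrices` (channels x channels x
#'   frequency complex array, density units).
#' @export
csd_multitaper <- function(epochs, bandwidth = 5, epoch_indices = NULL) {
  tensor <- csd_epoch_tensor(epochs, bandwidth)
  csd_from_tensor(tensor, epoch_indices)
}

# Per-epoch CSD tensor [ch, ch, freq, epoch]; computed once and reused
# across bootstrap segments.
csd_epoch_tensor <- function(epochs, bandwidth = 5) {
  stopifnot(inherits(epochs, "stn_epochs"))
  if (dim(epochs$data)[2] < 2) {
    stop("coupling requires at least two channels", call. = FALSE)
  }
  tf <- tapered_fft(epochs, bandwidth)
  co <- tf$coeffs # [freq, taper, epoch, channel]
  d <- dim(co)
  nf <- d[1]
  n_ch <- d[4]
  out <- array(0i, dim = c(n_ch, n_ch, nf, d[3]))
  i_left <- rep(seq_len(n_ch), times = n_ch)
  i_right <- rep(seq_len(n_ch), each = n_ch)
  for (e in seq_len(d[3])) {
    acc <- matrix(0i, nf, n_ch * n_ch)
    for (j in seq_len(d[2])) {
      X <- matrix(co[, j, e, ], nrow = nf) # freq x channel
      acc <- acc + X[, i_left, drop = FALSE] * Conj(X[, i_right, drop = FALSE])
    }
    # acc columns are (i, j) pairs in column-major (i fastest) order
    out[, , , e] <- aperm(array(acc, dim = c(nf, n_ch, n_ch)), c(2, 3, 1)) /
      (d[2] * tf$fs)
  }
  # one-sided density folding (interior bins carry both half-spectra)
  interior <- seq(2, nf - if (tf$n_samples %% 2 == 0) 1 else 0)
  out[, , interior, ] <- 2 * out[, , interior, , drop = FALSE]
  structure(
    list(
      tensor = out, freqs = tf$freqs, fs = tf$fs,
      n_samples = tf$n_samples,
      channel_info = epochs$channel_info, bandwidth = bandwidth
    ),
    class = "stn_csd_tensor"
  )
}

# Average a per-epoch CSD tensor over (a subset of) epochs.
csd_from_tensor <- function(tensor, epoch_indices = NULL) {
  stopifnot(inherits(tensor, "stn_csd_tensor"))
  idx <- epoch_indices %||% seq_len(dim(tensor$tensor)[4])
  d <- dim(tensor$tensor)
  flat <- matrix(tensor$tensor, nrow = d[1] * d[2] * d[3])
  avg <- flat[, idx, drop = FALSE] %*% matrix(1 / length(idx), length(idx), 1)
  structure(
    list(
      freqs = tensor$freqs,
      matrices = array(avg, dim = d[1:3]),
      fs = tensor$fs, n_samples = tensor$n_samples,
      channel_info = tensor$channel_info,
      n_epochs = length(idx), bandwidth = tensor$bandwidth
    ),
    class = "stn_csd"
  )
}

#' @export
print.stn_csd <- function(x, ...) {
  cat(sprintf(
    "<stn_csd> %d channels x %d frequency bins (%.3g-%.3g Hz), %d epochs\n",
    dim(x$matrices)[1], length(x$freqs), min(x$freqs), max(x$freqs),
    x$n_epochs
  ))
  invisible(x)
}

new_coupling_spectrum <- function(freqs, values, method, segment_count = 1L,
                                  ...) {
  structure(
    c(
      list(
        freqs = freqs, values = values, method = method,
        segment_count = segment_count
      ),
      list(...)
    ),
    class = "stn_coupling_spectrum"
  )
}

#' Grand-average imaginary coherency
#'
#' Coherency `C_ij(f) = S_ij / sqrt(S_ii S_jj)`; the absolute imaginary
#' part is taken per seed-target pair and averaged over all pairs. Being
#' blind to zero-lag interactions, the measure is immune to spurious
#' coupling from volume conduction and shared references.
#'
#' @param csd An `stn_csd`.
#' @param seed_idx,target_idx Channel indices of the two sets.
#' @param abs_per_pair Take the absolute value per pair before averaging
#'   (default); otherwise average signed values then take the absolute.
#' @return An `stn_coupling_spectrum` with method "imcoh", values in [0, 1].
#' @export
imcoh_grand_average <- function(csd, seed_idx, target_idx,
                                abs_per_pair = TRUE) {
  stopifnot(inherits(csd, "stn_csd"), length(seed_idx) >= 1, length(target_idx) >= 1)
  nf <- length(csd$freqs)
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    S <- csd$matrices[, , f]
    p <- Re(diag(S))
    if (any(p[c(seed_idx, target_idx)] <= 0)) {
      stop("zero diagonal power in CSD", call. = FALSE)
    }
    C <- S[seed_idx, target_idx, drop = FALSE] /
      sqrt(outer(p[seed_idx], p[target_idx]))
    vals[f] <- if (abs_per_pair) mean(abs(Im(C))) else abs(mean(Im(C)))
  }
  new_coupling_spectrum(csd$freqs, vals, "imcoh",
    seed_idx = seed_idx, target_idx = target_idx
  )
}

# Inverse principal square root of a Hermitian positive (semi)definite
# matrix, ridge-regularised when near-singular.
inv_sqrt_herm <- function(M, ridge = 1e-8) {
  M <- (M + Conj(t(M))) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- Re(e$values)
  ridged <- FALSE
  if (min(lam) < max(lam) * 1e-12) {
    lam <- lam + ridge * sum(lam) / length(lam)
    ridged <- TRUE
  }
  list(
    value = e$vectors %*% diag(1 / sqrt(lam), length(lam)) %*% Conj(t(e$vectors)),
    ridged = ridged
  )
}

#' Maximised imaginary coherency (MIC)
#'
#' Multivariate extension of the imaginary part of coherency: per
#' frequency, the seed and target blocks are whitened by the inverse
#' square roots of their real parts, and the largest singular value of the
#' imaginary part of the whitened cross-block is the maximised coupling.
#' Singular vectors are back-transformed to spatial filters, and spatial
#' patterns are computed as the real CSD block times the filter, absolute
#' values taken and Z-scored across channels.
#'
#' @param csd An `stn_csd` (typically of rank-normalised components).
#' @param seed_idx,target_idx Channel indices of the seed (cortex) and
#'   target (STN) sets.
#' @param ridge Relative ridge for near-singular real blocks.
#' @param seed_projection,target_projection Optional channels x components
#'   projections (from [reduce_rank()]) used to back-map patterns from
#'   component space to the physical contacts before Z-scoring.
#' @return An `stn_coupling_spectrum` with method "mic", plus
#'   `seed_patterns_z` and `target_patterns_z` (channels x frequency).
#' @export
mic <- function(csd, seed_idx, target_idx, ridge = 1e-8,
                seed_projection = NULL, target_projection = NULL) {
  stopifnot(inherits(csd, "stn_csd"))
  nf <- length(csd$freqs)
  vals <- numeric(nf)
  n_sp <- if (is.null(seed_projection)) length(seed_idx) else nrow(seed_projection)
  n_tp <- if (is.null(target_projection)) length(target_idx) else nrow(target_projection)
  sp <- matrix(0, n_sp, nf)
  tp <- matrix(0, n_tp, nf)
  ridged_any <- FALSE
  for (f in seq_len(nf)) {
    S <- csd$matrices[, , f]
    Saa <- Re(S[seed_idx, seed_idx, drop = FALSE])
    Sbb <- Re(S[target_idx, target_idx, drop = FALSE])
    Sab <- S[seed_idx, target_idx, drop = FALSE]
    wa <- inv_sqrt_herm(Saa, ridge)
    wb <- inv_sqrt_herm(Sbb, ridge)
    ridged_any <- ridged_any || wa$ridged || wb$ridged
    D <- Im(Re(wa$value) %*% Sab %*% Re(wb$value))
    sv <- svd(D)
    vals[f] <- sv$d[1]
    alpha <- Re(wa$value) %*% sv$u[, 1]
    beta <- Re(wb$value) %*% sv$v[, 1]
    if (alpha[which.max(abs(alpha))] < 0) {
      alpha <- -alpha
      beta <- -beta
    }
    pa <- Saa %*% alpha
    pb <- Sbb %*% beta
    if (!is.null(seed_projection)) pa <- seed_projection %*% pa
    if (!is.null(target_projection)) pb <- target_projection %*% pb
    pa <- abs(pa)
    pb <- abs(pb)
    zsc <- function(p) {
      s <- stats::sd(p)
      if (length(p) > 1 && is.finite(s) && s > 0) (p - mean(p)) / s else p * 0
    }
    sp[, f] <- zsc(pa)
    tp[, f] <- zsc(pb)
  }
  new_coupling_spectrum(csd$freqs, vals, "mic",
    seed_patterns_z = sp, target_patterns_z = tp,
    seed_idx = seed_idx, target_idx = target_idx, ridged = ridged_any
  )
}

# Autocovariance sequence R(0..max_lag) from a one-sided CSD by inverse
# Fourier transform over the full (two-sided) frequency grid.
csd_to_autocov <- function(csd, max_lag) {
  d <- dim(csd$matrices)
  nf <- d[3]
  n_fft <- 2L * (nf - 1L)
  if (max_lag >= n_fft) stop("max_lag too large for CSD grid", call. = FALSE)
  # undo the one-sided doubling to recover the two-sided density
  S1 <- csd$matrices
  interior <- seq(2, nf - if (csd$n_samples %% 2 == 0) 1 else 0)
  S1[, , interior] <- S1[, , interior, drop = FALSE] / 2
  two <- array(0i, dim = c(d[1], d[2], n_fft))
  two[, , seq_len(nf)] <- S1
  two[, , nf + seq_len(nf - 2L)] <- Conj(S1[, , seq(nf - 1L, 2L)])
  df <- csd$freqs[2] - csd$freqs[1]
  flat <- matrix(two, nrow = d[1] * d[2]) # rows: matrix entries, cols: freq
  ph <- exp(2i * pi * outer(seq_len(n_fft) - 1, 0:max_lag) / n_fft)
  R <- Re(array(flat %*% ph, dim = c(d[1], d[2], max_lag + 1L))) * df
  R
}

# Whittle's multivariate Levinson recursion: VAR coefficients from an
# autocovariance sequence R[, , 1:(p+1)] with R[, , 1] = lag 0.
whittle_lwr <- function(R, p) {
  m <- dim(R)[1]
  Rl <- function(k) {
    if (k >= 0) R[, , k + 1L] else t(R[, , -k + 1L])
  }
  A <- list() # forward coefficients
  B <- list() # backward coefficients
  sig_f <- Rl(0)
  sig_b <- Rl(0)
  for (n in 0:(p - 1L)) {
    delta <- Rl(n + 1L)
    if (n > 0) {
      for (k in seq_len(n)) delta <- delta - A[[k]] %*% Rl(n + 1L - k)
    }
    kf <- delta %*% solve(sig_b)
    kb <- t(delta) %*% solve(sig_f)
    A_new <- vector("list", n + 1L)
    B_new <- vector("list", n + 1L)
    if (n > 0) {
      for (k in seq_len(n)) {
        A_new[[k]] <- A[[k]] - kf %*% B[[n + 1L - k]]
        B_new[[k]] <- B[[k]] - kb %*% A[[n + 1L - k]]
      }
    }
    A_new[[n + 1L]] <- kf
    B_new[[n + 1L]] <- kb
    A <- A_new
    B <- B_new
    sig_f <- sig_f - kf %*% t(delta)
    sig_b <- sig_b - kb %*% delta
    sig_f <- (sig_f + t(sig_f)) / 2
    sig_b <- (sig_b + t(sig_b)) / 2
  }
  if (any(!is.finite(sig_f)) || min(eigen(sig_f, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("ill-conditioned autocovariance recursion: residual covariance ",
      "not positive definite (condition of R(0): ",
      signif(kappa(R[, , 1]), 3), ")",
      call. = FALSE
    )
  }
  list(A = A, Sigma = sig_f)
}

#' Fit a vector autoregressive model from a cross-spectral density
#'
#' The autocovariance sequence is obtained by inverse Fourier transform of
#' the CSD and the VAR solved by Whittle's Levinson-type recursion.
#'
#' @param csd An `stn_csd` on a full frequency grid.
#' @param order VAR model order (default 60, chosen to avoid excessive
#'   smoothing of Granger scores across frequencies).
#' @return List with `A` (list of lag coefficient matrices), `Sigma`
#'   (innovation covariance), `order`, `fs`.
#' @export
var_from_csd <- function(csd, order = 60) {
  stopifnot(inherits(csd, "stn_csd"))
  R <- csd_to_autocov(csd, order)
  fit <- whittle_lwr(R, order)
  list(A = fit$A, Sigma = fit$Sigma, order = order, fs = csd$fs)
}

# Frequency-resolved multivariate Granger causality from a fitted VAR:
# GC (a -> b) via the transfer function and partialised innovation
# covariance (full-model formulation).
spectral_gc <- function(fit, a_idx, b_idx, freqs) {
  spectral_gc_pair(fit, a_idx, b_idx, freqs)$ab
}

# Both directions in one pass (the transfer function is shared).
spectral_gc_pair <- function(fit, a_idx, b_idx, freqs) {
  m <- nrow(fit$Sigma)
  p <- length(fit$A)
  Sig <- fit$Sigma
  cond_cov <- function(i_idx, j_idx) {
    Sij <- Sig[i_idx, j_idx, drop = FALSE]
    Sig[i_idx, i_idx, drop = FALSE] -
      Sij %*% solve(Sig[j_idx, j_idx, drop = FALSE]) %*% t(Sij)
  }
  Sig_a_cond <- cond_cov(a_idx, b_idx)
  Sig_b_cond <- cond_cov(b_idx, a_idx)
  gc_ab <- numeric(length(freqs))
  gc_ba <- numeric(length(freqs))
  one_dir <- function(H, from_idx, to_idx, Sig_from_cond) {
    Ht <- H[to_idx, , drop = FALSE]
    S_to <- Ht %*% Sig %*% Conj(t(Ht))
    H_tf <- H[to_idx, from_idx, drop = FALSE]
    S_intr <- S_to - H_tf %*% Sig_from_cond %*% Conj(t(H_tf))
    num <- det_herm(S_to)
    den <- det_herm(S_intr)
    if (num > 0 && den > 0) log(num / den) else 0
  }
  for (i in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[i] * seq_len(p) / fit$fs)
    Af <- diag(m) + 0i
    for (k in seq_len(p)) Af <- Af - fit$A[[k]] * z[k]
    H <- solve(Af)
    gc_ab[i] <- one_dir(H, a_idx, b_idx, Sig_a_cond)
    gc_ba[i] <- one_dir(H, b_idx, a_idx, Sig_b_cond)
  }
  list(ab = gc_ab, ba = gc_ba)
}

det_herm <- function(M) {
  if (nrow(M) == 1L) {
    return(Re(M[1, 1]))
  }
  Re(prod(eigen((M + Conj(t(M))) / 2, only.values = TRUE)$values))
}

#' Time-reversed multivariate spectral Granger causality
#'
#' Net Granger scores (seed-to-target minus target-to-seed) are computed
#' from a VAR fitted to the CSD's autocovariance sequence; the same net
#' scores on time-reversed data (transposed autocovariance sequence) are
#' subtracted, suppressing spurious connectivity from non-causal signal
#' asymmetries. Positive values mean the seed (cortex) drives the target
#' (STN).
#'
#' @param csd An `stn_csd`.
#' @param seed_idx,target_idx Channel index sets.
#' @param order VAR model order (default 60).
#' @param freq_range Optional `c(lo, hi)` restriction of the output grid.
#' @return An `stn_coupling_spectrum` with method "trgc"; the forward net
#'   Granger spectrum is attached as `net`.
#' @export
trgc <- function(csd, seed_idx, target_idx, order = 60, freq_range = NULL) {
  stopifnot(inherits(csd, "stn_csd"))
  R <- csd_to_autocov(csd, order)
  freqs <- csd$freqs
  if (!is.null(freq_range)) {
    keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
    freqs <- freqs[keep]
  }
  fit <- whittle_lwr(R, order)
  fit$fs <- csd$fs
  pair <- spectral_gc_pair(fit, seed_idx, target_idx, freqs)
  gc_fwd <- pair$ab - pair$ba
  # time reversal: transpose each autocovariance matrix
  R_rev <- R
  for (k in seq_len(dim(R)[3])) R_rev[, , k] <- t(R[, , k])
  fit_rev <- whittle_lwr(R_rev, order)
  fit_rev$fs <- csd$fs
  pair_rev <- spectral_gc_pair(fit_rev, seed_idx, target_idx, freqs)
  gc_rev <- pair_rev$ab - pair_rev$ba
  new_coupling_spectrum(freqs, gc_fwd - gc_rev, "trgc",
    net = gc_fwd, net_reversed = gc_rev,
    seed_idx = seed_idx, target_idx = target_idx, order = order
  )
}

#' Average coupling spectra over bootstrap segments
#'
#' @param spectra List of `stn_coupling_spectrum` objects with identical
#'   frequency grids and method.
#' @return Element-wise mean spectrum; `segment_count` records the number
#'   averaged, and any spatial patterns are averaged too.
#' @export
average_segments <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$freqs
  m0 <- spectra[[1]]$method
  for (s in spectra) {
    if (!isTRUE(all.equal(s$freqs, f0)) || s$method != m0) {
      stop("mismatched frequency grids or methods", call. = FALSE)
    }
  }
  out <- spectra[[1]]
  out$values <- Reduce(`+`, lapply(spectra, `[[`, "values")) / length(spectra)
  for (field in c("seed_patterns_z", "target_patterns_z", "net", "net_reversed")) {
    if (!is.null(spectra[[1]][[field]])) {
      out[[field]] <- Reduce(`+`, lapply(spectra, `[[`, field)) / length(spectra)
    }
  }
  out$segment_count <- length(spectra)
  out
}
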