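# Discrete prolate spheroidal (Slepian) tapers.
#
# Computed from the well-conditioned symmetric tridiagonal formulation:
# the k-th Slepian sequence is the eigenvector of the tridiagonal matrix
# with diagonal ((N-1-2t)/2)^2 cos(2*pi*W) and off-diagonal t(N-t)/2,
# ordered by decreasing eigenvalue. Tapers are normalised to unit energy
# and sign-fixed so that symmetric tapers have positive mean.

.taper_cache <- new.env(parent = emptyenv())

#' Slepian (DPSS) tapers
#'
#' @param n Taper length in samples.
#' @param nw Time half-bandwidth product (N * W, W in cycles/sample).
#' @param k Number of tapers (defaults to `2 * nw - 1`).
#' @return An `n` x `k` matrix of unit-energy tapers.
#' @keywords internal
dpss_tapers <- function(n, nw, k = max(1L, floor(2 * nw) - 1L)) {
  stopifnot_scalar(n, "n", positive = TRUE)
  stopifnot_scalar(nw, "nw", positive = TRUE)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("invalid number of tapers", call. = FALSE)
  key <- sprintf("n%d_nw%g_k%d", n, nw, k)
  hit <- .taper_cache[[key]]
  if (!is.null(hit)) return(hit)

  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t[-1]) * (n - t[-1]) / 2
  # dense symmetric tridiagonal; n <= a few thousand in practice
  A <- diag(diag_main)
  idx <- seq_len(n - 1)
  A[cbind(idx, idx + 1)] <- diag_off
  A[cbind(idx + 1, idx)] <- diag_off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy and deterministic sign convention
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {
      # antisymmetric tapers: fix sign by the leading lobe
      if (tap[which.max(abs(tap[, j])), j] < 0) tap[, j] <- -tap[, j]
    }
  }
  .taper_cache[[key]] <- tap
  tap
}

# Taper count for a full smoothing bandwidth (Hz) and epoch duration (s):
# half-bandwidth W = bandwidth/2, NW = T*W, K = 2*NW - 1.
multitaper_params <- function(n_samples, fs, bandwidth) {
  duration <- n_samples / fs
  nw <- duration * bandwidth / 2
  k <- max(1L, floor(2 * nw) - 1L)
  if (nw < 1) {
    stop(sprintf(
      "multitaper bandwidth %g Hz incompatible with %.3g s epochs (no valid taper)",
      bandwidth, duration
    ), call. = FALSE)
  }
  list(nw = nw, k = k)
}
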