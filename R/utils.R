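# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed and a stage label, staying below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Power ratio in decibels.
db <- function(p_num, p_den) 10 * log10(p_num / p_den)

# Band power of a signal from its periodogram (rectangular window), used by
# tests and contract checks; `band` in Hz, inclusive.
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  pw <- Mod(X)^2 / n^2
  freqs <- (seq_len(n) - 1) * fs / n
  # include the mirrored negative-frequency bins directly
  sel <- (freqs >= band[1] & freqs <= band[2]) |
    (freqs >= fs - band[2] & freqs <= fs - band[1])
  sum(pw[sel])
}

sample_skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / (mean(x^2)^1.5)
}
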