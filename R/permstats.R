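# Non-parametric paired permutation tests with cluster correction.

#' Paired permutation test
#'
#' Tests a paired difference with the difference in means as the test
#' statistic. The null is built by independent per-pair sign flips of the
#' condition assignment; when the full 2^n flip set is no larger than
#' `n_perm` it is enumerated exactly, otherwise Monte Carlo sampling with
#' the +1-corrected estimator `p = (1 + #{|perm| >= |obs|}) / (1 + n_perm)`
#' is used (one-sided tests drop the absolute values).
#'
#' @param values_a,values_b Equal-length paired samples.
#' @param n_perm Number of permutations (default 100000).
#' @param sidedness "two" or "one" (one-sided tests `mean(a - b) > 0`).
#' @param seed Integer seed.
#' @return An `stn_permutation_result`.
#' @export
paired_permutation <- function(values_a, values_b, n_perm = 100000,
                               sidedness = c("two", "one"), seed = 1L) {
  sidedness <- match.arg(sidedness)
  if (length(values_a) != length(values_b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- values_a - values_b
  obs <- mean(d)
  exact <- 2^n <= n_perm
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- as.vector(signs %*% d) / n
    p <- if (sidedness == "two") {
      mean(abs(stats) >= abs(obs) - 1e-12)
    } else {
      mean(stats >= obs - 1e-12)
    }
    n_used <- nrow(signs)
  } else {
    stats <- with_seed(derive_seed(seed, "perm"), {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.vector(signs %*% d) / n
    })
    p <- if (sidedness == "two") {
      (1 + sum(abs(stats) >= abs(obs))) / (1 + n_perm)
    } else {
      (1 + sum(stats >= obs)) / (1 + n_perm)
    }
    n_used <- n_perm
  }
  structure(
    list(
      observed_stat = obs, p_value = p, n_permutations = n_used,
      sidedness = sidedness, exact = exact, clusters = NULL
    ),
    class = "stn_permutation_result"
  )
}

#' Cluster-corrected permutation test across bins
#'
#' Per-bin paired permutation statistics are thresholded at the pointwise
#' permutation alpha quantile; contiguous supra-threshold bins of common
#' sign form clusters scored by their summed statistic, and cluster
#' p-values come from the permutation null of the maximum absolute cluster
#' mass.
#'
#' @param binwise_a,binwise_b Matrices (pairs x bins) of paired per-bin
#'   values on a shared grid.
#' @param n_perm Number of permutations.
#' @param alpha Cluster-forming (pointwise) alpha level.
#' @param sidedness "two" or "one".
#' @param seed Integer seed.
#' @return An `stn_permutation_result`; `clusters` lists bin ranges,
#'   masses and cluster p-values, and `bin_stats` the observed per-bin
#'   statistics.
#' @export
cluster_permutation <- function(binwise_a, binwise_b, n_perm = 100000,
                                alpha = 0.05, sidedness = c("two", "one"),
                                seed = 1L) {
  sidedness <- match.arg(sidedness)
  binwise_a <- as.matrix(binwise_a)
  binwise_b <- as.matrix(binwise_b)
  stopifnot(all(dim(binwise_a) == dim(binwise_b)))
  n <- nrow(binwise_a)
  nb <- ncol(binwise_a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  if (nb < 2) {
    res <- paired_permutation(binwise_a[, 1], binwise_b[, 1],
      n_perm = n_perm, sidedness = sidedness, seed = seed
    )
    return(res)
  }
  D <- binwise_a - binwise_b
  obs <- colMeans(D)

  perm_stats <- with_seed(derive_seed(seed, "cluster_perm"), {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    (signs %*% D) / n # n_perm x bins
  })
  # pointwise cluster-forming thresholds from the permutation distribution
  if (sidedness == "two") {
    hi <- apply(perm_stats, 2, stats::quantile, probs = 1 - alpha / 2, type = 7)
    lo <- apply(perm_stats, 2, stats::quantile, probs = alpha / 2, type = 7)
  } else {
    hi <- apply(perm_stats, 2, stats::quantile, probs = 1 - alpha, type = 7)
    lo <- rep(-Inf, nb)
  }

  cluster_masses <- function(stat_row) {
    supra <- ifelse(stat_row > hi, 1L, ifelse(stat_row < lo, -1L, 0L))
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (!any(keep)) {
      return(data.frame(from = integer(0), to = integer(0), mass = numeric(0)))
    }
    data.frame(
      from = starts[keep], to = ends[keep],
      mass = mapply(
        function(a, b) sum(stat_row[a:b]),
        starts[keep], ends[keep]
      )
    )
  }

  obs_clusters <- cluster_masses(obs)
  # permutation null of the maximum absolute cluster mass
  null_max <- vapply(seq_len(n_perm), function(i) {
    cl <- cluster_masses(perm_stats[i, ])
    if (nrow(cl) == 0) 0 else max(abs(cl$mass))
  }, numeric(1))

  clusters <- lapply(seq_len(nrow(obs_clusters)), function(i) {
    m <- obs_clusters$mass[i]
    list(
      from = obs_clusters$from[i], to = obs_clusters$to[i], mass = m,
      p = (1 + sum(null_max >= abs(m))) / (1 + n_perm)
    )
  })
  structure(
    list(
      observed_stat = mean(obs), p_value = if (length(clusters)) {
        min(vapply(clusters, `[[`, numeric(1), "p"))
      } else {
        1
      },
      n_permutations = n_perm, sidedness = sidedness,
      clusters = clusters, bin_stats = obs,
      thresholds = list(lo = lo, hi = hi), alpha = alpha
    ),
    class = "stn_permutation_result"
  )
}

#' Bonferroni adjustment
#'
#' @param p_values Non-empty vector of p-values in [0, 1].
#' @return `pmin(1, m * p)` with `m = length(p_values)`.
#' @export
bonferroni <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value list", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}
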