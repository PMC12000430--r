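# Linkage of coupling spatial patterns to structural (streamline-count)
# and functional (seed-map parcel) connectivity via linear mixed-effects
# models.

#' Count streamlines connecting a contact pair
#'
#' A streamline counts if any of its vertices lies within `r_ecog` mm of
#' the cortex contact AND any vertex lies within `r_stn` mm of the STN
#' contact (Euclidean distance in MNI mm, boundary inclusive).
#'
#' @param atlas A `fiber_atlas` or list of polyline matrices (points x 3).
#' @param ecog_xyz,stn_xyz Contact coordinates (MNI mm).
#' @param r_ecog,r_stn Inclusion radii in mm (defaults 5 and 3).
#' @return Integer count.
#' @export
count_connecting_fibers <- function(atlas, ecog_xyz, stn_xyz,
                                    r_ecog = 5, r_stn = 3) {
  lines <- if (inherits(atlas, "fiber_atlas")) atlas$streamlines else atlas
  if (length(lines) == 0) {
    return(0L)
  }
  n <- 0L
  for (line in lines) {
    de <- sqrt(colSums((t(line) - ecog_xyz)^2))
    if (min(de) > r_ecog) next
    ds <- sqrt(colSums((t(line) - stn_xyz)^2))
    if (min(ds) <= r_stn) n <- n + 1L
  }
  n
}

#' Seed-based correlation map from a 4D functional volume
#'
#' The seed time course is the mean over voxels within `r` mm of the seed
#' coordinate; the map is the Pearson correlation of that time course with
#' every voxel's time course. Zero-variance voxels are masked (NA).
#'
#' @param volume_4d 4D array (x, y, z, time) or an RNifti image.
#' @param seed_xyz Seed coordinate in mm.
#' @param affine 4x4 voxel-to-mm affine; taken from the image when
#'   `volume_4d` is a NIfTI image.
#' @param r Seed radius in mm (default 5).
#' @return 3D array of correlations in [-1, 1], NA where undefined.
#' @export
seed_correlation_map <- function(volume_4d, seed_xyz, affine = NULL, r = 5) {
  if (inherits(volume_4d, "niftiImage")) {
    affine <- affine %||% RNifti::xform(volume_4d)
    volume_4d <- as.array(volume_4d)
  }
  if (is.null(affine)) stop("an affine is required for array input", call. = FALSE)
  d <- dim(volume_4d)
  stopifnot(length(d) == 4L)
  if (d[4] < 10) stop("need at least 10 time points", call. = FALSE)
  vox <- as.matrix(expand.grid(
    i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
    k = seq_len(d[3]) - 1
  ))
  mm <- vox %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(vox), 3, byrow = TRUE)
  dist <- sqrt(rowSums(sweep(mm, 2, seed_xyz)^2))
  in_seed <- dist <= r
  if (!any(in_seed)) stop("no voxels within the seed radius", call. = FALSE)
  mat <- matrix(volume_4d, nrow = prod(d[1:3]), ncol = d[4])
  seed_tc <- colMeans(mat[in_seed, , drop = FALSE])
  if (stats::sd(seed_tc) == 0) stop("constant seed time course", call. = FALSE)
  vox_sd <- apply(mat, 1, stats::sd)
  cors <- rep(NA_real_, nrow(mat))
  ok <- vox_sd > 0
  cors[ok] <- as.vector(stats::cor(t(mat[ok, , drop = FALSE]), seed_tc))
  array(cors, dim = d[1:3])
}

#' Mean of a correlation map over a parcel
#'
#' @param map 3D array (e.g. from [seed_correlation_map()]).
#' @param parcel_mask Logical/0-1 array on the same grid.
#' @return Mean of defined (non-NA) voxels inside the parcel.
#' @export
parcel_mean <- function(map, parcel_mask) {
  parcel_mask <- as.array(parcel_mask) != 0
  if (!all(dim(map) == dim(parcel_mask))) {
    stop("mask grid does not match map grid", call. = FALSE)
  }
  vals <- map[parcel_mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("empty parcel", call. = FALSE)
  mean(vals)
}

#' Linear mixed-effects linkage of connectivity and spatial patterns
#'
#' Fits `response ~ predictors + (1 | subject)` by restricted maximum
#' likelihood and reports per-term coefficients with Satterthwaite
#' p-values, variance components, conditional R^2 (fixed plus random
#' variance over total), BIC, and the Pearson correlation of fitted versus
#' observed response. The default predictor set is
#' `c("pattern", "medication")`, mirroring a model of connectomic
#' connectivity against coupling spatial patterns with medication state as
#' a fixed effect and subject as a random intercept; alternative sets
#' support model comparisons.
#'
#' @param table Data frame with a `response` and `subject` column plus the
#'   predictor columns.
#' @param predictors Character vector of fixed-effect column names.
#' @param response Name of the response column.
#' @return An `stn_mixed_model` with `fixed_effects` (data frame: term,
#'   beta, se, p), `random_intercept_variance`, `residual_variance`,
#'   `conditional_r2`, `bic`, `fit_quality_r`, `singular`, and the fit.
#' @export
lme_fit <- function(table, predictors = c("pattern", "medication"),
                    response = "response") {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(c(response, "subject", predictors), names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(unique(table$subject)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+ (1 | subject)"
  ))
  fit <- suppressMessages(lmerTest::lmer(fml, data = table, REML = TRUE))
  singular <- lme4::isSingular(fit)
  sm <- summary(fit)
  co <- stats::coef(sm)
  fe <- data.frame(
    term = rownames(co), beta = co[, "Estimate"],
    se = co[, "Std. Error"],
    p = co[, "Pr(>|t|)"], row.names = NULL,
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_rand <- vc$vcov[vc$grp == "subject"]
  var_resid <- vc$vcov[vc$grp == "Residual"]
  var_fixed <- stats::var(as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  cond_r2 <- (var_fixed + var_rand) / (var_fixed + var_rand + var_resid)
  fitted_vals <- stats::fitted(fit)
  obs <- table[[response]]
  r <- if (stats::sd(fitted_vals) > 0 && stats::sd(obs) > 0) {
    stats::cor(fitted_vals, obs)
  } else {
    NA_real_
  }
  structure(
    list(
      fixed_effects = fe,
      random_intercept_variance = var_rand,
      residual_variance = var_resid,
      conditional_r2 = cond_r2,
      bic = stats::BIC(fit),
      fit_quality_r = r,
      singular = singular,
      formula = fml,
      model = fit
    ),
    class = "stn_mixed_model"
  )
}

#' @export
print.stn_mixed_model <- function(x, ...) {
  cat(sprintf(
    "<stn_mixed_model> %s%s\n", deparse(x$formula),
    if (x$singular) " [singular fit: boundary variance]" else ""
  ))
  print(x$fixed_effects, digits = 4)
  cat(sprintf(
    "  conditional R2 = %.3f, BIC = %.1f, fit r = %.3f\n",
    x$conditional_r2, x$bic, x$fit_quality_r
  ))
  invisible(x)
}
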