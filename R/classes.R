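# Core S3 containers shared across the analysis stages.

#' Construct a multichannel recording
#'
#' A recording holds a channels x samples voltage matrix (microvolts)
#' together with per-channel metadata and the therapy condition under which
#' it was acquired.
#'
#' @param data Numeric matrix, channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_info Data frame with columns `name`, `site` ("cortex" or
#'   "stn"), `montage` ("unipolar" or "bipolar"), `region` (one of "motor",
#'   "sensory", "parietal", "prefrontal", "stn"), `mni_x`, `mni_y`, `mni_z`
#'   (mm) and `is_stim_contact` (logical).
#' @param condition One of "off", "levodopa", "dbs".
#' @param subject_id Subject identifier string.
#' @return An object of class `stn_recording`.
#' @export
new_recording <- function(data, sampling_rate, channel_info,
                          condition = c("off", "levodopa", "dbs"),
                          subject_id = "sim") {
  condition <- match.arg(condition)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  stopifnot_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  channel_info <- validate_channel_info(channel_info)
  if (nrow(channel_info) != nrow(data)) {
    stop("channel_info rows must match data rows", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording data contains non-finite samples", call. = FALSE)
  }
  rownames(data) <- channel_info$name
  structure(
    list(
      data = data, sampling_rate = sampling_rate,
      channel_info = channel_info, condition = condition,
      subject_id = subject_id
    ),
    class = "stn_recording"
  )
}

validate_channel_info <- function(ci) {
  ci <- as.data.frame(ci, stringsAsFactors = FALSE)
  needed <- c("name", "site", "montage", "region", "is_stim_contact")
  missing <- setdiff(needed, names(ci))
  if (length(missing)) {
    stop("channel_info lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in c("mni_x", "mni_y", "mni_z")) {
    if (is.null(ci[[col]])) ci[[col]] <- NA_real_
  }
  ok_region <- c("motor", "sensory", "parietal", "prefrontal", "stn")
  if (!all(ci$region %in% ok_region)) {
    stop("channel region outside the closed vocabulary: ",
      paste(setdiff(ci$region, ok_region), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(ci$site %in% c("cortex", "stn"))) stop("bad site", call. = FALSE)
  if (!all(ci$montage %in% c("unipolar", "bipolar"))) stop("bad montage", call. = FALSE)
  if (anyDuplicated(ci$name)) stop("duplicate channel names", call. = FALSE)
  ci
}

#' @export
print.stn_recording <- function(x, ...) {
  cat(sprintf(
    "<stn_recording> subject %s, condition %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$condition, nrow(x$data), ncol(x$data),
    x$sampling_rate, ncol(x$data) / x$sampling_rate
  ))
  cat("  sites:", paste(sprintf(
    "%s=%d", names(table(x$channel_info$site)),
    as.integer(table(x$channel_info$site))
  ), collapse = ", "), "\n")
  invisible(x)
}

#' Construct an epochs container
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param sampling_rate Hz.
#' @param channel_info As for [new_recording()].
#' @param kept_mask Logical per-epoch retention flag.
#' @param condition,subject_id Carried over from the recording.
#' @return An object of class `stn_epochs`.
#' @export
new_epochs <- function(data, sampling_rate, channel_info,
                       kept_mask = rep(TRUE, dim(data)[1]),
                       condition = "off", subject_id = "sim") {
  stopifnot(length(dim(data)) == 3L)
  channel_info <- validate_channel_info(channel_info)
  if (dim(data)[2] != nrow(channel_info)) {
    stop("epochs channel dimension must match channel_info", call. = FALSE)
  }
  structure(
    list(
      data = data, sampling_rate = sampling_rate,
      epoch_duration = dim(data)[3] / sampling_rate,
      channel_info = channel_info,
      kept_mask = as.logical(kept_mask),
      condition = condition, subject_id = subject_id
    ),
    class = "stn_epochs"
  )
}

#' @export
print.stn_epochs <- function(x, ...) {
  cat(sprintf(
    "<stn_epochs> %d epochs (%d kept) x %d channels x %d samples @ %g Hz (%.3g s epochs)\n",
    dim(x$data)[1], sum(x$kept_mask), dim(x$data)[2], dim(x$data)[3],
    x$sampling_rate, x$epoch_duration
  ))
  invisible(x)
}

# Epoch data restricted to kept epochs.
kept_epoch_data <- function(epochs) {
  epochs$data[epochs$kept_mask, , , drop = FALSE]
}

#' @export
print.stn_segment_set <- function(x, ...) {
  cat(sprintf(
    "<stn_segment_set> %d segments of %d epochs (seed %d, coverage %.1f%%)\n",
    length(x$segments), length(x$segments[[1]]), x$seed, 100 * x$coverage
  ))
  invisible(x)
}

#' @export
print.stn_power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<stn_power_spectrum> %d channels x %d bins (%.3g-%.3g Hz), normalisation %s\n",
    nrow(x$values), length(x$freqs), min(x$freqs), max(x$freqs), x$normalisation
  ))
  invisible(x)
}

#' @export
print.stn_coupling_spectrum <- function(x, ...) {
  cat(sprintf(
    "<stn_coupling_spectrum> method %s: %d bins (%.3g-%.3g Hz), %d segment(s)\n",
    x$method, length(x$freqs), min(x$freqs), max(x$freqs), x$segment_count
  ))
  invisible(x)
}

#' @export
print.stn_delay_estimate <- function(x, ...) {
  cat(sprintf(
    "<stn_delay_estimate> tau = %g ms%s\n", x$tau,
    if (!is.null(x$ci80)) {
      sprintf(
        ", 80%% CI [%g, %g] ms, %s", x$ci80[1], x$ci80[2],
        if (isTRUE(x$valid)) "valid" else "not valid"
      )
    } else {
      ""
    }
  ))
  invisible(x)
}

#' @export
print.stn_permutation_result <- function(x, ...) {
  cat(sprintf(
    "<stn_permutation_result> observed = %.4g, p = %.5g (%s-sided, %d permutations)\n",
    x$observed_stat, x$p_value, x$sidedness, x$n_permutations
  ))
  if (!is.null(x$clusters) && length(x$clusters)) {
    for (cl in x$clusters) {
      cat(sprintf(
        "  cluster bins %d-%d: mass %.4g, p = %.5g\n",
        cl$from, cl$to, cl$mass, cl$p
      ))
    }
  }
  invisible(x)
}
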