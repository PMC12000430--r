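# Reading and writing of the on-disk layout: recordings as raw binary
# (little-endian float64) with a JSON sidecar plus channels/electrodes
# TSVs, streamlines as a TSV polyline dialect, volumes as NIfTI, tables as
# TSV, ground truth and manifests as JSON.

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a recording to disk
#'
#' Produces an iEEG-BIDS-style file set under `dir`:
#' `<prefix>_ieeg.bin` (float64 little-endian, channel-major),
#' `<prefix>_ieeg.json` (rate, shape, dtype, condition, subject),
#' `<prefix>_channels.tsv` and `<prefix>_electrodes.tsv`.
#'
#' @param recording A recording.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (defaults to `sub-<id>_<condition>`).
#' @return The prefix path, invisibly.
#' @export
write_recording <- function(recording, dir, prefix = NULL) {
  stopifnot(inherits(recording, "stn_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prefix <- prefix %||%
    sprintf("sub-%s_%s", recording$subject_id, recording$condition)
  base <- file.path(dir, prefix)
  con <- file(paste0(base, "_ieeg.bin"), "wb")
  writeBin(as.vector(t(recording$data)), con,
    size = 8, endian = "little"
  )
  close(con)
  write_json(list(
    sampling_rate = recording$sampling_rate,
    n_channels = nrow(recording$data),
    n_samples = ncol(recording$data),
    dtype = "float64", byte_order = "little",
    order = "channel_major",
    condition = recording$condition,
    subject_id = recording$subject_id
  ), paste0(base, "_ieeg.json"))
  ci <- recording$channel_info
  write_tsv(
    ci[, c("name", "site", "montage", "region", "is_stim_contact")],
    paste0(base, "_channels.tsv")
  )
  write_tsv(
    data.frame(name = ci$name, x = ci$mni_x, y = ci$mni_y, z = ci$mni_z),
    paste0(base, "_electrodes.tsv")
  )
  invisible(base)
}

#' Read a recording written by [write_recording()]
#'
#' Metadata is joined to data rows by channel name; any mismatch between
#' the data shape, channels table and electrodes table is fatal.
#'
#' @param base Path prefix (as returned by [write_recording()]), i.e.
#'   without the `_ieeg.bin` suffix.
#' @return A recording.
#' @export
read_recording <- function(base) {
  sidecar_path <- paste0(base, "_ieeg.json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  con <- file(paste0(base, "_ieeg.bin"), "rb")
  vals <- readBin(con, "double",
    n = meta$n_channels * meta$n_samples,
    size = 8, endian = "little"
  )
  close(con)
  if (length(vals) != meta$n_channels * meta$n_samples) {
    stop("data file shorter than sidecar shape", call. = FALSE)
  }
  data <- t(matrix(vals, nrow = meta$n_samples, ncol = meta$n_channels))
  channels <- read_tsv(paste0(base, "_channels.tsv"))
  if (nrow(channels) != meta$n_channels) {
    stop(sprintf(
      "channels.tsv has %d rows but data has %d channels",
      nrow(channels), meta$n_channels
    ), call. = FALSE)
  }
  electrodes <- read_tsv(paste0(base, "_electrodes.tsv"))
  miss <- setdiff(channels$name, electrodes$name)
  if (length(miss)) {
    stop(
      "channel(s) missing from electrodes table: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  m <- match(channels$name, electrodes$name)
  channels$mni_x <- electrodes$x[m]
  channels$mni_y <- electrodes$y[m]
  channels$mni_z <- electrodes$z[m]
  new_recording(data, meta$sampling_rate, channels,
    condition = meta$condition, subject_id = meta$subject_id
  )
}

#' Write streamlines as a TSV polyline dialect
#'
#' Columns: `streamline_id`, `point_index`, `x`, `y`, `z` (MNI mm).
#'
#' @param atlas A `fiber_atlas` or list of polyline matrices.
#' @param path Output path.
#' @export
write_streamlines_tsv <- function(atlas, path) {
  lines <- if (inherits(atlas, "fiber_atlas")) atlas$streamlines else atlas
  rows <- do.call(rbind, lapply(seq_along(lines), function(i) {
    ln <- lines[[i]]
    data.frame(
      streamline_id = i, point_index = seq_len(nrow(ln)),
      x = ln[, 1], y = ln[, 2], z = ln[, 3]
    )
  }))
  write_tsv(rows, path)
}

#' Read streamlines from the TSV polyline dialect
#'
#' @param path Path written by [write_streamlines_tsv()].
#' @return List of polyline matrices (points x 3).
#' @export
read_streamlines_tsv <- function(path) {
  df <- read_tsv(path)
  lapply(split(df, df$streamline_id), function(part) {
    part <- part[order(part$point_index), ]
    as.matrix(part[, c("x", "y", "z")])
  })
}

#' Write a 4D volume as NIfTI
#'
#' @param volume_4d 4D array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path Output path (.nii or .nii.gz).
#' @export
write_volume_nifti <- function(volume_4d, affine, path) {
  img <- RNifti::asNifti(volume_4d)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `affine` (4x4).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim = dim(img))
  list(data = data, affine = unclass(RNifti::xform(img)))
}
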