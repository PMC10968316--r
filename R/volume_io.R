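#' Construct an MR volume object
#'
#' A thin container around a 3D intensity array. The third array axis is
#' always the slice-stacking (z) axis; in-plane axis 1 is treated downstream
#' as the phase-encode direction. Intensities must be finite and nonnegative
#' (MR magnitude data).
#'
#' @param data 3D numeric array (x, y, z with z the slice axis).
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @param provenance optional list recording where the volume came from
#'   (source path, extraction window, ...).
#' @return An object of class `mri_volume` with elements `data`,
#'   `voxel_size` and `provenance`.
#' @export
mri_volume <- function(data, voxel_size = c(1, 1, 1), provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_msg("volume data must be a 3D array, got %s dimension(s)",
             length(dim(data)))
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop_msg("volume intensities must all be finite")
  }
  if (any(data < 0)) {
    stop_msg("volume intensities must be nonnegative (MR magnitudes)")
  }
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop_msg("voxel_size must be three positive lengths (mm)")
  }
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         provenance = provenance),
    class = "mri_volume"
  )
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mri_volume> %d x %d x %d voxels (%.3g x %.3g x %.3g mm)\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.mri_volume <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' Loads a 3D NIfTI-1 file and returns an [mri_volume()] whose third axis is
#' the slice axis (NIfTI's third spatial dimension) and whose voxel sizes come
#' from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `mri_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_msg("cannot read volume: no such file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    stop_msg("failed to read NIfTI file '%s': %s",
                             path, conditionMessage(e))
                  })
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_msg("'%s' has %d dimension(s); a 3D volume is required",
             path, length(dim(arr)))
  }
  vox <- RNifti::pixdim(img)[seq_len(3)]
  mri_volume(array(as.numeric(arr), dim = dim(arr)), voxel_size = vox,
             provenance = list(source = path))
}

#' Write a volume to NIfTI-1
#'
#' @param v an `mri_volume` (or bare 3D array).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype storage type, `"double"` (bit-exact round trip) or
#'   `"float"` (32-bit, half the size).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, datatype = c("double", "float")) {
  datatype <- match.arg(datatype)
  if (is.array(v)) v <- mri_volume(v)
  img <- RNifti::asNifti(v$data,
                         pixdim = v$voxel_size)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Normalize a volume to unit maximum
#'
#' Divides all intensities by the volume maximum so the brightest voxel is
#' exactly 1. Applied before artifact simulation so peak-signal based metrics
#' have a defined scale.
#'
#' @param v an `mri_volume`.
#' @return The normalized `mri_volume`.
#' @export
normalize_volume <- function(v) {
  stopifnot(inherits(v, "mri_volume"))
  m <- max(v$data)
  if (m <= 0) stop_msg("cannot normalize an all-zero volume")
  v$data <- v$data / m
  v
}

#' Extract a centered window of slices
#'
#' Returns the contiguous `n`-slice sub-volume whose window starts at
#' `center_index - floor(n/2)` slices (so an `n = 50` window around the middle
#' of a 68-slice volume keeps slices 10..59, 1-based). The default center is
#' the geometric middle slice; `center = "auto"` instead picks the slice with
#' the largest area of voxels above the 95th intensity percentile, a proxy for
#' the bright CSF of the lateral ventricles on T2-weighted images.
#'
#' @param v an `mri_volume`.
#' @param n number of slices to keep.
#' @param center_index optional 1-based slice index at the window center.
#' @param center `"middle"` (default) or `"auto"` (bright-area heuristic);
#'   ignored when `center_index` is given.
#' @return An `mri_volume` with exactly `n` slices; its provenance records
#'   the window.
#' @export
extract_center_slices <- function(v, n, center_index = NULL,
                                  center = c("middle", "auto")) {
  stopifnot(inherits(v, "mri_volume"))
  center <- match.arg(center)
  nz <- dim(v$data)[3L]
  if (!is_count(n)) stop_msg("n must be a positive integer")
  n <- as.integer(n)
  if (n > nz) {
    stop_msg("cannot extract %d slices from a %d-slice volume", n, nz)
  }
  if (is.null(center_index)) {
    center_index <- if (center == "auto") {
      thr <- stats::quantile(v$data, 0.95, names = FALSE)
      area <- apply(v$data > thr, 3L, sum)
      which.max(area)
    } else {
      nz %/% 2L + 1L
    }
  }
  center_index <- as.integer(center_index)
  start <- center_index - n %/% 2L
  if (start < 1L || start + n - 1L > nz) {
    stop_msg("window of %d slices centered at %d falls outside 1..%d",
             n, center_index, nz)
  }
  keep <- start:(start + n - 1L)
  prov <- c(v$provenance,
            list(center_index = center_index, window = c(start, start + n - 1L)))
  mri_volume(v$data[, , keep, drop = FALSE], voxel_size = v$voxel_size,
             provenance = prov)
}
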