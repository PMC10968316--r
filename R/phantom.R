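#' Default phantom tissue classes
#'
#' Four intensity classes arranged as nested ellipsoids: background (air, 0),
#' a white-matter-like head ellipsoid (0.4), a gray-matter-like inner
#' ellipsoid (0.6) and a small bright CSF-like ventricle pair (0.95). On
#' T2-weighted images the CSF-filled ventricles are the brightest structures,
#' and that high-intensity class is what makes artifact behavior interesting,
#' so the default set always contains one.
#'
#' Each non-background class is a list with `name`, `mean` (intensity in
#' \[0, 1\]) and `ellipsoid`: center `c(cx, cy, cz)` and semi-axes
#' `c(ax, ay, az)`, both as fractions of the volume extent (center relative to
#' the volume center, semi-axes relative to the half-extent). Classes are
#' painted in order, so later (inner) classes overwrite earlier ones.
#'
#' @return A list of tissue class descriptors; element 1 is background.
#' @export
default_tissue_classes <- function() {
  list(
    list(name = "background", mean = 0),
    list(name = "white_matter", mean = 0.4,
         ellipsoid = list(center = c(0, 0, 0), semi_axes = c(0.85, 0.7, 0.9))),
    list(name = "gray_matter", mean = 0.6,
         ellipsoid = list(center = c(0, 0, 0), semi_axes = c(0.55, 0.45, 0.65))),
    list(name = "csf", mean = 0.95,
         ellipsoid = list(center = c(0, 0.12, 0), semi_axes = c(0.18, 0.12, 0.35)))
  )
}

#' Specify a synthetic brain-like phantom
#'
#' @param matrix_size in-plane matrix size (square), at least 16.
#' @param n_slices number of axial slices.
#' @param tissue_classes class list as from [default_tissue_classes()]; the
#'   first element is the background with mean 0.
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units (the generated volume is clipped to \[0, 1\]).
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 256L, n_slices = 68L,
                         tissue_classes = default_tissue_classes(),
                         noise_sd = 0.01, seed = 1L) {
  if (!is_count(matrix_size, min = 16L)) {
    stop_msg("matrix_size must be an integer >= 16")
  }
  if (!is_count(n_slices)) stop_msg("n_slices must be a positive integer")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_msg("noise_sd must be a single nonnegative number")
  }
  if (length(tissue_classes) < 1L || tissue_classes[[1L]]$mean != 0) {
    stop_msg("tissue_classes[[1]] must be the background class with mean 0")
  }
  for (cl in tissue_classes) {
    if (cl$mean < 0 || cl$mean > 1) {
      stop_msg("tissue class '%s' has mean %g outside [0, 1]", cl$name, cl$mean)
    }
    if (!is.null(cl$ellipsoid)) {
      e <- cl$ellipsoid
      if (any(e$semi_axes <= 0)) {
        stop_msg("tissue class '%s' has nonpositive semi-axes", cl$name)
      }
      if (any(abs(e$center) + e$semi_axes > 1 + 1e-12)) {
        stop_msg("tissue class '%s': ellipsoid extends outside the volume",
                 cl$name)
      }
    }
  }
  structure(
    list(matrix_size = as.integer(matrix_size), n_slices = as.integer(n_slices),
         tissue_classes = tissue_classes, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a labeled synthetic phantom volume
#'
#' Paints the spec's nested ellipsoids into a `matrix_size^2 x n_slices`
#' volume (voxel intensity = class mean + Gaussian noise, clipped to
#' \[0, 1\]) and returns the volume together with the integer label mask that
#' produced it, so segmentation and metric code can be validated against
#' ground truth. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `labeled_volume`: `volume` (an `mri_volume`),
#'   `labels` (3D integer array, 0 = background, k = `tissue_classes[[k+1]]`)
#'   and `class_means` (named vector of generating class means).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$matrix_size
  nz <- spec$n_slices
  # voxel centers in [-1, 1] along each axis
  gx <- if (m > 1) seq(-1, 1, length.out = m) else 0
  gz <- if (nz > 1) seq(-1, 1, length.out = nz) else 0
  labels <- array(0L, dim = c(m, m, nz))
  x2 <- matrix(gx, m, m)
  y2 <- matrix(gx, m, m, byrow = TRUE)
  for (ci in seq_along(spec$tissue_classes)[-1L]) {
    e <- spec$tissue_classes[[ci]]$ellipsoid
    if (is.null(e)) next
    q2d <- ((x2 - e$center[1]) / e$semi_axes[1])^2 +
           ((y2 - e$center[2]) / e$semi_axes[2])^2
    for (k in seq_len(nz)) {
      qz <- ((gz[k] - e$center[3]) / e$semi_axes[3])^2
      inside <- q2d + qz <= 1
      lk <- labels[, , k]
      lk[inside] <- ci - 1L
      labels[, , k] <- lk
    }
  }
  means <- vapply(spec$tissue_classes, `[[`, numeric(1), "mean")
  vol <- array(means[labels + 1L], dim = dim(labels))
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, stats::rnorm(length(vol), 0, spec$noise_sd))
    vol <- vol + noise
  }
  vol[vol < 0] <- 0
  vol[vol > 1] <- 1
  structure(
    list(volume = mri_volume(vol, provenance = list(phantom_seed = spec$seed)),
         labels = labels,
         class_means = stats::setNames(
           means, vapply(spec$tissue_classes, `[[`, character(1), "name"))),
    class = "labeled_volume"
  )
}
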