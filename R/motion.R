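#' Simulation parameters for rigid-motion artifact generation
#'
#' Defaults reproduce the study conditions: rotations up to ±5 degrees and
#' translations up to ±10 pixels on each axis, two to four cumulative
#' movements per slice acquisition, and a first movement that can only occur
#' after more than half of the k-space lines have been acquired (so the
#' contrast-carrying center of k-space stays motion-free under linear line
#' ordering).
#'
#' @param max_rotation_deg maximum absolute rotation per axis, degrees.
#' @param max_translation_px maximum absolute translation per axis, pixels.
#' @param n_movements_range integer range `c(lo, hi)` for the number of
#'   movement events per schedule.
#' @param min_onset_fraction fraction of acquisition that must be complete
#'   before the first movement (in `[0, 1)`).
#' @param per_slice_independent if `TRUE` (default) every slice of a volume
#'   gets its own independent schedule; if `FALSE` one schedule is shared.
#' @param cumulative_resampling if `TRUE` (default) each motion state is
#'   obtained by resampling the previous state (movements accumulate exactly
#'   as they would physically, at the cost of compounded interpolation); if
#'   `FALSE` each state resamples the original volume under the composed
#'   rigid transform.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param ordering phase-encode line acquisition ordering, `"linear"` or
#'   `"centric"`.
#' @param seed optional default seed used by pipeline code.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(max_rotation_deg = 5,
                              max_translation_px = 10,
                              n_movements_range = c(2L, 4L),
                              min_onset_fraction = 0.5,
                              per_slice_independent = TRUE,
                              cumulative_resampling = TRUE,
                              interpolation = c("trilinear", "nearest"),
                              ordering = c("linear", "centric"),
                              seed = NULL) {
  interpolation <- match.arg(interpolation)
  ordering <- match.arg(ordering)
  if (max_rotation_deg < 0 || max_translation_px < 0) {
    stop_msg("motion amplitude limits must be nonnegative")
  }
  if (length(n_movements_range) != 2L ||
      any(n_movements_range != round(n_movements_range)) ||
      n_movements_range[1] > n_movements_range[2] || n_movements_range[1] < 0) {
    stop_msg("n_movements_range must be an integer interval c(lo, hi), lo >= 0")
  }
  if (min_onset_fraction < 0 || min_onset_fraction >= 1) {
    stop_msg("min_onset_fraction must lie in [0, 1)")
  }
  structure(
    list(max_rotation_deg = max_rotation_deg,
         max_translation_px = max_translation_px,
         n_movements_range = as.integer(n_movements_range),
         min_onset_fraction = min_onset_fraction,
         per_slice_independent = isTRUE(per_slice_independent),
         cumulative_resampling = isTRUE(cumulative_resampling),
         interpolation = interpolation,
         ordering = ordering,
         seed = seed),
    class = "simulation_params"
  )
}

#' A single rigid-motion event
#'
#' @param onset_line 0-based acquisition-order position at which the movement
#'   happens: lines at positions `>= onset_line` are acquired after it.
#' @param rotation rotations `c(theta_x, theta_y, theta_z)` in degrees.
#' @param translation translations `c(tx, ty, tz)` in pixels.
#' @return An object of class `motion_event`.
#' @export
motion_event <- function(onset_line, rotation = c(0, 0, 0),
                         translation = c(0, 0, 0)) {
  if (!is_count(onset_line, min = 0L)) {
    stop_msg("onset_line must be a nonnegative integer")
  }
  stopifnot(length(rotation) == 3L, length(translation) == 3L)
  structure(list(onset_line = as.integer(onset_line),
                 rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "motion_event")
}

#' An ordered schedule of rigid-motion events for one slice acquisition
#'
#' @param events list of [motion_event()]s with strictly increasing
#'   `onset_line`; may be empty (motion-free acquisition).
#' @param n_lines total number of phase-encode lines.
#' @return An object of class `motion_schedule`.
#' @export
motion_schedule <- function(events, n_lines) {
  if (!is_count(n_lines)) stop_msg("n_lines must be a positive integer")
  n_lines <- as.integer(n_lines)
  onsets <- vapply(events, `[[`, integer(1), "onset_line")
  if (length(onsets) && (any(diff(onsets) <= 0))) {
    stop_msg("event onset lines must be strictly increasing")
  }
  if (length(onsets) && (min(onsets) < 0L || max(onsets) >= n_lines)) {
    stop_msg("onset lines must lie in [0, n_lines)")
  }
  structure(list(events = events, n_lines = n_lines),
            class = "motion_schedule")
}

#' @export
print.motion_schedule <- function(x, ...) {
  cat(sprintf("<motion_schedule> %d event(s) over %d phase-encode lines\n",
              length(x$events), x$n_lines))
  for (e in x$events) {
    cat(sprintf("  line %3d: rot (%+.2f, %+.2f, %+.2f) deg, shift (%+.2f, %+.2f, %+.2f) px\n",
                e$onset_line, e$rotation[1], e$rotation[2], e$rotation[3],
                e$translation[1], e$translation[2], e$translation[3]))
  }
  invisible(x)
}

#' Sample a random motion schedule
#'
#' The number of events is uniform on `n_movements_range`; onset lines are
#' drawn without replacement from the acquisition positions strictly after
#' `floor(min_onset_fraction * n_lines)` and sorted; each event's rotation
#' and translation components are uniform on the configured ranges. Because
#' all onsets are constrained past the fraction, the first movement always
#' occurs after that portion of k-space has been acquired.
#'
#' @param params a [simulation_params()].
#' @param n_lines number of phase-encode lines in the slice.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [motion_schedule()].
#' @export
sample_motion_schedule <- function(params, n_lines, seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is_count(n_lines, min = 4L)) stop_msg("n_lines must be an integer >= 4")
  n_lines <- as.integer(n_lines)
  lo <- params$n_movements_range[1]
  hi <- params$n_movements_range[2]
  first_allowed <- floor(params$min_onset_fraction * n_lines) + 1L
  candidates <- if (first_allowed > n_lines - 1L) integer(0) else
    seq.int(first_allowed, n_lines - 1L)
  if (length(candidates) < hi) {
    stop_msg("only %d candidate onset lines after line %d, but up to %d events requested",
             length(candidates), first_allowed - 1L, hi)
  }
  draw <- function() {
    n_ev <- if (lo == hi) lo else sample.int(hi - lo + 1L, 1L) + lo - 1L
    if (n_ev == 0L) return(motion_schedule(list(), n_lines))
    onsets <- sort(candidates[sample.int(length(candidates), n_ev)])
    events <- lapply(onsets, function(o) {
      motion_event(
        o,
        rotation = stats::runif(3, -params$max_rotation_deg,
                                params$max_rotation_deg),
        translation = stats::runif(3, -params$max_translation_px,
                                   params$max_translation_px)
      )
    })
    motion_schedule(events, n_lines)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# 3x3 rotation matrix for intrinsic rotations applied in fixed order x, y, z
# (R = Rz %*% Ry %*% Rx), angles in degrees.
rotation_matrix <- function(rotation) {
  a <- rotation * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Resample a volume under the rigid map p -> R (p - c) + c + t (voxel units,
# c = grid center). Interpolation outside the original extent yields 0.
resample_rigid <- function(v, rmat, translation, interpolation) {
  interp <- if (interpolation == "nearest") 0L else 1L
  d <- dim(v$data)
  out <- .resample_rigid_cpp(as.numeric(v$data), as.integer(d),
                             t(rmat), as.numeric(translation), interp)
  v$data <- out
  v
}

#' Apply a rigid-body transform to a volume
#'
#' Rotates the volume about its geometric center (intrinsic rotations applied
#' in the fixed order x, then y, then z, angles in degrees), then translates
#' it by whole or fractional pixels. Voxels sampled from outside the original
#' extent are zero; interpolated intensities are clipped at zero. The output
#' grid equals the input grid.
#'
#' @param v an `mri_volume`.
#' @param rotation degrees, `c(theta_x, theta_y, theta_z)`.
#' @param translation pixels, `c(tx, ty, tz)`.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return The transformed `mri_volume`.
#' @export
apply_rigid_transform <- function(v, rotation = c(0, 0, 0),
                                  translation = c(0, 0, 0),
                                  interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(v, "mri_volume"))
  interpolation <- match.arg(interpolation)
  resample_rigid(v, rotation_matrix(rotation), translation, interpolation)
}

#' Generate the sequence of moved volume states implied by a schedule
#'
#' Movements are never restored: state k is the volume position after the
#' k-th event. With `cumulative_resampling = TRUE` state k is obtained by
#' transforming state k-1 (the physical reading of accumulating motion, with
#' compounding interpolation); with `FALSE` state k resamples the original
#' volume once under the composed rigid transform of events 1..k.
#'
#' @param v the motion-free `mri_volume`.
#' @param schedule a [motion_schedule()].
#' @param params a [simulation_params()] (resampling mode, interpolation).
#' @return A list of `mri_volume`s, one per event (possibly empty).
#' @export
generate_motion_states <- function(v, schedule, params = simulation_params()) {
  stopifnot(inherits(v, "mri_volume"), inherits(schedule, "motion_schedule"))
  states <- vector("list", length(schedule$events))
  if (!length(states)) return(states)
  if (params$cumulative_resampling) {
    cur <- v
    for (k in seq_along(schedule$events)) {
      e <- schedule$events[[k]]
      cur <- apply_rigid_transform(cur, e$rotation, e$translation,
                                   params$interpolation)
      states[[k]] <- cur
    }
  } else {
    rc <- diag(3)
    tc <- c(0, 0, 0)
    for (k in seq_along(schedule$events)) {
      e <- schedule$events[[k]]
      re <- rotation_matrix(e$rotation)
      rc <- re %*% rc
      tc <- as.numeric(re %*% tc) + e$translation
      states[[k]] <- resample_rigid(v, rc, tc, params$interpolation)
    }
  }
  states
}
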