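#' Convert an image slice to centered 2D k-space
#'
#' Computes the unnormalized 2D discrete Fourier transform of a slice and
#' arranges it with the zero-frequency (DC) sample at the matrix center, the
#' layout in which the low-frequency, contrast-carrying lines occupy the
#' central rows. With this normalization Parseval's identity reads
#' `sum(|image|^2) = sum(|kspace|^2) / N`.
#'
#' @param s 2D numeric matrix (one slice).
#' @param phase_axis which in-plane axis indexes phase-encode lines (1 = rows,
#'   the default, or 2 = columns).
#' @return An object of class `kspace`: `data` (complex matrix, centered
#'   layout), `phase_axis`, `layout = "centered"`.
#' @export
slice_to_kspace <- function(s, phase_axis = 1L) {
  if (!is.matrix(s)) stop_msg("slice must be a 2D matrix")
  if (anyNA(s) || any(!is.finite(s))) stop_msg("slice must be finite")
  if (!phase_axis %in% c(1L, 2L)) stop_msg("phase_axis must be 1 or 2")
  k <- fftshift2(stats::fft(ifftshift2(s)))
  structure(list(data = k, phase_axis = as.integer(phase_axis),
                 layout = "centered"),
            class = "kspace")
}

#' Reconstruct an image from centered 2D k-space
#'
#' Applies the inverse centered transform and returns the complex magnitude
#' (MR images are magnitude images; a composed k-space is generally not
#' conjugate-symmetric, so its inverse transform is complex). `method =
#' "real"` instead keeps the real part, clipped at zero.
#'
#' @param k a `kspace` object (or bare complex matrix in centered layout).
#' @param method `"magnitude"` (default) or `"real"`.
#' @return A real, nonnegative matrix of the same shape.
#' @export
kspace_to_image <- function(k, method = c("magnitude", "real")) {
  method <- match.arg(method)
  kd <- if (inherits(k, "kspace")) k$data else k
  if (!is.matrix(kd)) stop_msg("k-space data must be a 2D matrix")
  img <- fftshift2(stats::fft(ifftshift2(kd), inverse = TRUE)) / length(kd)
  out <- if (method == "magnitude") Mod(img) else pmax(Re(img), 0)
  matrix(out, nrow(kd), ncol(kd))
}

#' Phase-encode line acquisition order
#'
#' Maps acquisition position to physical line index in the centered k-space
#' layout. `"linear"` acquires lines top-to-bottom (position i reads line i);
#' `"centric"` acquires the central line first and works outwards,
#' alternating below/above. One line is acquired per TR (echo-train length 1).
#'
#' @param n_lines number of phase-encode lines.
#' @param ordering `"linear"` or `"centric"`.
#' @return An integer permutation of `1:n_lines`: element i is the (1-based)
#'   physical line acquired at position i.
#' @export
acquisition_line_order <- function(n_lines, ordering = c("linear", "centric")) {
  ordering <- match.arg(ordering)
  if (!is_count(n_lines)) stop_msg("n_lines must be a positive integer")
  n_lines <- as.integer(n_lines)
  if (ordering == "linear") return(seq_len(n_lines))
  c0 <- n_lines %/% 2L + 1L
  ord <- integer(0)
  for (off in 0:n_lines) {
    for (cand in unique(c(c0 - off, c0 + off))) {
      if (cand >= 1L && cand <= n_lines) ord <- c(ord, cand)
    }
    if (length(ord) >= n_lines) break
  }
  ord[seq_len(n_lines)]
}

#' Compose motion-corrupted k-space by phase-encode line replacement
#'
#' Walks the phase-encode lines in acquisition order and takes each line from
#' the k-space of the motion state active at its acquisition time: state 0
#' (the motion-free slice) before the first movement onset, state k from the
#' k-th onset until the next. Because movements are never restored, the
#' active state is nondecreasing along the acquisition.
#'
#' @param clean `kspace` of the motion-free slice.
#' @param states list of `kspace` objects, one per motion event.
#' @param schedule the [motion_schedule()] whose onsets (0-based acquisition
#'   positions) drive the replacement.
#' @param ordering line acquisition ordering, as in
#'   [acquisition_line_order()].
#' @return A list: `kspace` (the composite), `provenance` (integer vector
#'   indexed by physical line: 0 = motion-free source, k = motion state k).
#' @export
compose_kspace <- function(clean, states, schedule,
                           ordering = c("linear", "centric")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(clean, "kspace"), inherits(schedule, "motion_schedule"))
  if (length(states) != length(schedule$events)) {
    stop_msg("got %d motion states for %d schedule events",
             length(states), length(schedule$events))
  }
  kd <- clean$data
  for (s in states) {
    sd <- if (inherits(s, "kspace")) s$data else s
    if (!all(dim(sd) == dim(kd))) stop_msg("k-space shapes differ")
  }
  n_lines <- if (clean$phase_axis == 1L) nrow(kd) else ncol(kd)
  if (schedule$n_lines != n_lines) {
    stop_msg("schedule covers %d lines but k-space has %d phase-encode lines",
             schedule$n_lines, n_lines)
  }
  perm <- acquisition_line_order(n_lines, ordering)
  onsets <- vapply(schedule$events, `[[`, integer(1), "onset_line")
  provenance <- integer(n_lines)
  out <- kd
  active <- 0L
  for (pos in seq_len(n_lines)) {
    # events at acquisition position pos-1 (0-based) and earlier are in effect
    while (active < length(onsets) && onsets[active + 1L] <= pos - 1L) {
      active <- active + 1L
    }
    line <- perm[pos]
    provenance[line] <- active
    if (active > 0L) {
      src <- states[[active]]
      sd <- if (inherits(src, "kspace")) src$data else src
      if (clean$phase_axis == 1L) out[line, ] <- sd[line, ]
      else out[, line] <- sd[, line]
    }
  }
  k <- clean
  k$data <- out
  list(kspace = k, provenance = provenance)
}

# Slice z of every motion state, without materializing the final state's
# full volume (and, in composed mode, without materializing any full state):
# identical values to extracting slice z from generate_motion_states().
motion_state_slices <- function(v, schedule, params, z) {
  events <- schedule$events
  n <- length(events)
  slices <- vector("list", n)
  if (!n) return(slices)
  d <- dim(v$data)
  interp <- if (params$interpolation == "nearest") 0L else 1L
  if (params$cumulative_resampling) {
    prev <- v$data
    for (k in seq_len(n)) {
      e <- events[[k]]
      rinv <- t(rotation_matrix(e$rotation))
      if (k < n) {
        prev <- .resample_rigid_cpp(as.numeric(prev), as.integer(d), rinv,
                                    as.numeric(e$translation), interp)
        slices[[k]] <- prev[, , z]
      } else {
        slices[[k]] <- .resample_rigid_slice_cpp(as.numeric(prev),
                                                 as.integer(d), rinv,
                                                 as.numeric(e$translation),
                                                 z - 1L, interp)
      }
    }
  } else {
    rc <- diag(3)
    tc <- c(0, 0, 0)
    for (k in seq_len(n)) {
      e <- events[[k]]
      re <- rotation_matrix(e$rotation)
      rc <- re %*% rc
      tc <- as.numeric(re %*% tc) + e$translation
      slices[[k]] <- .resample_rigid_slice_cpp(as.numeric(v$data),
                                               as.integer(d), t(rc),
                                               as.numeric(tc), z - 1L, interp)
    }
  }
  slices
}

# Simulate one slice given an already-sampled schedule and (optionally)
# precomputed motion-state volumes.
simulate_slice_core <- function(v, z, schedule, params, states = NULL) {
  state_slices <- if (is.null(states)) {
    motion_state_slices(v, schedule, params, z)
  } else {
    lapply(states, function(s) s$data[, , z])
  }
  clean_s <- v$data[, , z]
  k_clean <- slice_to_kspace(clean_s)
  k_states <- lapply(state_slices, slice_to_kspace)
  comp <- compose_kspace(k_clean, k_states, schedule, params$ordering)
  artifact <- kspace_to_image(comp$kspace)
  list(artifact = artifact, residual = artifact - clean_s,
       schedule = schedule, provenance = comp$provenance)
}

#' Simulate a motion-artifact slice
#'
#' Samples a motion schedule, moves the whole volume through its motion
#' states, converts the motion-free slice and each state's matching slice to
#' k-space, composes the corrupted k-space by phase-encode line replacement,
#' and reconstructs the artifact image. The residual map is the signed
#' difference `artifact - clean`, so `clean + residual` reproduces the
#' artifact exactly.
#'
#' The per-slice RNG stream is derived from `seed` and `z` (when
#' `params$per_slice_independent` is `TRUE`), so simulating one slice and
#' simulating the whole volume give identical results for that slice.
#'
#' @param v the motion-free `mri_volume` (normalized).
#' @param z 1-based slice index.
#' @param params a [simulation_params()].
#' @param seed integer seed.
#' @return A list: `artifact` (matrix), `residual` (signed matrix),
#'   `schedule`, `provenance` (per-line motion state indices).
#' @export
simulate_artifact_slice <- function(v, z, params = simulation_params(),
                                    seed = 1L) {
  stopifnot(inherits(v, "mri_volume"))
  nz <- dim(v$data)[3L]
  if (!is_count(z) || z > nz) stop_msg("slice index %s outside 1..%d", z, nz)
  n_lines <- dim(v$data)[1L]
  slice_seed <- if (params$per_slice_independent) derive_seed(seed, z) else seed
  schedule <- sample_motion_schedule(params, n_lines, seed = slice_seed)
  simulate_slice_core(v, z, schedule, params)
}

#' Simulate motion artifacts for every slice of a volume
#'
#' Applies [simulate_artifact_slice()] to each slice. By default every slice
#' gets an independent random schedule (its RNG stream derived from `seed`
#' and the slice index); with `params$per_slice_independent = FALSE` a single
#' schedule is sampled and shared by all slices, and the motion states are
#' computed once.
#'
#' @param v the motion-free `mri_volume`.
#' @param params a [simulation_params()].
#' @param seed integer seed.
#' @return A list: `artifact` (`mri_volume`), `residual` (signed 3D array),
#'   `schedules` (one [motion_schedule()] per slice, or a single-element list
#'   in shared-schedule mode).
#' @export
simulate_artifact_volume <- function(v, params = simulation_params(),
                                     seed = 1L) {
  stopifnot(inherits(v, "mri_volume"))
  d <- dim(v$data)
  art <- array(0, d)
  res <- array(0, d)
  if (params$per_slice_independent) {
    schedules <- vector("list", d[3L])
    for (z in seq_len(d[3L])) {
      sim <- simulate_artifact_slice(v, z, params, seed)
      art[, , z] <- sim$artifact
      res[, , z] <- sim$residual
      schedules[[z]] <- sim$schedule
    }
  } else {
    schedule <- sample_motion_schedule(params, d[1L], seed = seed)
    states <- generate_motion_states(v, schedule, params)
    for (z in seq_len(d[3L])) {
      sim <- simulate_slice_core(v, z, schedule, params, states = states)
      art[, , z] <- sim$artifact
      res[, , z] <- sim$residual
    }
    schedules <- list(schedule)
  }
  list(artifact = mri_volume(art, voxel_size = v$voxel_size,
                             provenance = c(v$provenance, list(seed = seed))),
       residual = res, schedules = schedules)
}
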