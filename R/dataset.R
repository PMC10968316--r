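#' Build paired clean/artifact/residual training samples
#'
#' Runs the artifact simulation over every slice of every input volume and
#' emits one paired sample per slice: the motion-free slice, the
#' motion-corrupted slice, the signed residual map (`artifact - clean`, so
#' the three are algebraically consistent by construction) and the motion
#' schedule that produced it. 200 volumes of 50 slices yield the study-sized
#' set of 10,000 pairs.
#'
#' @param clean_volumes list of `mri_volume`s, already window-extracted and
#'   normalized; names (if any) become subject ids, otherwise `S001`, ...
#' @param params a [simulation_params()].
#' @param seed integer seed; each volume gets a derived sub-stream.
#' @return A list of `paired_sample` objects with elements `clean`,
#'   `artifact`, `residual`, `subject`, `slice_index`, `schedule`.
#' @export
build_pairs <- function(clean_volumes, params = simulation_params(),
                        seed = 1L) {
  stopifnot(is.list(clean_volumes), length(clean_volumes) >= 1L)
  ids <- names(clean_volumes)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("S%03d", seq_along(clean_volumes))
  }
  samples <- vector("list", sum(vapply(clean_volumes,
                                       function(v) dim(v$data)[3L], numeric(1))))
  pos <- 0L
  for (i in seq_along(clean_volumes)) {
    v <- clean_volumes[[i]]
    stopifnot(inherits(v, "mri_volume"))
    sim <- simulate_artifact_volume(v, params, seed = derive_seed(seed, i))
    nz <- dim(v$data)[3L]
    for (z in seq_len(nz)) {
      pos <- pos + 1L
      sched <- if (params$per_slice_independent) sim$schedules[[z]]
               else sim$schedules[[1L]]
      samples[[pos]] <- structure(
        list(clean = v$data[, , z],
             artifact = sim$artifact$data[, , z],
             residual = sim$residual[, , z],
             subject = ids[i], slice_index = z, schedule = sched),
        class = "paired_sample"
      )
    }
  }
  samples
}

#' Split paired samples into train/validation/test partitions
#'
#' Shuffles deterministically by `seed` and partitions with sizes
#' `floor(fraction * N)` for each partition, any remainder going to the
#' training set (so 10,000 samples under the default 0.7/0.1/0.2 fractions
#' split 7000/1000/2000). With `by_subject = TRUE`, whole subjects are
#' assigned greedily to test, then validation, so no subject's slices leak
#' across partitions; partition sizes are then only approximate.
#'
#' @param samples list of `paired_sample`s.
#' @param fractions train/validation/test fractions, positive, summing to 1.
#' @param seed integer shuffle seed.
#' @param by_subject keep each subject's slices in a single partition.
#' @return An object of class `dataset_split` with integer index vectors
#'   `train`, `validation`, `test` plus the `fractions`, `seed` and
#'   `by_subject` flag used.
#' @export
split_dataset <- function(samples, fractions = c(0.7, 0.1, 0.2), seed = 1L,
                          by_subject = FALSE) {
  n <- length(samples)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_msg("fractions must be three positive numbers summing to 1")
  }
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (!by_subject) {
    perm <- with_seed(seed, sample.int(n))
    train <- perm[seq_len(n_train)]
    val <- perm[n_train + seq_len(n_val)]
    test <- perm[n_train + n_val + seq_len(n_test)]
  } else {
    subj <- vapply(samples, `[[`, character(1), "subject")
    subjects <- unique(subj)
    ord <- with_seed(seed, sample.int(length(subjects)))
    test <- integer(0); val <- integer(0); train <- integer(0)
    for (s in subjects[ord]) {
      idx <- which(subj == s)
      if (length(test) + length(idx) <= n_test) test <- c(test, idx)
      else if (length(val) + length(idx) <= n_val) val <- c(val, idx)
      else train <- c(train, idx)
    }
  }
  structure(list(train = sort(train), validation = sort(val),
                 test = sort(test), fractions = fractions,
                 seed = as.integer(seed), by_subject = isTRUE(by_subject)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d%s)\n",
              length(x$train), length(x$validation), length(x$test), x$seed,
              if (x$by_subject) ", by subject" else ""))
  invisible(x)
}

schedule_to_list <- function(s) {
  list(n_lines = s$n_lines,
       events = lapply(s$events, function(e) {
         list(onset_line = e$onset_line, rotation = e$rotation,
              translation = e$translation)
       }))
}

schedule_from_list <- function(l) {
  motion_schedule(lapply(l$events, function(e) {
    motion_event(e$onset_line, unlist(e$rotation), unlist(e$translation))
  }), n_lines = l$n_lines)
}

#' Persist a paired dataset to a directory container
#'
#' Writes the clean/artifact/residual slice stacks as three NIfTI-1 files
#' plus a JSON manifest holding subjects, slice indices, motion schedules and
#' the split assignment. With the default `datatype = "double"` the arrays
#' round-trip bit-exactly; `"float"` stores 32-bit values at half the size.
#'
#' @param samples list of `paired_sample`s (all slices the same shape).
#' @param split a [split_dataset()] result (or `NULL`).
#' @param path directory to create/fill.
#' @param datatype `"double"` or `"float"`.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(samples, split, path,
                         datatype = c("double", "float")) {
  datatype <- match.arg(datatype)
  stopifnot(length(samples) >= 1L)
  shp <- dim(samples[[1L]]$clean)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stack <- function(field) {
    a <- array(0, c(shp, length(samples)))
    for (i in seq_along(samples)) {
      m <- samples[[i]][[field]]
      if (!all(dim(m) == shp)) stop_msg("sample %d has inconsistent shape", i)
      a[, , i] <- m
    }
    a
  }
  for (field in c("clean", "artifact", "residual")) {
    RNifti::writeNifti(RNifti::asNifti(stack(field)),
                       file.path(path, paste0(field, ".nii.gz")),
                       datatype = datatype)
  }
  manifest <- list(
    n_samples = length(samples), shape = shp, datatype = datatype,
    subject = vapply(samples, `[[`, character(1), "subject"),
    slice_index = vapply(samples, `[[`, integer(1), "slice_index"),
    schedules = lapply(samples, function(s) schedule_to_list(s$schedule)),
    split = if (is.null(split)) NULL else unclass(split)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a paired dataset saved by [save_dataset()]
#'
#' @param path dataset directory.
#' @return A list: `samples` (list of `paired_sample`s) and `split` (a
#'   `dataset_split` or `NULL`).
#' @export
load_dataset <- function(path) {
  for (member in c("manifest.json", "clean.nii.gz", "artifact.nii.gz",
                   "residual.nii.gz")) {
    if (!file.exists(file.path(path, member))) {
      stop_msg("dataset container '%s' is missing member '%s'", path, member)
    }
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE,
                                  simplifyMatrix = FALSE)
  stacks <- lapply(c(clean = "clean", artifact = "artifact",
                     residual = "residual"), function(f) {
    a <- as.array(RNifti::readNifti(file.path(path, paste0(f, ".nii.gz"))))
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    if (dim(a)[3L] != manifest$n_samples) {
      stop_msg("member '%s.nii.gz' holds %d slices but manifest records %d",
               f, dim(a)[3L], manifest$n_samples)
    }
    a
  })
  samples <- vector("list", manifest$n_samples)
  for (i in seq_len(manifest$n_samples)) {
    samples[[i]] <- structure(
      list(clean = stacks$clean[, , i],
           artifact = stacks$artifact[, , i],
           residual = stacks$residual[, , i],
           subject = manifest$subject[i],
           slice_index = as.integer(manifest$slice_index[i]),
           schedule = schedule_from_list(manifest$schedules[[i]])),
      class = "paired_sample"
    )
  }
  split <- NULL
  if (!is.null(manifest$split)) {
    sp <- manifest$split
    split <- structure(
      list(train = as.integer(sp$train),
           validation = as.integer(sp$validation),
           test = as.integer(sp$test),
           fractions = as.numeric(sp$fractions),
           seed = as.integer(sp$seed), by_subject = isTRUE(sp$by_subject)),
      class = "dataset_split"
    )
  }
  list(samples = samples, split = split)
}
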