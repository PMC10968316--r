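test_that("pair building conserves slice counts and residual algebra", {
  vols <- list(A = make_volume(16, 6), B = make_volume(16, 6, seed = 2))
  samples <- build_pairs(vols, simulation_params(), seed = 3)
  expect_length(samples, 12)
  expect_setequal(unique(vapply(samples, `[[`, character(1), "subject")),
                  c("A", "B"))
  for (s in samples) {
    expect_identical(s$clean + s$residual, s$artifact)
    expect_equal(dim(s$clean), dim(s$artifact))
    expect_equal(dim(s$clean), dim(s$residual))
  }
  # single-slice volume gives a single sample
  one <- build_pairs(list(make_volume(16, 1)),
                     simulation_params(n_movements_range = c(0, 0)), seed = 1)
  expect_length(one, 1)
})

test_that("splitting uses floor sizes with the remainder in train", {
  samples <- build_pairs(list(make_volume(16, 10)), simulation_params(),
                         seed = 1)
  sp <- split_dataset(samples, c(0.7, 0.1, 0.2), seed = 5)
  expect_length(sp$train, 7)
  expect_length(sp$validation, 1)
  expect_length(sp$test, 2)
  # disjoint and exhaustive
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all_idx, seq_along(samples))
  expect_length(all_idx, length(samples))
  # deterministic
  expect_identical(sp, split_dataset(samples, c(0.7, 0.1, 0.2), seed = 5))
  expect_false(identical(sp$train,
                         split_dataset(samples, c(0.7, 0.1, 0.2),
                                       seed = 6)$train))
  expect_error(split_dataset(samples, c(0.5, 0.2, 0.2)), "fractions")
})

test_that("subject-level splitting never leaks a subject across partitions", {
  vols <- lapply(1:6, function(i) make_volume(16, 4, seed = i))
  names(vols) <- sprintf("P%02d", 1:6)
  samples <- build_pairs(vols, simulation_params(), seed = 2)
  sp <- split_dataset(samples, c(0.7, 0.1, 0.2), seed = 3, by_subject = TRUE)
  subj <- vapply(samples, `[[`, character(1), "subject")
  parts <- list(subj[sp$train], subj[sp$validation], subj[sp$test])
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_length(intersect(parts[[i]], parts[[j]]), 0)
    }
  }
  expect_setequal(c(sp$train, sp$validation, sp$test), seq_along(samples))
})

test_that("dataset containers round-trip samples and split exactly", {
  samples <- build_pairs(list(make_volume(16, 5)), simulation_params(),
                         seed = 7)
  sp <- split_dataset(samples, seed = 7)
  dir <- withr::local_tempdir()
  save_dataset(samples, sp, dir)
  back <- load_dataset(dir)
  expect_length(back$samples, length(samples))
  for (i in seq_along(samples)) {
    expect_identical(back$samples[[i]]$clean, samples[[i]]$clean)
    expect_identical(back$samples[[i]]$artifact, samples[[i]]$artifact)
    expect_identical(back$samples[[i]]$residual, samples[[i]]$residual)
    expect_equal(back$samples[[i]]$schedule, samples[[i]]$schedule)
  }
  expect_equal(back$split$train, sp$train)
  expect_equal(back$split$test, sp$test)
})

test_that("float32 storage is exact after one quantization", {
  samples <- build_pairs(list(make_volume(16, 3)), simulation_params(),
                         seed = 7)
  d1 <- withr::local_tempdir()
  save_dataset(samples, NULL, d1, datatype = "float")
  b1 <- load_dataset(d1)$samples
  d2 <- withr::local_tempdir()
  save_dataset(b1, NULL, d2, datatype = "float")
  b2 <- load_dataset(d2)$samples
  for (i in seq_along(b1)) {
    expect_identical(b1[[i]]$artifact, b2[[i]]$artifact)
  }
})

test_that("corrupt containers fail loudly, naming the missing member", {
  samples <- build_pairs(list(make_volume(16, 3)), simulation_params(),
                         seed = 7)
  dir <- withr::local_tempdir()
  save_dataset(samples, NULL, dir)
  unlink(file.path(dir, "residual.nii.gz"))
  expect_error(load_dataset(dir), "residual")
})
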