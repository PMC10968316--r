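test_that("forward transform basics: zero slice, impulse, Parseval", {
  z <- matrix(0, 16, 16)
  expect_true(all(slice_to_kspace(z)$data == 0))
  # unit impulse at the center maps to constant magnitude
  d <- matrix(0, 16, 16)
  d[9, 9] <- 1  # center for even size: index n/2 + 1
  kd <- slice_to_kspace(d)
  expect_equal(Mod(kd$data), matrix(1, 16, 16), tolerance = 1e-12,
               ignore_attr = TRUE)
  # Parseval under the unnormalized-forward convention
  s <- make_volume(32, 4)$data[, , 2]
  k <- slice_to_kspace(s)
  expect_equal(sum(s^2), sum(Mod(k$data)^2) / length(s), tolerance = 1e-9)
})

test_that("k-space of a real slice is conjugate-symmetric", {
  s <- make_volume(16, 4)$data[, , 2]
  k <- slice_to_kspace(s)$data
  n <- nrow(k)
  # in centered layout, K(-u,-v) = conj(K(u,v)); index map i -> 2*(n/2+1)-i
  for (i in 2:n) {
    for (j in 2:n) {
      expect_equal(k[i, j], Conj(k[n + 2 - i, n + 2 - j]), tolerance = 1e-8)
    }
  }
})

test_that("inverse transform round-trips and handles degenerate input", {
  s <- make_volume(32, 4, noise_sd = 0.01, seed = 3)$data[, , 2]
  expect_lt(max(abs(kspace_to_image(slice_to_kspace(s)) - s)), 1e-9)
  expect_true(all(kspace_to_image(slice_to_kspace(matrix(0, 8, 8))) == 0))
  # magnitude reconstruction is real and nonnegative even for asymmetric input
  k <- slice_to_kspace(s)
  k$data[3, ] <- k$data[3, ] * 2i  # break conjugate symmetry
  img <- kspace_to_image(k)
  expect_true(all(is.finite(img)) && all(img >= 0))
  expect_error(slice_to_kspace(array(0, c(4, 4, 2))), "2D")
})

test_that("acquisition orderings are bijective and centric starts centrally", {
  expect_identical(acquisition_line_order(4, "linear"), 1:4)
  expect_identical(acquisition_line_order(4, "centric"), c(3L, 2L, 4L, 1L))
  for (n in c(5, 8, 17)) {
    for (o in c("linear", "centric")) {
      expect_setequal(acquisition_line_order(n, o), seq_len(n))
    }
  }
  expect_error(acquisition_line_order(4, "spiral"))
})

test_that("line replacement takes each line from the active motion state", {
  set.seed(8)
  s <- matrix(runif(64), 8, 8)
  k <- slice_to_kspace(s)
  # empty schedule: untouched, provenance all zero
  out0 <- compose_kspace(k, list(), motion_schedule(list(), 8))
  expect_identical(out0$kspace$data, k$data)
  expect_identical(out0$provenance, rep(0L, 8))
  # one event at acquisition position 5 (0-based): last 3 lines replaced
  k1 <- slice_to_kspace(s * 0.5)
  out1 <- compose_kspace(k, list(k1),
                         motion_schedule(list(motion_event(5)), 8))
  expect_identical(out1$provenance, c(rep(0L, 5), rep(1L, 3)))
  expect_identical(out1$kspace$data[1:5, ], k$data[1:5, ])
  expect_identical(out1$kspace$data[6:8, ], k1$data[6:8, ])
  # mismatched state count errors
  expect_error(compose_kspace(k, list(), motion_schedule(list(motion_event(5)), 8)),
               "states")
})

test_that("composition matches a naive per-line walk on random instances", {
  naive <- function(kc, kstates, onsets, perm) {
    out <- kc
    prov <- integer(nrow(kc))
    for (pos in seq_along(perm)) {
      state <- sum(onsets <= pos - 1)
      prov[perm[pos]] <- state
      out[perm[pos], ] <- if (state == 0) kc[perm[pos], ]
                          else kstates[[state]][perm[pos], ]
    }
    list(out = out, prov = prov)
  }
  set.seed(99)
  for (trial in 1:25) {
    n <- sample(4:16, 1)
    n_ev <- sample(0:3, 1)
    kc <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
    ks <- replicate(n_ev, matrix(complex(real = rnorm(n * n),
                                         imaginary = rnorm(n * n)), n, n),
                    simplify = FALSE)
    onsets <- sort(sample(0:(n - 1), n_ev))
    if (n_ev && any(diff(onsets) == 0)) next
    ordering <- sample(c("linear", "centric"), 1)
    sched <- motion_schedule(lapply(onsets, motion_event), n)
    kobj <- structure(list(data = kc, phase_axis = 1L, layout = "centered"),
                      class = "kspace")
    got <- compose_kspace(kobj, ks, sched, ordering)
    want <- naive(kc, ks, onsets, acquisition_line_order(n, ordering))
    expect_identical(got$kspace$data, want$out)
    expect_identical(got$provenance, as.integer(want$prov))
  }
})

test_that("zero or identity motion reproduces the input slice", {
  v <- make_volume(32, 6)
  p0 <- simulation_params(n_movements_range = c(0, 0))
  sim <- simulate_artifact_slice(v, 3, p0, seed = 5)
  expect_lt(max(abs(sim$artifact - v$data[, , 3])), 1e-6)
  expect_lt(max(abs(sim$residual)), 1e-6)
  # a single identity-transform event also leaves the slice unchanged
  sched <- motion_schedule(list(motion_event(20)), 32)
  ns <- asNamespace("mrmotionsim")
  sim1 <- ns$simulate_slice_core(v, 3, sched, simulation_params())
  expect_lt(max(abs(sim1$residual)), 1e-6)
})

test_that("simulated artifacts are nontrivial and algebraically consistent", {
  v <- make_volume(32, 6)
  sim <- simulate_artifact_slice(v, 3, simulation_params(), seed = 11)
  expect_gt(rmse(v$data[, , 3], sim$artifact), 0)
  expect_identical(v$data[, , 3] + sim$residual, sim$artifact)
  # energy is redistributed, not grossly amplified
  expect_lt(sum(sim$artifact^2), 2 * sum(v$data[, , 3]^2) + 1e-9)
})

test_that("volume simulation is deterministic and consistent with per-slice runs", {
  v <- make_volume(24, 5)
  p <- simulation_params()
  a <- simulate_artifact_volume(v, p, seed = 2)
  b <- simulate_artifact_volume(v, p, seed = 2)
  expect_identical(a$artifact$data, b$artifact$data)
  expect_equal(dim(a$artifact$data), dim(v$data))
  expect_length(a$schedules, 5)
  # single-slice simulation agrees with the volume run
  s3 <- simulate_artifact_slice(v, 3, p, seed = 2)
  expect_identical(s3$artifact, a$artifact$data[, , 3])
  expect_identical(s3$schedule, a$schedules[[3]])
  # shared-schedule mode: one schedule for all slices
  ps <- simulation_params(per_slice_independent = FALSE)
  sh <- simulate_artifact_volume(v, ps, seed = 2)
  expect_length(sh$schedules, 1)
})
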