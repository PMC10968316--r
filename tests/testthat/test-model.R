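test_that("encoder channels start at base and double per level", {
  ns <- asNamespace("mrmotionsim")
  expect_identical(ns$unet_channels(4L, 64L), c(64L, 128L, 256L, 512L))
  m <- build_unet(unet_config(depth = 3, base_channels = 4, seed = 1))
  expect_identical(m$channels, c(4L, 8L, 16L))
  # each level's second conv maps within that level's channel count
  expect_equal(dim(m$params$enc2_c2_W), c(3, 3, 8, 8))
  # bottleneck doubles once more
  expect_equal(dim(m$params$bott_c1_W)[4], 32)
  # decoder halves back down to the base and the head maps to one channel
  expect_equal(dim(m$params$dec1_c2_W), c(3, 3, 4, 4))
  expect_equal(dim(m$params$out_W), c(4L, 1L))
})

test_that("network output preserves spatial shape and rejects bad sizes", {
  cfg <- unet_config(depth = 2, base_channels = 4, seed = 2)
  m <- build_unet(cfg)
  out <- predict_slice(m, matrix(runif(32 * 32), 32))
  expect_equal(dim(out), c(32L, 32L))
  out2 <- predict_slice(m, matrix(runif(16 * 48), 16, 48))
  expect_equal(dim(out2), c(16L, 48L))
  expect_error(predict_slice(m, matrix(0, 30, 30)), "divisible")
})

test_that("builds are deterministic given the config seed", {
  a <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 7))
  b <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 7))
  expect_identical(a$params, b$params)
  c <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 8))
  expect_false(identical(a$params, c$params))
})

test_that("backpropagated gradients match central finite differences", {
  ns <- asNamespace("mrmotionsim")
  m <- build_unet(unet_config(depth = 1, base_channels = 2, seed = 3))
  m$params$out_W[] <- 0.1  # nonzero head so all layers receive gradient
  set.seed(1)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  tgt <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  fw <- ns$unet_forward(m, x, training = TRUE)
  grads <- ns$unet_backward(m, fw$tape, 2 * (fw$y - tgt) / length(tgt))
  lossat <- function(mm) mean((ns$unet_forward(mm, x, TRUE)$y - tgt)^2)
  eps <- 1e-5
  set.seed(2)
  for (nm in names(grads)) {
    j <- sample(length(grads[[nm]]), 1)
    mp <- m; mp$params[[nm]][j] <- mp$params[[nm]][j] + eps
    mn <- m; mn$params[[nm]][j] <- mn$params[[nm]][j] - eps
    num <- (lossat(mp) - lossat(mn)) / (2 * eps)
    expect_equal(grads[[nm]][j], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s", nm))
  }
})

test_that("training runs, records losses, and can overfit a small set", {
  vols <- list(make_volume(32, 8, noise_sd = 0.01, seed = 31))
  samples <- build_pairs(vols, simulation_params(), seed = 5)
  cfg <- unet_config(depth = 2, base_channels = 4, epochs = 30,
                     batch_size = 4, learning_rate = 2e-3,
                     mode = "direct", seed = 6)
  m0 <- build_unet(cfg)
  # epochs = 0 leaves the model untouched
  expect_identical(train_unet(m0, samples, epochs = 0), m0)
  m <- train_unet(m0, samples)
  expect_length(m$loss_history, 30)
  expect_lt(m$loss_history[30], 0.1 * m$loss_history[1])
})

test_that("the two training modes differ only in the target tensor", {
  vols <- list(make_volume(32, 6, noise_sd = 0.01, seed = 31))
  samples <- build_pairs(vols, simulation_params(), seed = 5)
  mk <- function(mode) unet_config(depth = 2, base_channels = 4, epochs = 2,
                                   batch_size = 4, learning_rate = 1e-3,
                                   mode = mode, seed = 6)
  md <- train_unet(build_unet(mk("direct")), samples)
  mr <- train_unet(build_unet(mk("residual")), samples)
  # identical initialization, different losses because targets differ
  expect_identical(build_unet(mk("direct"))$params,
                   build_unet(mk("residual"))$params)
  expect_false(identical(md$loss_history, mr$loss_history))
})

test_that("residual-mode correction is algebraically exact", {
  m <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 2,
                              mode = "residual"))
  a <- matrix(runif(32 * 32, 0.2, 1), 32)
  pred <- predict_slice(m, a)
  corrected <- correct_image(m, a)
  # corrected + predicted residual reproduces the artifact (before clipping)
  expect_equal(corrected, pmax(a - pred, 0))
  expect_true(all(corrected >= 0))
  # a network predicting the true residual recovers the clean slice exactly:
  # the untrained zero-head network predicts a zero residual, so correction
  # of an artifact equal to clean + 0 returns the clean image
  expect_equal(correct_image(m, a), a, tolerance = 1e-12)
  # direct mode returns the network output itself
  md <- build_unet(unet_config(depth = 2, base_channels = 4, seed = 2,
                               mode = "direct"))
  expect_equal(correct_image(md, a), pmax(predict_slice(md, a), 0))
})
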