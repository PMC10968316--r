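test_that("rmse matches hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1.0)
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  expect_error(rmse(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("psnr follows its closed form and decreases with rmse", {
  f <- c(0, 1)  # s_peak = 1
  expect_equal(psnr(c(1, 1), c(0.5, 1.5), s_peak = 0.5), 0)  # rmse == s_peak
  g <- c(0.1, 1.1)  # rmse = 0.1
  expect_equal(psnr(f, g), 20)
  g2 <- c(0.05, 1.05)  # rmse halved
  expect_equal(psnr(f, g2) - psnr(f, g), 20 * log10(2))
  expect_identical(psnr(f, f), Inf)
  # strictly decreasing in rmse at fixed peak
  es <- c(0.5, 0.2, 0.1, 0.01)
  ps <- vapply(es, function(e) psnr(c(0, 1), c(e, 1), s_peak = 1), numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("cc is a Pearson correlation with its symmetries", {
  f <- matrix(runif(16, 0, 1), 4)
  expect_equal(cc(f, f), 1)
  expect_equal(cc(f, 2.5 * f + 0.3), 1)
  expect_equal(cc(f, -f), -1)
  expect_error(cc(f, matrix(1, 4, 4)), "constant")
})

test_that("uqi matches the printed formula evaluated by hand", {
  f <- matrix(runif(16, 0.2, 1), 4)
  expect_equal(uqi(f, f), 1)
  g <- f + matrix(rnorm(16, 0, 0.1), 4)
  expect_equal(uqi(f, g), uqi(g, f))
  # brute-force evaluation on a 4-pixel pair
  fv <- c(1, 2, 3, 4); gv <- c(1, 2, 3, 5)
  mf <- mean(fv); mg <- mean(gv)
  vf <- mean((fv - mf)^2); vg <- mean((gv - mg)^2)
  sfg <- mean((fv - mf) * (gv - mg))
  expect_equal(uqi(fv, gv), 4 * mf * mg * sfg / ((mf^2 + mg^2) * (vf + vg)))
  # optimum only at equality
  expect_lt(uqi(fv, gv), 1)
})

test_that("k-means segmentation separates intensity classes", {
  two <- matrix(rep(c(0, 1), each = 32), 8)
  lab <- kmeans_segment(two, k = 2, seed = 1)
  expect_identical(lab == 1, two == 1)
  expect_identical(lab, kmeans_segment(two, k = 2, seed = 1))
  expect_error(kmeans_segment(matrix(1:2 / 2, 2), k = 3), "distinct")
})

test_that("k-means recovers phantom tissue labels at low noise", {
  ph <- make_phantom(48, 9, noise_sd = 0.01, seed = 5)
  z <- 5  # middle slice contains all four classes
  truth <- ph$labels[, , z]
  expect_length(unique(as.vector(truth)), 4)
  lab <- kmeans_segment(ph$volume$data[, , z], k = 4, seed = 2)
  expect_gte(mean(lab == truth), 0.99)
})

test_that("COV and CNR match closed forms and invariances", {
  img <- matrix(c(1, 3, 5, 5), 2)
  m_b <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(cov_background(img, m_b), 0.5)  # sd 1 (population), mean 2
  expect_equal(cov_background(img * 4.2, m_b), 0.5)  # scale invariance
  expect_equal(cov_background(matrix(2, 2, 2), matrix(TRUE, 2, 2)), 0)
  # CNR: tissue (7, 13): mean 10, sd 3; background (-2, 6): mean 2, sd 4
  img2 <- matrix(c(7, 13, -2, 6), 2)
  m_t <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  m_b2 <- !m_t
  expect_equal(cnr(img2, m_t, m_b2), 1.6)
  expect_equal(cnr(img2 + 11, m_t, m_b2), 1.6)  # shift invariance
  expect_error(cnr(img2 * 0 + 5, m_t, m_b2), "constant")
})

test_that("paired t-test reduces to its closed form", {
  expect_equal(paired_ttest(1:5, 1:5), list(t = 0, p = 1))
  a <- c(2, 3, 4, 6); b <- c(1, 2, 3, 4)  # differences 1,1,1,2
  d <- a - b
  want_t <- mean(d) / (sd(d) / sqrt(length(d)))
  got <- paired_ttest(a, b)
  expect_equal(got$t, want_t)
  expect_gt(got$p, 0)
  expect_lte(got$p, 1)
  expect_error(paired_ttest(c(1, 2), c(0, 1)), "constant")
})

test_that("pair evaluation aggregates correctly", {
  refs <- lapply(1:4, function(i) make_volume(16, 4, noise_sd = 0.01,
                                              seed = i)$data[, , 2])
  # comparisons equal to references: perfect scores, zero spread
  rep0 <- evaluate_pairs(refs, refs)
  expect_equal(rep0$aggregate$mean[rep0$aggregate$metric == "rmse"], 0)
  expect_equal(rep0$aggregate$sd[rep0$aggregate$metric == "uqi"], 0)
  expect_equal(rep0$per_pair$cc, rep(1, 4))
  expect_equal(rep0$n_infinite_psnr, 4)
  # noisy comparisons: aggregate equals the mean of per-pair values
  cmps <- lapply(refs, function(r) pmax(r + rnorm(length(r), 0, 0.05), 0))
  rep1 <- evaluate_pairs(refs, cmps)
  expect_equal(rep1$aggregate$mean[rep1$aggregate$metric == "rmse"],
               mean(rep1$per_pair$rmse))
  # single pair: sd degenerates to zero
  rep2 <- evaluate_pairs(refs[1], cmps[1])
  expect_true(all(rep2$aggregate$sd == 0))
  # paired tests between two methods
  rep3 <- evaluate_pairs(refs, cmps, comparisons2 = lapply(refs, `+`, 0.01))
  expect_true(all(vapply(rep3$tests, function(t) t$p, numeric(1)) <= 1))
})
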