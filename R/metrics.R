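# Population (divide-by-N) moments: the metric definitions are plain sums
# over pixels, so the population convention is used throughout this module.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
pop_cov <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

check_pair <- function(f, g) {
  if (is.null(dim(f))) f <- as.matrix(f)
  if (is.null(dim(g))) g <- as.matrix(g)
  if (!all(dim(f) == dim(g))) {
    stop_msg("image shapes differ: %s vs %s",
             paste(dim(f), collapse = "x"), paste(dim(g), collapse = "x"))
  }
  list(f = as.numeric(f), g = as.numeric(g))
}

#' Root mean square error between a reference and comparison image
#'
#' `sqrt(sum((f - g)^2) / N)` with `N` the pixel count.
#'
#' @param f reference image (matrix or vector).
#' @param g comparison image, same shape.
#' @return Nonnegative scalar.
#' @export
rmse <- function(f, g) {
  p <- check_pair(f, g)
  sqrt(mean((p$f - p$g)^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(s_peak^2 / rmse^2)`. `s_peak` defaults to the maximum
#' intensity of the reference image over the whole frame (an explicit
#' region-of-interest maximum can be passed instead). Identical images give
#' `Inf`, reported as a sentinel rather than an error so batch evaluation can
#' proceed.
#'
#' @param f reference image.
#' @param g comparison image.
#' @param s_peak peak signal intensity; default `max(f)`.
#' @return PSNR in dB (`Inf` when `f == g`).
#' @export
psnr <- function(f, g, s_peak = NULL) {
  if (is.null(s_peak)) s_peak <- max(f)
  if (s_peak <= 0) stop_msg("s_peak must be positive")
  e <- rmse(f, g)
  if (e == 0) return(Inf)
  10 * log10(s_peak^2 / e^2)
}

#' Pearson correlation coefficient between two images
#'
#' @param f reference image (non-constant).
#' @param g comparison image (non-constant).
#' @return Value in `[-1, 1]`.
#' @export
cc <- function(f, g) {
  p <- check_pair(f, g)
  if (pop_sd(p$f) == 0 || pop_sd(p$g) == 0) {
    stop_msg("correlation is undefined for a constant image")
  }
  stats::cor(p$f, p$g)
}

#' Universal image quality index
#'
#' `4 * mu_f * mu_g * sigma_fg / ((mu_f^2 + mu_g^2) * (sigma_f^2 +
#' sigma_g^2))`, computed globally over the image (no sliding window). The
#' index combines luminance, contrast and correlation agreement and equals 1
#' only when the images are identical.
#'
#' @param f reference image.
#' @param g comparison image.
#' @return Value in `[-1, 1]`.
#' @export
uqi <- function(f, g) {
  p <- check_pair(f, g)
  mf <- mean(p$f); mg <- mean(p$g)
  vf <- mean((p$f - mf)^2); vg <- mean((p$g - mg)^2)
  denom <- (mf^2 + mg^2) * (vf + vg)
  if (denom == 0) stop_msg("UQI denominator is zero (constant zero-mean images)")
  4 * mf * mg * pop_cov(p$f, p$g) / denom
}

#' Intensity-based k-means segmentation of a slice
#'
#' Clusters pixel intensities with k-means and relabels clusters by ascending
#' mean, so label 0 is always the darkest cluster (background/air) and label
#' `k - 1` the brightest (CSF-like on T2-weighted images). Used to derive the
#' background and gray-matter masks for the reference-free COV/CNR metrics.
#'
#' @param image 2D matrix.
#' @param k number of clusters (default 4: background, white-, gray-,
#'   CSF-like).
#' @param seed integer seed; the primary initialization (centers evenly
#'   spaced over the intensity range) is deterministic, and the seed governs
#'   the random-restart fallback used if it degenerates.
#' @return Integer label matrix (values `0:(k-1)`), with attribute
#'   `"centers"` giving the ascending cluster means.
#' @export
kmeans_segment <- function(image, k = 4L, seed = 1L) {
  if (!is.matrix(image)) stop_msg("image must be a 2D matrix")
  if (!is_count(k, min = 2L)) stop_msg("k must be an integer >= 2")
  x <- as.numeric(image)
  if (length(unique(x)) < k) {
    stop_msg("image has fewer than k = %d distinct intensities", k)
  }
  # intensity clustering with heavily imbalanced classes (background air
  # dominates, CSF is small): centers spread evenly over the intensity range
  # give Lloyd's algorithm a start near every mode, unlike random subsets
  init <- matrix(min(x) + (2 * seq_len(k) - 1) / (2 * k) * (max(x) - min(x)),
                 ncol = 1L)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(x, centers = init, iter.max = 100L)),
    error = function(e) NULL
  )
  if (is.null(km) || isTRUE(km$ifault > 2) ||
      length(unique(km$cluster)) < k) {
    km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 25L,
                                        iter.max = 100L))
  }
  ord <- order(km$centers)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k) - 1L
  lab <- matrix(relabel[km$cluster], nrow(image), ncol(image))
  attr(lab, "centers") <- as.numeric(km$centers[ord])
  lab
}

#' Coefficient of variation of the background signal
#'
#' `sigma_b / mu_b` over the masked background (air) pixels, population SD.
#' Motion artifacts spray signal into the air, so a lower background COV
#' after correction indicates more effective artifact removal.
#'
#' @param image 2D matrix.
#' @param background_mask logical matrix selecting background pixels.
#' @return Nonnegative scalar.
#' @export
cov_background <- function(image, background_mask) {
  b <- image[background_mask]
  if (!length(b)) stop_msg("background mask is empty")
  mu <- mean(b)
  if (mu <= 0) stop_msg("background mean must be positive for COV")
  pop_sd(b) / mu
}

#' Contrast-to-noise ratio between tissue and background
#'
#' `(mu_t - mu_b) / sqrt(sigma_t^2 + sigma_b^2)` with population SDs;
#' measures how well tissue signal is maintained relative to combined
#' tissue/background variability.
#'
#' @param image 2D matrix.
#' @param tissue_mask logical matrix selecting tissue (gray-matter) pixels.
#' @param background_mask logical matrix selecting background pixels.
#' @return Scalar (can be negative if tissue is darker than background).
#' @export
cnr <- function(image, tissue_mask, background_mask) {
  t_px <- image[tissue_mask]
  b_px <- image[background_mask]
  if (!length(t_px) || !length(b_px)) stop_msg("CNR masks must be non-empty")
  denom <- sqrt(pop_sd(t_px)^2 + pop_sd(b_px)^2)
  if (denom == 0) stop_msg("CNR undefined: both regions are constant")
  (mean(t_px) - mean(b_px)) / denom
}

#' Two-sided paired t-test on per-pair metric values
#'
#' @param a,b equal-length numeric vectors (metric per pair under two
#'   methods).
#' @return A list with `t` and `p`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stop_msg("paired t-test needs two equal-length vectors of length >= 2")
  }
  d <- a - b
  if (pop_sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1))
    stop_msg("paired differences are constant; t statistic undefined")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Evaluate image similarity over a set of pairs
#'
#' Computes RMSE, PSNR, UQI and CC for every reference/comparison pair and
#' aggregates each metric as mean +/- SD (population SD, consistent with the
#' per-pair formulas). When a second comparison set is supplied, paired
#' t-tests between the two methods are added for every metric. Pairs with
#' infinite PSNR (identical images) are flagged and excluded from the PSNR
#' aggregate.
#'
#' @param references list of reference images.
#' @param comparisons list of comparison images, same length.
#' @param comparisons2 optional second comparison method for paired testing.
#' @param s_peak peak signal for PSNR; default per-pair `max(reference)`.
#' @return An object of class `metrics_report`: `per_pair` (data.frame),
#'   `aggregate` (data.frame of mean/sd per metric), and optionally `tests`.
#' @export
evaluate_pairs <- function(references, comparisons, comparisons2 = NULL,
                           s_peak = NULL) {
  if (length(references) != length(comparisons)) {
    stop_msg("reference and comparison lists differ in length")
  }
  eval_one <- function(cmp) {
    data.frame(
      rmse = vapply(seq_along(references),
                    function(i) rmse(references[[i]], cmp[[i]]), numeric(1)),
      psnr = vapply(seq_along(references),
                    function(i) psnr(references[[i]], cmp[[i]], s_peak),
                    numeric(1)),
      uqi = vapply(seq_along(references),
                   function(i) uqi(references[[i]], cmp[[i]]), numeric(1)),
      cc = vapply(seq_along(references),
                  function(i) cc(references[[i]], cmp[[i]]), numeric(1))
    )
  }
  per_pair <- eval_one(comparisons)
  agg <- do.call(rbind, lapply(names(per_pair), function(m) {
    x <- per_pair[[m]]
    if (m == "psnr") x <- x[is.finite(x)]
    data.frame(metric = m, mean = mean(x), sd = pop_sd(x))
  }))
  report <- list(per_pair = per_pair, aggregate = agg,
                 n_infinite_psnr = sum(!is.finite(per_pair$psnr)))
  if (!is.null(comparisons2)) {
    per_pair2 <- eval_one(comparisons2)
    report$per_pair2 <- per_pair2
    report$tests <- lapply(stats::setNames(nm = names(per_pair)), function(m) {
      a <- per_pair[[m]]; b <- per_pair2[[m]]
      keep <- is.finite(a) & is.finite(b)
      paired_ttest(a[keep], b[keep])
    })
  }
  structure(report, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d pair(s)\n", nrow(x$per_pair)))
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %-5s %8.4f +/- %.4f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  }
  if (!is.null(x$tests)) {
    for (m in names(x$tests)) {
      cat(sprintf("  paired t-test (%s): t = %.3f, p = %.3g\n",
                  m, x$tests[[m]]$t, x$tests[[m]]$p))
    }
  }
  invisible(x)
}
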