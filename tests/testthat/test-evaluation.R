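make_roi_fixture <- function(seed = 1) {
  set.seed(seed)
  grid <- c(12, 12, 12)
  ref <- blob_volume(grid, n_blobs = 3, sigma = 2.5, seed = seed) + 0.05
  roi <- array(FALSE, grid)
  roi[3:10, 3:10, 3:10] <- TRUE
  ref <- ref / max(ref[roi])       # reference convention: ROI maximum is 1
  list(ref = ref, roi = roi, grid = grid)
}

test_that("scaled ROI MSE has its closed form and scale invariance", {
  fx <- make_roi_fixture()
  r <- scaled_roi_mse(fx$ref, fx$ref, fx$roi)
  expect_equal(r$mse, 0)
  expect_equal(r$scale, 1)
  r2 <- scaled_roi_mse(2 * fx$ref, fx$ref, fx$roi)
  expect_equal(r2$mse, 0, tolerance = 1e-14)
  expect_equal(r2$scale, 0.5, tolerance = 1e-12)
  # closed-form alpha matches a brute-force scan
  set.seed(2)
  recon <- fx$ref + array(stats::rnorm(prod(fx$grid), sd = 0.1), fx$grid)
  rc <- scaled_roi_mse(recon, fx$ref, fx$roi)
  alphas <- seq(0.01, 3, length.out = 10000)
  rm <- Mod(fx$ref)[fx$roi]; rm <- rm / max(rm)
  cm <- Mod(recon)[fx$roi]
  mses <- vapply(alphas, function(a) mean((rm - a * cm)^2), 0)
  expect_lt(abs(rc$scale - alphas[which.min(mses)]), diff(alphas[1:2]))
  expect_lte(rc$mse, min(mses))
  # invariance to global complex scaling of the reconstruction
  c0 <- complex(real = -1.3, imaginary = 0.7)
  rs <- scaled_roi_mse(c0 * recon, fx$ref, fx$roi)
  expect_lt(abs(rs$mse - rc$mse), 1e-12)
  expect_error(scaled_roi_mse(0 * recon, fx$ref, fx$roi), "zero")
  expect_error(scaled_roi_mse(recon, fx$ref, array(FALSE, fx$grid)), "ROI")
})

test_that("scaled ROI SSIM is 1 for identical images and optimization helps", {
  fx <- make_roi_fixture()
  expect_equal(scaled_roi_ssim(fx$ref, fx$ref, fx$roi)$ssim, 1, tolerance = 1e-6)
  set.seed(3)
  recon <- 0.4 * fx$ref + array(stats::rnorm(prod(fx$grid), sd = 0.05), fx$grid)
  opt <- scaled_roi_ssim(recon, fx$ref, fx$roi)
  # compare against the un-optimized scale 1 on normalized magnitudes
  idx <- which(fx$roi, arr.ind = TRUE)
  bb <- lapply(1:3, function(a) seq.int(min(idx[, a]), max(idx[, a])))
  rm <- Mod(fx$ref); rm <- rm / max(rm[fx$roi])
  cmn <- Mod(recon); cmn <- cmn / max(cmn[fx$roi])
  s1 <- supermoco:::ssim3(cmn[bb[[1]], bb[[2]], bb[[3]]],
                          rm[bb[[1]], bb[[2]], bb[[3]]])
  expect_gte(opt$ssim, s1 - 1e-9)
  # SSIM degrades monotonically with additive noise
  set.seed(4)
  noise <- array(stats::rnorm(prod(fx$grid)), fx$grid)
  vals <- vapply(c(0.01, 0.05, 0.1), function(s)
    scaled_roi_ssim(fx$ref + s * noise, fx$ref, fx$roi)$ssim, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("vessel sharpness hits its analytic anchors", {
  grid <- c(24, 24, 8)
  ctr <- cbind(seq(4, 20, length.out = 9), 12, 4)
  # ideal step tube: transition within one voxel
  X <- array(rep(seq_len(grid[1]) - 1, times = grid[2] * grid[3]), grid)
  Y <- aperm(array(rep(seq_len(grid[2]) - 1, times = grid[1] * grid[3]),
                   grid[c(2, 1, 3)]), c(2, 1, 3))
  step_img <- array(0.1, grid)
  step_img[abs(Y - 12) <= 2] <- 1
  expect_equal(vessel_sharpness(step_img, ctr, voxel_size = 1), 100,
               tolerance = 1e-6)
  # constant image: no edge
  expect_equal(vessel_sharpness(array(0.7, grid), ctr, voxel_size = 1), 0)
  # linear ramp over 5 voxels: 20-80% distance of 3 voxels -> 33.3%
  dist <- abs(Y - 12)
  ramp <- array(pmax(0, pmin(1, (5 - dist) / 5)), grid)
  s <- vessel_sharpness(ramp, ctr, voxel_size = 1, halfwidth_vox = 8)
  expect_lt(abs(s - 100 / 3), 4)
  # invariance to intensity scaling and offset
  s2 <- vessel_sharpness(5 * ramp + 2, ctr, voxel_size = 1, halfwidth_vox = 8)
  expect_lt(abs(s - s2), 1e-9)
  expect_error(vessel_sharpness(ramp, ctr[1, , drop = FALSE], 1), "two")
})

test_that("paired comparisons apply Bonferroni thresholds", {
  set.seed(8)
  va <- stats::rnorm(10); vb <- va + 0.5 + stats::rnorm(10, sd = 0.3)
  r15 <- paired_comparison(va, vb, test = "t", n_comparisons = 15)
  expect_equal(r15$threshold, 0.05 / 15)
  expect_lt(abs(r15$threshold - 0.0033), 2e-4)
  r6 <- paired_comparison(va, vb, test = "wilcoxon", n_comparisons = 6)
  expect_equal(r6$threshold, 0.05 / 6)
  expect_lt(abs(r6$threshold - 0.00833), 5e-5)
  same <- paired_comparison(1:8, 1:8, test = "t", n_comparisons = 15)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)
  expect_error(paired_comparison(1:5, 1:6), "length")
  # a strong consistent difference is significant even after correction
  set.seed(5)
  a <- stats::rnorm(20); b <- a + 2 + stats::rnorm(20, sd = 0.1)
  expect_true(paired_comparison(a, b, "t", 15)$significant)
})

test_that("metric report aggregation matches recomputed summaries", {
  df <- data.frame(subject = rep(1:5, 2),
                   metric = rep(c("mse", "ssim"), each = 5),
                   value = c(stats::runif(5), stats::runif(5)))
  rep_ <- metric_report(df)
  for (m in c("mse", "ssim")) {
    v <- df$value[df$metric == m]
    row <- rep_$summary[rep_$summary$metric == m, ]
    expect_identical(row$mean, mean(v))
    expect_identical(row$sd, stats::sd(v))
  }
})
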