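test_that("full-sampling trajectory covers every shutter point", {
  tj <- generate_vdcaspr(c(24, 20), undersampling = 1, n_heartbeats = 30, seed = 2)
  m <- sampling_mask(tj)
  sh <- elliptical_shutter(c(24, 20))
  expect_true(all(m[sh]))
  expect_true(all(!m[!sh]))
})

test_that("requested undersampling is achieved within 10%", {
  tj <- generate_vdcaspr(c(48, 40), undersampling = 4.5, n_heartbeats = 60, seed = 2)
  pts <- unique(do.call(rbind, tj$readouts))
  achieved <- sum(tj$shutter) / nrow(pts)
  expect_lt(abs(achieved - 4.5) / 4.5, 0.1)
  # sampling density decreases with elliptical radius
  prof <- measure_density_profile(sampling_mask(tj), n_annuli = 5)
  expect_gt(prof$density[1], prof$density[5])
})

test_that("trajectory generation is deterministic and validates inputs", {
  a <- generate_vdcaspr(c(32, 32), undersampling = 3, n_heartbeats = 40, seed = 9)
  b <- generate_vdcaspr(c(32, 32), undersampling = 3, n_heartbeats = 40, seed = 9)
  expect_identical(a$readouts, b$readouts)
  expect_error(generate_vdcaspr(c(32, 32), undersampling = 0.5, n_heartbeats = 10),
               "undersampling")
  expect_error(generate_vdcaspr(c(2, 2), undersampling = 1, n_heartbeats = 4),
               "too small")
  expect_error(generate_vdcaspr(c(32, 32), undersampling = 1, n_heartbeats = 2,
                                readouts_per_heartbeat = 4), "capacity")
})

make_inav_stack <- function(shifts) {
  base <- blob_volume(c(32, 32, 1), n_blobs = 4, sigma = 4, seed = 3)[, , 1]
  arr <- array(0, c(32, 32, nrow(shifts) + 1L))
  arr[, , 1] <- base
  for (i in seq_len(nrow(shifts))) {
    arr[, , i + 1] <- Re(supermoco:::translate2(base, shifts[i, ]))
  }
  arr
}

test_that("iNAV registration recovers injected shifts to sub-pixel accuracy", {
  inavs <- make_inav_stack(rbind(c(0, 0), c(3, -2), c(1.5, 0), c(-2.5, 1.5)))
  est <- estimate_inav_translations(inavs, reference = "first")
  expect_lt(max(abs(est$fh[2] - 0)), 1e-6)   # frame 2 is the unshifted copy
  expect_lt(abs(est$fh[3] - 3), 0.2)
  expect_lt(abs(est$lr[3] - (-2)), 0.2)
  expect_lt(abs(est$fh[4] - 1.5), 0.25)
  expect_lt(abs(est$fh[5] - (-2.5)), 0.25)
  expect_lt(abs(est$lr[5] - 1.5), 0.25)
})

test_that("identical navigators give zero shifts and flat templates error", {
  arr <- array(rep(blob_volume(c(16, 16, 1), seed = 1)[, , 1], 5), c(16, 16, 5))
  est <- estimate_inav_translations(arr)
  expect_true(all(est$fh == 0) && all(est$lr == 0))
  flat <- array(1, c(16, 16, 3))
  expect_error(estimate_inav_translations(flat), "flat")
})

test_that("translational correction is a unitary phase with exact inverse", {
  fx <- static_full_acquisition(grid = c(8, 8, 8))
  sig <- fx$truth$breathing
  sig$fh <- stats::runif(nrow(sig), -2, 2)
  sig$lr <- stats::runif(nrow(sig), -2, 2)
  corr <- apply_translational_correction(fx$raw, sig)
  for (h in c(1, 5)) {
    expect_equal(Mod(corr$kspace[[h]]), Mod(fx$raw$kspace[[h]]), tolerance = 1e-12)
  }
  sig0 <- sig; sig0$fh <- 0; sig0$lr <- 0
  expect_identical(apply_translational_correction(fx$raw, sig0)$kspace,
                   fx$raw$kspace)
  back <- sig; back$fh <- -sig$fh; back$lr <- -sig$lr
  rt <- apply_translational_correction(corr, back)
  expect_lt(max(Mod(rt$kspace[[3]] - fx$raw$kspace[[3]])), 1e-12)
  bad <- sig[1:3, ]
  expect_error(apply_translational_correction(fx$raw, bad), "heartbeats")
})

test_that("integer-shift correction equals a circular image shift", {
  fx <- static_full_acquisition(grid = c(8, 8, 8))
  ref <- fx$truth$bin_images[[fx$truth$reference_bin]]
  sig <- fx$truth$breathing
  sig$fh <- rep(2, nrow(sig)); sig$lr <- rep(3, nrow(sig))
  corr <- apply_translational_correction(fx$raw, sig)
  plan <- soft_gated_binning(corr, sig, n_bins = 1)
  zf <- zero_filled_recon(binned_kspace(corr, plan), fx$truth$coil_maps)[[1]]
  shifted <- supermoco:::circshift(ref, c(2, 3, 0))
  expect_lt(max(Mod(zf - shifted)), 1e-10)
})

test_that("soft-gated binning populates bins equally with valid weights", {
  set.seed(4)
  tj <- generate_vdcaspr(c(16, 16), undersampling = 2, n_heartbeats = 100, seed = 1)
  sig <- data.frame(heartbeat = 1:100, fh = stats::rnorm(100, sd = 2),
                    lr = stats::rnorm(100))
  plan <- soft_gated_binning(tj, sig, n_bins = 4)
  pops <- tabulate(plan$hard_assignment, 4)
  expect_equal(pops, rep(25L, 4))
  expect_equal(sum(pops), 100L)
  for (b in 1:4) {
    expect_true(all(plan$bins[[b]]$w >= 0 & plan$bins[[b]]$w <= 1))
    expect_true(all(plan$bins[[b]]$w[plan$hard_assignment[plan$bins[[b]]$hb] == b] == 1))
  }
  # linear ramp signal: some heartbeat carries weight in at least two bins
  ramp <- data.frame(heartbeat = 1:100, fh = seq(-3, 3, length.out = 100), lr = 0)
  plan_r <- soft_gated_binning(tj, ramp, n_bins = 4)
  membership <- table(unlist(lapply(plan_r$bins, `[[`, "hb")))
  expect_gte(max(membership), 2)
})

test_that("constant signals and degenerate bin counts are handled", {
  tj <- generate_vdcaspr(c(16, 16), undersampling = 2, n_heartbeats = 10, seed = 1)
  flat <- data.frame(heartbeat = 1:10, fh = rep(1.5, 10), lr = 0)
  plan <- soft_gated_binning(tj, flat, n_bins = 2)
  for (b in 1:2) expect_true(all(plan$bins[[b]]$w == 1))
  # each heartbeat hard-assigned exactly once
  expect_equal(sort(unlist(lapply(1:2, function(b)
    plan$bins[[b]]$hb[plan$hard_assignment[plan$bins[[b]]$hb] == b]))), 1:10)
  expect_error(soft_gated_binning(tj, flat, n_bins = 11), "more bins")
})

test_that("acceleration accounting is exact point-count arithmetic", {
  tj <- generate_vdcaspr(c(16, 16), undersampling = 1, n_heartbeats = 30, seed = 1)
  acc <- compute_acceleration_factors(tj, c(16, 16))
  expect_equal(acc$vdcaspr, 1)
  expect_equal(acc$sr, 1)
  expect_equal(acc$overall, 1)
  # reference accounting: VD-CASPR 1.15 x SR 16.33 -> overall 18.8 (1 d.p.)
  expect_equal(round(1.15 * 16.33, 1), 18.8)
  # 2x2 super-resolution with ~4.5-fold undersampling lands near 18x overall
  tj2 <- generate_vdcaspr(c(32, 32), undersampling = 4.5, n_heartbeats = 60, seed = 3)
  acc2 <- compute_acceleration_factors(tj2, c(64, 64))
  pts <- nrow(unique(do.call(rbind, tj2$readouts)))
  expect_equal(acc2$vdcaspr, sum(tj2$shutter) / pts)
  expect_equal(acc2$sr, sum(elliptical_shutter(c(64, 64))) / sum(tj2$shutter))
  expect_lt(abs(acc2$overall - 18) / 18, 0.1)
  expect_error(compute_acceleration_factors(tj2, c(16, 16)), "contained")
})
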