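test_that("perceptual loss weights, taps and reductions behave as specified", {
  w <- loss_weights()
  expect_equal(unname(w$psi), c(3.0, 0.04, 0.016, 0.01, 14.0))
  expect_equal(names(w$psi), c("1_1", "2_2", "3_3", "4_3", "5_4"))
  expect_equal(w$gamma, c(100, 1))
  expect_equal(w$eta, c(10, 1, 100))
  expect_error(loss_weights(psi = c(a = 1)), "five")
  expect_error(loss_weights(gamma = c(-1, 1)), "> 0")

  ex <- make_feature_extractor(channels = 3, seed = 2)
  set.seed(3)
  a <- rand_cplx(c(4, 16, 16))
  expect_equal(perceptual_loss(a, a, ex), 0)
  # identity extractor with weight 1 reduces to pixelwise MSE (real input)
  b1 <- array(stats::rnorm(4 * 8 * 8), c(4, 8, 8))
  b2 <- array(stats::rnorm(4 * 8 * 8), c(4, 8, 8))
  expect_equal(perceptual_loss(b1, b2, identity_extractor(), c(id = 1)),
               mean((b1 - b2)^2))
  # additivity: doubling one psi changes the loss by that map's contribution
  c1 <- rand_cplx(c(4, 16, 16))
  psi <- loss_weights()$psi
  l0 <- perceptual_loss(a, c1, ex, psi)
  psi1 <- psi; psi1["3_3"] <- 0.001 * psi1["3_3"]   # isolate one tap
  lsub <- perceptual_loss(a, c1, ex, psi1)
  contrib <- (l0 - lsub) / (1 - 0.001)
  psi2 <- psi; psi2["3_3"] <- 2 * psi2["3_3"]
  expect_equal(perceptual_loss(a, c1, ex, psi2), l0 + contrib, tolerance = 1e-10)
})

test_that("pre-training and end-to-end losses evaluate with their default weights", {
  expect_equal(pretrain_loss(0, 0), 0)
  expect_equal(pretrain_loss(0.5, 2), 52)
  w <- loss_weights()
  expect_equal(w$gamma[1], 100)
  expect_equal(w$gamma[2], 1)
  expect_equal(end_to_end_loss(0, 0, 0), 0)
  expect_equal(end_to_end_loss(0.1, 0.2, 0.3), 10 * 0.1 + 1 * 0.2 + 100 * 0.3)
  expect_equal(w$eta, c(10, 1, 100))
  # kernel norms can be passed as parameter lists
  net <- sr_net(widths = c(2, 3, 4), seed = 1)
  ks <- supermoco:::kernel_sqnorm(net$params)
  expect_equal(pretrain_loss(0, net$params), ks)
  expect_equal(end_to_end_loss(0, list(net$params, net$params), 0), 2 * ks)
})

test_that("annulus density profiles count exactly as specified", {
  m <- matrix(TRUE, 32, 32)
  pr <- measure_density_profile(m)
  expect_length(pr$density, 20)
  expect_true(all(pr$density[pr$n_points > 0] == 1))
  # half-sampling by alternate retention within each annulus: every
  # annulus density within one line of 0.5 (verified by exhaustive counting)
  r <- supermoco:::shutter_radius(c(32, 32))
  ann <- pmin(pmax(ceiling(r * 20), 1L), 20L)
  half <- matrix(FALSE, 32, 32)
  for (a in 1:20) {
    pts <- which(r <= 1 & ann == a)
    half[pts[seq_along(pts) %% 2 == 1]] <- TRUE
  }
  pc <- measure_density_profile(half)
  ok <- pc$n_points > 0
  expect_true(all(abs(pc$density[ok] * pc$n_points[ok] -
                      0.5 * pc$n_points[ok]) <= 1))
  expect_error(measure_density_profile(matrix(TRUE, 0, 0)), "shutter")
})

test_that("retrospective down-sampling retains a matched subset of lines", {
  sp <- phantom_spec(grid_shape = c(8, 32, 32), n_heartbeats = 24, n_coils = 1,
                     motion_amplitude_vox = 0, seed = 4)
  tr <- generate_phantom(sp)
  tj_hr <- generate_vdcaspr(c(32, 32), undersampling = 1.2, n_heartbeats = 24,
                            seed = 2)
  raw <- simulate_acquisition(tr, tj_hr)
  # prospective-style low-resolution mask defines the target profile
  tj_lr <- generate_vdcaspr(c(16, 16), undersampling = 1.5, n_heartbeats = 24,
                            seed = 3)
  target <- measure_density_profile(sampling_mask(tj_lr))
  ds <- retrospective_downsample(raw, sr_factor = 2, target_profile = target,
                                 seed = 7)
  # retained readouts are a strict subset with bit-identical values
  for (h in seq_len(raw$n_heartbeats)) {
    ro_lr <- ds$traj[[h]]
    ro_hr <- raw$traj[[h]]
    key_hr <- paste(ro_hr[, 1], ro_hr[, 2])
    key_lr <- paste(ro_lr[, 1], ro_lr[, 2])
    expect_true(all(key_lr %in% key_hr))
    sel <- match(key_lr, key_hr)
    expect_identical(ds$kspace[[h]], raw$kspace[[h]][, sel, , drop = FALSE])
  }
  # everything outside the scaled outer annulus is gone
  pts <- do.call(rbind, ds$traj)
  yn <- (pts[, 1] - 16) / 16; zn <- (pts[, 2] - 16) / 16
  expect_true(all(sqrt((2 * yn)^2 + (2 * zn)^2) <= 1 + 1e-12))
  # per-annulus achieved density within max(5%, one line) of the target
  achieved <- attr(ds, "achieved_profile")
  short <- attr(ds, "shortfall")
  rg <- supermoco:::shutter_radius(c(32, 32)) * 2
  for (a in 1:20) {
    n_ann <- sum(rg <= 1 & pmin(pmax(ceiling(rg * 20), 1), 20) == a)
    if (n_ann == 0 || short[a] > 0) next
    expect_lte(abs(achieved[a] - target$density[a]),
               max(0.05, 1 / n_ann) + 1e-12)
  }
  # deterministic for a fixed seed
  ds2 <- retrospective_downsample(raw, 2, target, seed = 7)
  expect_identical(ds$traj, ds2$traj)
  # sr_factor 1 with the source profile keeps all in-shutter lines
  src <- measure_density_profile(sampling_mask(raw))
  id <- retrospective_downsample(raw, 1, src, seed = 1)
  expect_equal(sum(vapply(id$traj, nrow, 1L)), sum(vapply(raw$traj, nrow, 1L)))
})

test_that("k-space padding reaches multiples of 16 and preserves the image", {
  expect_equal(supermoco:::next_multiple_16(128), 128L)
  expect_equal(supermoco:::next_multiple_16(129), 144L)
  sp <- phantom_spec(grid_shape = c(8, 20, 12), n_heartbeats = 12, n_coils = 1,
                     motion_amplitude_vox = 0, seed = 4)
  tr <- generate_phantom(sp)
  tj <- generate_vdcaspr(c(20, 12), undersampling = 1, n_heartbeats = 12,
                         seed = 1, shutter = "full")
  raw <- simulate_acquisition(tr, tj)
  padded <- pad_kspace_to_multiple16(raw)
  expect_equal(padded$grid, c(8L, 32L, 16L))
  # recover the original image by cropping the padded k-space back
  plan <- soft_gated_binning(padded, tr$breathing, n_bins = 1)
  b <- binned_kspace(padded, plan)
  kfull <- array(0i, padded$grid)
  for (j in seq_len(nrow(b$bins[[1]]$idx))) {
    kfull[, b$bins[[1]]$idx[j, 1] + 1, b$bins[[1]]$idx[j, 2] + 1] <-
      b$bins[[1]]$data[, j, 1]
  }
  off <- c(16L - 10L, 8L - 6L)
  kcrop <- kfull[, off[1] + (1:20), off[2] + (1:12)] /
    sqrt((32 * 16) / (20 * 12))
  ref <- tr$bin_images[[tr$reference_bin]]
  expect_lt(max(Mod(ift3(kcrop) - ref)) / max(Mod(ref)), 1e-10)
})

test_that("patch plans have the specified geometry", {
  pl <- patch_plan()
  expect_equal(pl$thickness, 32L)
  expect_equal(pl$retained, 22L)
  expect_equal(pl$stride, 18L)
  expect_error(patch_plan(thickness = 24), "multiple of 16")
  expect_error(patch_plan(discard = 16), "interior")
  # x = 32: single fully retained patch
  x <- array(stats::rnorm(32 * 4 * 4), c(32, 4, 4))
  ps <- split_into_patches(x, pl)
  expect_length(ps$patches, 1)
  expect_equal(ps$retained[1, ], c(lo = 0L, hi = 31L))
  expect_error(split_into_patches(x[1:20, , ], pl), "smaller")
  # x = 100: full coverage, interior retained intervals overlap by exactly 4
  x100 <- array(stats::rnorm(100 * 4 * 4), c(100, 4, 4))
  ps100 <- split_into_patches(x100, pl)
  covered <- rep(0L, 100)
  for (p in seq_len(nrow(ps100$retained))) {
    covered[(ps100$retained[p, 1]:ps100$retained[p, 2]) + 1] <-
      covered[(ps100$retained[p, 1]:ps100$retained[p, 2]) + 1] + 1L
  }
  expect_true(all(covered >= 1))
  np <- nrow(ps100$retained)
  for (p in seq_len(np - 2)) {
    ov <- ps100$retained[p, 2] - ps100$retained[p + 1, 1] + 1
    expect_equal(unname(ov), 4)
  }
})

test_that("patch recombination averages overlaps and is an exact round trip", {
  pl <- patch_plan()
  for (X in c(32, 50, 70, 100)) {
    x <- array(stats::rnorm(X * 3 * 3), c(X, 3, 3))
    expect_identical(recombine_patches(split_into_patches(x, pl), pl), x)
  }
  # overlap regions equal the mean of contributing patches
  X <- 64
  x <- array(stats::rnorm(X * 2 * 2), c(X, 2, 2))
  ps <- split_into_patches(x, pl)
  for (p in seq_along(ps$patches)) ps$patches[[p]] <- ps$patches[[p]] + p
  out <- recombine_patches(ps, pl)
  acc <- array(0, dim(x)); cnt <- rep(0, X)
  for (p in seq_along(ps$patches)) {
    gl <- (ps$retained[p, 1]:ps$retained[p, 2]) + 1
    ll <- gl - ps$starts[p]
    acc[gl, , ] <- acc[gl, , ] + ps$patches[[p]][ll, , ]
    cnt[gl] <- cnt[gl] + 1
  }
  expect_true(all(cnt >= 1))
  expect_equal(out, acc / cnt)
})

test_that("pre-training with zero learning rate leaves parameters unchanged", {
  set.seed(6)
  lo <- rand_cplx(c(8, 16, 16))
  hi <- rand_cplx(c(8, 16, 16))
  net <- sr_net(widths = c(2, 3, 4), seed = 9)
  ex <- make_feature_extractor(channels = 2, seed = 1)
  res <- train_pretrain(net, list(list(lo = lo, hi = hi)),
                        config = list(epochs = 2, lr = 0), extractor = ex)
  expect_identical(res$net$params, net$params)
  expect_equal(nrow(res$history), 2)
  expect_error(train_pretrain(net, list(), config = list(epochs = 1)), "empty")
  # deterministic training for a fixed seed
  r1 <- train_pretrain(net, list(list(lo = lo, hi = hi)),
                       config = list(epochs = 2, lr = 1e-3, seed = 3),
                       extractor = ex)
  r2 <- train_pretrain(net, list(list(lo = lo, hi = hi)),
                       config = list(epochs = 2, lr = 1e-3, seed = 3),
                       extractor = ex)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("toy pre-training improves validation perceptual loss and keeps S near-idempotent", {
  set.seed(21)
  grid <- c(16, 16, 16)
  lowpass <- function(x) {
    k <- ft3(x)
    r <- sqrt(outer(outer((supermoco:::kcoords(16) / 8)^2,
                          (supermoco:::kcoords(16) / 8)^2, `+`),
                    (supermoco:::kcoords(16) / 8)^2, `+`))
    ift3(k * (r <= 0.5))
  }
  # structured fine detail (many small blobs), near-noiseless: the
  # restorable content must be anatomy-like, not noise
  mkpair <- function(seed) {
    set.seed(seed)
    hi <- (blob_volume(grid, n_blobs = 8, sigma = 1.6, seed = seed) +
           0.02 * array(stats::rnorm(prod(grid)), grid)) * exp(0.2i)
    list(lo = lowpass(hi), hi = hi)
  }
  train <- lapply(1:4, mkpair)
  # clean-input pairs teach S to act as the identity on already
  # high-resolution images (the projector property the iteration assumes)
  train <- c(train, lapply(train[1:2], function(p) list(lo = p$hi, hi = p$hi)))
  val <- lapply(5:6, mkpair)
  net <- sr_net(widths = c(2, 4, 8), seed = 3)
  ex <- make_feature_extractor(channels = 3, seed = 7)
  val_loss <- function(net) mean(vapply(val, function(p) {
    sc <- max(Mod(p$lo))
    perceptual_loss(p$hi / sc, apply_denoiser(net, p$lo / sc), ex)
  }, 0))
  v0 <- val_loss(net)
  res <- train_pretrain(net, train, config = list(epochs = 50, lr = 3e-4,
                                                  seed = 4), extractor = ex)
  expect_lt(val_loss(res$net), 0.8 * v0)
  # near-idempotence of the trained denoiser on held-out inputs
  # (a property approached by training, checked statistically)
  rel <- vapply(val, function(p) {
    s1 <- apply_denoiser(res$net, p$lo / max(Mod(p$lo)))
    s2 <- apply_denoiser(res$net, s1)
    sqrt(sum(Mod(s2 - s1)^2)) / sqrt(sum(Mod(s1)^2))
  }, 0)
  expect_lt(mean(rel), 0.1)
})
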