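# Desk-scale end-to-end experiments. These functions define the package's
# study conditions (phantom geometry, acquisition schemes, training
# schedules) in one place; the test suite and the acceptance script both
# run them.

#' Motion-recovery experiment
#'
#' Trains the motion branch by self-supervised registration on pairs of a
#' smooth synthetic volume and copies displaced by known random
#' breathing-like translations (foot-head up to +-3 voxels, left-right and
#' through-plane proportionally smaller), then measures how well the
#' estimated fields recover the held-out displacements
#' (intensity-weighted mean displacement against truth, worst component).
#'
#' @param seed master seed.
#' @param grid volume grid (default `c(12, 24, 12)`).
#' @param n_train,n_test training and held-out pair counts.
#' @param epochs,lr,levels,batch_size,smooth_weight training configuration
#'   of the motion branch (coarse-to-fine pyramid levels, minibatching and
#'   the velocity smoothness prior are discussed in the methods vignette).
#' @param widths motion network channel widths.
#' @return list with per-pair `errors` (voxels), `mean_error`,
#'   `max_error`, the trained `net` and the training `history`.
#' @export
experiment_motion_recovery <- function(seed = 1L, grid = c(12L, 24L, 12L),
                                       n_train = 32L, n_test = 5L,
                                       epochs = 220L, lr = 1e-3,
                                       widths = c(4L, 8L, 16L),
                                       levels = c(1L, 2L, 4L),
                                       batch_size = 1L,
                                       smooth_weight = 0.05) {
  base <- blob_phantom(grid, n_blobs = 5L, sigma = 3, seed = seed + 10L)
  shift_vol <- function(img, t) {
    d <- array(0, c(dim(img), 3L))
    d[, , , 1] <- t[1]; d[, , , 2] <- t[2]; d[, , , 3] <- t[3]
    warp_image(img, d)
  }
  set.seed(seed)
  mkpair <- function() {
    t <- c(stats::runif(1, -3, 3), stats::runif(1, -1.2, 1.2),
           stats::runif(1, -0.6, 0.6))
    list(fixed = base, moving = shift_vol(base, -t), true_t = t)
  }
  train_pairs <- replicate(n_train, mkpair(), simplify = FALSE)
  test_pairs <- replicate(n_test, mkpair(), simplify = FALSE)
  net <- motion_net(widths = widths, seed = seed + 1L, n_steps = 4L,
                    out_scale = 2)
  res <- train_motion_net(net, train_pairs,
                          config = list(epochs = epochs, lr = lr,
                                        seed = seed + 2L, levels = levels,
                                        batch_size = batch_size,
                                        smooth_weight = smooth_weight,
                                        schedule_epoch = 140L,
                                        schedule_factor = 0.3))
  errors <- vapply(test_pairs, function(p) {
    mf <- estimate_motion_fields(list(p$fixed, p$moving), res$net, 1L)
    wts <- p$fixed / sum(p$fixed)
    est <- vapply(1:3, function(c) sum(mf$fields[[2]][, , , c] * wts), 0)
    max(abs(est + p$true_t))      # fields map reference -> moving: truth -t
  }, 0)
  list(errors = errors, mean_error = mean(errors), max_error = max(errors),
       net = res$net, history = res$history, test_pairs = test_pairs,
       untrained_net = net)
}

# smooth sum-of-Gaussians volume used by the motion experiment
blob_phantom <- function(grid, n_blobs = 5L, sigma = 3, seed = 1L) {
  set.seed(seed)
  ctr <- cbind(stats::runif(n_blobs, grid[1] * 0.25, grid[1] * 0.75),
               stats::runif(n_blobs, grid[2] * 0.25, grid[2] * 0.75),
               stats::runif(n_blobs, grid[3] * 0.25, grid[3] * 0.75))
  ax <- lapply(1:3, function(a) seq_len(grid[a]) - 1)
  img <- array(0, grid)
  for (i in seq_len(n_blobs)) {
    gx <- exp(-(ax[[1]] - ctr[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2]] - ctr[i, 2])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3]] - ctr[i, 3])^2 / (2 * sigma^2))
    img <- img + outer(outer(gx, gy), gz)
  }
  img / max(img)
}

#' Build one synthetic study subject for an acquisition scheme
#'
#' Simulates a moving phantom, a 3x-undersampled high-resolution VD-CASPR
#' acquisition with per-heartbeat translation, applies the exact
#' translational correction, and retrospectively down-samples to the
#' requested scheme: `"4x4"` (SR factor 4 per axis, ~1.15x variable-density
#' undersampling of the low-res shutter) or `"2x2"` (SR factor 2, 4.5x
#' undersampling), both ~18x overall acceleration.
#'
#' @param seed subject seed.
#' @param scheme `"2x2"` or `"4x4"`.
#' @param grid,n_heartbeats,n_coils,motion_amplitude_vox,noise_snr phantom
#'   study conditions.
#' @return a training subject (see [build_training_subject()]) with the
#'   phantom `truth` and the down-sampled `raw` attached.
#' @export
make_study_subject <- function(seed, scheme = c("2x2", "4x4"),
                               grid = c(16L, 64L, 32L), n_heartbeats = 48L,
                               n_coils = 2L, motion_amplitude_vox = 3,
                               noise_snr = 30) {
  scheme <- match.arg(scheme)
  sp <- phantom_spec(grid_shape = grid, n_heartbeats = n_heartbeats,
                     n_coils = n_coils,
                     motion_amplitude_vox = motion_amplitude_vox,
                     noise_snr = noise_snr, seed = seed)
  tr <- generate_phantom(sp)
  tj_hr <- generate_vdcaspr(grid[2:3], undersampling = 3,
                            n_heartbeats = n_heartbeats, seed = seed)
  raw <- simulate_acquisition(tr, tj_hr)
  sigc <- tr$breathing
  sigc$fh <- -sigc$fh; sigc$lr <- -sigc$lr
  raw <- apply_translational_correction(raw, sigc)
  if (scheme == "4x4") {
    tj_lr <- generate_vdcaspr(grid[2:3] %/% 4L, undersampling = 1.15,
                              n_heartbeats = n_heartbeats, seed = seed + 100L)
    ds <- retrospective_downsample(raw, 4,
                                   measure_density_profile(sampling_mask(tj_lr)),
                                   seed = seed + 200L)
  } else {
    tj_lr <- generate_vdcaspr(grid[2:3] %/% 2L, undersampling = 4.5,
                              n_heartbeats = n_heartbeats, seed = seed + 100L)
    ds <- retrospective_downsample(raw, 2,
                                   measure_density_profile(sampling_mask(tj_lr)),
                                   seed = seed + 200L)
  }
  sub <- build_training_subject(tr, ds, n_bins = 4L)
  sub$truth <- tr
  sub$raw <- ds
  sub$scheme <- scheme
  sub
}

# heart ROI of the study phantom: central half of y and z, full x
study_roi <- function(grid) {
  roi <- array(FALSE, grid)
  roi[, (grid[2] %/% 4 + 1):(3 * grid[2] %/% 4),
      (grid[3] %/% 4 + 1):(3 * grid[3] %/% 4)] <- TRUE
  roi
}

# evaluate one subject: scale-optimized ROI MSE of the zero-filled
# reference bin, padded iterative SENSE, and the full reconstruction
evaluate_study_subject <- function(sub, framework, config) {
  rb <- sub$reference_bin
  ref <- sub$truth$bin_images[[sub$truth$reference_bin]]
  roi <- study_roi(dim(ref))
  zf_ref <- sub$zf_bins[[rb]]
  mse_zf <- scaled_roi_mse(zf_ref, ref, roi)$mse
  sense_ref <- iterative_sense(zf_ref, sub$samp[[rb]], sub$coil_maps,
                               n_iter = config$n_sense)
  mse_sense <- scaled_roi_mse(sense_ref, ref, roi)$mse
  sc <- max(Mod(zf_ref))
  aux <- lapply(seq_along(sub$zf_bins), function(bn)
    iterative_sense(sub$zf_bins[[bn]], sub$samp[[bn]], sub$coil_maps,
                    n_iter = config$n_sense))
  motion <- if (is.null(framework$motion)) NULL else
    estimate_motion_fields(aux, framework$motion, rb,
                           n_steps = config$motion_n_steps)
  img <- admm_core(sub$samp, lapply(sub$zf_bins, function(v) v / sc),
                   sub$coil_maps, motion, framework$sr, config) * sc
  list(mse = c(zero_filled = mse_zf, sense = mse_sense,
               super_moco_modl = scaled_roi_mse(img, ref, roi)$mse),
       image = img, reference = ref, roi = roi)
}

#' Scheme-comparison experiment
#'
#' Trains the full framework end-to-end at desk scale for one acquisition
#' scheme on `n_subjects - n_heldout` synthetic subjects and evaluates the
#' held-out subjects: scale-optimized ROI MSE of the reconstruction
#' against the zero-filled and padded iterative-SENSE baselines, averaged
#' over the held-out group.
#'
#' @param seed master seed (subjects use `seed + 1000 + i`).
#' @param scheme `"2x2"` or `"4x4"`.
#' @param n_subjects total subjects.
#' @param n_heldout held-out subjects (the last ones).
#' @param epochs,lr end-to-end training schedule.
#' @param sr_widths,motion_widths desk-scale channel widths.
#' @return list with the held-out-mean `mse` vector (`zero_filled`,
#'   `sense`, `super_moco_modl`), `mse_per_subject`, the training
#'   `history`, the trained `framework`, and the first held-out subject's
#'   `evaluation` (image, reference, ROI) for downstream metrics.
#' @export
experiment_scheme_comparison <- function(seed = 1L, scheme = c("2x2", "4x4"),
                                         n_subjects = 8L, n_heldout = 3L,
                                         epochs = 5L, lr = 5e-4,
                                         sr_widths = c(2L, 4L, 8L),
                                         motion_widths = c(4L, 8L, 16L)) {
  scheme <- match.arg(scheme)
  cfg <- recon_config(patch = patch_plan(16L), motion_n_steps = 4L)
  subs <- lapply(seq_len(n_subjects), function(i)
    make_study_subject(seed + 1000L + i, scheme))
  framework <- list(sr = sr_net(widths = sr_widths, seed = seed + 1L),
                    motion = motion_net(widths = motion_widths,
                                        seed = seed + 2L, n_steps = 4L),
                    recon = cfg)
  res <- train_end_to_end(framework, subs[seq_len(n_subjects - n_heldout)],
                          config = list(epochs = epochs, lr = lr,
                                        seed = seed + 3L),
                          extractor = make_feature_extractor(channels = 3L,
                                                             seed = 7L))
  held <- subs[seq.int(n_subjects - n_heldout + 1L, n_subjects)]
  evs <- lapply(held, evaluate_study_subject, framework = res$framework,
                config = cfg)
  per <- t(vapply(evs, function(e) e$mse, numeric(3)))
  list(mse = colMeans(per), mse_per_subject = per, history = res$history,
       framework = res$framework, heldout = held[[1]],
       evaluation = evs[[1]])
}
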