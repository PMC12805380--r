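# Desk-scale training loops: super-resolving U-Net pre-training on paired
# low/high-resolution volumes, self-supervised motion-network training, and
# end-to-end training through the unrolled ADMM reconstruction.
#
# Gradients through the Step-1 CG solve use the standard model-based
# deep-learning identity: treating the fixed-depth CG as an approximate
# solve of (E*E + lambda I) x = rhs, the vector-Jacobian product w.r.t. the
# right-hand side is another CG solve with the same normal matrix. Motion
# fields act as constants inside the data-consistency backward pass; the
# motion network is driven by the self-supervised Charbonnier loss, whose
# gradients flow through the warp and scaling-and-squaring layers.

#' Pre-train the super-resolving network
#'
#' Minimizes `gamma1 * L_perc(hi, S(lo)) + gamma2 * ||kernels||^2` over
#' paired low/high-resolution complex volumes with Adam. Each pair is
#' normalized so the low-resolution magnitude maximum is 1. Deterministic
#' for a fixed `config$seed`.
#'
#' @param net an [sr_net()].
#' @param dataset list of `list(lo, hi)` complex volume pairs.
#' @param config list: `epochs`, `lr` (default 1e-5), `seed`,
#'   optional `validation` (list of pairs, perceptual loss recorded per
#'   epoch).
#' @param extractor a feature extractor (default [make_feature_extractor()]).
#' @param weights a [loss_weights()].
#' @return list `net` (trained), `history` (per-epoch data frame).
#' @export
train_pretrain <- function(net, dataset, config = list(),
                           extractor = make_feature_extractor(),
                           weights = loss_weights()) {
  if (length(dataset) == 0L) stop("empty dataset")
  epochs <- config$epochs %||% 50L
  lr <- config$lr %||% 1e-5
  set.seed(config$seed %||% 1L)
  st <- adam_init(net$params)
  hist <- data.frame(epoch = integer(), loss = numeric(), val_perc = numeric())
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (pair in dataset) {
      sc <- max(Mod(pair$lo))
      if (sc == 0) sc <- 1
      lo <- pair$lo / sc
      hi <- pair$hi / sc
      fw <- apply_denoiser(net, lo, want_cache = TRUE)
      pg <- perceptual_loss_grad(hi, fw$y, extractor, weights)
      loss <- pretrain_loss(pg$loss, net$params, weights)
      tot <- tot + loss
      if (lr > 0) {
        g <- denoiser_vjp(net, fw$cache, weights$gamma[1] * pg$grad)$gparams
        g <- add_grads(g, kernel_sqnorm_grads(net$params, weights$gamma[2]))
        up <- adam_step(net$params, g, st, lr)
        net$params <- up$params
        st <- up$state
      }
    }
    valp <- NA_real_
    if (!is.null(config$validation)) {
      valp <- mean(vapply(config$validation, function(pair) {
        sc <- max(Mod(pair$lo)); if (sc == 0) sc <- 1
        perceptual_loss(pair$hi / sc, apply_denoiser(net, pair$lo / sc),
                        extractor, weights)
      }, 0))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / length(dataset),
                                   val_perc = valp))
  }
  list(net = net, history = hist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the motion network by self-supervised registration
#'
#' Minimizes the Charbonnier loss between each pair's fixed volume and the
#' moving volume warped by the inverse of the estimated diffeomorphic
#' field. No ground-truth motion is used.
#'
#' @param net a [motion_net()].
#' @param pairs list of `list(fixed, moving)` magnitude volumes.
#' @param config list: `epochs`, `lr` (default 1e-3), `seed`, `epsilon`.
#' @return list `net`, `history`.
#' @export
train_motion_net <- function(net, pairs, config = list()) {
  if (length(pairs) == 0L) stop("empty dataset")
  epochs <- config$epochs %||% 30L
  lr <- config$lr %||% 1e-3
  eps <- config$epsilon %||% 1e-3
  levels <- config$levels %||% 1L
  batch <- config$batch_size %||% 1L
  sched_ep <- config$schedule_epoch %||% Inf
  sched_f <- config$schedule_factor %||% 0.5
  set.seed(config$seed %||% 1L)
  st <- adam_init(net$params)
  hist <- numeric(epochs)
  lr0 <- lr
  for (ep in seq_len(epochs)) {
    lr <- lr0 * ifelse(ep > sched_ep, sched_f, 1)
    tot <- 0
    ord <- sample(seq_along(pairs))
    gacc <- NULL
    nacc <- 0L
    for (i in seq_along(ord)) {
      pr <- pairs[[ord[i]]]
      mags <- list(Mod(pr$fixed), Mod(pr$moving))
      r <- motion_loss_and_grads(net, mags, mags, reference_bin = 1L,
                                 epsilon = eps, levels = levels,
                                 smooth_weight = config$smooth_weight %||% 0.05)
      tot <- tot + r$loss
      gacc <- add_grads(gacc, r$gparams)
      nacc <- nacc + 1L
      if (nacc == batch || i == length(ord)) {
        if (lr > 0) {
          up <- adam_step(net$params, scale_grads(gacc, 1 / nacc), st, lr)
          net$params <- up$params
          st <- up$state
        }
        gacc <- NULL
        nacc <- 0L
      }
    }
    hist[ep] <- tot / length(pairs)
  }
  list(net = net, history = data.frame(epoch = seq_len(epochs), loss = hist))
}

# ---------------------------------------------------------------------------
# End-to-end training through the unrolled ADMM
# ---------------------------------------------------------------------------

# forward ADMM keeping the caches needed for backpropagation
admm_train_fwd <- function(E, Eb, sr, config) {
  c1 <- config$mu / (config$mu + config$lambda)
  c2 <- config$lambda / (config$mu + config$lambda)
  rho <- Eb
  omega <- rho
  a <- array(0i, dim(rho))
  scaches <- vector("list", config$n_admm - 1L)
  for (j in seq_len(config$n_admm)) {
    rho <- cg_solve_step1(E, NULL, g = omega - a, lambda = config$lambda,
                          n_iter = config$n_cg, Eb_adj = Eb)
    if (j == config$n_admm) break
    omega_tilde <- rho + a
    sf <- apply_denoiser(sr, omega_tilde, want_cache = TRUE)
    scaches[[j]] <- sf$cache
    omega <- c1 * sf$y + c2 * omega_tilde
    a <- a + rho - omega
  }
  list(rho = rho, scaches = scaches, c1 = c1, c2 = c2)
}

# backward pass: gradient of the loss w.r.t. the SR network parameters
admm_train_bwd <- function(E, fw, sr, config, grho_final) {
  lam <- config$lambda
  A <- function(x) apply_adjoint(E, apply_forward(E, x)) + lam * x
  Ainv <- function(g) cg_run(A, g, x0 = 0i * g, n_iter = config$n_cg)
  gparams <- NULL
  J <- config$n_admm
  u <- Ainv(grho_final)
  gw <- lam * u
  ga <- -lam * u
  if (J >= 2L) {
    for (t in rev(seq_len(J - 1L))) {
      grho <- ga
      gw <- gw - ga
      ga_prev <- ga
      vjp <- denoiser_vjp(sr, fw$scaches[[t]], fw$c1 * gw)
      gparams <- add_grads(gparams, vjp$gparams)
      got <- fw$c2 * gw + vjp$gx
      grho <- grho + got
      ga_prev <- ga_prev + got
      u <- Ainv(grho)
      if (t > 1L) {
        gw <- lam * u
        ga <- ga_prev - lam * u
      }
    }
  }
  gparams
}

#' Build an end-to-end training subject from phantom data
#'
#' Prepares the quantities consumed by [train_end_to_end()]: soft-gated
#' binned k-space of the (retrospectively down-sampled) acquisition, per-bin
#' zero-filled images, the sampling geometry, coil maps and the
#' high-resolution ground-truth bin images.
#'
#' @param truth a [generate_phantom()] result.
#' @param raw_lr the (low-resolution / undersampled) `raw_kspace`, already
#'   translational-corrected or simulated without translation.
#' @param n_bins respiratory bins.
#' @param signal respiratory signal used for binning (default: the phantom's
#'   true breathing signal).
#' @return a training-subject list.
#' @export
build_training_subject <- function(truth, raw_lr, n_bins = 4L, signal = NULL) {
  if (is.null(signal)) {
    signal <- truth$breathing
    class(signal) <- c("resp_signal", "data.frame")
  }
  plan <- soft_gated_binning(raw_lr, signal, n_bins = n_bins)
  b <- binned_kspace(raw_lr, plan)
  zf <- zero_filled_recon(b, truth$coil_maps)
  list(zf_bins = zf,
       samp = lapply(b$bins, function(bb) list(idx = bb$idx, w = bb$w)),
       coil_maps = truth$coil_maps,
       hr_bins = truth$bin_images,
       reference_bin = plan$reference_bin,
       plan = plan,
       grid = raw_lr$grid)
}

#' End-to-end training of the full framework
#'
#' Jointly fine-tunes the super-resolving network (through the unrolled
#' ADMM: gradients flow through the CG data-consistency solves and the
#' Step-2 convex combination) and the motion network (self-supervised
#' Charbonnier loss on high-resolution bin images warped to the reference
#' bin). The loss is `eta1 * L_perc + eta2 * L_reg + eta3 * L_mot`. Each
#' epoch a random readout patch from the central 50% of the x-axis is
#' drawn per subject; the learning rate is halved after
#' `config$schedule_epoch` epochs (default 500).
#'
#' @param framework list: `sr` ([sr_net()]), `motion` ([motion_net()] or
#'   `NULL`), `recon` ([recon_config()]).
#' @param dataset list of subjects from [build_training_subject()].
#' @param config list: `epochs`, `lr` (default 1e-4), `schedule_epoch`
#'   (default 500), `schedule_factor` (default 0.5), `seed`.
#' @param extractor,weights perceptual extractor and [loss_weights()].
#' @return list `framework` (trained), `history`.
#' @export
train_end_to_end <- function(framework, dataset, config = list(),
                             extractor = make_feature_extractor(),
                             weights = loss_weights()) {
  if (length(dataset) == 0L) stop("empty dataset")
  epochs <- config$epochs %||% 30L
  lr0 <- config$lr %||% 1e-4
  sched_ep <- config$schedule_epoch %||% 500L
  sched_f <- config$schedule_factor %||% 0.5
  set.seed(config$seed %||% 1L)
  cfg <- framework$recon %||% recon_config()
  sr <- framework$sr
  mnet <- framework$motion
  st_sr <- adam_init(sr$params)
  st_m <- if (!is.null(mnet)) adam_init(mnet$params)
  th <- cfg$patch$thickness
  hist <- data.frame(epoch = integer(), loss = numeric(), perc = numeric(),
                     mot = numeric(), lr = numeric())

  for (ep in seq_len(epochs)) {
    lr <- lr0 * ifelse(ep > sched_ep, sched_f, 1)
    tot <- totp <- totm <- 0
    for (sub in dataset) {
      X <- sub$grid[1]
      if (X < th) stop("subject x-dimension smaller than the patch thickness")
      if (X > th) {
        lo <- max(0L, floor(X / 4))
        hi <- min(X - th, ceiling(3 * X / 4) - th)
        s0 <- if (hi > lo) sample(lo:hi, 1L) else lo
      } else s0 <- 0L
      xr <- s0 + seq_len(th)
      zf <- lapply(sub$zf_bins, function(v) v[xr, , , drop = FALSE])
      hr <- lapply(sub$hr_bins, function(v) v[xr, , , drop = FALSE])
      cm <- sub$coil_maps[xr, , , , drop = FALSE]
      rb <- sub$reference_bin
      sc <- max(Mod(zf[[rb]]))
      if (sc == 0) sc <- 1
      zf <- lapply(zf, function(v) v / sc)
      hr <- lapply(hr, function(v) v / sc)

      aux <- lapply(seq_along(zf), function(bn)
        iterative_sense(zf[[bn]], sub$samp[[bn]], cm, n_iter = cfg$n_sense,
                        epsilon = cfg$sense_epsilon))
      motion <- if (is.null(mnet)) NULL else
        estimate_motion_fields(aux, mnet, rb, n_steps = cfg$motion_n_steps)

      grid <- dim(zf[[1]])
      E <- encoding_operator(sub$samp, cm, motion, grid = grid)
      Eb <- array(0i, grid)
      for (bn in seq_along(zf)) {
        Eb <- Eb + if (is.null(motion)) zf[[bn]] else
          warp_adjoint(zf[[bn]], motion$fields[[bn]])
      }
      fw <- admm_train_fwd(E, Eb, sr, cfg)
      pg <- perceptual_loss_grad(hr[[rb]], fw$rho, extractor, weights)

      lmot <- 0
      gm <- NULL
      if (!is.null(mnet)) {
        r <- motion_loss_and_grads(mnet, lapply(aux, Mod), lapply(hr, Mod), rb)
        lmot <- r$loss
        gm <- r$gparams
      }
      kk <- kernel_sqnorm(sr$params) + if (!is.null(mnet)) kernel_sqnorm(mnet$params) else 0
      loss <- weights$eta[1] * pg$loss + weights$eta[2] * kk + weights$eta[3] * lmot
      tot <- tot + loss
      totp <- totp + pg$loss
      totm <- totm + lmot

      if (lr > 0) {
        gsr <- admm_train_bwd(E, fw, sr, cfg, weights$eta[1] * pg$grad)
        if (is.null(gsr)) gsr <- scale_grads(kernel_sqnorm_grads(sr$params, 1), 0)
        gsr <- add_grads(gsr, kernel_sqnorm_grads(sr$params, weights$eta[2]))
        up <- adam_step(sr$params, gsr, st_sr, lr)
        sr$params <- up$params
        st_sr <- up$state
        if (!is.null(mnet)) {
          gm <- scale_grads(gm, weights$eta[3])
          gm <- add_grads(gm, kernel_sqnorm_grads(mnet$params, weights$eta[2]))
          up <- adam_step(mnet$params, gm, st_m, lr)
          mnet$params <- up$params
          st_m <- up$state
        }
      }
    }
    n <- length(dataset)
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / n, perc = totp / n,
                                   mot = totm / n, lr = lr))
  }
  framework$sr <- sr
  framework$motion <- mnet
  list(framework = framework, history = hist)
}
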