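# ADMM-unrolled plug-and-play reconstruction: the split objective
#   argmin_{rho, omega}  1/2 ||E rho - b||^2 + mu/2 ||omega - S(omega)||^2
#   subject to rho = omega
# is solved with a scaled augmented Lagrangian; Step 1 is a fixed-depth CG
# data-consistency solve, Step 2 has the closed form
# omega = mu/(mu+lambda) S(omega~) + lambda/(mu+lambda) omega~, and Step 3
# accumulates the scaled dual with the standard residual a + rho - omega
# (the conventional scaled-ADMM sign). The final iteration stops after
# Step 1.

#' Reconstruction configuration
#'
#' Defaults are the framework's reference operating point: `lambda = 1.5`,
#' `mu = 10`, 4 ADMM iterations, 5 CG iterations in Step 1, 10 iterative
#' SENSE iterations for the auxiliary de-noising, 4 respiratory bins.
#'
#' @param lambda ADMM penalty (data-consistency coupling), > 0.
#' @param mu denoiser prior weight, > 0.
#' @param n_admm number of ADMM iterations.
#' @param n_cg CG iterations per Step-1 solve.
#' @param n_sense iterative-SENSE iterations for auxiliary images.
#' @param n_bins respiratory bins.
#' @param patch a [patch_plan()] for readout-direction patching.
#' @param sense_epsilon Tikhonov term inside iterative SENSE.
#' @param motion_n_steps scaling-and-squaring steps.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda = 1.5, mu = 10, n_admm = 4L, n_cg = 5L,
                         n_sense = 10L, n_bins = 4L, patch = patch_plan(),
                         sense_epsilon = 1e-6, motion_n_steps = 6L) {
  if (lambda <= 0 || mu <= 0) stop("lambda and mu must be > 0")
  if (n_admm < 1L || n_cg < 1L || n_sense < 1L || n_bins < 1L)
    stop("iteration counts and n_bins must be >= 1")
  structure(list(lambda = lambda, mu = mu, n_admm = as.integer(n_admm),
                 n_cg = as.integer(n_cg), n_sense = as.integer(n_sense),
                 n_bins = as.integer(n_bins), patch = patch,
                 sense_epsilon = sense_epsilon,
                 motion_n_steps = as.integer(motion_n_steps)),
            class = "recon_config")
}

as_denoiser <- function(S) {
  if (is.null(S)) return(identity)
  if (inherits(S, "sr_net")) return(function(x) apply_denoiser(S, x))
  if (is.function(S)) return(S)
  stop("S must be NULL, a function, or an sr_net")
}

#' Second ADMM step (plug-and-play denoising)
#'
#' Convex combination `mu/(mu+lambda) * S(omega~) + lambda/(mu+lambda) *
#' omega~`: the closed-form minimizer of the Step-2 objective under the
#' assumption that S projects onto its output set.
#'
#' @param omega_tilde complex volume `rho + a`.
#' @param S denoiser: an [sr_net()], a function, or `NULL` for identity.
#' @param mu,lambda positive penalty parameters.
#' @return the updated `omega`.
#' @export
admm_step2 <- function(omega_tilde, S, mu, lambda) {
  if (mu <= 0 || lambda <= 0) stop("mu and lambda must be > 0")
  Sf <- as_denoiser(S)
  (mu / (mu + lambda)) * Sf(omega_tilde) + (lambda / (mu + lambda)) * omega_tilde
}

#' Third ADMM step (scaled dual update)
#'
#' Accumulates the primal residual: `a + rho - omega`.
#'
#' @param a scaled dual variable.
#' @param rho_new,omega_new current primal variables.
#' @return updated dual variable.
#' @export
dual_update <- function(a, rho_new, omega_new) {
  if (!identical(dim(a), dim(rho_new)) || !identical(dim(a), dim(omega_new)))
    stop("shape mismatch in dual update")
  a + rho_new - omega_new
}

# Core ADMM loop on one (patch) grid. zf_bins are the zero-filled bin
# images; data consistency uses E* b = sum_b M* rho_ZF,b so raw k-space is
# not needed. Returns rho after the final Step-1 solve.
admm_core <- function(samp, zf_bins, coil_maps, motion, S, config,
                      trace = FALSE) {
  grid <- dim(zf_bins[[1]])
  E <- encoding_operator(samp, coil_maps, motion, grid = grid)
  Eb <- array(0i, grid)
  for (b in seq_along(zf_bins)) {
    Eb <- Eb + if (is.null(motion)) zf_bins[[b]] else
      warp_adjoint(zf_bins[[b]], motion$fields[[b]])
  }
  Sf <- as_denoiser(S)
  rho <- Eb
  omega <- rho
  a <- array(0i, grid)
  resid <- numeric(0)
  for (j in seq_len(config$n_admm)) {
    rho <- cg_solve_step1(E, NULL, g = omega - a, lambda = config$lambda,
                          n_iter = config$n_cg, Eb_adj = Eb)
    if (j == config$n_admm) break
    omega_tilde <- rho + a
    omega <- admm_step2(omega_tilde, Sf, config$mu, config$lambda)
    a <- dual_update(a, rho, omega)
    if (trace) resid <- c(resid, sqrt(cdot(rho - omega, rho - omega)))
  }
  if (trace) attr(rho, "primal_residual") <- resid
  rho
}

#' Full super-resolving motion-corrected model-based reconstruction
#'
#' Pipeline: iNAV translation estimation and k-space phase correction,
#' soft-gated respiratory binning, zero-padding of the (ky, kz) grid to
#' multiples of 16, zero-filled bin reconstruction at the high-resolution
#' array size, readout-direction patching, per-bin iterative-SENSE
#' auxiliary images, network motion estimation, the ADMM loop (stopping
#' after Step 1 in the final iteration), and patch recombination. The
#' initial image is the motion-corrected adjoint, `sum_b M* rho_ZF,b`.
#' Inference is deterministic given fixed inputs.
#'
#' @param raw a `raw_kspace`.
#' @param coil_maps complex `[X, Y, Z, Nc]` maps on the (padded) grid.
#' @param nets `list(sr = , motion = )`: trained networks; either may be
#'   `NULL` (identity denoiser / zero motion).
#' @param config a [recon_config()].
#' @param signal optional precomputed respiratory signal (image voxels);
#'   when `NULL` it is estimated from the navigators.
#' @return complex high-resolution volume of the reference respiratory bin,
#'   with the sampling plan and signal attached as attributes.
#' @export
super_moco_modl_reconstruct <- function(raw, coil_maps, nets = list(),
                                        config = recon_config(),
                                        signal = NULL) {
  stopifnot(inherits(raw, "raw_kspace"))
  raw <- pad_kspace_to_multiple16(raw)
  if (!all(dim(coil_maps)[1:3] == raw$grid))
    stop("coil maps must be supplied on the (padded) reconstruction grid")
  if (is.null(signal)) {
    signal <- estimate_inav_translations(raw$inav, reference = "median",
                                         scale = raw$inav_scale)
  }
  corr <- signal
  corr$fh <- -corr$fh
  corr$lr <- -corr$lr
  raw <- apply_translational_correction(raw, corr)
  plan <- soft_gated_binning(raw, signal, n_bins = config$n_bins)
  b <- binned_kspace(raw, plan)
  zf <- zero_filled_recon(b, coil_maps)
  sc <- max(Mod(zf[[plan$reference_bin]]))
  if (sc == 0) stop("zero-filled reference image is identically zero")
  zf <- lapply(zf, function(v) v / sc)
  samp <- lapply(b$bins, function(bb) list(idx = bb$idx, w = bb$w))

  ps <- split_into_patches(zf[[1]], config$patch)
  zf_patches <- lapply(zf, split_into_patches, plan = config$patch)
  out_ps <- ps
  for (p in seq_along(ps$starts)) {
    xr <- ps$starts[p] + seq_len(config$patch$thickness)
    cm <- coil_maps[xr, , , , drop = FALSE]
    zfp <- lapply(zf_patches, function(z) z$patches[[p]])
    aux <- lapply(seq_along(zfp), function(bn)
      iterative_sense(zfp[[bn]], samp[[bn]], cm, n_iter = config$n_sense,
                      epsilon = config$sense_epsilon))
    motion <- if (is.null(nets$motion)) NULL else
      estimate_motion_fields(aux, nets$motion, plan$reference_bin,
                             n_steps = config$motion_n_steps)
    out_ps$patches[[p]] <- admm_core(samp, zfp, cm, motion, nets$sr, config)
  }
  img <- recombine_patches(out_ps, config$patch) * sc
  attr(img, "plan") <- plan
  attr(img, "signal") <- signal
  attr(img, "scale") <- sc
  img
}
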