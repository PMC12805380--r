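# The multi-bin motion-compensated encoding operator E = W D F C M and its
# exact adjoint, zero-filled reconstruction, the conjugate-gradient
# data-consistency solve of the first ADMM step, and single-bin iterative
# SENSE.
#
# F is the centered unitary 3D DFT (see fft.R), so F* = F^-1 exactly; D
# selects acquired (ky, kz) lines (all kx samples of each line), removing
# both undersampled-away lines and everything outside the low-resolution
# shutter; W applies the soft-gating weight of each line; C multiplies by
# the normalized coil maps; M warps the reference-bin image into each bin.

#' Assemble soft-gated binned k-space from raw data
#'
#' Concatenates each bin's member-heartbeat readout blocks, expanding the
#' per-heartbeat soft-gating weight to every readout line of that heartbeat.
#'
#' @param raw a `raw_kspace` object (typically translational-corrected).
#' @param plan a [soft_gated_binning()] sampling plan.
#' @return object of class `binned_kspace`: per-bin `data` `[Nx, Ki, Nc]`,
#'   line indices `idx` `[Ki, 2]` (0-based high-res grid), weights `w`.
#' @export
binned_kspace <- function(raw, plan) {
  stopifnot(inherits(raw, "raw_kspace"), inherits(plan, "sampling_plan"))
  if (length(plan$ro_counts) != raw$n_heartbeats)
    stop("plan and raw data disagree on the number of heartbeats")
  bins <- vector("list", plan$n_bins)
  for (b in seq_len(plan$n_bins)) {
    hbs <- plan$bins[[b]]$hb
    wts <- plan$bins[[b]]$w
    data <- array(0i, c(raw$grid[1], plan$Ki[b], raw$n_coils))
    idx <- matrix(0L, plan$Ki[b], 2)
    w <- numeric(plan$Ki[b])
    at <- 0L
    for (j in seq_along(hbs)) {
      h <- hbs[j]
      nh <- nrow(raw$traj[[h]])
      if (nh == 0L) next
      sel <- at + seq_len(nh)
      data[, sel, ] <- raw$kspace[[h]]
      idx[sel, ] <- raw$traj[[h]]
      w[sel] <- wts[j]
      at <- at + nh
    }
    bins[[b]] <- list(data = data, idx = idx, w = w)
  }
  structure(list(bins = bins, grid = raw$grid, n_coils = raw$n_coils,
                 n_bins = plan$n_bins, reference_bin = plan$reference_bin,
                 lr_grid = raw$lr_grid, lr_offset = raw$lr_offset),
            class = "binned_kspace")
}

#' Construct the motion-compensated encoding operator
#'
#' @param sampling either a `binned_kspace` (its `idx`/`w` define D and W) or
#'   a list with one `list(idx, w)` element per bin.
#' @param coil_maps complex `[X, Y, Z, Nc]` normalized coil maps.
#' @param motion a [motion_field_set()] mapping the reference bin to each
#'   bin, or `NULL` for identity motion.
#' @param grid image grid `c(Nx, Ny, Nz)` (taken from `sampling` when it is a
#'   `binned_kspace`).
#' @return object of class `encoding_operator`, applied with
#'   [apply_forward()] / [apply_adjoint()].
#' @export
encoding_operator <- function(sampling, coil_maps, motion = NULL, grid = NULL) {
  if (inherits(sampling, "binned_kspace")) {
    grid <- sampling$grid
    samp <- lapply(sampling$bins, function(b) list(idx = b$idx, w = b$w))
  } else {
    samp <- sampling
    if (is.null(grid)) stop("grid must be given when sampling is a plain list")
  }
  grid <- as.integer(grid)
  stopifnot(length(dim(coil_maps)) == 4L, all(dim(coil_maps)[1:3] == grid))
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_field_set"))
    if (length(motion$fields) != length(samp))
      stop("motion field count does not match bin count")
    if (!all(motion$grid == grid)) stop("motion field grid mismatch")
  }
  structure(list(samp = samp, coil_maps = coil_maps, motion = motion,
                 grid = grid, n_bins = length(samp), n_coils = dim(coil_maps)[4]),
            class = "encoding_operator")
}

# column index (into the Ny*Nz flattened plane) of each (ky, kz) line
line_cols <- function(idx, grid) idx[, 1] + 1L + grid[2] * idx[, 2]

# accumulate weighted complex line data [Nx, Ki] into a [Nx, Ny*Nz] plane,
# summing duplicates
accumulate_lines <- function(data, w, cols, grid) {
  wd <- sweep(data, 2, w, `*`)
  re <- rowsum(t(Re(wd)), group = cols)
  im <- rowsum(t(Im(wd)), group = cols)
  ucols <- as.integer(rownames(re))
  k <- matrix(0i, grid[1], grid[2] * grid[3])
  k[, ucols] <- t(matrix(complex(real = re, imaginary = im), nrow(re), ncol(re)))
  k
}

#' Apply the encoding operator
#'
#' Forward model `E rho = W D F C M rho`: the reference image is warped into
#' each bin, multiplied by each coil map, Fourier transformed, restricted to
#' the acquired lines and soft-gate weighted.
#'
#' @param E an [encoding_operator()].
#' @param rho complex 3D image on the operator grid.
#' @return a `binned_kspace`-shaped object holding the predicted samples.
#' @export
apply_forward <- function(E, rho) {
  stopifnot(inherits(E, "encoding_operator"))
  if (!all(dim(rho) == E$grid)) stop("image shape does not match operator grid")
  grid <- E$grid
  bins <- vector("list", E$n_bins)
  for (b in seq_len(E$n_bins)) {
    img <- if (is.null(E$motion)) rho else warp_image(rho, E$motion$fields[[b]])
    idx <- E$samp[[b]]$idx
    w <- E$samp[[b]]$w
    cols <- line_cols(idx, grid)
    data <- array(0i, c(grid[1], nrow(idx), E$n_coils))
    for (c in seq_len(E$n_coils)) {
      km <- matrix(ft3(img * E$coil_maps[, , , c]), grid[1], grid[2] * grid[3])
      data[, , c] <- sweep(km[, cols, drop = FALSE], 2, w, `*`)
    }
    bins[[b]] <- list(data = data, idx = idx, w = w)
  }
  structure(list(bins = bins, grid = grid, n_coils = E$n_coils,
                 n_bins = E$n_bins), class = "binned_kspace")
}

#' Apply the adjoint encoding operator
#'
#' `E* b = M* C* F^-1 D^T W^T b`, summed over bins: equivalently the
#' warp-adjoint applied to each bin's zero-filled reconstruction.
#'
#' @param E an [encoding_operator()].
#' @param b a `binned_kspace` consistent with `E`.
#' @return complex 3D image.
#' @export
apply_adjoint <- function(E, b) {
  stopifnot(inherits(E, "encoding_operator"), inherits(b, "binned_kspace"))
  if (length(b$bins) != E$n_bins) stop("bin count mismatch between operator and data")
  grid <- E$grid
  out <- array(0i, grid)
  for (bn in seq_len(E$n_bins)) {
    if (nrow(b$bins[[bn]]$idx) != nrow(E$samp[[bn]]$idx))
      stop("sampling plan mismatch between operator and data")
    acc <- array(0i, grid)
    cols <- line_cols(E$samp[[bn]]$idx, grid)
    for (c in seq_len(E$n_coils)) {
      dc <- array(b$bins[[bn]]$data[, , c], c(grid[1], length(cols)))
      k <- accumulate_lines(dc, E$samp[[bn]]$w, cols, grid)
      dim(k) <- grid
      acc <- acc + Conj(E$coil_maps[, , , c]) * ift3(k)
    }
    out <- out + if (is.null(E$motion)) acc else warp_adjoint(acc, E$motion$fields[[bn]])
  }
  out
}

#' Zero-filled reconstruction of each respiratory bin
#'
#' `rho_ZF = C* F^-1 D^T W^T b` per bin: coil-combined images at the full
#' high-resolution array size with every unacquired sample set to zero, and
#' no motion operator applied.
#'
#' @param b a `binned_kspace`.
#' @param coil_maps complex `[X, Y, Z, Nc]` maps.
#' @return list of complex 3D volumes, one per bin.
#' @export
zero_filled_recon <- function(b, coil_maps) {
  stopifnot(inherits(b, "binned_kspace"))
  grid <- b$grid
  lapply(seq_len(b$n_bins), function(bn) {
    acc <- array(0i, grid)
    cols <- line_cols(b$bins[[bn]]$idx, grid)
    for (c in seq_len(dim(coil_maps)[4])) {
      dc <- array(b$bins[[bn]]$data[, , c], c(grid[1], length(cols)))
      k <- accumulate_lines(dc, b$bins[[bn]]$w, cols, grid)
      dim(k) <- grid
      acc <- acc + Conj(coil_maps[, , , c]) * ift3(k)
    }
    acc
  })
}

# real inner product <x, y> = Re(sum(conj(x) y))
cdot <- function(x, y) Re(sum(Conj(x) * y))

#' Conjugate-gradient solve of the first ADMM step
#'
#' Approximately solves `(E*E + lambda I) rho = E*b + lambda g` by CG,
#' initialized at `g`, with a fixed iteration count and no early exit (the
#' unrolled, differentiable design uses a fixed graph depth).
#'
#' @param E an [encoding_operator()].
#' @param b a `binned_kspace`, or `NULL` if `Eb_adj` is supplied.
#' @param g complex 3D image `omega - a`.
#' @param lambda positive data-consistency penalty (default 1.5).
#' @param n_iter number of CG iterations (default 5).
#' @param Eb_adj optional precomputed `E* b` (e.g. the motion-corrected
#'   combination of zero-filled bins).
#' @return complex 3D image.
#' @export
cg_solve_step1 <- function(E, b, g, lambda = 1.5, n_iter = 5L, Eb_adj = NULL) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (is.null(Eb_adj)) Eb_adj <- apply_adjoint(E, b)
  A <- function(x) apply_adjoint(E, apply_forward(E, x)) + lambda * x
  rhs <- Eb_adj + lambda * g
  cg_run(A, rhs, x0 = g, n_iter = n_iter)
}

# fixed-iteration CG on a Hermitian positive (semi)definite operator
cg_run <- function(A, rhs, x0, n_iter) {
  x <- x0
  r <- rhs - A(x)
  p <- r
  rs <- cdot(r, r)
  for (it in seq_len(n_iter)) {
    if (rs <= 0 || !is.finite(rs)) break
    Ap <- A(p)
    alpha <- rs / cdot(p, Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- cdot(r, r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

#' Iterative SENSE reconstruction of one bin
#'
#' CG solution of the single-bin SENSE normal equations (no motion operator)
#' with a small Tikhonov term for conditioning of rank-deficient undersampled
#' single-coil problems: `(E_b* E_b + epsilon I) x = rho_ZF`.
#'
#' @param zero_filled_bin the bin's zero-filled image (`C* F^-1 D^T W^T b`,
#'   which equals the normal-equation right-hand side).
#' @param samp_bin the bin's sampling: `list(idx, w)`.
#' @param coil_maps complex `[X, Y, Z, Nc]` maps.
#' @param n_iter CG iterations (default 10).
#' @param epsilon Tikhonov regularization (default 1e-6).
#' @return complex 3D de-noised auxiliary image.
#' @export
iterative_sense <- function(zero_filled_bin, samp_bin, coil_maps, n_iter = 10L,
                            epsilon = 1e-6) {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  grid <- dim(zero_filled_bin)
  cols <- line_cols(samp_bin$idx, grid)
  w2 <- samp_bin$w^2
  A <- function(x) {
    acc <- array(0i, grid)
    for (c in seq_len(dim(coil_maps)[4])) {
      km <- matrix(ft3(x * coil_maps[, , , c]), grid[1], grid[2] * grid[3])
      k <- accumulate_lines(km[, cols, drop = FALSE], w2, cols, grid)
      dim(k) <- grid
      acc <- acc + Conj(coil_maps[, , , c]) * ift3(k)
    }
    acc + epsilon * x
  }
  cg_run(A, zero_filled_bin, x0 = array(0i, grid), n_iter = n_iter)
}
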