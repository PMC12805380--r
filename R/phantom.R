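# Synthetic moving-heart phantom: reference anatomy with ellipsoidal chambers
# and a thin bright vessel, per-bin diffeomorphic motion built from a smooth
# random stationary velocity field (so invertibility holds by construction),
# smooth normalized coil maps, a pseudo-periodic breathing signal, simulated
# multi-coil k-space acquisition and 2D coronal image navigators.

#' Phantom specification
#'
#' @param grid_shape three positive integers (x = readout, y, z), each >= 8.
#' @param voxel_size_mm voxel size in mm per axis.
#' @param n_bins number of respiratory bins Nb (default 4).
#' @param n_coils number of receiver coils Nc.
#' @param n_heartbeats number of heartbeats (>= n_bins).
#' @param motion_amplitude_vox peak foot-head respiratory displacement in
#'   voxels; 0 gives a static phantom with all bins identical.
#' @param noise_snr acquisition SNR (mean |signal| / complex noise std), or
#'   `NULL` for noiseless simulation.
#' @param seed integer seed controlling all randomness in the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 64L, 48L),
                         voxel_size_mm = c(1.5, 1.5, 1.5),
                         n_bins = 4L,
                         n_coils = 4L,
                         n_heartbeats = 96L,
                         motion_amplitude_vox = 3,
                         noise_snr = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers, each >= 8")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_coils < 1L) stop("n_coils must be >= 1")
  if (n_heartbeats < n_bins) stop("n_heartbeats must be >= n_bins")
  if (motion_amplitude_vox < 0) stop("motion_amplitude_vox must be >= 0")
  if (!is.null(noise_snr) && noise_snr <= 0) stop("noise_snr must be positive")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_bins = as.integer(n_bins), n_coils = as.integer(n_coils),
                 n_heartbeats = as.integer(n_heartbeats),
                 motion_amplitude_vox = motion_amplitude_vox,
                 noise_snr = noise_snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth zero-mean random scalar field, normalized to max |.| = 1, built by
# low-pass filtering white noise in k-space with a Gaussian envelope.
smooth_random_field <- function(grid, cutoff = 0.12) {
  noise <- array(stats::rnorm(prod(grid)), grid)
  k <- ft3(noise)
  r2 <- outer(outer((kcoords(grid[1]) / grid[1])^2, (kcoords(grid[2]) / grid[2])^2, `+`),
              (kcoords(grid[3]) / grid[3])^2, `+`)
  f <- Re(ift3(k * exp(-r2 / (2 * cutoff^2))))
  f <- f - mean(f)
  f / max(abs(f))
}

# Zero-mean random field band-limited to an annulus of normalized spatial
# frequency, peak-normalized; used for anatomical texture.
bandpass_random_field <- function(grid, r_lo, r_hi) {
  noise <- array(stats::rnorm(prod(grid)), grid)
  k <- ft3(noise)
  r2 <- outer(outer((kcoords(grid[1]) / (grid[1] / 2))^2,
                    (kcoords(grid[2]) / (grid[2] / 2))^2, `+`),
              (kcoords(grid[3]) / (grid[3] / 2))^2, `+`)
  r <- sqrt(r2)
  f <- Re(ift3(k * (r >= r_lo & r <= r_hi)))
  f <- f - mean(f)
  f / stats::sd(f)
}

# Pseudo-periodic breathing trace: two incommensurate sinusoids plus seeded
# jitter, normalized to a given peak amplitude.
breathing_trace <- function(n, amplitude) {
  if (amplitude == 0) return(rep(0, n))
  t <- seq_len(n)
  p <- stats::runif(2, 0, 2 * pi)
  s <- 0.7 * sin(2 * pi * t / 4.3 + p[1]) + 0.3 * sin(2 * pi * t / 13.7 + p[2]) +
    0.05 * stats::rnorm(n)
  s / max(abs(s)) * amplitude
}

# Equal-population hard bin assignment by quantiles of a signal
# (ties broken by heartbeat order).
quantile_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

# Reference anatomy: soft-edged ellipsoids plus a curved 2-voxel-diameter
# bright tube; returns list(image = complex volume, centerline = [n,3] 0-based
# voxel coordinates of the vessel).
phantom_anatomy <- function(grid) {
  u <- (seq_len(grid[1]) - 1 - (grid[1] - 1) / 2) / (grid[1] / 2)
  v <- (seq_len(grid[2]) - 1 - (grid[2] - 1) / 2) / (grid[2] / 2)
  w <- (seq_len(grid[3]) - 1 - (grid[3] - 1) / 2) / (grid[3] / 2)
  U <- array(rep(u, times = grid[2] * grid[3]), grid)
  V <- aperm(array(rep(v, times = grid[1] * grid[3]), grid[c(2, 1, 3)]), c(2, 1, 3))
  W <- aperm(array(rep(w, times = grid[1] * grid[2]), grid[c(3, 1, 2)]), c(2, 3, 1))
  soft <- function(q, edge = 0.05) pmin(pmax((1 - q) / edge, 0), 1)
  ellipsoid <- function(c0, rad) {
    soft(sqrt(((U - c0[1]) / rad[1])^2 + ((V - c0[2]) / rad[2])^2 + ((W - c0[3]) / rad[3])^2))
  }
  mag <- 0.30 * ellipsoid(c(0, 0, 0), c(0.88, 0.88, 0.88))
  mag <- mag + 0.70 * ellipsoid(c(-0.10, -0.18, 0.10), c(0.34, 0.30, 0.32))
  mag <- mag + 0.50 * ellipsoid(c(0.18, 0.26, -0.12), c(0.28, 0.24, 0.34))
  mag <- mag + 0.35 * ellipsoid(c(0.32, -0.30, 0.22), c(0.16, 0.16, 0.16))
  # curved bright vessel, ~2 voxel diameter, running mostly along x
  tpar <- seq(0, 1, length.out = 256)
  cx <- (-0.55 + 1.10 * tpar) * (grid[1] / 2) + (grid[1] - 1) / 2
  cy <- (0.38 * sin(pi * tpar)) * (grid[2] / 2) + (grid[2] - 1) / 2
  cz <- (0.30 * cos(pi * tpar) * 0.6) * (grid[3] / 2) + (grid[3] - 1) / 2
  Xv <- array(rep(seq_len(grid[1]) - 1, times = grid[2] * grid[3]), grid)
  Yv <- aperm(array(rep(seq_len(grid[2]) - 1, times = grid[1] * grid[3]), grid[c(2, 1, 3)]), c(2, 1, 3))
  Zv <- aperm(array(rep(seq_len(grid[3]) - 1, times = grid[1] * grid[2]), grid[c(3, 1, 2)]), c(2, 3, 1))
  dmin <- array(Inf, grid)
  for (s in seq_along(tpar)) {
    d2 <- (Xv - cx[s])^2 + (Yv - cy[s])^2 + (Zv - cz[s])^2
    dmin <- pmin(dmin, d2)
  }
  mag <- mag + 0.9 * exp(-dmin / (2 * 0.55^2))
  # band-limited anatomical texture (trabeculation / fine-structure
  # surrogate): real whole-heart images carry spatial-frequency content
  # well beyond the low-resolution shutter, which is precisely what a
  # super-resolving reconstruction must recover
  tex <- bandpass_random_field(grid, r_lo = 0.15, r_hi = 0.45)
  mag <- mag * pmax(0, 1 + 0.2 * tex)
  phase <- 0.3 * smooth_random_field(grid)
  list(image = mag * exp(1i * phase),
       centerline = cbind(cx, cy, cz))
}

#' Generate a synthetic moving-heart phantom
#'
#' Builds a complex 3D reference anatomy (end-expiration state), a
#' pseudo-periodic breathing signal, per-bin true motion fields (a bulk
#' foot-head/left-right translation plus a low-spatial-frequency non-rigid
#' component obtained by scaling-and-squaring of a smooth random velocity, so
#' the deformations are diffeomorphic by construction), per-bin images, and
#' normalized coil maps. Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth` with elements `bin_images` (list of
#'   complex volumes), `reference_bin`, `true_fields` and `nonrigid_fields`
#'   ([motion_field_set()]s), `coil_maps`, `breathing` (per-heartbeat `fh`,
#'   `lr` displacements in voxels), `bin_assignment`, `bin_centers`,
#'   `vessel_centerline`, and the input `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid_shape
  set.seed(spec$seed)
  anat <- phantom_anatomy(grid)
  ref <- anat$image

  fh <- breathing_trace(spec$n_heartbeats, spec$motion_amplitude_vox)
  lr <- breathing_trace(spec$n_heartbeats, 0.4 * spec$motion_amplitude_vox)
  bins <- quantile_bins(fh, spec$n_bins)
  centers_fh <- vapply(seq_len(spec$n_bins), function(b) mean(fh[bins == b]), 0)
  centers_lr <- vapply(seq_len(spec$n_bins), function(b) mean(lr[bins == b]), 0)
  reference_bin <- which.min(abs(centers_fh))

  # shared low-frequency velocity shape, scaled per bin with the foot-head
  # displacement of the bin relative to the reference
  vbase <- array(0, c(grid, 3))
  for (c in 1:3) vbase[, , , c] <- smooth_random_field(grid, cutoff = 0.06)
  vbase <- vbase / max(abs(vbase))

  nonrigid <- vector("list", spec$n_bins)
  fields <- vector("list", spec$n_bins)
  bin_images <- vector("list", spec$n_bins)
  zerof <- array(0, c(grid, 3))
  for (b in seq_len(spec$n_bins)) {
    dfh <- centers_fh[b] - centers_fh[reference_bin]
    dlr <- centers_lr[b] - centers_lr[reference_bin]
    if (b == reference_bin || spec$motion_amplitude_vox == 0) {
      nonrigid[[b]] <- zerof
      fields[[b]] <- zerof
      bin_images[[b]] <- ref
    } else {
      nonrigid[[b]] <- scaling_and_squaring(vbase * (0.5 * dfh))
      f <- nonrigid[[b]]
      f[, , , 1] <- f[, , , 1] + dfh
      f[, , , 2] <- f[, , , 2] + dlr
      fields[[b]] <- f
      bin_images[[b]] <- warp_image(ref, f)
    }
  }

  structure(list(
    spec = spec,
    bin_images = bin_images,
    reference_bin = reference_bin,
    true_fields = motion_field_set(fields, reference_bin),
    nonrigid_fields = motion_field_set(nonrigid, reference_bin),
    coil_maps = simulate_coil_maps(grid, spec$n_coils, spec$seed + 1L),
    breathing = data.frame(heartbeat = seq_len(spec$n_heartbeats), fh = fh, lr = lr),
    bin_assignment = bins,
    bin_centers = data.frame(bin = seq_len(spec$n_bins), fh = centers_fh, lr = centers_lr),
    vessel_centerline = anat$centerline
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> grid %s, %d bins (reference %d), %d coils, %d heartbeats\n",
              paste(x$spec$grid_shape, collapse = "x"), x$spec$n_bins,
              x$reference_bin, x$spec$n_coils, x$spec$n_heartbeats))
  invisible(x)
}

#' Simulate smooth normalized coil sensitivity maps
#'
#' Gaussian sensitivity lobes centered around the volume with smooth phase,
#' normalized so the per-voxel sum over coils of squared magnitudes is exactly
#' one. A single coil gives the identity map.
#'
#' @param grid_shape three positive integers.
#' @param n_coils number of coils (>= 1).
#' @param seed integer seed.
#' @return complex array `[X, Y, Z, n_coils]`.
#' @export
simulate_coil_maps <- function(grid_shape, n_coils, seed = 1L) {
  grid <- as.integer(grid_shape)
  stopifnot(length(grid) == 3L, all(grid >= 1L), n_coils >= 1L)
  if (n_coils == 1L) return(array(1 + 0i, c(grid, 1L)))
  set.seed(as.integer(seed))
  u <- (seq_len(grid[1]) - 1 - (grid[1] - 1) / 2) / (grid[1] / 2)
  v <- (seq_len(grid[2]) - 1 - (grid[2] - 1) / 2) / (grid[2] / 2)
  w <- (seq_len(grid[3]) - 1 - (grid[3] - 1) / 2) / (grid[3] / 2)
  U <- array(rep(u, times = grid[2] * grid[3]), grid)
  V <- aperm(array(rep(v, times = grid[1] * grid[3]), grid[c(2, 1, 3)]), c(2, 1, 3))
  W <- aperm(array(rep(w, times = grid[1] * grid[2]), grid[c(3, 1, 2)]), c(2, 3, 1))
  maps <- array(0i, c(grid, n_coils))
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils + stats::runif(1, 0, 2 * pi)
  for (k in seq_len(n_coils)) {
    c0 <- c(0.2 * sin(ang[k]), 1.15 * cos(ang[k]), 1.15 * sin(ang[k]))
    amp <- exp(-(((U - c0[1])^2 + (V - c0[2])^2 + (W - c0[3])^2)) / (2 * 0.9^2))
    ph <- stats::runif(1, 0, 2 * pi) + 0.6 * (V * sin(ang[k]) - W * cos(ang[k]))
    maps[, , , k] <- amp * exp(1i * ph)
  }
  ss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  for (k in seq_len(n_coils)) maps[, , , k] <- maps[, , , k] / ss
  maps
}

# central-slab coronal (x-y) magnitude projection, block-averaged by `scale`
inav_projection <- function(vol, scale = 2L) {
  d <- dim(vol)
  slab <- seq.int(max(1L, floor(d[3] / 3)), min(d[3], ceiling(2 * d[3] / 3)))
  proj <- apply(Mod(vol[, , slab, drop = FALSE]), c(1, 2), mean)
  nx <- (d[1] %/% scale) * scale
  ny <- (d[2] %/% scale) * scale
  proj <- proj[seq_len(nx), seq_len(ny)]
  blk <- array(proj, c(scale, nx %/% scale, scale, ny %/% scale))
  apply(blk, c(2, 4), mean)
}

#' Simulate a VD-CASPR acquisition of a moving phantom
#'
#' For every heartbeat, the sampled k-space readouts are drawn from the
#' non-rigid motion state of that heartbeat's respiratory bin, with the full
#' per-heartbeat in-plane (foot-head, left-right) translation applied as a
#' k-space phase ramp -- so the downstream translational correction has real
#' work to do. A 2D coronal image navigator (central-slab magnitude
#' projection at 2x coarser resolution, shifted with the current breathing
#' position) is produced per heartbeat. Optional complex Gaussian noise is
#' added at the requested SNR (mean |signal| / complex noise std).
#'
#' @param truth a [generate_phantom()] result.
#' @param trajectory a [generate_vdcaspr()] trajectory on the low-resolution
#'   (ky, kz) grid.
#' @param noise_snr SNR, or `NULL` (default: `truth$spec$noise_snr`).
#' @param seed seed for the noise draw (default derived from the phantom seed).
#' @return object of class `raw_kspace`: per-heartbeat k-space readout blocks,
#'   high-resolution-grid trajectory indices, iNAV stack and geometry
#'   attributes.
#' @export
simulate_acquisition <- function(truth, trajectory, noise_snr = NULL, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(trajectory, "vdcaspr_trajectory"))
  spec <- truth$spec
  grid <- spec$grid_shape
  hb <- spec$n_heartbeats
  if (length(trajectory$readouts) != hb)
    stop("trajectory heartbeats do not match the breathing signal length")
  if (is.null(noise_snr)) noise_snr <- spec$noise_snr

  lr_grid <- trajectory$grid_yz
  offs <- c(grid[2] %/% 2L - lr_grid[1] %/% 2L, grid[3] %/% 2L - lr_grid[2] %/% 2L)
  nb <- spec$n_bins
  nc <- spec$n_coils

  # per-bin non-rigid states and their coil k-spaces
  kbins <- vector("list", nb)
  projs <- vector("list", nb)
  for (b in seq_len(nb)) {
    state <- if (b == truth$reference_bin) truth$bin_images[[truth$reference_bin]] else
      warp_image(truth$bin_images[[truth$reference_bin]], truth$nonrigid_fields$fields[[b]])
    kb <- vector("list", nc)
    for (c in seq_len(nc)) kb[[c]] <- ft3(state * truth$coil_maps[, , , c])
    kbins[[b]] <- kb
    projs[[b]] <- apply(Mod(state[, , seq.int(max(1L, floor(grid[3] / 3)),
                                              min(grid[3], ceiling(2 * grid[3] / 3))), drop = FALSE]),
                        c(1, 2), mean)
  }

  kx <- kcoords(grid[1])
  kspace <- vector("list", hb)
  traj_hr <- vector("list", hb)
  inav_scale <- 2L
  nx2 <- (grid[1] %/% inav_scale)
  ny2 <- (grid[2] %/% inav_scale)
  inavs <- array(0, c(nx2, ny2, hb))

  for (h in seq_len(hb)) {
    ro <- trajectory$readouts[[h]]            # [Rh, 2] 0-based lr (ky, kz)
    hr <- cbind(ro[, 1] + offs[1], ro[, 2] + offs[2])
    if (any(hr[, 1] < 0L) || any(hr[, 1] >= grid[2]) ||
        any(hr[, 2] < 0L) || any(hr[, 2] >= grid[3]))
      stop("trajectory indices outside grid")
    traj_hr[[h]] <- hr
    b <- truth$bin_assignment[h]
    cols <- hr[, 1] + 1L + grid[2] * hr[, 2]
    fh <- truth$breathing$fh[h]
    lrs <- truth$breathing$lr[h]
    kyc <- hr[, 1] - grid[2] %/% 2L
    ph <- exp(-2i * pi * (outer(kx * fh / grid[1], rep(1, nrow(hr))) +
                          outer(rep(1, grid[1]), kyc * lrs / grid[2])))
    blk <- array(0i, c(grid[1], nrow(hr), nc))
    for (c in seq_len(nc)) {
      km <- matrix(kbins[[b]][[c]], grid[1], grid[2] * grid[3])
      blk[, , c] <- km[, cols, drop = FALSE] * ph
    }
    kspace[[h]] <- blk
    pj <- translate2(projs[[b]], c(fh, lrs))
    pj <- pj[seq_len(nx2 * inav_scale), seq_len(ny2 * inav_scale)]
    bk <- array(pj, c(inav_scale, nx2, inav_scale, ny2))
    inavs[, , h] <- apply(bk, c(2, 4), mean)
  }

  if (!is.null(noise_snr)) {
    if (is.null(seed)) seed <- spec$seed + 1000L
    set.seed(as.integer(seed))
    sig <- mean(Mod(unlist(kspace)))
    sigma <- sig / noise_snr
    for (h in seq_len(hb)) {
      n <- length(kspace[[h]])
      if (n == 0L) next
      kspace[[h]] <- kspace[[h]] + array(
        complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * sigma / sqrt(2),
        dim(kspace[[h]]))
    }
  }

  structure(list(kspace = kspace, traj = traj_hr, inav = inavs,
                 grid = grid, voxel_size_mm = spec$voxel_size_mm,
                 lr_grid = lr_grid, lr_offset = offs,
                 lr_shutter = trajectory$shutter,
                 inav_scale = inav_scale, n_coils = nc,
                 n_heartbeats = hb),
            class = "raw_kspace")
}

#' @export
print.raw_kspace <- function(x, ...) {
  cat(sprintf("<raw_kspace> grid %s, %d heartbeats, %d coils, lr grid %s\n",
              paste(x$grid, collapse = "x"), x$n_heartbeats, x$n_coils,
              paste(x$lr_grid, collapse = "x")))
  invisible(x)
}
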