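# VD-CASPR trajectory generation, iNAV-based translational correction and
# soft-gated respiratory binning.
#
# Trajectory construction (no canonical interleave formula exists for this
# sequence family, so this generator defines its own): candidate (ky, kz) points inside an elliptical
# shutter are selected with density decreasing in normalized elliptical
# radius, then distributed over heartbeats as spiral-like interleaves whose
# arm phase rotates by the golden angle (~111.25 deg) every heartbeat; each
# heartbeat's readouts are ordered center-out.

GOLDEN_ANGLE_RAD <- 111.24611 * pi / 180

# normalized elliptical radius of every (ky, kz) point of a grid (0-based
# indices, DC at floor(N/2)); the inscribed ellipse is r <= 1
shutter_radius <- function(grid_yz) {
  y <- (seq_len(grid_yz[1]) - 1 - grid_yz[1] %/% 2) / (grid_yz[1] / 2)
  z <- (seq_len(grid_yz[2]) - 1 - grid_yz[2] %/% 2) / (grid_yz[2] / 2)
  sqrt(outer(y^2, z^2, `+`))
}

#' Elliptical shutter mask
#'
#' Logical mask of the ellipse inscribed in a rectangular (ky, kz) grid,
#' centered on the DC index `floor(N/2)`.
#'
#' @param grid_yz two integers `c(Ny, Nz)`.
#' @return logical `[Ny, Nz]` matrix.
#' @export
elliptical_shutter <- function(grid_yz) shutter_radius(grid_yz) <= 1

#' Generate a VD-CASPR sampling trajectory
#'
#' Variable-density Cartesian sampling with spiral profile order in the
#' (ky, kz) phase-encoding plane; every sampled point is a fully sampled kx
#' readout. Sampling density decreases with elliptical radius, interleaves
#' rotate by the golden angle per heartbeat, and all points lie within the
#' shutter. Deterministic for a fixed seed.
#'
#' @param grid_yz phase-encoding grid `c(Ny, Nz)`.
#' @param undersampling nominal undersampling factor (>= 1) relative to the
#'   shutter; the number of unique sampled points is `round(shutter / factor)`.
#' @param n_heartbeats number of heartbeats over which readouts are spread.
#' @param readouts_per_heartbeat maximum readouts acquired per heartbeat
#'   (default `ceiling(n_points / n_heartbeats)`).
#' @param seed integer seed.
#' @param shutter `"ellipse"` (default) or `"full"` for a rectangular shutter.
#' @return object of class `vdcaspr_trajectory`: per-heartbeat 0-based
#'   `[R, 2]` (ky, kz) index matrices, the shutter mask and geometry.
#' @export
generate_vdcaspr <- function(grid_yz, undersampling = 1, n_heartbeats,
                             readouts_per_heartbeat = NULL, seed = 1L,
                             shutter = c("ellipse", "full")) {
  shutter <- match.arg(shutter)
  grid_yz <- as.integer(grid_yz)
  stopifnot(length(grid_yz) == 2L, n_heartbeats >= 1L)
  if (undersampling < 1) stop("undersampling must be >= 1")
  r <- shutter_radius(grid_yz)
  mask <- if (shutter == "ellipse") r <= 1 else r <= Inf
  S <- sum(mask)
  if (S < 4L) stop("grid too small to host one interleave")
  M <- max(1L, as.integer(round(S / undersampling)))

  set.seed(as.integer(seed))
  idx <- which(mask, arr.ind = TRUE)             # 1-based (ky, kz)
  rr <- r[mask]
  w <- (pmax(1 - rr, 0) + 0.05)^2                # variable-density weight
  kept <- if (M >= S) seq_len(S) else sample.int(S, M, prob = w)

  yn <- (idx[kept, 1] - 1 - grid_yz[1] %/% 2) / (grid_yz[1] / 2)
  zn <- (idx[kept, 2] - 1 - grid_yz[2] %/% 2) / (grid_yz[2] / 2)
  rk <- rr[kept]
  theta <- atan2(zn, yn)
  phi <- (theta - 2 * pi * rk) %% (2 * pi)       # spiral arm phase

  if (is.null(readouts_per_heartbeat))
    readouts_per_heartbeat <- ceiling(M / n_heartbeats)
  readouts_per_heartbeat <- as.integer(readouts_per_heartbeat)
  if (readouts_per_heartbeat < 1L) stop("readouts_per_heartbeat must be >= 1")
  if (n_heartbeats * readouts_per_heartbeat < M)
    stop("requested sampling exceeds total readout capacity of the scan")

  psi <- (GOLDEN_ANGLE_RAD * (seq_len(n_heartbeats) - 1)) %% (2 * pi)
  cap <- rep(readouts_per_heartbeat, n_heartbeats)
  assign_hb <- integer(M)
  # greedy nearest-arm assignment with capacity, center-out point order
  for (p in order(rk)) {
    d <- abs(((phi[p] - psi + pi) %% (2 * pi)) - pi)
    for (h in order(d)) {
      if (cap[h] > 0L) { assign_hb[p] <- h; cap[h] <- cap[h] - 1L; break }
    }
  }

  readouts <- vector("list", n_heartbeats)
  for (h in seq_len(n_heartbeats)) {
    pts <- which(assign_hb == h)
    pts <- pts[order(rk[pts], phi[pts])]
    readouts[[h]] <- cbind(ky = idx[kept[pts], 1] - 1L, kz = idx[kept[pts], 2] - 1L)
  }

  structure(list(readouts = readouts, shutter = mask, grid_yz = grid_yz,
                 nominal_undersampling = undersampling,
                 n_unique_points = M, seed = as.integer(seed)),
            class = "vdcaspr_trajectory")
}

#' @export
print.vdcaspr_trajectory <- function(x, ...) {
  cat(sprintf("<vdcaspr_trajectory> %s grid, %d heartbeats, %d unique points (nominal %.2fx)\n",
              paste(x$grid_yz, collapse = "x"), length(x$readouts),
              x$n_unique_points, x$nominal_undersampling))
  invisible(x)
}

#' Estimate in-plane translations from image navigators
#'
#' Normalized cross-correlation of a template box over integer shifts with
#' parabolic sub-pixel refinement, per heartbeat, relative to the first
#' navigator (or re-centered on the per-axis median).
#'
#' @param inavs real array `[nx, ny, n_heartbeats]` of 2D coronal navigators.
#' @param template_box list with 1-based inclusive index ranges `x` and `y`
#'   defining the template region (default: central half of the frame).
#' @param max_shift integer search radius in navigator pixels (default: the
#'   largest radius the box allows, capped at 8).
#' @param reference `"first"` (shifts relative to heartbeat 1) or `"median"`
#'   (per-axis median position subtracted).
#' @param scale multiply estimated shifts by this factor (e.g. the navigator
#'   downsampling factor, to express shifts in image voxels).
#' @return a `resp_signal` data frame with per-heartbeat `fh` (x) and `lr`
#'   (y) displacements.
#' @export
estimate_inav_translations <- function(inavs, template_box = NULL, max_shift = NULL,
                                       reference = c("first", "median"), scale = 1) {
  reference <- match.arg(reference)
  d <- dim(inavs)
  stopifnot(length(d) == 3L, d[3] >= 1L)
  if (is.null(template_box)) {
    template_box <- list(x = c(floor(d[1] / 4) + 1L, floor(3 * d[1] / 4)),
                         y = c(floor(d[2] / 4) + 1L, floor(3 * d[2] / 4)))
  }
  bx <- seq.int(template_box$x[1], template_box$x[2])
  by <- seq.int(template_box$y[1], template_box$y[2])
  if (min(bx) < 1L || max(bx) > d[1] || min(by) < 1L || max(by) > d[2])
    stop("template box outside the navigator frame")
  tmpl <- as.vector(inavs[bx, by, 1])
  if (stats::sd(tmpl) == 0) stop("flat (zero-variance) template")
  margin <- min(min(bx) - 1L, d[1] - max(bx), min(by) - 1L, d[2] - max(by))
  if (is.null(max_shift)) max_shift <- min(8L, margin)
  max_shift <- min(as.integer(max_shift), margin)
  if (max_shift < 1L) stop("template box leaves no room to search for shifts")

  shifts <- -max_shift:max_shift
  ns <- length(shifts)
  est <- matrix(0, d[3], 2)
  for (h in seq_len(d[3])) {
    cc <- matrix(-Inf, ns, ns)
    for (a in seq_len(ns)) for (b in seq_len(ns)) {
      patch <- as.vector(inavs[bx + shifts[a], by + shifts[b], h])
      if (stats::sd(patch) > 0) cc[a, b] <- stats::cor(tmpl, patch)
    }
    pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    refine <- function(vals, i) {
      if (i <= 1L || i >= length(vals)) return(0)
      den <- vals[i - 1] - 2 * vals[i] + vals[i + 1]
      if (!is.finite(den) || den >= 0) return(0)
      0.5 * (vals[i - 1] - vals[i + 1]) / den
    }
    est[h, 1] <- shifts[pk[1]] + refine(cc[, pk[2]], pk[1])
    est[h, 2] <- shifts[pk[2]] + refine(cc[pk[1], ], pk[2])
  }
  if (reference == "first") {
    est <- sweep(est, 2, est[1, ])
  } else {
    est <- sweep(est, 2, apply(est, 2, stats::median))
  }
  out <- data.frame(heartbeat = seq_len(d[3]), fh = est[, 1] * scale, lr = est[, 2] * scale)
  class(out) <- c("resp_signal", "data.frame")
  out
}

#' Apply k-space translational correction
#'
#' Multiplies each heartbeat's readout samples by the linear phase
#' `exp(-2i*pi*(kx*dx/Nx + ky*dy/Ny))` (centered integer frequencies), the
#' k-space equivalent of an in-plane (x, y) image shift by `(dx, dy)`. The
#' operation is unitary on each sample. To undo a measured heart displacement
#' `s`, pass `-s`.
#'
#' @param raw a `raw_kspace` object.
#' @param signal a `resp_signal` data frame with one `(fh, lr)` row per
#'   heartbeat, in image voxels.
#' @return the corrected `raw_kspace`.
#' @export
apply_translational_correction <- function(raw, signal) {
  stopifnot(inherits(raw, "raw_kspace"))
  if (nrow(signal) != raw$n_heartbeats)
    stop("signal length does not match the number of heartbeats")
  kx <- kcoords(raw$grid[1])
  for (h in seq_len(raw$n_heartbeats)) {
    dx <- signal$fh[h]; dy <- signal$lr[h]
    if (dx == 0 && dy == 0) next
    hr <- raw$traj[[h]]
    if (nrow(hr) == 0L) next
    kyc <- hr[, 1] - raw$grid[2] %/% 2L
    ph <- exp(-2i * pi * (outer(kx * dx / raw$grid[1], rep(1, nrow(hr))) +
                          outer(rep(1, raw$grid[1]), kyc * dy / raw$grid[2])))
    for (c in seq_len(raw$n_coils)) raw$kspace[[h]][, , c] <- raw$kspace[[h]][, , c] * ph
  }
  raw
}

#' Soft-gated respiratory binning
#'
#' Heartbeats are hard-assigned to `n_bins` equally populated bins by
#' quantiles of the foot-head signal (ties broken by heartbeat order). Each
#' heartbeat additionally receives Gaussian soft-gating weights in
#' neighboring bins, `exp(-d^2 / (2 sigma^2))` with `d` the distance from the
#' bin's signal center and `sigma` half the bin's quantile width, truncated
#' to zero below 0.05; the weight in the hard-assigned bin is 1. The
#' reference bin is the one with the smallest mean foot-head displacement
#' (end expiration).
#'
#' @param traj a `vdcaspr_trajectory` or `raw_kspace` (used for per-heartbeat
#'   readout counts).
#' @param signal a `resp_signal` data frame (one row per heartbeat).
#' @param n_bins number of respiratory bins.
#' @return object of class `sampling_plan`: per-bin heartbeat members with
#'   weights, per-bin sample counts `Ki`, total acquired count `K`, bin
#'   centers and the reference bin.
#' @export
soft_gated_binning <- function(traj, signal, n_bins = 4L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  ro_counts <- if (inherits(traj, "raw_kspace")) {
    vapply(traj$traj, nrow, 1L)
  } else if (inherits(traj, "vdcaspr_trajectory")) {
    vapply(traj$readouts, nrow, 1L)
  } else stop("traj must be a vdcaspr_trajectory or raw_kspace")
  hb <- length(ro_counts)
  if (nrow(signal) != hb) stop("signal length does not match heartbeats")
  if (n_bins > hb) stop("more bins than heartbeats")

  fh <- signal$fh
  assign_hb <- quantile_bins(fh, n_bins)
  centers <- vapply(seq_len(n_bins), function(b) mean(fh[assign_hb == b]), 0)
  sigma <- vapply(seq_len(n_bins), function(b) {
    v <- fh[assign_hb == b]; (max(v) - min(v)) / 2
  }, 0)
  reference_bin <- which.min(abs(centers))

  bins <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    w <- ifelse(assign_hb == b, 1,
                if (sigma[b] > 0) exp(-(fh - centers[b])^2 / (2 * sigma[b]^2)) else 0)
    w[w < 0.05] <- 0
    w[assign_hb == b] <- 1
    keep <- which(w > 0)
    bins[[b]] <- list(hb = keep, w = w[keep])
  }
  Ki <- vapply(bins, function(b) sum(ro_counts[b$hb]), 0)
  structure(list(n_bins = n_bins, bins = bins, centers = centers, sigma = sigma,
                 reference_bin = reference_bin, hard_assignment = assign_hb,
                 Ki = Ki, K = sum(ro_counts), ro_counts = ro_counts,
                 signal = signal),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> %d bins (reference %d), K = %d readouts, Ki = %s\n",
              x$n_bins, x$reference_bin, x$K, paste(x$Ki, collapse = "/")))
  invisible(x)
}

#' Acceleration factor accounting
#'
#' Exact point-count arithmetic: the VD-CASPR factor is the number of
#' low-resolution shutter points divided by the number of unique acquired
#' points; the super-resolution factor is the ratio of high- to
#' low-resolution shutter point counts; the overall factor is their product.
#'
#' @param traj a `vdcaspr_trajectory` (acquired points and low-res shutter).
#' @param hr_grid high-resolution `c(Ny, Nz)` phase-encoding grid.
#' @param lr_grid low-resolution grid (default: the trajectory grid).
#' @return list with `vdcaspr`, `sr` and `overall` factors.
#' @export
compute_acceleration_factors <- function(traj, hr_grid, lr_grid = NULL) {
  stopifnot(inherits(traj, "vdcaspr_trajectory"))
  if (is.null(lr_grid)) lr_grid <- traj$grid_yz
  hr_grid <- as.integer(hr_grid); lr_grid <- as.integer(lr_grid)
  if (any(lr_grid > hr_grid)) stop("low-res grid must be contained in the high-res grid")
  pts <- do.call(rbind, traj$readouts)
  if (is.null(pts) || nrow(pts) == 0L) stop("empty acquisition")
  n_unique <- nrow(unique(pts))
  lr_pts <- sum(traj$shutter)
  hr_pts <- sum(elliptical_shutter(hr_grid))
  vd <- lr_pts / n_unique
  sr <- hr_pts / lr_pts
  list(vdcaspr = vd, sr = sr, overall = vd * sr)
}
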