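# Training-data preparation and patch bookkeeping: annulus density profiles
# of (ky, kz) sampling masks, retrospective down-sampling that retains a
# subset of genuinely acquired lines (never synthesizing samples), zero
# padding of k-space to multiples of 16, and overlapping x-direction
# patching with edge-discarding recombination.

#' Sampling mask of an acquisition
#'
#' Logical (ky, kz) matrix marking every line acquired at least once.
#'
#' @param x a `vdcaspr_trajectory` (low-res grid) or `raw_kspace` (high-res
#'   grid).
#' @return logical matrix.
#' @export
sampling_mask <- function(x) {
  if (inherits(x, "vdcaspr_trajectory")) {
    m <- matrix(FALSE, x$grid_yz[1], x$grid_yz[2])
    for (ro in x$readouts) if (nrow(ro)) m[ro[, 1:2, drop = FALSE] + 1L] <- TRUE
    m
  } else if (inherits(x, "raw_kspace")) {
    m <- matrix(FALSE, x$grid[2], x$grid[3])
    for (ro in x$traj) if (nrow(ro)) m[ro[, 1:2, drop = FALSE] + 1L] <- TRUE
    m
  } else stop("x must be a vdcaspr_trajectory or raw_kspace")
}

#' Annulus density profile of a sampling mask
#'
#' Segments the elliptical shutter into `n_annuli` concentric elliptic
#' annuli of equal width in normalized elliptical radius and reports the
#' mean acquired fraction in each.
#'
#' @param mask_yz logical (ky, kz) acquisition mask.
#' @param n_annuli number of annuli (default 20).
#' @return object of class `annulus_density_profile` with `density`
#'   (length `n_annuli`, values in `[0, 1]`), per-annulus point counts and
#'   the outer boundary radius (1, the inscribed ellipse).
#' @export
measure_density_profile <- function(mask_yz, n_annuli = 20L) {
  n_annuli <- as.integer(n_annuli)
  r <- shutter_radius(dim(mask_yz))
  inside <- r <= 1
  if (!any(inside)) stop("empty shutter")
  ann <- pmin(pmax(ceiling(r * n_annuli), 1L), n_annuli)
  density <- numeric(n_annuli)
  n_points <- integer(n_annuli)
  for (a in seq_len(n_annuli)) {
    sel <- inside & ann == a
    n_points[a] <- sum(sel)
    density[a] <- if (n_points[a] > 0) mean(mask_yz[sel]) else 0
  }
  structure(list(density = density, n_points = n_points, n_annuli = n_annuli,
                 outer_radius = 1, grid = dim(mask_yz)),
            class = "annulus_density_profile")
}

#' Retrospective k-space down-sampling
#'
#' Emulates a prospective low-resolution, undersampled scan from acquired
#' high-resolution data: the target density profile's annuli are scaled onto
#' the high-resolution grid by the super-resolution factor, every line
#' outside the outermost annulus is discarded, and within each annulus
#' acquired lines are randomly retained until the target density is matched
#' (all available lines are kept, and the shortfall recorded, when the
#' target exceeds availability). Retained samples are a strict subset of the
#' acquired data -- values are never synthesized. Deterministic for a fixed
#' seed.
#'
#' @param raw_hr a high-resolution `raw_kspace`.
#' @param sr_factor super-resolution factor per phase-encoding axis (scalar
#'   or length 2): the annuli are scaled by `1/sr_factor`.
#' @param target_profile an [measure_density_profile()] result from a
#'   prospective-style low-resolution mask.
#' @param seed integer seed for the line-retention draw.
#' @return the down-sampled `raw_kspace`, with attributes
#'   `achieved_profile` (per-annulus retained density) and `shortfall`.
#' @export
retrospective_downsample <- function(raw_hr, sr_factor, target_profile, seed = 1L) {
  stopifnot(inherits(raw_hr, "raw_kspace"),
            inherits(target_profile, "annulus_density_profile"))
  s <- rep(sr_factor, length.out = 2)
  if (any(s < 1)) stop("sr_factor must be >= 1")
  na <- target_profile$n_annuli
  grid <- raw_hr$grid

  # unique acquired lines and their scaled (low-res) elliptical radius
  all_pts <- unique(do.call(rbind, raw_hr$traj))
  yn <- (all_pts[, 1] - grid[2] %/% 2) / (grid[2] / 2)
  zn <- (all_pts[, 2] - grid[3] %/% 2) / (grid[3] / 2)
  r_lr <- sqrt((yn * s[1])^2 + (zn * s[2])^2)

  # per-annulus grid point counts of the scaled shutter on the hr grid
  rg <- shutter_radius(grid[2:3])
  yg <- (seq_len(grid[2]) - 1 - grid[2] %/% 2) / (grid[2] / 2)
  zg <- (seq_len(grid[3]) - 1 - grid[3] %/% 2) / (grid[3] / 2)
  r_lr_grid <- sqrt(outer((yg * s[1])^2, (zg * s[2])^2, `+`))
  ann_grid <- pmin(pmax(ceiling(r_lr_grid * na), 1L), na)
  inside_grid <- r_lr_grid <= 1

  set.seed(as.integer(seed))
  keep <- logical(nrow(all_pts))
  shortfall <- numeric(na)
  achieved <- numeric(na)
  ann_pt <- pmin(pmax(ceiling(r_lr * na), 1L), na)
  for (a in seq_len(na)) {
    avail <- which(r_lr <= 1 & ann_pt == a)
    n_ann <- sum(inside_grid & ann_grid == a)
    if (n_ann == 0L) next
    target_n <- round(target_profile$density[a] * n_ann)
    if (target_n >= length(avail)) {
      keep[avail] <- TRUE
      shortfall[a] <- (target_n - length(avail)) / max(1L, n_ann)
    } else if (target_n > 0L) {
      keep[avail[sample.int(length(avail), target_n)]] <- TRUE
    }
    achieved[a] <- sum(keep[avail]) / n_ann
  }
  kept_key <- paste(all_pts[keep, 1], all_pts[keep, 2])

  out <- raw_hr
  for (h in seq_len(raw_hr$n_heartbeats)) {
    ro <- raw_hr$traj[[h]]
    if (nrow(ro) == 0L) next
    sel <- paste(ro[, 1], ro[, 2]) %in% kept_key
    out$traj[[h]] <- ro[sel, , drop = FALSE]
    out$kspace[[h]] <- raw_hr$kspace[[h]][, sel, , drop = FALSE]
  }
  lr_grid <- as.integer(round(grid[2:3] / s))
  out$lr_grid <- lr_grid
  out$lr_offset <- c(grid[2] %/% 2L - lr_grid[1] %/% 2L,
                     grid[3] %/% 2L - lr_grid[2] %/% 2L)
  out$lr_shutter <- elliptical_shutter(lr_grid)
  attr(out, "achieved_profile") <- achieved
  attr(out, "shortfall") <- shortfall
  out
}

next_multiple_16 <- function(n) as.integer(ceiling(n / 16) * 16)

#' Zero-pad k-space to the next multiple of 16
#'
#' Enlarges the ky and kz grid dimensions to the next multiple of 16 (so
#' pooling/upsampling network layers never meet odd sizes), re-centers the
#' readout indices on the new grid, and rescales sample values so image
#' amplitudes are preserved under the centered unitary DFT convention.
#'
#' @param raw a `raw_kspace`.
#' @return the padded `raw_kspace`.
#' @export
pad_kspace_to_multiple16 <- function(raw) {
  stopifnot(inherits(raw, "raw_kspace"))
  old <- raw$grid
  new_yz <- c(next_multiple_16(old[2]), next_multiple_16(old[3]))
  if (all(new_yz == old[2:3])) return(raw)
  offs <- c(new_yz[1] %/% 2L - old[2] %/% 2L, new_yz[2] %/% 2L - old[3] %/% 2L)
  amp <- sqrt(prod(new_yz) / prod(old[2:3]))
  for (h in seq_len(raw$n_heartbeats)) {
    ro <- raw$traj[[h]]
    if (nrow(ro)) {
      raw$traj[[h]] <- cbind(ro[, 1] + offs[1], ro[, 2] + offs[2])
      raw$kspace[[h]] <- raw$kspace[[h]] * amp
    }
  }
  raw$grid <- c(old[1], new_yz)
  raw$lr_offset <- raw$lr_offset + offs
  raw
}

#' Readout-direction patch plan
#'
#' Overlapping patches along the fully sampled x direction: each patch is
#' `thickness` voxels thick (a multiple of 16), a `discard`-voxel edge layer
#' is dropped on each interior side after processing, and adjacent retained
#' intervals overlap by `overlap` voxels, giving a stride of
#' `thickness - 2*discard - overlap`.
#'
#' @param thickness patch thickness in voxels (multiple of 16, default 32).
#' @param discard edge voxels discarded per interior side (default 5).
#' @param overlap retained-interval overlap in voxels (default 4).
#' @return object of class `patch_plan`.
#' @export
patch_plan <- function(thickness = 32L, discard = 5L, overlap = 4L) {
  thickness <- as.integer(thickness); discard <- as.integer(discard)
  overlap <- as.integer(overlap)
  if (thickness %% 16L != 0L) stop("patch thickness must be a multiple of 16")
  retained <- thickness - 2L * discard
  stride <- retained - overlap
  if (retained < 1L || stride < 1L) stop("discard/overlap leave no usable patch interior")
  structure(list(thickness = thickness, discard = discard, overlap = overlap,
                 retained = retained, stride = stride),
            class = "patch_plan")
}

# 0-based patch start offsets for an x-dimension X; regular stride spacing
# with the final patch anchored at the end; chosen so no voxel is covered by
# more than two retained intervals (exact overlap averaging).
patch_starts <- function(X, plan) {
  th <- plan$thickness
  if (X < th) stop("x dimension is smaller than the patch thickness")
  if (X == th) return(0L)
  reg <- seq.int(0L, X - th - 1L, by = plan$stride)
  gap <- (X - th) - reg[length(reg)]
  if (gap > 0L && gap < plan$overlap && length(reg) > 1L)
    reg <- reg[-length(reg)]
  c(reg, X - th)
}

patch_retained <- function(starts, X, plan) {
  np <- length(starts)
  lo <- ifelse(seq_len(np) == 1L, 0L, starts + plan$discard)
  hi <- ifelse(seq_len(np) == np, X - 1L, starts + plan$thickness - 1L - plan$discard)
  cbind(lo = lo, hi = hi)
}

#' Split a volume into overlapping x-direction patches
#'
#' @param x 3D array (numeric or complex).
#' @param plan a [patch_plan()].
#' @return object of class `patch_set`: `patches` (list of
#'   `[thickness, Y, Z]` arrays), 0-based `starts`, retained intervals and
#'   the original x dimension.
#' @export
split_into_patches <- function(x, plan = patch_plan()) {
  d <- dim(x)
  stopifnot(length(d) == 3L)
  starts <- patch_starts(d[1], plan)
  retained <- patch_retained(starts, d[1], plan)
  patches <- lapply(starts, function(s) x[s + seq_len(plan$thickness), , , drop = FALSE])
  structure(list(patches = patches, starts = starts, retained = retained,
                 X = d[1], plan = plan), class = "patch_set")
}

#' Recombine processed patches into a volume
#'
#' Discards each patch's edge layers (except at the volume boundary) and
#' averages the overlapping retained regions.
#'
#' @param patches a `patch_set` whose `patches` have been processed (shapes
#'   must be unchanged).
#' @param plan the [patch_plan()] (default: the one stored in `patches`).
#' @return the recombined 3D array.
#' @export
recombine_patches <- function(patches, plan = patches$plan) {
  stopifnot(inherits(patches, "patch_set"))
  d <- dim(patches$patches[[1]])
  if (d[1] != plan$thickness) stop("patch thickness inconsistent with the plan")
  cplx <- any(vapply(patches$patches, is.complex, TRUE))
  out <- array(if (cplx) 0i else 0, c(patches$X, d[2], d[3]))
  cnt <- numeric(patches$X)
  for (p in seq_along(patches$patches)) {
    if (!identical(dim(patches$patches[[p]]), d)) stop("inconsistent patch set")
    lo <- patches$retained[p, 1]; hi <- patches$retained[p, 2]
    gl <- (lo:hi) + 1L
    ll <- (lo:hi) - patches$starts[p] + 1L
    out[gl, , ] <- out[gl, , ] + patches$patches[[p]][ll, , , drop = FALSE]
    cnt[gl] <- cnt[gl] + 1
  }
  if (any(cnt == 0)) stop("patch set does not cover the volume")
  out / cnt
}
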