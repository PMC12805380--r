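# The two learned components: the super-resolving residual denoiser S and
# the diffeomorphic motion-estimation network (U-Net + scaling-and-squaring),
# with hand-written vector-Jacobian products for training.

c2ch <- function(x) {
  d <- dim(x)
  out <- array(0, c(d, 2L))
  out[, , , 1] <- Re(x)
  out[, , , 2] <- Im(x)
  out
}

ch2c <- function(a) {
  array(complex(real = a[, , , 1], imaginary = a[, , , 2]), dim(a)[1:3])
}

pad_to_mult <- function(x, mult) {
  d <- dim(x)
  nd <- as.integer(ceiling(d[1:3] / mult) * mult)
  if (all(nd == d[1:3])) return(x)
  if (length(d) == 3L) {
    out <- array(if (is.complex(x)) 0i else 0, nd)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  } else {
    out <- array(if (is.complex(x)) 0i else 0, c(nd, d[4]))
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x
  }
  out
}

#' Super-resolving denoiser network
#'
#' Residual 3-level 3D U-Net acting on the 2-channel (real, imaginary)
#' representation of a complex volume: `S(x) = x + UNet(x)`. Desk-scale
#' channel widths are configurable.
#'
#' @param widths three channel widths (default `c(8, 16, 32)`).
#' @param seed initialization seed.
#' @return object of class `sr_net`.
#' @export
sr_net <- function(widths = c(8L, 16L, 32L), seed = 1L) {
  structure(list(params = unet3_init(2L, 2L, widths, seed), pad_mult = 4L),
            class = "sr_net")
}

#' Apply the denoiser S to a complex volume
#'
#' @param net an [sr_net()].
#' @param x complex 3D volume.
#' @param want_cache keep intermediate activations for a backward pass.
#' @return the denoised volume, or `list(y, cache)` when `want_cache`.
#' @export
apply_denoiser <- function(net, x, want_cache = FALSE) {
  d <- dim(x)
  xp <- pad_to_mult(x, net$pad_mult)
  fw <- unet3_fwd(net$params, c2ch(xp))
  yp <- xp + ch2c(fw$y)
  y <- yp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  dim(y) <- d
  if (!want_cache) return(y)
  list(y = y, cache = list(unet = fw$cache, d = d, dp = dim(xp)))
}

# VJP of apply_denoiser: gy (complex, original dims) ->
# list(gx complex, gparams). Residual path contributes identity.
denoiser_vjp <- function(net, cache, gy) {
  gp <- array(0i, cache$dp)
  gp[seq_len(cache$d[1]), seq_len(cache$d[2]), seq_len(cache$d[3])] <- gy
  bw <- unet3_bwd(net$params, cache$unet, c2ch(gp))
  gx_p <- gp + ch2c(bw$gx)
  gx <- gx_p[seq_len(cache$d[1]), seq_len(cache$d[2]), seq_len(cache$d[3]), drop = FALSE]
  dim(gx) <- cache$d
  list(gx = gx, gparams = bw$gparams)
}

#' Diffeomorphic motion-estimation network
#'
#' A 3-level 3D U-Net consuming a concatenated pair of magnitude volumes
#' (reference, moving), internally downsampled by 2, producing a stationary
#' velocity field which a scaling-and-squaring layer turns into a
#' diffeomorphic displacement. Inputs are zero-padded so every pooling stage
#' meets even sizes; output velocities are upsampled (displacements scaled
#' by 2) and cropped back to the input geometry.
#'
#' @param widths three channel widths.
#' @param seed initialization seed.
#' @param n_steps scaling-and-squaring steps (default 6).
#' @param out_scale multiplier on the predicted velocity (an optimization
#'   aid: larger values let small kernel weights express voxel-scale
#'   displacements).
#' @return object of class `motion_net`.
#' @export
motion_net <- function(widths = c(8L, 16L, 32L), seed = 1L, n_steps = 6L,
                       out_scale = 1) {
  structure(list(params = unet3_init(2L, 3L, widths, seed), pad_mult = 8L,
                 n_steps = as.integer(n_steps), out_scale = out_scale),
            class = "motion_net")
}

# velocity field for a (reference, moving) magnitude pair
motion_net_velocity <- function(net, ref_mag, mov_mag, want_cache = FALSE) {
  d <- dim(ref_mag)
  if (!identical(d, dim(mov_mag))) stop("volume pair geometry mismatch")
  xp <- array(0, c(as.integer(ceiling(d / net$pad_mult) * net$pad_mult), 2L))
  xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 1] <- ref_mag
  xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), 2] <- mov_mag
  xd <- pool_fwd(xp, c(2L, 2L, 2L))
  fw <- unet3_fwd(net$params, xd)
  vfull <- (2 * (net$out_scale %||% 1)) * ups_fwd(fw$y, c(2L, 2L, 2L))
  v <- vfull[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE]
  dim(v) <- c(d, 3L)
  if (!want_cache) return(v)
  list(v = v, cache = list(unet = fw$cache, d = d, dp = dim(xp), dhalf = dim(fw$y)))
}

# VJP: gv [X,Y,Z,3] -> gparams
motion_net_vjp <- function(net, cache, gv) {
  gfull <- array(0, c(cache$dp[1:3], 3L))
  gfull[seq_len(cache$d[1]), seq_len(cache$d[2]), seq_len(cache$d[3]), ] <- gv
  gy <- (2 * (net$out_scale %||% 1)) * ups_bwd(gfull, cache$dhalf, c(2L, 2L, 2L))
  unet3_bwd(net$params, cache$unet, gy)$gparams
}

# scaling-and-squaring with cached intermediates for the backward pass
sns_fwd <- function(v, n_steps) {
  phis <- vector("list", n_steps + 1L)
  phis[[1]] <- v / 2^n_steps
  for (s in seq_len(n_steps)) phis[[s + 1]] <- compose_displacement(phis[[s]], phis[[s]])
  phis
}

# VJP of scaling_and_squaring: gphi (grad w.r.t. final displacement) -> gv
sns_bwd <- function(phis, n_steps, gphi) {
  d <- dim(gphi)
  g <- gphi
  for (s in rev(seq_len(n_steps))) {
    phi <- phis[[s]]
    gnew <- g                                      # direct w-dependence
    for (c in 1:3) {
      gc <- as.double(g[, , , c])
      gnew[, , , c] <- gnew[, , , c] +
        array(.cpp_warp_adj(gc, as.integer(d[1:3]), as.double(phi)), d[1:3])
      gnew <- gnew + array(.cpp_warp_bwd_disp(as.double(phi[, , , c]),
                                              as.integer(d[1:3]),
                                              as.double(phi), gc), d)
    }
    g <- gnew
  }
  g / 2^n_steps
}

#' Estimate per-bin motion fields from auxiliary bin images
#'
#' Each non-reference bin is paired with the reference auxiliary image
#' (magnitudes, normalized by the reference maximum), passed through the
#' motion network and exponentiated by scaling-and-squaring; the resulting
#' displacement fields map reference coordinates into each bin. The
#' reference bin's field is identically zero. Output deformations have
#' positive Jacobian determinant by construction for any network
#' parameters.
#'
#' @param aux_bins list of per-bin auxiliary volumes (complex or real).
#' @param net a [motion_net()], or `NULL` for identity (zero) fields.
#' @param reference_bin index of the reference bin.
#' @param n_steps scaling-and-squaring steps (default: the network setting).
#' @return a [motion_field_set()] with the velocities attached as attribute
#'   `"velocities"`.
#' @export
estimate_motion_fields <- function(aux_bins, net, reference_bin,
                                   n_steps = NULL) {
  nb <- length(aux_bins)
  stopifnot(reference_bin >= 1L, reference_bin <= nb)
  d <- dim(aux_bins[[reference_bin]])
  mags <- lapply(aux_bins, function(v) {
    if (!identical(dim(v), d)) stop("bin volume geometry mismatch")
    Mod(v)
  })
  sc <- max(mags[[reference_bin]])
  if (sc > 0) mags <- lapply(mags, function(m) m / sc)
  fields <- vector("list", nb)
  vels <- vector("list", nb)
  zero <- array(0, c(d, 3L))
  if (is.null(net)) {
    for (b in seq_len(nb)) { fields[[b]] <- zero; vels[[b]] <- zero }
  } else {
    if (is.null(n_steps)) n_steps <- net$n_steps
    for (b in seq_len(nb)) {
      if (b == reference_bin) { fields[[b]] <- zero; vels[[b]] <- zero; next }
      v <- motion_net_velocity(net, mags[[reference_bin]], mags[[b]])
      fields[[b]] <- scaling_and_squaring(v, n_steps)
      vels[[b]] <- v
    }
  }
  out <- motion_field_set(fields, reference_bin)
  attr(out, "velocities") <- vels
  out
}

# Self-supervised Charbonnier motion loss and parameter gradients.
# The network consumes `input_mags` pairs (reference, bin); the loss warps
# `loss_mags[[b]]` toward `loss_mags[[ref]]` with exp(-v_b). `levels` adds
# coarse (average-pooled) pyramid terms to the Charbonnier loss -- the
# standard coarse-to-fine aid for registering displacements larger than the
# image gradient scale; the default is the single-scale loss.
motion_loss_and_grads <- function(net, input_mags, loss_mags, reference_bin,
                                  epsilon = 1e-3, levels = 1L,
                                  smooth_weight = 0) {
  nb <- length(input_mags)
  other <- setdiff(seq_len(nb), reference_bin)
  d <- dim(input_mags[[reference_bin]])
  sc <- max(input_mags[[reference_bin]])
  inm <- if (sc > 0) lapply(input_mags, function(m) m / sc) else input_mags
  total <- 0
  gparams <- NULL
  ref_l <- lapply(levels, function(l) {
    if (l == 1L) loss_mags[[reference_bin]] else
      pool_fwd(array(loss_mags[[reference_bin]], c(d, 1L)), rep(l, 3))[, , , 1]
  })
  for (b in other) {
    mv <- motion_net_velocity(net, inm[[reference_bin]], inm[[b]], want_cache = TRUE)
    phis <- sns_fwd(-mv$v, net$n_steps)
    dinv <- phis[[net$n_steps + 1L]]
    warped <- array(.cpp_warp_fwd(as.double(loss_mags[[b]]), as.integer(d),
                                  as.double(dinv)), d)
    gw <- array(0, d)
    lb <- 0
    for (k in seq_along(levels)) {
      l <- levels[k]
      if (l == 1L) {
        lb <- lb + charbonnier_loss(warped, ref_l[[k]], epsilon)
        gw <- gw + charbonnier_grad(warped, ref_l[[k]], epsilon)
      } else {
        wl <- pool_fwd(array(warped, c(d, 1L)), rep(l, 3))[, , , 1]
        dl <- dim(wl)
        lb <- lb + charbonnier_loss(wl, ref_l[[k]], epsilon)
        gl <- charbonnier_grad(wl, ref_l[[k]], epsilon)
        gw <- gw + pool_bwd(array(gl, c(dl, 1L)), c(d, 1L), rep(l, 3))[, , , 1]
      }
    }
    total <- total + lb / length(levels)
    gw <- gw / (length(levels) * length(other))
    gdisp <- array(.cpp_warp_bwd_disp(as.double(loss_mags[[b]]), as.integer(d),
                                      as.double(dinv), as.double(gw)), c(d, 3L))
    gv <- -sns_bwd(phis, net$n_steps, gdisp)
    if (smooth_weight > 0) {
      sm <- velocity_smoothness(mv$v)
      total <- total + smooth_weight * sm$value
      gv <- gv + (smooth_weight / length(other)) * sm$grad
    }
    gparams <- add_grads(gparams, motion_net_vjp(net, mv$cache, gv))
  }
  list(loss = total / length(other), gparams = gparams)
}

# diffusion regularizer on a velocity field: mean squared forward
# difference over components and axes, with its gradient (negative
# discrete Laplacian). Propagates motion into regions the intensity loss
# leaves unconstrained.
velocity_smoothness <- function(v) {
  d <- dim(v)
  val <- 0
  grad <- array(0, d)
  n <- prod(d[1:3]) * 3
  for (ax in 1:3) {
    idx <- seq_len(d[ax] - 1L)
    sel <- function(a, shift) {
      switch(ax,
             a[idx + shift, , , , drop = FALSE],
             a[, idx + shift, , , drop = FALSE],
             a[, , idx + shift, , drop = FALSE])
    }
    dv <- sel(v, 1L) - sel(v, 0L)
    val <- val + sum(dv^2) / n
    g <- 2 * dv / n
    add_at <- function(gr, shift, x) {
      switch(ax, {
        gr[idx + shift, , , ] <- gr[idx + shift, , , ] + x; gr
      }, {
        gr[, idx + shift, , ] <- gr[, idx + shift, , ] + x; gr
      }, {
        gr[, , idx + shift, ] <- gr[, , idx + shift, ] + x; gr
      })
    }
    grad <- add_at(grad, 1L, g)
    grad <- add_at(grad, 0L, -g)
  }
  list(value = val, grad = grad)
}
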