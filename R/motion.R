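# Diffeomorphic motion primitives: trilinear warping with its exact adjoint,
# scaling-and-squaring exponentiation of stationary velocity fields, numerical
# field inversion and finite-difference Jacobians.
#
# A displacement field is a [X, Y, Z, 3] numeric array in voxel units with
# component order (dx, dy, dz); warping evaluates img(x + d(x)) with trilinear
# interpolation and clamped (zero-flux) boundary sampling.

check_disp <- function(disp, gd) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) stop("displacement must be an [X,Y,Z,3] array")
  if (!is.null(gd) && !all(d[1:3] == gd)) stop("displacement grid does not match image grid")
  invisible(d)
}

#' Warp a 3D image by a dense displacement field
#'
#' Trilinear resampling at `x + d(x)` with clamped boundary handling. Complex
#' images are warped component-wise. The companion [warp_adjoint()] is the
#' exact transpose of the interpolation matrix, so `<warp_image(x, d), y> ==
#' <x, warp_adjoint(y, d)>` to numerical precision.
#'
#' @param image 3D numeric or complex array.
#' @param displacement `[X,Y,Z,3]` displacement in voxels.
#' @return array of the same shape and mode as `image`.
#' @export
warp_image <- function(image, displacement) {
  d <- dim(image)
  if (length(d) != 3L) stop("image must be a 3D array")
  check_disp(displacement, d)
  gd <- as.integer(d)
  if (is.complex(image)) {
    re <- .cpp_warp_fwd(Re(image), gd, as.double(displacement))
    im <- .cpp_warp_fwd(Im(image), gd, as.double(displacement))
    out <- complex(real = re, imaginary = im)
  } else {
    out <- .cpp_warp_fwd(as.double(image), gd, as.double(displacement))
  }
  array(out, d)
}

#' @param y 3D array on which the adjoint acts (same grid as the warp output).
#' @param displacement `[X,Y,Z,3]` displacement in voxels.
#' @rdname warp_image
#' @export
warp_adjoint <- function(y, displacement) {
  d <- dim(y)
  if (length(d) != 3L) stop("y must be a 3D array")
  check_disp(displacement, d)
  gd <- as.integer(d)
  if (is.complex(y)) {
    re <- .cpp_warp_adj(Re(y), gd, as.double(displacement))
    im <- .cpp_warp_adj(Im(y), gd, as.double(displacement))
    out <- complex(real = re, imaginary = im)
  } else {
    out <- .cpp_warp_adj(as.double(y), gd, as.double(displacement))
  }
  array(out, d)
}

# Compose two displacement fields: (u after w)(x) = w(x) + u(x + w(x)).
compose_displacement <- function(u, w) {
  d <- dim(u)
  out <- w
  for (c in 1:3) {
    out[, , , c] <- w[, , , c] +
      array(.cpp_warp_fwd(as.double(u[, , , c]), as.integer(d[1:3]), as.double(w)), d[1:3])
  }
  out
}

#' Exponentiate a stationary velocity field by scaling and squaring
#'
#' Computes the displacement field of `exp(v)`: the velocity is scaled by
#' `2^-n_steps` and the resulting small deformation is self-composed
#' `n_steps` times. By construction the output deformation is diffeomorphic
#' (positive Jacobian determinant) for smooth, moderate-magnitude velocities.
#'
#' @param v `[X,Y,Z,3]` stationary velocity field in voxels.
#' @param n_steps integer >= 1, number of squaring steps (default 6).
#' @return `[X,Y,Z,3]` displacement field.
#' @export
scaling_and_squaring <- function(v, n_steps = 6L) {
  check_disp(v, NULL)
  if (!all(is.finite(v))) stop("velocity field contains non-finite values")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  phi <- v / 2^n_steps
  for (s in seq_len(n_steps)) phi <- compose_displacement(phi, phi)
  phi
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the inverse deformation:
#' `inv(x) = -d(x + inv(x))`.
#'
#' @param disp `[X,Y,Z,3]` displacement field.
#' @param n_iter number of fixed-point iterations.
#' @return `[X,Y,Z,3]` displacement field of the inverse map.
#' @export
invert_displacement <- function(disp, n_iter = 30L) {
  d <- dim(disp)
  inv <- -disp
  for (it in seq_len(n_iter)) {
    nxt <- inv
    for (c in 1:3) {
      nxt[, , , c] <- -array(
        .cpp_warp_fwd(as.double(disp[, , , c]), as.integer(d[1:3]), as.double(inv)), d[1:3])
    }
    inv <- nxt
  }
  inv
}

#' Finite-difference Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of `x + d(x)` by central differences on the
#' interior of the grid (one-sided at the edges).
#'
#' @param disp `[X,Y,Z,3]` displacement field.
#' @return 3D array of Jacobian determinants.
#' @export
jacobian_determinant <- function(disp) {
  d <- dim(disp)[1:3]
  grad <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    g <- (ap[ip, , , drop = FALSE] - ap[im, , , drop = FALSE]) / (ip - im)
    aperm(array(g, dim(ap)), order(perm))
  }
  J <- array(0, c(d, 3, 3))
  for (ci in 1:3) for (ax in 1:3) {
    J[, , , ci, ax] <- grad(disp[, , , ci], ax) + as.numeric(ci == ax)
  }
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}

#' Charbonnier loss
#'
#' Smooth approximation to the mean absolute difference:
#' `mean(sqrt(|x - y|^2 + epsilon^2))`. Used as the self-supervised motion
#' loss between the reference-bin image and other bins warped to the
#' reference.
#'
#' @param x,y arrays of identical shape (numeric or complex).
#' @param epsilon smoothing constant, > 0 (default 1e-3).
#' @return scalar loss value.
#' @export
charbonnier_loss <- function(x, y, epsilon = 1e-3) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shape")
  mean(sqrt(Mod(x - y)^2 + epsilon^2))
}

# Gradient of the Charbonnier loss w.r.t. x (real arrays).
charbonnier_grad <- function(x, y, epsilon = 1e-3) {
  r <- x - y
  r / sqrt(r^2 + epsilon^2) / length(x)
}

#' Container for a set of per-bin motion fields
#'
#' Dense displacement fields mapping reference-bin coordinates to each bin
#' (so warping the reference image with field `i` produces the bin-`i` image).
#' The reference bin's field is identically zero.
#'
#' @param fields list of `[X,Y,Z,3]` displacement arrays, one per bin.
#' @param reference_bin 1-based index of the reference (end-expiration) bin.
#' @return object of class `motion_field_set`.
#' @export
motion_field_set <- function(fields, reference_bin) {
  stopifnot(length(fields) >= 1L, reference_bin >= 1L, reference_bin <= length(fields))
  d <- dim(fields[[1]])
  for (f in fields) check_disp(f, d[1:3])
  structure(list(fields = fields, reference_bin = as.integer(reference_bin),
                 grid = d[1:3]),
            class = "motion_field_set")
}

#' @export
print.motion_field_set <- function(x, ...) {
  cat(sprintf("<motion_field_set> %d bins on %s grid, reference bin %d\n",
              length(x$fields), paste(x$grid, collapse = "x"), x$reference_bin))
  invisible(x)
}
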