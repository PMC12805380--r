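# Centered, unitary discrete Fourier transforms.
#
# Convention used throughout the package: the DC sample sits at 0-based index
# floor(N/2) along every transformed axis, and both directions are scaled by
# 1/sqrt(N) so that the adjoint of the forward transform is exactly its
# inverse. Sampled (ky, kz) indices are 0-based on this centered grid.

circshift <- function(x, s) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[((seq_len(n) - 1 - s) %% n) + 1])
  }
  idx <- lapply(seq_along(d), function(a) ((seq_len(d[a]) - 1 - s[a]) %% d[a]) + 1)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftshift <- function(x) circshift(x, dim(x) %/% 2)
ifftshift <- function(x) circshift(x, -(dim(x) %/% 2))

#' Centered unitary 3D Fourier transform
#'
#' Forward transform of a 3D complex array with the DC component centered at
#' 0-based index `floor(N/2)` per axis and unitary `1/sqrt(N)` scaling, so that
#' [ift3()] is both the inverse and the exact adjoint.
#'
#' @param x complex (or numeric) 3D array.
#' @return complex 3D array of the same shape.
#' @export
ft3 <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  fftshift(stats::fft(ifftshift(x))) / sqrt(length(x))
}

#' Centered unitary inverse 3D Fourier transform
#'
#' @param x complex 3D array (centered k-space).
#' @return complex 3D array.
#' @rdname ft3
#' @export
ift3 <- function(x) {
  stopifnot(length(dim(x)) == 3L)
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))
}

# 2D variants (used for image-navigator simulation and registration checks)
ft2 <- function(x) fftshift(stats::fft(ifftshift(x))) / sqrt(length(x))
ift2 <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))

# Centered integer frequency coordinates for an axis of length n: -floor(n/2) ...
kcoords <- function(n) seq_len(n) - 1L - n %/% 2L

# Subpixel periodic translation of a 2D image by t = c(tx, ty) via the Fourier
# shift theorem; out(x) = img(x - t).
translate2 <- function(img, t) {
  d <- dim(img)
  ph <- exp(-2i * pi * (outer(kcoords(d[1]) * t[1] / d[1], kcoords(d[2]) * t[2] / d[2], `+`)))
  out <- ift2(ft2(img) * ph)
  if (is.double(img)) Re(out) else out
}
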