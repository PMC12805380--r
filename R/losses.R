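# Training losses: weighted multi-tap perceptual loss, the pre-training
# objective (perceptual + kernel regularization) and the end-to-end
# objective (perceptual + kernel regularization of both networks +
# self-supervised Charbonnier motion loss).

#' Loss weight configuration
#'
#' The five perceptual feature-map weights (block_conv names), pre-training
#' weights `gamma = (gamma1, gamma2)` and end-to-end weights
#' `eta = (eta1, eta2, eta3)`. Defaults are the framework's reference
#' operating point: psi(1,1)=3.0, psi(2,2)=0.04, psi(3,3)=0.016,
#' psi(4,3)=0.01, psi(5,4)=14.0; gamma = (100, 1); eta = (10, 1, 100).
#'
#' @param psi named positive weights for exactly five feature maps.
#' @param gamma length-2 positive pre-training weights.
#' @param eta length-3 positive end-to-end weights.
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(psi = c("1_1" = 3.0, "2_2" = 0.04, "3_3" = 0.016,
                                 "4_3" = 0.01, "5_4" = 14.0),
                         gamma = c(100, 1),
                         eta = c(10, 1, 100)) {
  if (length(psi) != 5L) stop("psi must contain exactly five perceptual entries")
  if (any(psi <= 0) || any(gamma <= 0) || any(eta <= 0))
    stop("all loss weights must be > 0")
  if (length(gamma) != 2L || length(eta) != 3L)
    stop("gamma must have length 2 and eta length 3")
  structure(list(psi = psi, gamma = gamma, eta = eta), class = "loss_weights")
}

as_psi <- function(weights) {
  if (inherits(weights, "loss_weights")) weights$psi
  else if (is.numeric(weights) && !is.null(names(weights))) weights
  else stop("weights must be a loss_weights object or a named numeric vector")
}

# magnitude of a possibly complex volume plus the VJP back to the input
as_magnitude <- function(x) {
  if (is.complex(x)) {
    m <- sqrt(Re(x)^2 + Im(x)^2 + 1e-24)
    list(m = m, back = function(gm) gm * x / m)
  } else {
    list(m = x, back = function(gm) gm)
  }
}

pad_yz <- function(x, mult) {
  d <- dim(x)
  ny <- ceiling(d[2] / mult) * mult
  nz <- ceiling(d[3] / mult) * mult
  if (ny == d[2] && nz == d[3]) return(x)
  out <- array(0, c(d[1], ny, nz))
  out[, seq_len(d[2]), seq_len(d[3])] <- x
  out
}

#' Weighted perceptual loss between two volumes
#'
#' Magnitude images are sliced along the fully sampled readout (x) direction
#' (the batch dimension of the 2D feature network); each of the extractor's
#' tapped feature maps contributes its mean squared error, normalized over
#' batch, feature width/height and channels, weighted by the matching `psi`
#' entry.
#'
#' @param rho_hr,rho_out complex or real volumes of identical shape.
#' @param extractor a [make_feature_extractor()] (or [identity_extractor()]).
#' @param weights a [loss_weights()] or named numeric `psi` vector; every
#'   extractor tap must have a weight.
#' @return scalar loss.
#' @export
perceptual_loss <- function(rho_hr, rho_out, extractor, weights = loss_weights()) {
  perceptual_loss_grad(rho_hr, rho_out, extractor, weights, want_grad = FALSE)$loss
}

# internal: loss plus gradient w.r.t. rho_out
perceptual_loss_grad <- function(rho_hr, rho_out, extractor, weights = loss_weights(),
                                 want_grad = TRUE) {
  stopifnot(inherits(extractor, "feature_extractor"))
  psi <- as_psi(weights)
  if (!all(extractor$taps %in% names(psi)))
    stop("missing feature map weight for tap(s): ",
         paste(setdiff(extractor$taps, names(psi)), collapse = ", "))
  if (!identical(dim(rho_hr), dim(rho_out))) stop("volumes must share a shape")
  d0 <- dim(rho_out)
  mult <- max(1L, 2L^extractor$n_pools)
  mh <- as_magnitude(rho_hr)
  mo <- as_magnitude(rho_out)
  xh <- pad_yz(mh$m, mult)
  xo <- pad_yz(mo$m, mult)
  fh <- extractor_fwd(extractor, xh)
  fo <- extractor_fwd(extractor, xo)
  loss <- 0
  tap_grads <- list()
  for (tp in extractor$taps) {
    dfm <- fo$features[[tp]] - fh$features[[tp]]
    loss <- loss + psi[[tp]] * mean(dfm^2)
    if (want_grad) tap_grads[[tp]] <- 2 * psi[[tp]] * dfm / length(dfm)
  }
  if (!want_grad) return(list(loss = loss))
  gpad <- extractor_bwd(extractor, fo$caches, tap_grads, dim(xo))
  gm <- gpad[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), drop = FALSE]
  dim(gm) <- d0
  list(loss = loss, grad = mo$back(gm))
}

#' Pre-training loss
#'
#' `gamma1 * L_perc + gamma2 * ||kernels||^2` with defaults
#' `gamma = (100, 1)`; the regularizer is the sum of squared convolution
#' kernel entries of the super-resolving network.
#'
#' @param L_perc scalar perceptual loss.
#' @param kernel_params either a network parameter list or the precomputed
#'   scalar sum of squared kernel entries.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
pretrain_loss <- function(L_perc, kernel_params, weights = loss_weights()) {
  ks <- if (is.numeric(kernel_params) && length(kernel_params) == 1L) kernel_params
        else kernel_sqnorm(kernel_params)
  weights$gamma[1] * L_perc + weights$gamma[2] * ks
}

#' End-to-end training loss
#'
#' `eta1 * L_perc + eta2 * L_reg + eta3 * L_mot` with defaults
#' `eta = (10, 1, 100)`; `L_reg` sums the squared kernel entries of both
#' networks and `L_mot` is the self-supervised Charbonnier motion loss.
#'
#' @param L_perc scalar perceptual loss on the reconstruction.
#' @param kernel_params_both_nets a scalar, or a list of network parameter
#'   lists whose kernel squared norms are summed.
#' @param L_mot scalar Charbonnier motion loss.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
end_to_end_loss <- function(L_perc, kernel_params_both_nets, L_mot,
                            weights = loss_weights()) {
  ks <- if (is.numeric(kernel_params_both_nets) && length(kernel_params_both_nets) == 1L)
    kernel_params_both_nets
  else sum(vapply(kernel_params_both_nets, kernel_sqnorm, 0))
  weights$eta[1] * L_perc + weights$eta[2] * ks + weights$eta[3] * L_mot
}
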