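# Minimal neural-network machinery: 3D convolution layers with hand-written
# backward passes (Rcpp kernels), a 3-level 3D U-Net, the Adam optimizer and
# a fixed-weight convolutional feature extractor for perceptual losses.
#
# Tensors are numeric arrays [X, Y, Z, C]. All parameter initialization is
# driven by R's RNG so fixed seeds give bit-identical networks.

conv_fwd <- function(x, W, b) {
  xd <- dim(x); wd <- dim(W)
  array(.cpp_conv3d_fwd(as.double(x), as.integer(xd), as.double(W),
                        as.integer(wd), as.double(b)),
        c(xd[1:3], wd[5]))
}

conv_bwd <- function(x, W, gy) {
  xd <- dim(x); wd <- dim(W)
  r <- .cpp_conv3d_bwd(as.double(x), as.integer(xd), as.double(W),
                       as.integer(wd), as.double(gy))
  list(gx = array(r$gx, xd), gw = array(r$gw, wd), gb = as.double(r$gb))
}

pool_fwd <- function(x, p = c(2L, 2L, 2L)) {
  xd <- dim(x)
  array(.cpp_avgpool_fwd(as.double(x), as.integer(xd), as.integer(p)),
        c(xd[1:3] %/% p, xd[4]))
}

pool_bwd <- function(gy, xd, p = c(2L, 2L, 2L)) {
  array(.cpp_avgpool_bwd(as.double(gy), as.integer(xd), as.integer(p)), xd)
}

ups_fwd <- function(x, p = c(2L, 2L, 2L)) {
  xd <- dim(x)
  array(.cpp_upsample_fwd(as.double(x), as.integer(xd), as.integer(p)),
        c(xd[1:3] * p, xd[4]))
}

ups_bwd <- function(gy, xd, p = c(2L, 2L, 2L)) {
  array(.cpp_upsample_bwd(as.double(gy), as.integer(xd), as.integer(p)), xd)
}

relu <- function(x) pmax(x, 0)

conv_init <- function(k, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (prod(k) * cin))
  list(W = array(stats::rnorm(prod(k) * cin * cout, sd = sd), c(k, cin, cout)),
       b = numeric(cout))
}

#' Initialize a 3-level 3D U-Net
#'
#' Two 3x3x3 convolution + ReLU blocks per level, 2x average-pool
#' downsampling, nearest-neighbour upsampling with skip concatenation, and a
#' linear 3x3x3 output convolution initialized near zero (so the untrained
#' network output is small).
#'
#' @param c_in,c_out input/output channel counts.
#' @param widths channel widths of the three levels.
#' @param seed integer seed for the weight initialization.
#' @return parameter list of class `unet3`.
#' @export
unet3_init <- function(c_in, c_out, widths = c(16L, 32L, 64L), seed = 1L) {
  set.seed(as.integer(seed))
  w <- as.integer(widths)
  k <- c(3L, 3L, 3L)
  p <- list(
    e1a = conv_init(k, c_in, w[1]),      e1b = conv_init(k, w[1], w[1]),
    e2a = conv_init(k, w[1], w[2]),      e2b = conv_init(k, w[2], w[2]),
    boa = conv_init(k, w[2], w[3]),      bob = conv_init(k, w[3], w[3]),
    d2a = conv_init(k, w[3] + w[2], w[2]), d2b = conv_init(k, w[2], w[2]),
    d1a = conv_init(k, w[2] + w[1], w[1]), d1b = conv_init(k, w[1], w[1]),
    out = conv_init(k, w[1], c_out, gain = 0.1))
  p$out$b[] <- 0
  structure(p, class = "unet3", c_in = c_in, c_out = c_out, widths = w)
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# forward pass; cache retains every convolution input and pre-ReLU output
unet3_fwd <- function(p, x) {
  cb <- function(x, l) {              # conv + relu with cache
    z <- conv_fwd(x, p[[l]]$W, p[[l]]$b)
    list(a = relu(z), x = x, z = z)
  }
  c1a <- cb(x, "e1a"); c1b <- cb(c1a$a, "e1b")
  p1 <- pool_fwd(c1b$a)
  c2a <- cb(p1, "e2a"); c2b <- cb(c2a$a, "e2b")
  p2 <- pool_fwd(c2b$a)
  c3a <- cb(p2, "boa"); c3b <- cb(c3a$a, "bob")
  u2 <- ups_fwd(c3b$a)
  m2 <- cat_ch(u2, c2b$a)
  c4a <- cb(m2, "d2a"); c4b <- cb(c4a$a, "d2b")
  u1 <- ups_fwd(c4b$a)
  m1 <- cat_ch(u1, c1b$a)
  c5a <- cb(m1, "d1a"); c5b <- cb(c5a$a, "d1b")
  y <- conv_fwd(c5b$a, p$out$W, p$out$b)
  list(y = y,
       cache = list(c1a = c1a, c1b = c1b, c2a = c2a, c2b = c2b, c3a = c3a,
                    c3b = c3b, c4a = c4a, c4b = c4b, c5a = c5a, c5b = c5b,
                    d_p1 = dim(c1b$a), d_p2 = dim(c2b$a),
                    d_u2 = dim(c3b$a), d_u1 = dim(c4b$a)))
}

# backward pass; returns gradient lists (same shape as params) and gx
unet3_bwd <- function(p, cache, gy) {
  g <- list()
  back <- function(cblk, l, gout) {    # relu + conv backward
    gz <- gout * (cblk$z > 0)
    r <- conv_bwd(cblk$x, p[[l]]$W, gz)
    g[[l]] <<- list(W = r$gw, b = r$gb)
    r$gx
  }
  r_out <- conv_bwd(cache$c5b$a, p$out$W, gy)
  g$out <- list(W = r_out$gw, b = r_out$gb)
  gm1 <- back(cache$c5a, "d1a", back(cache$c5b, "d1b", r_out$gx))
  n1 <- dim(cache$c4b$a)[4]
  gu1 <- gm1[, , , seq_len(n1), drop = FALSE]
  gskip1 <- gm1[, , , n1 + seq_len(dim(gm1)[4] - n1), drop = FALSE]
  gm2 <- back(cache$c4a, "d2a", back(cache$c4b, "d2b", ups_bwd(gu1, cache$d_u1)))
  n2 <- dim(cache$c3b$a)[4]
  gu2 <- gm2[, , , seq_len(n2), drop = FALSE]
  gskip2 <- gm2[, , , n2 + seq_len(dim(gm2)[4] - n2), drop = FALSE]
  gp2 <- back(cache$c3a, "boa", back(cache$c3b, "bob", ups_bwd(gu2, cache$d_u2)))
  g2 <- pool_bwd(gp2, cache$d_p2) + gskip2
  gp1 <- back(cache$c2a, "e2a", back(cache$c2b, "e2b", g2))
  g1 <- pool_bwd(gp1, cache$d_p1) + gskip1
  gx <- back(cache$c1a, "e1a", back(cache$c1b, "e1b", g1))
  list(gparams = g, gx = gx)
}

# sum of squared convolution-kernel entries (biases excluded)
kernel_sqnorm <- function(p) sum(vapply(p, function(l) sum(l$W^2), 0))

kernel_sqnorm_grads <- function(p, scale) {
  lapply(p, function(l) list(W = 2 * scale * l$W, b = 0 * l$b))
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (n in names(b)) {
    a[[n]]$W <- a[[n]]$W + b[[n]]$W
    a[[n]]$b <- a[[n]]$b + b[[n]]$b
  }
  a
}

scale_grads <- function(g, s) lapply(g, function(l) list(W = l$W * s, b = l$b * s))

#' Adam optimizer state and update
#'
#' @param params a `unet3` (or compatible) parameter list.
#' @return optimizer state for [adam_step()].
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(l) list(W = 0 * l$W, b = 0 * l$b)),
       v = lapply(params, function(l) list(W = 0 * l$W, b = 0 * l$b)),
       t = 0L)
}

#' @param params parameter list; @param grads matching gradient list.
#' @param state optimizer state from [adam_init()].
#' @param lr learning rate; `0` leaves the parameters unchanged.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return list(params, state).
#' @rdname adam_init
#' @export
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (n in names(params)) {
    for (f in c("W", "b")) {
      gg <- grads[[n]][[f]]
      state$m[[n]][[f]] <- beta1 * state$m[[n]][[f]] + (1 - beta1) * gg
      state$v[[n]][[f]] <- beta2 * state$v[[n]][[f]] + (1 - beta2) * gg^2
      params[[n]][[f]] <- params[[n]][[f]] -
        lr * (state$m[[n]][[f]] / bc1) / (sqrt(state$v[[n]][[f]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# Fixed-weight 2D convolutional feature extractor (perceptual loss)
# ---------------------------------------------------------------------------

#' Construct a fixed-seed convolutional feature extractor
#'
#' A frozen random 2D convolutional network with the same five tap points as
#' the VGG-19 feature maps conventionally used for perceptual losses (block
#' 1 conv 1, block 2 conv 2, block 3 conv 3, block 4 conv 3, block 5 conv
#' 4). Convolutions act in the (y, z) plane so readout-direction (x) slices
#' form the batch; 2x average pooling separates blocks. Weights are drawn
#' once from a fixed seed and never trained, providing a deterministic,
#' offline stand-in for a pretrained feature network; a pretrained extractor
#' with the same tap interface can be swapped in.
#'
#' @param channels feature channels per layer.
#' @param seed integer seed for the frozen weights.
#' @return object of class `feature_extractor`.
#' @export
make_feature_extractor <- function(channels = 4L, seed = 7L) {
  set.seed(as.integer(seed))
  k <- c(1L, 3L, 3L)
  ops <- list()
  cin <- 1L
  blocks <- list(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 3L, `5` = 4L)
  taps <- c("1_1", "2_2", "3_3", "4_3", "5_4")
  for (bl in names(blocks)) {
    if (bl != "1") ops[[length(ops) + 1L]] <- list(type = "pool")
    for (cv in seq_len(blocks[[bl]])) {
      tap <- paste0(bl, "_", cv)
      ops[[length(ops) + 1L]] <- c(conv_init(k, cin, channels),
                                   list(type = "conv",
                                        tap = if (tap %in% taps) tap else NA_character_))
      cin <- channels
    }
  }
  structure(list(ops = ops, taps = taps, n_pools = length(blocks) - 1L),
            class = "feature_extractor")
}

#' Identity feature extractor
#'
#' Returns its input as the single feature map named `"id"`; with weight 1
#' the perceptual loss then reduces to the pixelwise mean squared error.
#'
#' @return object of class `feature_extractor`.
#' @export
identity_extractor <- function() {
  structure(list(ops = list(list(type = "identity", tap = "id")),
                 taps = "id", n_pools = 0L),
            class = "feature_extractor")
}

# forward through the extractor; x is a real [X, Y, Z] volume
extractor_fwd <- function(extr, x) {
  a <- array(x, c(dim(x), 1L))
  feats <- list()
  caches <- vector("list", length(extr$ops))
  for (i in seq_along(extr$ops)) {
    op <- extr$ops[[i]]
    if (op$type == "pool") {
      caches[[i]] <- list(type = "pool", d = dim(a))
      a <- pool_fwd(a, c(1L, 2L, 2L))
    } else if (op$type == "conv") {
      z <- conv_fwd(a, op$W, op$b)
      caches[[i]] <- list(type = "conv", x = a, z = z)
      a <- relu(z)
      if (!is.na(op$tap)) feats[[op$tap]] <- a
    } else {                            # identity
      caches[[i]] <- list(type = "identity")
      if (!is.na(op$tap)) feats[[op$tap]] <- a
    }
  }
  list(features = feats, caches = caches)
}

# backward: tap_grads is a named list of gradients w.r.t. the tap outputs;
# returns the gradient w.r.t. the input volume
extractor_bwd <- function(extr, caches, tap_grads, in_dim) {
  g <- NULL
  for (i in rev(seq_along(extr$ops))) {
    op <- extr$ops[[i]]
    ca <- caches[[i]]
    if (op$type != "pool" && !is.na(op$tap) && !is.null(tap_grads[[op$tap]])) {
      g <- if (is.null(g)) tap_grads[[op$tap]] else g + tap_grads[[op$tap]]
    }
    if (is.null(g)) next
    if (op$type == "pool") {
      g <- pool_bwd(g, ca$d, c(1L, 2L, 2L))
    } else if (op$type == "conv") {
      g <- conv_bwd(ca$x, op$W, g * (ca$z > 0))$gx
    }
  }
  if (is.null(g)) g <- array(0, c(in_dim, 1L))
  array(g, in_dim)
}
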