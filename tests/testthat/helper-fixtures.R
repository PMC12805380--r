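# Shared fixtures: tiny phantoms, dense operator materialization, direct DFT
# oracle, smooth blob volumes. Everything is generated in code at test time.

rand_cplx <- function(dims) {
  array(complex(real = stats::rnorm(prod(dims)),
                imaginary = stats::rnorm(prod(dims))), dims)
}

# direct centered unitary DFT at a single (kx, ky, kz) centered frequency
dft_point <- function(img, kx, ky, kz) {
  d <- dim(img)
  s <- 0i
  for (x in 0:(d[1] - 1)) for (y in 0:(d[2] - 1)) for (z in 0:(d[3] - 1)) {
    s <- s + img[x + 1, y + 1, z + 1] *
      exp(-2i * pi * (kx * (x - d[1] %/% 2) / d[1] +
                      ky * (y - d[2] %/% 2) / d[2] +
                      kz * (z - d[3] %/% 2) / d[3]))
  }
  s / sqrt(prod(d))
}

# materialize the encoding operator as a dense matrix (column by column)
dense_forward_matrix <- function(E, grid) {
  vec_b <- function(bk) unlist(lapply(bk$bins, function(x) as.vector(x$data)))
  N <- prod(grid)
  M <- length(vec_b(apply_forward(E, array(0i, grid))))
  mat <- matrix(0i, M, N)
  for (j in seq_len(N)) {
    e <- array(0i, grid)
    e[j] <- 1
    mat[, j] <- vec_b(apply_forward(E, e))
  }
  mat
}

vec_bins <- function(bk) unlist(lapply(bk$bins, function(x) as.vector(x$data)))

# smooth random velocity field with unit peak vector magnitude
smooth_velocity <- function(grid, cutoff = 0.03, amp = 1, seed = 1) {
  set.seed(seed)
  v <- array(0, c(grid, 3))
  for (c in 1:3) v[, , , c] <- supermoco:::smooth_random_field(grid, cutoff)
  vmag <- sqrt(apply(v^2, 1:3, sum))
  v / max(vmag) * amp
}

# sum-of-Gaussian-blobs test volume (smooth, registration-friendly)
blob_volume <- function(grid, n_blobs = 5, sigma = 3.5, seed = 1) {
  set.seed(seed)
  ctr <- cbind(stats::runif(n_blobs, grid[1] * 0.25, grid[1] * 0.75),
               stats::runif(n_blobs, grid[2] * 0.25, grid[2] * 0.75),
               stats::runif(n_blobs, grid[3] * 0.25, grid[3] * 0.75))
  X <- array(rep(seq_len(grid[1]) - 1, times = grid[2] * grid[3]), grid)
  Y <- aperm(array(rep(seq_len(grid[2]) - 1, times = grid[1] * grid[3]),
                   grid[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(rep(seq_len(grid[3]) - 1, times = grid[1] * grid[2]),
                   grid[c(3, 1, 2)]), c(2, 3, 1))
  img <- array(0, grid)
  for (i in seq_len(n_blobs)) {
    img <- img + exp(-((X - ctr[i, 1])^2 + (Y - ctr[i, 2])^2 +
                       (Z - ctr[i, 3])^2) / (2 * sigma^2))
  }
  img / max(img)
}

# constant-displacement warp of a volume
shift_volume <- function(img, t) {
  d <- array(0, c(dim(img), 3))
  d[, , , 1] <- t[1]; d[, , , 2] <- t[2]; d[, , , 3] <- t[3]
  warp_image(img, d)
}

# small static phantom + fully sampled single-coil acquisition
static_full_acquisition <- function(grid = c(8, 8, 8), seed = 5) {
  sp <- phantom_spec(grid_shape = grid, n_heartbeats = 8, n_coils = 1,
                     motion_amplitude_vox = 0, seed = seed)
  tr <- generate_phantom(sp)
  tj <- generate_vdcaspr(grid[2:3], undersampling = 1,
                         n_heartbeats = sp$n_heartbeats, seed = 1,
                         shutter = "full")
  list(truth = tr, traj = tj, raw = simulate_acquisition(tr, tj))
}
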