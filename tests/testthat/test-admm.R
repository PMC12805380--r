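test_that("ADMM Step 2 is the stated convex combination", {
  set.seed(1)
  ot <- rand_cplx(c(4, 8, 8))
  expect_equal(admm_step2(ot, identity, mu = 3, lambda = 2), ot)
  # S == 0 with the default lambda = 1.5, mu = 10
  out <- admm_step2(ot, function(x) 0 * x, mu = 10, lambda = 1.5)
  expect_equal(out, (1.5 / 11.5) * ot, tolerance = 1e-12)
  expect_lt(abs(1.5 / 11.5 - 0.130435), 1e-6)
  # coefficients are nonnegative and sum to one for any mu, lambda > 0
  for (ml in list(c(0.3, 7), c(10, 1.5), c(5, 5))) {
    c1 <- ml[1] / (ml[1] + ml[2]); c2 <- ml[2] / (ml[1] + ml[2])
    expect_gte(c1, 0); expect_gte(c2, 0)
    expect_equal(c1 + c2, 1)
  }
  expect_error(admm_step2(ot, identity, mu = 0, lambda = 1), "mu")
  expect_error(admm_step2(ot, identity, mu = 1, lambda = -1), "lambda")
})

test_that("Step 2 matches brute-force minimization of its scalar objective", {
  # constant S(omega~) = s: omega minimizes mu/2 (omega - s)^2 +
  # lambda/2 (omega~ - omega)^2
  mu <- 10; lambda <- 1.5
  s <- 0.4; ot_val <- 1.3
  ot <- array(ot_val + 0i, c(2, 2, 2))
  out <- admm_step2(ot, function(x) array(s + 0i, dim(x)), mu, lambda)
  grid_w <- seq(-2, 3, length.out = 20001)
  obj <- mu / 2 * (grid_w - s)^2 + lambda / 2 * (ot_val - grid_w)^2
  wstar <- grid_w[which.min(obj)]
  expect_lt(abs(Re(out[1]) - wstar), diff(grid_w[1:2]))
})

test_that("the dual update accumulates the primal residual", {
  a <- array(0 + 0i, c(2, 2, 2))
  rho <- array(1 + 0i, c(2, 2, 2))
  omega <- array(0.5 + 0i, c(2, 2, 2))
  expect_equal(dual_update(a, rho, rho), a)
  expect_equal(Re(dual_update(a, rho, omega)[1]), 0.5)
  expect_error(dual_update(a, rho, array(0i, c(2, 2, 1))), "shape")
  # explicit accumulation over several steps
  set.seed(2)
  acc <- array(0i, c(2, 2, 2))
  aj <- acc
  for (j in 1:5) {
    r <- rand_cplx(c(2, 2, 2)); w <- rand_cplx(c(2, 2, 2))
    aj <- dual_update(aj, r, w)
    acc <- acc + (r - w)
  }
  expect_equal(aj, acc)
})

test_that("with identity S and exact solves the primal residual vanishes", {
  grid <- c(4, 4, 4)
  cm <- simulate_coil_maps(grid, 2, seed = 3)
  set.seed(3)
  samp <- list(list(idx = cbind(sample(0:3, 6, TRUE), sample(0:3, 6, TRUE)),
                    w = stats::runif(6, 0.5, 1)))
  E <- encoding_operator(samp, cm, NULL, grid = grid)
  b <- apply_forward(E, rand_cplx(grid))
  zf <- zero_filled_recon(b, cm)
  cfg <- recon_config(n_admm = 50, n_cg = 30, n_bins = 1)
  rho <- supermoco:::admm_core(samp, zf, cm, NULL, identity, cfg, trace = TRUE)
  res <- attr(rho, "primal_residual")
  expect_lt(res[length(res)], 1e-8)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("the ADMM iterates match a dense replica of the algorithm", {
  grid <- c(4, 4, 4)
  cm <- simulate_coil_maps(grid, 2, seed = 5)
  set.seed(5)
  samp <- list(list(idx = cbind(sample(0:3, 5, TRUE), sample(0:3, 5, TRUE)),
                    w = stats::runif(5, 0.4, 1)),
               list(idx = cbind(sample(0:3, 4, TRUE), sample(0:3, 4, TRUE)),
                    w = stats::runif(4, 0.4, 1)))
  E <- encoding_operator(samp, cm, NULL, grid = grid)
  x_true <- rand_cplx(grid)
  b <- apply_forward(E, x_true)
  zf <- zero_filled_recon(b, cm)
  cfg <- recon_config(lambda = 1.5, mu = 10, n_admm = 20, n_cg = 40, n_bins = 2)
  rho <- supermoco:::admm_core(samp, zf, cm, NULL, identity, cfg)
  # dense replica: exact linear solves instead of CG
  mat <- dense_forward_matrix(E, grid)
  N <- prod(grid)
  A <- Conj(t(mat)) %*% mat + cfg$lambda * diag(N)
  Eb <- Conj(t(mat)) %*% vec_bins(b)
  r <- Eb * 0
  omega <- Eb; a <- 0 * Eb
  rho_d <- Eb
  omega <- Eb
  for (j in seq_len(cfg$n_admm)) {
    rho_d <- solve(A, Eb + cfg$lambda * (omega - a))
    if (j == cfg$n_admm) break
    omega_t <- rho_d + a
    omega <- omega_t                     # identity S: convex combo is exact
    a <- a + rho_d - omega
  }
  expect_lt(max(Mod(as.vector(rho) - rho_d)) / max(Mod(rho_d)), 1e-3)
})

test_that("fully sampled single-coil reconstruction recovers the image", {
  sp <- phantom_spec(grid_shape = c(16, 16, 16), n_heartbeats = 16, n_coils = 1,
                     motion_amplitude_vox = 0, seed = 8)
  tr <- generate_phantom(sp)
  tj <- generate_vdcaspr(c(16, 16), undersampling = 1, n_heartbeats = 16,
                         seed = 1, shutter = "full")
  raw <- simulate_acquisition(tr, tj)
  cfg <- recon_config(n_admm = 4, n_cg = 5, n_bins = 1,
                      patch = patch_plan(thickness = 16))
  img <- super_moco_modl_reconstruct(raw, tr$coil_maps, nets = list(),
                                     config = cfg)
  ref <- tr$bin_images[[tr$reference_bin]]
  expect_lt(max(Mod(img - ref)) / max(Mod(ref)), 1e-4)
  # deterministic at inference
  img2 <- super_moco_modl_reconstruct(raw, tr$coil_maps, nets = list(),
                                      config = cfg)
  expect_identical(as.vector(img), as.vector(img2))
})

test_that("patch boundary placement does not change identity-processed output", {
  set.seed(9)
  x <- rand_cplx(c(64, 3, 3))
  p32 <- recombine_patches(split_into_patches(x, patch_plan(32)))
  p48 <- recombine_patches(split_into_patches(x, patch_plan(48)))
  expect_identical(p32, x)
  expect_identical(p48, x)
})

test_that("reconstruction configuration carries the reference defaults", {
  cfg <- recon_config()
  expect_equal(cfg$lambda, 1.5)
  expect_equal(cfg$mu, 10)
  expect_equal(cfg$n_admm, 4L)
  expect_equal(cfg$n_cg, 5L)
  expect_equal(cfg$n_sense, 10L)
  expect_equal(cfg$n_bins, 4L)
  expect_error(recon_config(lambda = 0), "lambda")
  expect_error(recon_config(n_admm = 0), "iteration")
})
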