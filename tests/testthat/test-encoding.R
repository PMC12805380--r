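# Adjointness, dense oracles and CG behaviour of the encoding operator
# E = W D F C M on small grids.

make_small_operator <- function(grid = c(8, 8, 8), n_coils = 2, with_motion = TRUE,
                                seed = 2) {
  cm <- simulate_coil_maps(grid, n_coils, seed = seed)
  motion <- NULL
  if (with_motion) {
    v <- smooth_velocity(grid, cutoff = 0.06, amp = 1.5, seed = seed + 1)
    motion <- motion_field_set(list(array(0, c(grid, 3)),
                                    scaling_and_squaring(v)), 1)
  }
  set.seed(seed + 2)
  samp <- lapply(1:2, function(b) {
    n <- sample(3:6, 1)
    list(idx = cbind(sample(0:(grid[2] - 1), n, replace = TRUE),
                     sample(0:(grid[3] - 1), n, replace = TRUE)),
         w = stats::runif(n, 0.2, 1))
  })
  encoding_operator(samp, cm, motion, grid = grid)
}

test_that("every operator factor and the composed E pass adjoint tests", {
  set.seed(10)
  grid <- c(8, 8, 8)
  # F
  x <- rand_cplx(grid); y <- rand_cplx(grid)
  expect_lt(Mod(sum(Conj(ft3(x)) * y) - sum(Conj(x) * ift3(y))), 1e-10)
  # C (multiply by maps / conjugate multiply and sum)
  cm <- simulate_coil_maps(grid, 3, seed = 1)
  yc <- lapply(1:3, function(c) rand_cplx(grid))
  lhs <- sum(vapply(1:3, function(c) sum(Conj(cm[, , , c] * x) * yc[[c]]), 0i))
  rhs <- sum(Conj(x) * Reduce(`+`, lapply(1:3, function(c) Conj(cm[, , , c]) * yc[[c]])))
  expect_lt(Mod(lhs - rhs), 1e-10)
  # M (warp / scatter adjoint)
  v <- smooth_velocity(grid, cutoff = 0.06, amp = 2, seed = 3)
  disp <- scaling_and_squaring(v)
  a <- rand_cplx(grid); b <- rand_cplx(grid)
  lhs <- sum(Conj(warp_image(a, disp)) * b)
  rhs <- sum(Conj(a) * warp_adjoint(b, disp))
  expect_lt(Mod(lhs - rhs) / (Mod(lhs) + 1e-12), 1e-10)
  # composed E (W and D included), randomized
  for (seed in 1:3) {
    E <- make_small_operator(seed = seed)
    rho <- rand_cplx(grid)
    bfwd <- apply_forward(E, rho)
    brand <- bfwd
    for (i in seq_along(brand$bins)) {
      brand$bins[[i]]$data <- rand_cplx(dim(brand$bins[[i]]$data))
    }
    lhs <- sum(Conj(vec_bins(bfwd)) * vec_bins(brand))
    rhs <- sum(Conj(rho) * apply_adjoint(E, brand))
    scale <- sqrt(sum(Mod(vec_bins(bfwd))^2)) * sqrt(sum(Mod(vec_bins(brand))^2))
    expect_lt(Mod(lhs - rhs) / scale, 1e-6)
  }
})

test_that("E matches its explicitly materialized dense matrix", {
  grid <- c(4, 4, 4)
  E <- make_small_operator(grid = grid, seed = 4)
  mat <- dense_forward_matrix(E, grid)
  set.seed(5)
  x <- rand_cplx(grid)
  expect_lt(max(Mod(mat %*% as.vector(x) - vec_bins(apply_forward(E, x)))), 1e-10)
  # adjoint equals the conjugate transpose
  b <- apply_forward(E, x)
  for (i in seq_along(b$bins)) b$bins[[i]]$data <- rand_cplx(dim(b$bins[[i]]$data))
  expect_lt(max(Mod(Conj(t(mat)) %*% vec_bins(b) - as.vector(apply_adjoint(E, b)))),
            1e-10)
})

test_that("E is linear and E*E is positive semidefinite", {
  grid <- c(8, 8, 8)
  E <- make_small_operator(grid = grid, seed = 6)
  set.seed(6)
  x1 <- rand_cplx(grid); x2 <- rand_cplx(grid)
  a <- complex(real = 0.7, imaginary = -1.2)
  lin <- apply_forward(E, a * x1 + 2 * x2)
  ref <- apply_forward(E, x1)
  ref2 <- apply_forward(E, x2)
  expect_lt(max(Mod(vec_bins(lin) - (a * vec_bins(ref) + 2 * vec_bins(ref2)))),
            1e-10)
  for (k in 1:3) {
    x <- rand_cplx(grid)
    q <- Re(sum(Conj(x) * apply_adjoint(E, apply_forward(E, x))))
    expect_gte(q, -1e-10)
  }
})

test_that("zero-filled reconstruction reduces to F inverse and is linear in W", {
  fx <- static_full_acquisition(grid = c(8, 8, 8))
  sig <- fx$truth$breathing
  plan <- soft_gated_binning(fx$raw, sig, n_bins = 1)
  b <- binned_kspace(fx$raw, plan)
  zf <- zero_filled_recon(b, fx$truth$coil_maps)[[1]]
  # assemble the dense k-space grid and invert directly
  k <- array(0i, fx$raw$grid)
  for (h in seq_along(fx$raw$traj)) {
    ro <- fx$raw$traj[[h]]
    for (r in seq_len(nrow(ro))) {
      k[, ro[r, 1] + 1, ro[r, 2] + 1] <- fx$raw$kspace[[h]][, r, 1]
    }
  }
  expect_lt(max(Mod(zf - ift3(k))), 1e-10)
  # doubling the soft-gate weights doubles rho_ZF
  b2 <- b
  b2$bins[[1]]$w <- 2 * b2$bins[[1]]$w
  zf2 <- zero_filled_recon(b2, fx$truth$coil_maps)[[1]]
  expect_lt(max(Mod(zf2 - 2 * zf)), 1e-10)
})

test_that("a DC-only bin reconstructs to a y-z constant per x slice", {
  grid <- c(8, 8, 8)
  cm <- simulate_coil_maps(grid, 1, seed = 1)
  samp <- list(list(idx = cbind(4L, 4L), w = 1))     # DC at floor(N/2)
  E <- encoding_operator(samp, cm, NULL, grid = grid)
  set.seed(8)
  b <- apply_forward(E, rand_cplx(grid))
  zf <- zero_filled_recon(b, cm)[[1]]
  for (x in 1:8) {
    sl <- zf[x, , ]
    expect_lt(max(Mod(sl - sl[1, 1])), 1e-12)
  }
})

test_that("the Step-1 CG solve matches a dense normal-equation solve", {
  grid <- c(4, 4, 4)
  E <- make_small_operator(grid = grid, seed = 9)
  mat <- dense_forward_matrix(E, grid)
  N <- prod(grid)
  set.seed(9)
  x <- rand_cplx(grid)
  g <- rand_cplx(grid)
  b <- apply_forward(E, x)
  lam <- 0.8
  dense <- solve(Conj(t(mat)) %*% mat + lam * diag(N),
                 Conj(t(mat)) %*% vec_bins(b) + lam * as.vector(g))
  xc <- cg_solve_step1(E, b, g, lambda = lam, n_iter = 50)
  expect_lt(max(Mod(as.vector(xc) - dense)) / max(Mod(dense)), 1e-6)
  # dominant-penalty limit returns g
  x0 <- cg_solve_step1(E, b, g, lambda = 1e8, n_iter = 5)
  expect_lt(max(Mod(x0 - g)) / max(Mod(g)), 1e-4)
  expect_error(cg_solve_step1(E, b, g, lambda = 0), "lambda")
  # right-hand side identity: E*b equals the motion-adjoint of the
  # zero-filled bins
  zf <- zero_filled_recon(b, E$coil_maps)
  eb <- Reduce(`+`, lapply(seq_along(zf), function(i)
    warp_adjoint(zf[[i]], E$motion$fields[[i]])))
  expect_lt(max(Mod(apply_adjoint(E, b) - eb)), 1e-10)
})

test_that("CG residuals are monotonically non-increasing", {
  grid <- c(4, 4, 4)
  E <- make_small_operator(grid = grid, seed = 12)
  set.seed(12)
  b <- apply_forward(E, rand_cplx(grid))
  g <- rand_cplx(grid)
  lam <- 0.5
  rhs <- apply_adjoint(E, b) + lam * g
  A <- function(z) apply_adjoint(E, apply_forward(E, z)) + lam * z
  res <- vapply(1:8, function(k) {
    xk <- cg_solve_step1(E, b, g, lambda = lam, n_iter = k)
    sqrt(sum(Mod(A(xk) - rhs)^2))
  }, 0)
  expect_true(all(diff(res) <= 1e-8))
})

test_that("iterative SENSE matches dense solves and its well-posed limit", {
  grid <- c(4, 4, 4)
  cm <- simulate_coil_maps(grid, 2, seed = 3)
  set.seed(13)
  samp <- list(idx = cbind(sample(0:3, 5, replace = TRUE),
                           sample(0:3, 5, replace = TRUE)),
               w = stats::runif(5, 0.3, 1))
  E <- encoding_operator(list(samp), cm, NULL, grid = grid)
  mat <- dense_forward_matrix(E, grid)
  x <- rand_cplx(grid)
  b <- apply_forward(E, x)
  zf <- zero_filled_recon(b, cm)[[1]]
  eps <- 1e-6
  dense <- solve(Conj(t(mat)) %*% mat + eps * diag(prod(grid)),
                 Conj(t(mat)) %*% vec_bins(b))
  xs <- iterative_sense(zf, samp, cm, n_iter = 60, epsilon = eps)
  expect_lt(max(Mod(as.vector(xs) - dense)) / max(Mod(dense)), 1e-6)
  # fully sampled single coil with no regularization: exact inverse DFT
  fx <- static_full_acquisition(grid = c(8, 8, 8))
  plan <- soft_gated_binning(fx$raw, fx$truth$breathing, n_bins = 1)
  bk <- binned_kspace(fx$raw, plan)
  zf1 <- zero_filled_recon(bk, fx$truth$coil_maps)[[1]]
  s1 <- list(idx = bk$bins[[1]]$idx, w = bk$bins[[1]]$w)
  xs1 <- iterative_sense(zf1, s1, fx$truth$coil_maps, n_iter = 2, epsilon = 0)
  expect_lt(max(Mod(xs1 - zf1)) / max(Mod(zf1)), 1e-8)
  # default iteration count is 10
  expect_identical(eval(formals(iterative_sense)$n_iter), 10L)
})
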