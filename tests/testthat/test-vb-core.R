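test_that("marginal log prior behaves like a rescaled Student-t", {
  hy <- hyper_params(b_a = 2, c_a = 1.5)
  # lambda = 1: standard Student-t shape c_a, scale b_a (up to a constant)
  x <- seq(-3, 3, by = 0.5)
  ref <- 0.5 * log(hy$b_a) - (hy$c_a + 0.5) * log1p(hy$b_a * x^2)
  expect_equal(marginal_log_prior(x, 1, hy), ref, tolerance = 1e-12)
  # maximum at x = 0
  expect_true(all(marginal_log_prior(0, 1, hy) >=
                  marginal_log_prior(x, 1, hy)))
  # doubling lambda rescales x by 1/sqrt(2) in the density argument
  lhs <- marginal_log_prior(x, 2, hy) - marginal_log_prior(0, 2, hy)
  rhs <- marginal_log_prior(sqrt(2) * x, 1, hy) -
    marginal_log_prior(0, 1, hy)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(marginal_log_prior(1, -1, hy), "must be > 0")
})

test_that("covariance update matches closed forms and dense inversion", {
  # H = I, beta = 1, Lambda = I -> C = I/2
  H <- diag(5)
  st <- vb_state_init(H, rep(1, 5))
  st$beta_hat <- 1
  st <- update_covariance(H, st)
  expect_equal(st$C_x, diag(0.5, 5), tolerance = 1e-12)

  # beta = 0 -> prior covariance Lambda^{-1}
  st$beta_hat <- 0
  st$a_hat <- c(1, 2, 4, 8, 16)
  st <- update_covariance(H, st)
  expect_equal(st$C_x, diag(1 / c(1, 2, 4, 8, 16)), tolerance = 1e-12)

  # random 4 x 6: Woodbury equals direct dense inversion of the 6x6 matrix
  set.seed(10)
  H46 <- matrix(rnorm(24), 4, 6)
  st <- vb_state_init(H46, rnorm(4))
  st$beta_hat <- 2.5
  st$a_hat <- runif(6, 0.5, 2)
  direct <- solve(2.5 * crossprod(H46) + diag(st$a_hat * st$lam))
  stw <- update_covariance(H46, st, method = "woodbury")
  std <- update_covariance(H46, st, method = "dense")
  expect_lt(max(abs(stw$C_x - direct)), 1e-10)
  expect_lt(max(abs(std$C_x - direct)), 1e-10)
})

test_that("mean update recovers the classical limits", {
  set.seed(11)
  # y = 0 -> x_hat = 0
  H <- matrix(rnorm(20), 4, 5)
  st <- vb_state_init(H, rep(0, 4))
  st <- update_mean(H, rep(0, 4), st)
  expect_equal(st$x_hat, rep(0, 5))

  # vanishing prior precision with square invertible H -> H^{-1} y
  H5 <- matrix(rnorm(25), 5, 5) + diag(5)
  y <- rnorm(5)
  st <- vb_state_init(H5, y)
  st$beta_hat <- 1
  st$a_hat <- rep(1e-12, 5)
  st <- update_mean(H5, y, st)
  expect_equal(st$x_hat, solve(H5, y), tolerance = 1e-8)

  # orthonormal rows, beta = 1, Lambda = I -> x_hat = H' y / 2
  Ho <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:3]  # 6 x 3 orthonormal cols
  Ho <- t(Ho)                                     # 3 x 6 orthonormal rows
  y3 <- rnorm(3)
  st <- vb_state_init(Ho, y3)
  st$beta_hat <- 1
  st <- update_mean(Ho, y3, st)
  expect_equal(st$x_hat, drop(crossprod(Ho, y3)) / 2, tolerance = 1e-12)
})

test_that("precision-scale update follows the conjugate Gamma formulas", {
  hy <- hyper_params(b_a = 1e6, c_a = 1e-6)
  H <- diag(3)
  st <- vb_state_init(H, rep(1, 3), solver_config(hyper = hy))
  # degenerate x = 0, C_ii = 0: 1/b' = 1/b_a so a_hat = b_a (c_a + 1/2)
  st$x_hat <- rep(0, 3); st$c_diag <- rep(0, 3)
  st <- update_a(st, hy)
  expect_equal(st$a_hat, rep(hy$b_a * (hy$c_a + 0.5), 3), tolerance = 1e-12)
  expect_equal(st$c_prime_a, rep(hy$c_a + 0.5, 3))

  # lambda = 0 removes the data weight regardless of x_hat
  st$x_hat <- c(5, -3, 100); st$c_diag <- rep(7, 3); st$lam <- rep(0, 3)
  st <- update_a(st, hy)
  expect_equal(st$a_hat, rep(hy$b_a * (hy$c_a + 0.5), 3), tolerance = 1e-12)

  # hand-evaluated case: lambda=2, x=1, C_ii=0.5
  st$x_hat <- c(1, 0, 0); st$c_diag <- c(0.5, 0, 0); st$lam <- c(2, 0, 0)
  st <- update_a(st, hy)
  expect_equal(1 / st$b_prime_a[1], 1.5 + 1e-6, tolerance = 1e-12)
  expect_equal(st$a_hat[1], (0.5 + 1e-6) / 1.500001, tolerance = 1e-9)
})

test_that("lambda reweighting uses the magnitude with a floor", {
  H <- diag(4)
  cfg <- solver_config(lam_floor = 1e-8)
  st <- vb_state_init(H, rep(1, 4), cfg)
  st$x_hat <- c(2, -0.5, 0, 1e-12)
  st <- update_lambda(st, cfg)
  expect_equal(st$lam, c(0.5, 2, 1e8, 1e8))
  # fixed_ones mode ignores x_hat entirely
  cfg1 <- solver_config(lam_mode = "fixed_ones")
  st <- update_lambda(st, cfg1)
  expect_equal(st$lam, rep(1, 4))
})

test_that("noise-precision update matches conjugate algebra and a sampling oracle", {
  hy <- hyper_params()
  # perfect fit, C -> 0, vague prior: beta_hat -> b (c + N/2)
  H <- diag(4); y <- rnorm(4)
  st <- vb_state_init(H, y)
  st$x_hat <- y; st$c_diag <- rep(0, 4); st$tr_HCHt <- 0
  st <- update_beta(H, y, st, hy)
  expect_equal(st$beta_hat, hy$b * (hy$c + 2), tolerance = 1e-6)
  expect_equal(st$c_prime, hy$c + 2)

  # Monte-Carlo oracle for E_q ||y - Hx||^2 on a random 6 x 10 instance
  set.seed(21)
  H <- matrix(rnorm(60), 6, 10)
  y <- rnorm(6)
  A <- 1.7 * crossprod(H) + diag(runif(10, 0.5, 2))
  C <- solve(A)
  x_hat <- drop(C %*% crossprod(H, y)) * 1.7
  n_draw <- 2e5
  L <- t(chol(C))
  X <- x_hat + L %*% matrix(rnorm(10 * n_draw), 10)
  R <- y - H %*% X
  mc <- mean(colSums(R^2))
  analytic <- sum((y - H %*% x_hat)^2) + sum((H %*% C) * H)
  expect_equal(mc, analytic, tolerance = 0.02)

  st <- vb_state_init(H, y)
  st$x_hat <- x_hat
  st$c_diag <- diag(C)
  st$tr_HCHt <- sum((H %*% C) * H)
  st <- update_beta(H, y, st, hy)
  expect_equal(1 / st$b_prime, 1 / hy$b + analytic / 2, tolerance = 1e-10)
})

test_that("one engine cycle equals the composed single-update operations", {
  set.seed(31)
  H <- matrix(rnorm(48), 8, 6)
  y <- rnorm(8)
  cfg <- solver_config(max_iter = 1, lam_mode = "fixed_ones")
  engine <- run_fan(H, y, cfg)

  st <- vb_state_init(H, y, cfg)
  st <- update_lambda(st, cfg)
  st <- update_covariance(H, st, method = "dense")
  st <- update_mean(H, y, st)
  st <- update_a(st, cfg$hyper)
  st <- update_beta(H, y, st, cfg$hyper)
  expect_equal(engine$x_hat, st$x_hat, tolerance = 1e-12)
  expect_equal(engine$a_hat, st$a_hat, tolerance = 1e-12)
  expect_equal(engine$beta_hat, st$beta_hat, tolerance = 1e-12)
})

test_that("the full solver recovers a single active column noise-free", {
  prob <- tiny_problem(seed = 3, n_channels = 32, m = 128)
  st <- run_fan(prob$leadfield, prob$measurement)
  expect_true(st$converged)
  am <- amplitude_map(st, prob$leadfield)
  expect_equal(which.max(am), prob$scene$active_indices)

  # determinism: identical runs are bit-identical
  st2 <- run_fan(prob$leadfield, prob$measurement)
  expect_identical(st$x_hat, st2$x_hat)
  expect_identical(st$beta_hat, st2$beta_hat)

  # Gamma shape invariant c'_a_i = c_a + 1/2 holds after convergence
  expect_equal(st$c_prime_a, rep(1e-6 + 0.5, 128))

  # posterior covariance is symmetric positive definite at the solution
  stc <- update_covariance(prob$leadfield, st)
  expect_equal(stc$C_x, t(stc$C_x), tolerance = 1e-10)
  expect_gt(min(eigen(stc$C_x, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("y = 0 is a fixed point", {
  prob <- tiny_problem(seed = 5, n_channels = 8, m = 20)
  st <- run_fan(prob$leadfield, rep(0, 8))
  expect_equal(st$x_hat, rep(0, 20))
  expect_true(st$converged)
})

test_that("Woodbury and dense posteriors agree across random instances", {
  set.seed(77)
  for (i in 1:10) {
    N <- sample(4:20, 1); K <- sample((N + 1):60, 1)
    H <- matrix(rnorm(N * K), N, K)
    st <- vb_state_init(H, rnorm(N))
    st$beta_hat <- runif(1, 0.1, 10)
    st$a_hat <- runif(K, 0.01, 100)
    d <- update_covariance(H, st, method = "dense")
    w <- update_covariance(H, st, method = "woodbury")
    rel <- max(abs(d$C_x - w$C_x)) / max(abs(d$C_x))
    expect_lt(rel, 1e-8)
  }
})

test_that("inactive sources are self-reinforcingly pruned", {
  prob <- tiny_problem(seed = 3, n_channels = 32, m = 128)
  st <- run_fan(prob$leadfield, prob$measurement,
                solver_config(track = TRUE))
  inactive <- setdiff(seq_len(128), prob$scene$active_indices)[1]
  prec <- vapply(st$precision_trace, function(p) p[inactive], numeric(1))
  # prior precision a*lambda at a known inactive index grows monotonically
  # after the first reweighted cycle
  expect_true(all(diff(prec[-1]) >= -1e-6 * prec[-c(1, length(prec))]))
  expect_gt(prec[length(prec)], prec[2])
})

test_that("the sparse solver concentrates more mass on the support than MNE", {
  prob <- tiny_problem(seed = 9, n_channels = 32, m = 128)
  st <- run_fan(prob$leadfield, prob$measurement)
  am_fan <- amplitude_map(st, prob$leadfield)
  am_mne <- amplitude_map(mne_solve(prob$leadfield, prob$measurement),
                          prob$leadfield)
  j <- prob$scene$active_indices
  expect_gt(am_fan[j] / sum(am_fan), am_mne[j] / sum(am_mne))
})

test_that("amplitude maps collapse components correctly", {
  ssf <- make_source_space(2, "cube_grid", 10, "free", seed = 1)
  lff <- make_leadfield(ssf, 4, "random_gaussian", seed = 1)
  expect_equal(amplitude_map(c(3, 4, 0, 0, 0, 0), lff), c(5, 0))
  ss <- make_source_space(3, "cube_grid", 10, "fixed", seed = 1)
  lf <- make_leadfield(ss, 4, "random_gaussian", seed = 1)
  expect_equal(amplitude_map(c(-2, 0, 1), lf), c(2, 0, 1))
  expect_equal(amplitude_map(rep(0, 3), lf), rep(0, 3))
})
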