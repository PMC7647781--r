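test_that("cube-grid source spaces have the requested geometry", {
  ss1 <- make_source_space(1, "cube_grid", spacing = 10,
                           orientation_mode = "fixed", seed = 0)
  expect_equal(nrow(ss1$positions), 1L)
  expect_equal(sum(ss1$orientations^2), 1, tolerance = 1e-12)

  ss <- make_source_space(125, "cube_grid", spacing = 10,
                          orientation_mode = "free", seed = 1)
  expect_equal(nrow(ss$positions), 125L)
  expect_null(ss$orientations)
  D <- source_distances(ss)
  diag(D) <- Inf
  expect_equal(min(D), 10)              # nearest-neighbour distance = spacing
  expect_equal(sort(unique(ss$positions[, 1])), (-2:2) * 10)  # 5x5x5

  expect_error(make_source_space(0, "cube_grid"), "positive integer")
})

test_that("sphere-surface spaces put sources at equal radius with radial normals", {
  ss <- make_source_space(500, "sphere_surface", spacing = 8,
                          orientation_mode = "fixed", seed = 2)
  radii <- sqrt(rowSums(ss$positions^2))
  expect_lt(diff(range(radii)), 1e-9)
  # orientations are outward radial: pos_i proportional to orient_i
  cosang <- rowSums(ss$positions * ss$orientations) /
    (radii * sqrt(rowSums(ss$orientations^2)))
  expect_equal(cosang, rep(1, 500), tolerance = 1e-9)
})

test_that("random-Gaussian lead fields have unit-norm columns and right shape", {
  ss <- make_source_space(40, "cube_grid", 10, "fixed", seed = 5)
  lf <- make_leadfield(ss, 64, "random_gaussian", seed = 7)
  expect_equal(dim(lf$matrix), c(64L, 40L))
  expect_equal(colSums(lf$matrix^2), rep(1, 40), tolerance = 1e-9)

  ss1 <- make_source_space(1, "cube_grid", 10, "fixed", seed = 5)
  lf1 <- make_leadfield(ss1, 8, "random_gaussian", seed = 7)
  expect_equal(dim(lf1$matrix), c(8L, 1L))

  ssf <- make_source_space(10, "cube_grid", 10, "free", seed = 5)
  lff <- make_leadfield(ssf, 16, "random_gaussian", seed = 7)
  expect_equal(ncol(lff$matrix), 30L)
  expect_identical(lff$columns_per_source, 3L)
})

test_that("sphere-model potentials match the analytic kernel and its symmetry", {
  # two mirror-symmetric sources; mirror electrodes see swapped potentials
  pos <- rbind(c(30, 0, 0), c(-30, 0, 0))
  moment <- c(0, 0, 1)
  e1 <- c(60, 10, 20); e2 <- c(-60, 10, 20)  # reflected through x = 0
  v11 <- dipole_potential(e1, pos[1, ], moment)
  v22 <- dipole_potential(e2, pos[2, ], moment)
  v12 <- dipole_potential(e1, pos[2, ], moment)
  v21 <- dipole_potential(e2, pos[1, ], moment)
  expect_equal(v11, v22, tolerance = 1e-12)
  expect_equal(v12, v21, tolerance = 1e-12)

  # assembled free-orientation matrix agrees with direct kernel evaluation
  ss <- make_source_space(4, "cube_grid", 20, "free", seed = 1)
  lf <- make_leadfield(ss, 12, "single_shell_sphere")
  elec <- vbsource:::fibonacci_sphere(12, 1.2 * max(sqrt(rowSums(ss$positions^2))))
  for (j in 1:4) for (cc in 1:3) {
    mom <- c(0, 0, 0); mom[cc] <- 1
    direct <- apply(elec, 1, dipole_potential, dipole_pos = ss$positions[j, ],
                    moment = mom)
    expect_equal(lf$matrix[, 3 * (j - 1) + cc], direct, tolerance = 1e-12)
  }

  # deeper sources give weaker columns (depth bias preserved)
  ssd <- make_source_space(64, "cube_grid", 15, "free", seed = 1)
  lfd <- make_leadfield(ssd, 32, "single_shell_sphere")
  depth <- rep(sqrt(rowSums(ssd$positions^2)), each = 3)
  norms <- sqrt(colSums(lfd$matrix^2))
  expect_gt(stats::cor(depth, norms, method = "spearman"), 0.5)

  # average reference makes every column sum to zero
  lfa <- make_leadfield(ssd, 32, "single_shell_sphere",
                        average_reference = TRUE)
  expect_equal(max(abs(colSums(lfa$matrix))), 0, tolerance = 1e-12)
})

test_that("scenes have the requested sparsity, separation, and determinism", {
  ss <- make_source_space(100, "cube_grid", 10, "fixed", seed = 1)
  sc <- simulate_scene(ss, 1, amplitude_seed = 4)
  expect_length(sc$active_indices, 1L)
  expect_equal(sum(sc$amplitudes != 0), 1L)

  expect_error(simulate_scene(ss, 0), "between 1")

  sc3 <- simulate_scene(ss, 3, amplitude_seed = 9, min_separation = 25)
  expect_gte(min(dist(sc3$truth_positions)), 25)

  # free orientation: 3 nonzero components per active dipole
  ssf <- make_source_space(50, "cube_grid", 10, "free", seed = 1)
  scf <- simulate_scene(ssf, 2, amplitude_seed = 4)
  expect_equal(sum(scf$amplitudes != 0), 6L)

  expect_identical(simulate_scene(ss, 2, amplitude_seed = 11),
                   simulate_scene(ss, 2, amplitude_seed = 11))

  # infeasible separation is reported
  expect_error(simulate_scene(ss, 5, min_separation = 1e5, max_tries = 10),
               "infeasible")
})

test_that("projection is the exact linear forward model", {
  prob <- tiny_problem(seed = 8, n_active = 3)
  lf <- prob$leadfield; sc <- prob$scene
  # brute-force sum over active columns
  oracle <- rowSums(sapply(which(sc$amplitudes != 0),
                           function(j) lf$matrix[, j] * sc$amplitudes[j]))
  expect_equal(prob$clean$y, oracle, tolerance = 1e-12)

  # linearity in the scene amplitudes
  sc2 <- sc; sc2$amplitudes <- 2.5 * sc$amplitudes
  expect_equal(project(lf, sc2)$y, 2.5 * prob$clean$y, tolerance = 1e-12)

  sc0 <- sc; sc0$amplitudes <- 0 * sc$amplitudes
  expect_equal(project(lf, sc0)$y, rep(0, 16))

  # single active column with unit amplitude reproduces that column
  sc1 <- sc; sc1$amplitudes <- 0 * sc$amplitudes; sc1$amplitudes[7] <- 1
  expect_equal(project(lf, sc1)$y, lf$matrix[, 7])

  expect_error(project(lf, list(amplitudes = rep(1, 3))), "does not match")
})

test_that("noise calibration hits the configured SNR exactly", {
  prob <- tiny_problem(seed = 2)
  y <- prob$clean$y
  for (snr in c(60, 20, 0, -10)) {
    noisy <- add_noise_snr(y, snr, seed = 123)
    expect_equal(realized_snr_db(y, noisy$y), snr, tolerance = 1e-9)
  }
  expect_equal(add_noise_snr(y, Inf)$y, y)
  # 0 dB: noise norm equals signal norm
  n0 <- add_noise_snr(y, 0, seed = 1)
  expect_equal(sum((n0$y - y)^2), sum(y^2), tolerance = 1e-9)
  expect_error(add_noise_snr(rep(0, 8), 60), "all-zero")
  expect_identical(add_noise_snr(y, 60, seed = 5), add_noise_snr(y, 60, seed = 5))
})

test_that("simulated problems are bit-reproducible under a fixed seed", {
  p1 <- simulate_problem(n_channels = 8, m = 30, seed = 42, snr_db = 20)
  p2 <- simulate_problem(n_channels = 8, m = 30, seed = 42, snr_db = 20)
  expect_identical(p1$leadfield$matrix, p2$leadfield$matrix)
  expect_identical(p1$scene$amplitudes, p2$scene$amplitudes)
  expect_identical(p1$measurement$y, p2$measurement$y)
})
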