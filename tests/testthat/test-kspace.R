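test_that("golden-angle trajectory geometry is as specified", {
  tr <- golden_angle_trajectory(4, 8, theta0_rad = 0)
  expect_equal(tr$angles_rad[2], 111.25 * pi / 180)
  expect_equal(tr$angles_rad[3], (2 * 111.25 * pi / 180) %% (2 * pi))
  expect_true(all(abs(tr$sample_coords) <= pi + 1e-12))
  one <- golden_angle_trajectory(1, 8, theta0_rad = 0.4)
  off_centre <- abs(one$radii) > 1e-9   # the r = 0 sample has no azimuth
  expect_equal(unique(round(atan2(one$sample_coords[off_centre, 2],
                                  one$sample_coords[off_centre, 1]) %% pi, 12)),
               0.4, tolerance = 1e-12)
  vert <- golden_angle_trajectory(1, 16, theta0_rad = pi / 2)
  expect_true(all(abs(vert$sample_coords[, 1]) < 1e-12))
  # radii span the full diameter, duplicate endpoint excluded by default
  expect_equal(tr$radii[1], -pi)
  expect_lt(max(tr$radii), pi)
  expect_equal(diff(tr$radii)[1], 2 * pi / 8)
  withend <- golden_angle_trajectory(1, 9, include_endpoint = TRUE)
  expect_equal(range(withend$radii), c(-pi, pi))
  # random initial angle is reproducible from its seed
  a <- golden_angle_trajectory(2, 8, seed_for_theta0 = 11)
  b <- golden_angle_trajectory(2, 8, seed_for_theta0 = 11)
  expect_identical(a$theta0_rad, b$theta0_rad)
  expect_true(a$theta0_rad >= 0 && a$theta0_rad < 2 * pi)
})

test_that("forward NUDFT matches the brute-force direct sum", {
  set.seed(41)
  H <- 8; W <- 8; D <- 2
  vol <- complex_volume(array(complex(real = rnorm(H * W * D),
                                      imaginary = rnorm(H * W * D)), c(H, W, D)))
  traj <- golden_angle_trajectory(3, 8, theta0_rad = 0.3)
  k <- nudft_forward(vol, traj)
  for (d in 1:D) {
    bf <- brute_nudft_slice(vol$data[, , d], traj$sample_coords)
    expect_lt(max(Mod(k$values[, d] - bf)) / max(Mod(bf)), 1e-10)
  }
  zero <- nudft_forward(complex_volume(array(0i, c(H, W, D))), traj)
  expect_true(all(Mod(zero$values) == 0))
})

test_that("centred delta transforms to unit-magnitude samples with energy N_k", {
  H <- 8; W <- 8
  imp <- array(0i, c(H, W, 1)); imp[floor(H / 2) + 1, floor(W / 2) + 1, 1] <- 1
  traj <- golden_angle_trajectory(3, 8, theta0_rad = 1.1)
  k <- nudft_forward(complex_volume(imp), traj)
  expect_equal(Mod(k$values[, 1]), rep(1, nrow(k$values)), tolerance = 1e-12)
  expect_equal(sum(Mod(k$values[, 1])^2), nrow(k$values), tolerance = 1e-9)
})

test_that("adjoint satisfies the inner-product identity and normalisation", {
  set.seed(42)
  H <- 8; W <- 8; D <- 2
  traj <- golden_angle_trajectory(3, 8, theta0_rad = 0.9)
  x <- complex_volume(array(complex(real = rnorm(H * W * D),
                                    imaginary = rnorm(H * W * D)), c(H, W, D)))
  ns <- 3 * 8
  y <- kspace_data(matrix(complex(real = rnorm(ns * D), imaginary = rnorm(ns * D)),
                          ns, D), traj, c(H, W, D))
  Ax <- nudft_forward(x, traj)
  Aty <- nudft_adjoint(y, normalize = FALSE)
  ip1 <- sum(Conj(y$values) * Ax$values)
  ip2 <- sum(Conj(Aty$data) * x$data)
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
  expect_equal(nudft_adjoint(y)$data, Aty$data / ns, tolerance = 1e-12)
  zero <- kspace_data(matrix(0i, ns, D), traj, c(H, W, D))
  expect_true(all(Mod(nudft_adjoint(zero)$data) == 0))
})

test_that("forward and adjoint are linear operators", {
  set.seed(43)
  traj <- golden_angle_trajectory(4, 8)
  mk <- function() complex_volume(array(complex(real = rnorm(128),
                                                imaginary = rnorm(128)), c(8, 8, 2)))
  x <- mk(); y <- mk(); a <- 1.7 - 0.4i
  lhs <- nudft_forward(complex_volume(a * x$data + y$data), traj)$values
  rhs <- a * nudft_forward(x, traj)$values + nudft_forward(y, traj)$values
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("adjoint reconstruction error decreases with spoke count", {
  subj <- fixture("recon_subject", function() {
    generate_cohort(1, default_phantom_spec(c(24, 24, 8)),
                    motion = motion_model(c(0.5, 0.3, 1), 4, 3), seed = 3)[[1]]
  })
  vol <- subj$bins_clean[[1]]
  mag <- Mod(vol$data)
  res <- vapply(c(5, 13, 50), function(ns) {
    traj <- golden_angle_trajectory(ns, 48, theta0_rad = 0.2)
    rec <- nudft_adjoint(nudft_forward(vol, traj), density_weights = "ramp")
    # compare shapes up to the adjoint's global scale
    sc <- sum(Mod(rec$data) * mag) / sum(mag^2)
    metric_re(Mod(rec$data) / sc, mag)
  }, numeric(1))
  expect_true(res[2] < res[1] && res[3] < res[2])
})

test_that("radial acceleration factors reproduce the printed values", {
  expect_equal(acceleration_factor(256, 13, rounded = TRUE), 31)
  expect_equal(acceleration_factor(256, 9, rounded = TRUE), 45)
  expect_equal(acceleration_factor(256, 5, rounded = TRUE), 80)
  n <- 64
  expect_equal(acceleration_factor(n, pi / 2 * n), 1)
})

test_that("preprocessing stacks the six planes in the documented order", {
  case <- tiny_case()
  pc <- preprocess_case(case$S_FI, case$T_UK)
  expect_equal(dim(pc$X)[4], 6L)
  expect_equal(pc$X[, , , 1], Re(case$S_FI$data))
  expect_equal(pc$X[, , , 2], Im(case$S_FI$data))
  expect_equal(pc$X[, , , 3], Re(pc$S_UI$data))
  expect_equal(pc$X[, , , 5], Re(pc$T_UI$data))
  # recomputation is bitwise identical
  pc2 <- preprocess_case(case$S_FI, case$T_UK)
  expect_identical(pc$X, pc2$X)
  # S_UK uses the target trajectory
  expect_identical(pc$S_UK$trajectory$angles_rad, case$T_UK$trajectory$angles_rad)
  bad <- complex_volume(array(0i, c(4, 4, 4)))
  expect_error(preprocess_case(bad, case$T_UK), "shape")
})
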