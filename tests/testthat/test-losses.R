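test_that("deformation discrepancy loss follows its closed forms", {
  shp <- c(4, 4, 2)
  a <- dvf(array(rnorm(prod(shp) * 3), c(shp, 3)))
  expect_equal(loss_stepA(a, a), 0)
  b <- dvf(a$data + 1)
  expect_equal(loss_stepA(a, b), 3, tolerance = 1e-12)
  expect_equal(loss_stepA(a, b), loss_stepA(b, a))
  expect_error(loss_stepA(a, dvf(array(0, c(5, 4, 2, 3)))), "differ")
})

test_that("k-space fidelity loss is the mean squared complex residual", {
  traj <- golden_angle_trajectory(2, 8)
  v1 <- matrix(complex(real = rnorm(32), imaginary = rnorm(32)), 16, 2)
  k1 <- kspace_data(v1, traj, c(8, 8, 2))
  expect_equal(loss_kspace(k1, k1), 0)
  k2 <- kspace_data(v1 + (2 + 0i), traj, c(8, 8, 2))
  expect_equal(loss_kspace(k2, k1), 4, tolerance = 1e-12)
  k3 <- kspace_data(v1 + complex(real = rnorm(32), imaginary = rnorm(32)), traj,
                    c(8, 8, 2))
  expect_gte(loss_kspace(k3, k1), 0)
  other <- golden_angle_trajectory(2, 8, theta0_rad = 0.5)
  expect_error(loss_kspace(kspace_data(v1, other, c(8, 8, 2)), k1), "trajectory")
})

test_that("embedding similarity loss matches hand-computed cosines", {
  E1 <- rbind(c(1, 0), c(1, 1))
  E2 <- rbind(c(2, 0), c(0, 3))
  by_hand <- mean(c(1, cos(pi / 4)))
  expect_equal(loss_embed(E1, E2, "printed"), by_hand, tolerance = 1e-12)
  expect_equal(loss_embed(E1, E2), -by_hand, tolerance = 1e-12)
  expect_equal(loss_embed(E1, E1, "printed"), 1)
  orth <- rbind(c(0, 1), c(1, 0))
  expect_equal(loss_embed(E1[1, , drop = FALSE], orth[1, , drop = FALSE]), 0)
  expect_warning(z <- loss_embed(rbind(c(0, 0)), rbind(c(1, 1))), "zero-norm")
  expect_equal(z, 0)
  expect_error(loss_embed(E1, matrix(1, 3, 2)), "dimensions")
})

test_that("smoothness loss matches a brute-force finite-difference oracle", {
  shp <- c(5, 4, 3)
  expect_equal(loss_smooth(dvf(array(3.2, c(shp, 3)))), 0)
  set.seed(61)
  d <- array(rnorm(prod(shp) * 3), c(shp, 3))
  # independent double-loop oracle with replicate boundary
  oracle <- 0
  for (j in 1:3) {
    acc <- 0
    for (x in 1:shp[1]) for (y in 1:shp[2]) for (z in 1:shp[3]) {
      v <- d[x, y, z, j]
      dx <- if (x < shp[1]) d[x + 1, y, z, j] - v else 0
      dy <- if (y < shp[2]) d[x, y + 1, z, j] - v else 0
      dz <- if (z < shp[3]) d[x, y, z + 1, j] - v else 0
      acc <- acc + dx^2 + dy^2 + dz^2
    }
    oracle <- oracle + acc / prod(shp)
  }
  expect_equal(loss_smooth(dvf(d)), oracle, tolerance = 1e-12)
  expect_equal(loss_smooth(dvf(2.5 * d)), 2.5^2 * loss_smooth(dvf(d)),
               tolerance = 1e-12)
  # the linear ramp d_x = x has unit forward differences except the last
  ramp <- array(0, c(shp, 3))
  ramp[, , , 1] <- array(grid_positions(shp)$x, shp)
  expect_equal(loss_smooth(dvf(ramp)), (shp[1] - 1) * prod(shp[2:3]) / prod(shp),
               tolerance = 1e-12)
})

test_that("step-B combination is the stated weighted sum", {
  expect_equal(loss_stepB(2, -1, 4), 3.5)
  expect_equal(loss_stepB(7, 9, 11, loss_weights(1, 0, 0)), 7)
  expect_equal(loss_stepB(7, 9, 11, loss_weights(0, 0, 0)), 0)
  expect_error(loss_weights(-1, 0, 0))
})

test_that("in-graph losses agree with their plain counterparts and gradients", {
  set.seed(62)
  shp <- c(5, 4, 3)
  n <- prod(shp)
  dmat <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  dref <- matrix(rnorm(n * 3), n, 3)
  f <- function(p) {
    dd <- dvf(array(p$d, c(shp, 3)))
    loss_stepA(dd, dvf(array(dref, c(shp, 3)))) + loss_smooth(dd)
  }
  tp <- ag_tape()
  pn <- params_to_nodes(tp, list(d = dmat))
  loss <- ag_add(ag_loss_stepA(pn$d, dref), ag_loss_smooth(pn$d, shp))
  ag_backward(loss)
  expect_equal(loss$value, f(list(d = dmat)), tolerance = 1e-12)
  g <- grads_from_nodes(pn)
  for (i in sample(n * 3, 5)) {
    expect_equal(as.numeric(g$d[i]), fd_grad(f, list(d = dmat), "d", i),
                 tolerance = 1e-4)
  }
})
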