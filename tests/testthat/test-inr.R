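test_that("coordinate grid maps corners to +-1 with the documented count", {
  g <- coordinate_grid(c(3, 3, 3), 1)
  expect_equal(g$coords[14, ], c(x = 0, y = 0, z = 0))
  expect_equal(nrow(g$coords), 27)
  expect_equal(range(g$coords), c(-1, 1))
  g2 <- coordinate_grid(c(16, 15, 8), c(2, 4, 2))
  expect_equal(nrow(g2$coords), prod(ceiling(c(16, 15, 8) / c(2, 4, 2))))
  expect_equal(min(g2$coords[, 1]), -1)
  expect_equal(max(g2$coords[, 1]), 1)
  expect_error(coordinate_grid(c(8, 8, 4), 0))
})

test_that("template initialisation honours the SIREN bounds and parameter count", {
  w <- c(3L, 32L, 32L, 32L, 3L)
  tmpl <- init_template(w, omega0 = 30, seed = 9)
  # closed-form count over the five affine layers
  expected <- (3 * 32 + 32) + (32 * 32 + 32) * 3 + (32 * 3 + 3)
  expect_equal(template_n_params(tmpl), expected)
  expect_true(all(abs(tmpl$params$Wi) <= 1 / 3))
  bnd <- sqrt(6 / 32) / 30
  for (nm in c("W1", "W2", "W3")) {
    expect_true(all(abs(tmpl$params[[nm]]) <= bnd))
  }
  expect_identical(init_template(w, 30, seed = 9)$params, tmpl$params)
  expect_error(init_template(c(3, 16, 16, 3), 30, 1))
  expect_error(init_template(c(2, 16, 16, 16, 3), 30, 1))
})

test_that("all-ones modulation reproduces the plain SIREN layer recursion", {
  w <- c(3L, 2L, 2L, 2L, 3L)
  tmpl <- init_template(w, omega0 = 2, seed = 5)
  p <- tmpl$params
  coords <- matrix(c(0.3, -0.2, 0.8), 1, 3)
  # independent layer-by-layer hand computation
  F0 <- sin(2 * (coords %*% p$Wi + p$bi))
  F1 <- sin(F0 %*% p$W1 + p$b1)
  F2 <- sin(F1 %*% p$W2 + p$b2)
  F3 <- sin(F2 %*% p$W3 + p$b3)
  by_hand <- F3 %*% p$Wo + p$bo
  got <- siren_forward(tmpl, modulation_identity(w), coords)
  expect_equal(got, by_hand, tolerance = 1e-14)
})

test_that("hand-set modulation scales activations and shifts biases as written", {
  w <- c(3L, 2L, 2L, 2L, 3L)
  tmpl <- init_template(w, omega0 = 2, seed = 5)
  p <- tmpl$params
  mod <- modulation_identity(w)
  mod$gamma <- list(c(1.5, 0.5), c(2, 1), c(1, 3))
  mod$beta <- list(c(0.5, 2), c(1, 0), c(-1, 1))
  coords <- matrix(c(-0.4, 0.1, 0.6), 1, 3)
  F0 <- sin(2 * (coords %*% p$Wi + p$bi))
  F1 <- sin(mod$gamma[[1]] * (F0 %*% p$W1) + mod$beta[[1]] * p$b1)
  F2 <- sin(mod$gamma[[2]] * (F1 %*% p$W2) + mod$beta[[2]] * p$b2)
  F3 <- sin(mod$gamma[[3]] * (F2 %*% p$W3) + mod$beta[[3]] * p$b3)
  by_hand <- F3 %*% p$Wo + p$bo
  expect_equal(siren_forward(tmpl, mod, coords), by_hand, tolerance = 1e-14)
})

test_that("zero output weights collapse the network to its output bias", {
  tmpl <- init_template(c(3L, 8L, 8L, 8L, 3L), seed = 3)
  tmpl$params$Wo[] <- 0
  out <- siren_forward(tmpl, modulation_identity(c(3L, 8L, 8L, 8L, 3L)),
                       coordinate_grid(c(4, 4, 4), 1)$coords)
  expect_true(all(abs(sweep(out, 2, tmpl$params$bo, "-")) < 1e-14))
})

test_that("a default-width template fits a smooth field to sub-0.05-voxel error", {
  # expressivity: gradient descent on a 16^3 grid against an analytic field
  shape <- c(16L, 16L, 16L)
  grid <- coordinate_grid(shape, 1)
  target <- cbind(0.8 * sin(pi * grid$coords[, 1]) * cos(pi * grid$coords[, 2]),
                  0.5 * grid$coords[, 2]^2,
                  0.6 * cos(pi * grid$coords[, 3]))
  tmpl <- init_template(c(3L, 48L, 48L, 48L, 3L), omega0 = 30, seed = 17)
  params <- tmpl$params
  opt <- adam_init(params, lr = 2e-3)
  mod <- modulation_identity(c(3L, 48L, 48L, 48L, 3L))
  for (it in 1:500) {
    tp <- ag_tape()
    pn <- params_to_nodes(tp, params)
    out <- ag_siren_forward(tp, pn, mod, grid$coords, tmpl$omega0)
    loss <- ag_mean(ag_pow(ag_sub(out, target), 2))
    ag_backward(loss)
    upd <- adam_step(params, grads_from_nodes(pn), opt)
    params <- upd$params; opt <- upd$state
  }
  tmpl$params <- params
  mae <- mean(abs(siren_forward(tmpl, mod, grid$coords) - target))
  expect_lt(mae, 0.05)
})
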