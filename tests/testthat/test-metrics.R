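test_that("SSIM is 1 on identity, penalises mismatch, and matches a hand formula", {
  set.seed(71)
  truth <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_equal(metric_ssim(truth, truth), 1, tolerance = 1e-12)
  # constant offset: covariance equals the (equal) variances
  off <- 0.1
  mp <- mean(truth) + off; mt <- mean(truth)
  v <- mean((truth - mt)^2)
  c1 <- 0.01^2; c2 <- 0.03^2
  by_hand <- ((2 * mp * mt + c1) * (2 * v + c2)) /
    ((mp^2 + mt^2 + c1) * (2 * v + c2))
  expect_equal(metric_ssim(truth + off, truth), by_hand, tolerance = 1e-12)
  flat <- array(mean(truth), dim(truth))
  expect_lt(metric_ssim(flat, truth), 1)
  expect_error(metric_ssim(truth, truth[1:8, , ]))
})

test_that("relative error follows its closed forms", {
  set.seed(72)
  truth <- array(runif(512, 0.1, 1), c(8, 8, 8))
  expect_equal(metric_re(truth, truth), 0)
  expect_equal(metric_re(2 * truth, truth), 100)
  expect_equal(metric_re(truth * 0, truth), 100)
  expect_error(metric_re(truth, truth * 0), "zero")
})

test_that("Dice covers identity, disjoint and the offset-cube half overlap", {
  m <- array(0L, c(12, 12, 12))
  m[3:6, 3:6, 3:6] <- 1L
  expect_equal(metric_dice(m, m), 1)
  shifted2 <- array(0L, c(12, 12, 12)); shifted2[5:8, 3:6, 3:6] <- 1L
  expect_equal(metric_dice(m, shifted2), 0.5)
  far <- array(0L, c(12, 12, 12)); far[9:12, 9:12, 9:12] <- 1L
  expect_equal(metric_dice(m, far), 0)
  expect_warning(d0 <- metric_dice(m * 0L, m * 0L), "empty")
  expect_equal(d0, 1)
})

test_that("single-voxel offset masks give HD95 and COME of one spacing", {
  m1 <- array(0L, c(8, 8, 8)); m1[4, 4, 4] <- 1L
  m2 <- array(0L, c(8, 8, 8)); m2[5, 4, 4] <- 1L
  s <- c(1.7, 1, 1)
  expect_equal(metric_hd95(m1, m2, s), 1.7)
  expect_equal(metric_come(m1, m2, s), 1.7)
  expect_equal(metric_hd95(m1, m1, s), 0)
  expect_equal(metric_come(m1, m1, s), 0)
  expect_error(metric_hd95(m1, m1 * 0L, s), "empty")
  expect_error(metric_come(m1 * 0L, m1, s), "empty")
})

test_that("HD95 matches a brute-force all-pairs oracle on random masks", {
  set.seed(73)
  # independent reimplementation: boundary by neighbour scan, all-pairs
  oracle_hd95 <- function(a, b, sp) {
    bound <- function(m) {
      pts <- which(m > 0, arr.ind = TRUE)
      keep <- logical(nrow(pts))
      d <- dim(m)
      for (i in seq_len(nrow(pts))) {
        p <- pts[i, ]
        onb <- FALSE
        for (ax in 1:3) for (s in c(-1L, 1L)) {
          q <- p; q[ax] <- q[ax] + s
          if (q[ax] < 1 || q[ax] > d[ax] || m[q[1], q[2], q[3]] == 0) onb <- TRUE
        }
        keep[i] <- onb
      }
      sweep(pts[keep, , drop = FALSE], 2, sp, "*")
    }
    pa <- bound(a); pb <- bound(b)
    dm <- matrix(0, nrow(pa), nrow(pb))
    for (i in seq_len(nrow(pa))) for (j in seq_len(nrow(pb))) {
      dm[i, j] <- sqrt(sum((pa[i, ] - pb[j, ])^2))
    }
    max(quantile(apply(dm, 1, min), 0.95, names = FALSE),
        quantile(apply(dm, 2, min), 0.95, names = FALSE))
  }
  for (rep in 1:3) {
    sp <- c(runif(1, 0.5, 2), 1, 1.3)
    mk <- function() {
      m <- array(0L, c(10, 10, 10))
      ctr <- sample(4:7, 3, replace = TRUE)
      r <- sample(2:3, 3, replace = TRUE)
      g <- expand.grid(x = 1:10, y = 1:10, z = 1:10)
      inside <- ((g$x - ctr[1]) / r[1])^2 + ((g$y - ctr[2]) / r[2])^2 +
        ((g$z - ctr[3]) / r[3])^2 <= 1
      m[cbind(g$x, g$y, g$z)[inside, ]] <- 1L
      m
    }
    a <- mk(); b <- mk()
    expect_equal(metric_hd95(a, b, sp), oracle_hd95(a, b, sp), tolerance = 1e-12)
    expect_equal(metric_hd95(a, b, sp), metric_hd95(b, a, sp))
  }
})

test_that("distance metrics scale linearly with isotropic spacing", {
  m1 <- array(0L, c(10, 10, 10)); m1[3:5, 3:5, 3:5] <- 1L
  m2 <- array(0L, c(10, 10, 10)); m2[5:7, 4:6, 3:5] <- 1L
  for (s in c(1, 2.5)) {
    expect_equal(metric_hd95(m1, m2, rep(s, 3)), s * metric_hd95(m1, m2, c(1, 1, 1)),
                 tolerance = 1e-12)
    expect_equal(metric_come(m1, m2, rep(s, 3)), s * metric_come(m1, m2, c(1, 1, 1)),
                 tolerance = 1e-12)
  }
  # COME: integer translation equals the scaled offset norm
  t_off <- c(2, 1, 0)
  m3 <- array(0L, c(10, 10, 10)); m3[(3:5) + 2, (3:5) + 1, 3:5] <- 1L
  sp <- c(1.1, 2, 3)
  expect_equal(metric_come(m1, m3, sp), sqrt(sum((t_off * sp)^2)), tolerance = 1e-12)
})
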