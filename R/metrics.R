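#' Global structural similarity (single-window SSIM)
#'
#' The single-window global SSIM over the whole magnitude volume:
#' `(2*mu_p*mu_t + c1)(2*cov + c2) / ((mu_p^2 + mu_t^2 + c1)(var_p + var_t + c2))`
#' with `c1 = 0.01^2`, `c2 = 0.03^2` on images normalised to `[0, 1]`.
#' Means, variances and covariance are population moments over all voxels
#' (no sliding window).
#'
#' @param pred,truth numeric arrays of equal shape (magnitude images)
#' @param c1,c2 stabilising constants
#' @return scalar, at most 1
#' @export
metric_ssim <- function(pred, truth, c1 = 0.01^2, c2 = 0.03^2) {
  if (!identical(dim(pred), dim(truth))) stop("shapes differ")
  mp <- mean(pred); mt <- mean(truth)
  vp <- mean((pred - mp)^2); vt <- mean((truth - mt)^2)
  cv <- mean((pred - mp) * (truth - mt))
  ((2 * mp * mt + c1) * (2 * cv + c2)) /
    ((mp^2 + mt^2 + c1) * (vp + vt + c2))
}

#' Relative error (percent)
#'
#' `sqrt(sum((pred - truth)^2) / sum(truth^2)) * 100` on magnitude images.
#'
#' @param pred,truth numeric arrays of equal shape; `truth` must not be
#'   identically zero
#' @return percent
#' @export
metric_re <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shapes differ")
  den <- sum(truth^2)
  if (den == 0) stop("reference volume is identically zero")
  sqrt(sum((pred - truth)^2) / den) * 100
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined as
#' identical (Dice 1) with a warning.
#'
#' @param m1,m2 binary masks on the same grid
#' @return scalar in `[0, 1]`
#' @export
metric_dice <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2))) stop("mask grids differ")
  a <- m1 > 0; b <- m2 > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (sa + sb)
}

# boundary voxels: foreground voxels with at least one 6-connected neighbour
# outside the mask (grid edges count as outside)
mask_boundary <- function(mask) {
  m <- mask > 0
  d <- dim(m)
  inner <- m
  for (ax in 1:3) {
    n <- d[ax]
    lo <- pmax(seq_len(n) - 1L, 1L); hi <- pmin(seq_len(n) + 1L, n)
    shift <- function(idx) switch(ax, m[idx, , , drop = FALSE],
                                  m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
    a <- shift(lo); b <- shift(hi)
    # voxels on the grid edge have themselves as "neighbour"; force outside
    if (n > 1L) {
      edge_lo <- switch(ax, slice.index(m, 1) == 1, slice.index(m, 2) == 1,
                        slice.index(m, 3) == 1)
      edge_hi <- switch(ax, slice.index(m, 1) == n, slice.index(m, 2) == n,
                        slice.index(m, 3) == n)
      a[edge_lo] <- FALSE; b[edge_hi] <- FALSE
    } else {
      a[] <- FALSE; b[] <- FALSE
    }
    inner <- inner & a & b
  }
  m & !inner
}

mask_points_mm <- function(mask, spacing_mm) {
  w <- which(mask > 0, arr.ind = TRUE)
  sweep(w, 2L, spacing_mm, "*")
}

# for each point in a (rows), distance to the nearest point of b (rows)
min_dists <- function(a, b) {
  # chunked all-pairs; masks used here are small
  out <- numeric(nrow(a))
  bt <- t(b)
  bb <- colSums(bt^2)
  for (i in seq_len(nrow(a))) {
    d2 <- bb - 2 * as.vector(a[i, ] %*% bt) + sum(a[i, ]^2)
    out[i] <- sqrt(max(min(d2), 0))
  }
  out
}

#' 95th-percentile symmetric boundary (Hausdorff) distance
#'
#' Boundary voxels are extracted by 6-connectivity erosion difference,
#' converted to physical coordinates, and point-to-set distances are taken
#' in both directions; the 95th percentile (linear interpolation, R type 7)
#' of each direction is computed and the maximum of the two returned.
#'
#' @param m1,m2 non-empty binary masks on the same grid
#' @param spacing_mm voxel spacing
#' @return distance in mm
#' @export
metric_hd95 <- function(m1, m2, spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(m1), dim(m2))) stop("mask grids differ")
  if (sum(m1 > 0) == 0 || sum(m2 > 0) == 0) stop("empty mask in HD95")
  p1 <- mask_points_mm(mask_boundary(m1), spacing_mm)
  p2 <- mask_points_mm(mask_boundary(m2), spacing_mm)
  d12 <- stats::quantile(min_dists(p1, p2), 0.95, names = FALSE)
  d21 <- stats::quantile(min_dists(p2, p1), 0.95, names = FALSE)
  max(d12, d21)
}

#' Centre-of-mass error
#'
#' Euclidean distance between the foreground centroids of two masks in
#' physical (mm) coordinates.
#'
#' @param m1,m2 non-empty binary masks on the same grid
#' @param spacing_mm voxel spacing
#' @return distance in mm
#' @export
metric_come <- function(m1, m2, spacing_mm = c(1, 1, 1)) {
  if (!identical(dim(m1), dim(m2))) stop("mask grids differ")
  if (sum(m1 > 0) == 0 || sum(m2 > 0) == 0) stop("empty mask in COME")
  c1 <- colMeans(mask_points_mm(m1, spacing_mm))
  c2 <- colMeans(mask_points_mm(m2, spacing_mm))
  sqrt(sum((c1 - c2)^2))
}

#' Full metric report for a registration result
#'
#' @param pred_mag,truth_mag magnitude volumes
#' @param pred_mask,truth_mask optional binary structure masks
#' @param spacing_mm voxel spacing
#' @return list with `ssim`, `re_percent`, and (when masks are given)
#'   `dice`, `hd95_mm`, `come_mm`
#' @export
metric_report <- function(pred_mag, truth_mag, pred_mask = NULL,
                          truth_mask = NULL, spacing_mm = c(1, 1, 1)) {
  rep <- list(ssim = metric_ssim(pred_mag, truth_mag),
              re_percent = metric_re(pred_mag, truth_mag))
  if (!is.null(pred_mask) && !is.null(truth_mask)) {
    rep$dice <- metric_dice(pred_mask, truth_mask)
    rep$hd95_mm <- metric_hd95(pred_mask, truth_mask, spacing_mm)
    rep$come_mm <- metric_come(pred_mask, truth_mask, spacing_mm)
  }
  rep
}
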