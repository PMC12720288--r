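#' Dense deformation vector field
#'
#' Displacement per voxel in full-resolution voxel units, component order
#' `(x, y, z)` = array dimensions 1, 2, 3. The field follows the backward
#' (pull) convention: a displacement `d(v)` points from target coordinates
#' into the source volume, `warped(v) = source(v + d(v))`.
#'
#' @param data numeric 4D array `(H, W, D, 3)`
#' @param spacing_mm voxel spacing in mm
#' @return object of class `dvf`
#' @export
dvf <- function(data, spacing_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == 3L, all(is.finite(data)))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)), class = "dvf")
}

#' @export
print.dvf <- function(x, ...) {
  cat("<dvf> ", paste(dim(x$data)[1:3], collapse = "x"),
      " max |d| = ", format(max(abs(x$data)), digits = 4), " voxels\n", sep = "")
  invisible(x)
}

#' Zero deformation field on a grid
#' @param shape grid shape `(H, W, D)`
#' @param spacing_mm voxel spacing
#' @export
dvf_zero <- function(shape, spacing_mm = c(1, 1, 1)) {
  dvf(array(0, c(shape, 3L)), spacing_mm)
}

# voxel-centre positions of a full grid, 1-based, as three vectors of length
# prod(shape) in column-major order
grid_positions <- function(shape) {
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  list(
    x = rep(seq_len(H), times = W * D),
    y = rep(rep(seq_len(W), each = H), times = D),
    z = rep(seq_len(D), each = H * W)
  )
}

# Trilinear sampling of `vol` (numeric or complex 3D array) at fractional
# 1-based positions (px, py, pz), with border clamping. When `want_grad`,
# also returns the analytic derivative of the sampled value with respect to
# each position component (numeric vol only); the derivative is zero where
# the position is clamped.
sample_trilinear <- function(vol, px, py, pz, want_grad = FALSE) {
  d <- dim(vol); H <- d[1]; W <- d[2]; D <- d[3]
  mx <- (px > 1) & (px < H)
  my <- (py > 1) & (py < W)
  mz <- (pz > 1) & (pz < D)
  px <- pmin(pmax(px, 1), H); py <- pmin(pmax(py, 1), W); pz <- pmin(pmax(pz, 1), D)
  fx <- pmin(floor(px), H - 1); fy <- pmin(floor(py), W - 1); fz <- pmin(floor(pz), D - 1)
  if (H == 1L) fx <- rep(1, length(px))
  if (W == 1L) fy <- rep(1, length(py))
  if (D == 1L) fz <- rep(1, length(pz))
  tx <- px - fx; ty <- py - fy; tz <- pz - fz
  HW <- H * W
  base <- fx + (fy - 1) * H + (fz - 1) * HW
  sx <- if (H > 1L) 1 else 0
  sy <- if (W > 1L) H else 0
  sz <- if (D > 1L) HW else 0
  v000 <- vol[base]
  v100 <- vol[base + sx]; v010 <- vol[base + sy]; v001 <- vol[base + sz]
  v110 <- vol[base + sx + sy]; v101 <- vol[base + sx + sz]
  v011 <- vol[base + sy + sz]; v111 <- vol[base + sx + sy + sz]
  cx0 <- 1 - tx; cy0 <- 1 - ty; cz0 <- 1 - tz
  # interpolate along x first
  c00 <- v000 * cx0 + v100 * tx
  c10 <- v010 * cx0 + v110 * tx
  c01 <- v001 * cx0 + v101 * tx
  c11 <- v011 * cx0 + v111 * tx
  c0 <- c00 * cy0 + c10 * ty
  c1 <- c01 * cy0 + c11 * ty
  val <- c0 * cz0 + c1 * tz
  if (!want_grad) return(list(value = val))
  dx00 <- v100 - v000; dx10 <- v110 - v010; dx01 <- v101 - v001; dx11 <- v111 - v011
  gx <- ((dx00 * cy0 + dx10 * ty) * cz0 + (dx01 * cy0 + dx11 * ty) * tz) * mx
  gy <- ((c10 - c00) * cz0 + (c11 - c01) * tz) * my
  gz <- (c1 - c0) * mz
  list(value = val, gx = gx, gy = gy, gz = gz)
}

#' Warp a complex volume by a deformation field
#'
#' Backward warping with trilinear interpolation applied identically to the
#' real and imaginary parts; out-of-bounds samples clamp to the border.
#'
#' @param vol a [complex_volume()]
#' @param d a [dvf()] on the same grid
#' @return the deformed [complex_volume()]
#' @export
warp_complex <- function(vol, d) {
  shp <- dim(vol$data)
  if (!identical(shp, dim(d$data)[1:3])) stop("volume and DVF grids differ")
  g <- grid_positions(shp)
  dd <- d$data
  n <- prod(shp)
  s <- sample_trilinear(vol$data,
                        g$x + dd[seq_len(n)],
                        g$y + dd[n + seq_len(n)],
                        g$z + dd[2 * n + seq_len(n)])
  complex_volume(array(s$value, shp), vol$spacing_mm)
}

#' Warp a binary mask by a deformation field (nearest neighbour)
#'
#' Nearest-neighbour resampling preserves binarity; used to propagate
#' structure masks with ground-truth or predicted fields.
#'
#' @param mask logical/0-1 3D array
#' @param d a [dvf()]
#' @return 0/1 integer array of the same shape
#' @export
warp_mask <- function(mask, d) {
  shp <- dim(mask)
  g <- grid_positions(shp)
  dd <- d$data
  n <- prod(shp)
  ix <- pmin(pmax(round(g$x + dd[seq_len(n)]), 1), shp[1])
  iy <- pmin(pmax(round(g$y + dd[n + seq_len(n)]), 1), shp[2])
  iz <- pmin(pmax(round(g$z + dd[2 * n + seq_len(n)]), 1), shp[3])
  out <- array(as.integer(mask[ix + (iy - 1) * shp[1] + (iz - 1) * shp[1] * shp[2]] > 0),
               shp)
  out
}

# Precompute the aligned-corners trilinear map from a coarse grid to a fine
# grid: per fine voxel, 8 flat coarse indices and weights. Fine index 0 maps
# to coarse index 0 and fine N-1 to coarse N-1, so displacement values (which
# are in full-resolution voxel units) pass through unchanged.
build_upsample_map <- function(coarse_shape, target_shape) {
  pos <- lapply(1:3, function(a) {
    Nf <- target_shape[a]; Nc <- coarse_shape[a]
    if (Nf == 1L || Nc == 1L) rep(1, Nf)
    else 1 + (seq_len(Nf) - 1) * (Nc - 1) / (Nf - 1)
  })
  g <- grid_positions(target_shape)
  px <- pos[[1]][g$x]; py <- pos[[2]][g$y]; pz <- pos[[3]][g$z]
  H <- coarse_shape[1]; W <- coarse_shape[2]; D <- coarse_shape[3]
  fx <- pmin(floor(px), max(H - 1, 1)); tx <- px - fx
  fy <- pmin(floor(py), max(W - 1, 1)); ty <- py - fy
  fz <- pmin(floor(pz), max(D - 1, 1)); tz <- pz - fz
  sx <- if (H > 1L) 1 else 0; sy <- if (W > 1L) H else 0; sz <- if (D > 1L) H * W else 0
  base <- fx + (fy - 1) * H + (fz - 1) * H * W
  idx <- cbind(base, base + sx, base + sy, base + sz,
               base + sx + sy, base + sx + sz, base + sy + sz, base + sx + sy + sz)
  w <- cbind((1 - tx) * (1 - ty) * (1 - tz), tx * (1 - ty) * (1 - tz),
             (1 - tx) * ty * (1 - tz), (1 - tx) * (1 - ty) * tz,
             tx * ty * (1 - tz), tx * (1 - ty) * tz,
             (1 - tx) * ty * tz, tx * ty * tz)
  list(idx = idx, w = w)
}

#' Upsample a deformation field to a target grid
#'
#' Trilinear interpolation of each displacement component with aligned
#' corners. Displacement values are already expressed in full-resolution
#' voxel units, so no value rescaling occurs.
#'
#' @param coarse a [dvf()] on the coarse grid
#' @param target_shape fine grid shape `(H, W, D)`
#' @return a [dvf()] on the fine grid
#' @export
upsample_dvf <- function(coarse, target_shape) {
  cs <- dim(coarse$data)[1:3]
  target_shape <- as.integer(target_shape)
  if (identical(cs, target_shape)) return(coarse)
  mp <- build_upsample_map(cs, target_shape)
  n <- prod(cs)
  out <- array(0, c(target_shape, 3L))
  for (j in 1:3) {
    comp <- coarse$data[(j - 1) * n + seq_len(n)]
    vals <- matrix(comp[mp$idx], nrow(mp$idx))
    out[, , , j] <- rowSums(vals * mp$w)
  }
  dvf(out, coarse$spacing_mm)
}

#' Approximate inverse of a deformation field
#'
#' Fixed-point iteration `d_inv(v) = -d(v + d_inv(v))`, which converges for
#' the smooth, moderate-amplitude fields the motion generator produces. Used
#' to map a deformed bin back to the reference bin.
#'
#' @param d a [dvf()]
#' @param n_iter fixed-point iterations
#' @return a [dvf()] with `warp(warp(x, d), invert_dvf(d)) ~ x` away from
#'   boundaries
#' @export
invert_dvf <- function(d, n_iter = 10L) {
  shp <- dim(d$data)[1:3]
  g <- grid_positions(shp)
  n <- prod(shp)
  comp <- function(j) d$data[(j - 1) * n + seq_len(n)]
  inv <- matrix(0, n, 3L)
  for (it in seq_len(n_iter)) {
    px <- g$x + inv[, 1]; py <- g$y + inv[, 2]; pz <- g$z + inv[, 3]
    for (j in 1:3) {
      inv[, j] <- -sample_trilinear(array(comp(j), shp), px, py, pz)$value
    }
  }
  dvf(array(inv, c(shp, 3L)), d$spacing_mm)
}

# --- autodiff bridges --------------------------------------------------------

# Upsample inside an autodiff graph. `node` is an (N_coarse x 3) matrix node;
# returns an (N_fine x 3) matrix node.
ag_upsample_dvf <- function(node, coarse_shape, target_shape) {
  if (identical(as.integer(coarse_shape), as.integer(target_shape))) return(node)
  mp <- build_upsample_map(coarse_shape, target_shape)
  comps <- lapply(1:3, function(j) {
    cj <- ag_cols(node, j)
    gj <- ag_gather(cj, mp$idx)
    ag_rowsums(ag_mul(gj, mp$w))
  })
  do.call(ag_cbind, comps)
}

# Warp one fixed real-valued plane by a DVF node inside an autodiff graph.
# `plane` is a numeric 3D array; `dvf_node` an (N_vox x 3) matrix node on the
# same grid (column-major voxel order). Returns an (N_vox x 1) node.
ag_warp_plane <- function(plane, dvf_node) {
  shp <- dim(plane)
  g <- grid_positions(shp)
  dd <- dvf_node$value
  s <- sample_trilinear(plane, g$x + dd[, 1], g$y + dd[, 2], g$z + dd[, 3],
                        want_grad = TRUE)
  ag_new_node(dvf_node$tape, matrix(s$value, ncol = 1L), list(dvf_node),
              list(function(gr) {
                gr <- as.vector(gr)
                cbind(gr * s$gx, gr * s$gy, gr * s$gz)
              }))
}
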