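#' Step-B loss weights
#'
#' Weights of the adaptation objective: `l1` multiplies the k-space fidelity
#' term, `l2` the embedding similarity term, `l3` the smoothness term.
#' Defaults `(1.0, 0.5, 0.5)`.
#'
#' @param l1,l2,l3 non-negative finite reals
#' @return object of class `loss_weights`
#' @export
loss_weights <- function(l1 = 1.0, l2 = 0.5, l3 = 0.5) {
  stopifnot(is.finite(l1), is.finite(l2), is.finite(l3),
            l1 >= 0, l2 >= 0, l3 >= 0)
  structure(list(l1 = l1, l2 = l2, l3 = l3), class = "loss_weights")
}

as_dvf_array <- function(d) {
  if (inherits(d, "dvf")) d$data else d
}

#' Deformation discrepancy loss (step A)
#'
#' Sum over the three Cartesian components of the per-component mean
#' absolute difference between the INR-predicted and the reference
#' (population-prior) displacement fields.
#'
#' @param d_inr,d_reg [dvf()] objects or `(H, W, D, 3)` arrays of equal shape
#' @return scalar
#' @export
loss_stepA <- function(d_inr, d_reg) {
  a <- as_dvf_array(d_inr); b <- as_dvf_array(d_reg)
  if (!identical(dim(a), dim(b))) stop("DVF shapes differ")
  n <- prod(dim(a)[1:3])
  s <- 0
  for (j in 1:3) {
    s <- s + mean(abs(a[(j - 1) * n + seq_len(n)] - b[(j - 1) * n + seq_len(n)]))
  }
  s
}

#' k-space fidelity loss
#'
#' Mean squared complex-modulus error between two k-space data sets sampled
#' on the same trajectory: `(1/N_k) * sum |S_DK(k_i) - T_UK(k_i)|^2` over all
#' `N_k` samples (spokes x samples x slices).
#'
#' @param S_DK,T_UK [kspace_data()] on identical trajectories
#' @return scalar
#' @export
loss_kspace <- function(S_DK, T_UK) {
  ta <- S_DK$trajectory; tb <- T_UK$trajectory
  if (!isTRUE(all.equal(ta$sample_coords, tb$sample_coords)) ||
      !identical(dim(S_DK$values), dim(T_UK$values))) {
    stop("k-space data are not on the same trajectory")
  }
  mean(Mod(S_DK$values - T_UK$values)^2)
}

#' Embedding similarity loss
#'
#' Mean cosine similarity over paired embedding vectors. By default the
#' value is negated so that *minimising* the loss *increases* semantic
#' similarity; `sign_convention = "printed"` returns the raw mean cosine.
#' Zero-norm vectors contribute 0 with a warning.
#'
#' @param E1,E2 `N_e x C` embedding matrices
#' @param sign_convention `"negated"` (default) or `"printed"`
#' @return scalar
#' @export
loss_embed <- function(E1, E2, sign_convention = c("negated", "printed")) {
  sign_convention <- match.arg(sign_convention)
  if (!identical(dim(E1), dim(E2))) stop("embedding dimensions differ")
  n1 <- sqrt(rowSums(E1^2)); n2 <- sqrt(rowSums(E2^2))
  num <- rowSums(E1 * E2)
  zero <- n1 == 0 | n2 == 0
  if (any(zero)) warning("zero-norm embedding vectors contribute 0")
  cosv <- ifelse(zero, 0, num / (n1 * n2))
  m <- mean(cosv)
  if (sign_convention == "negated") -m else m
}

#' Deformation smoothness loss (mean deformation energy)
#'
#' Sum over components of the voxel-mean squared forward-difference partial
#' derivatives along x, y and z. Differences are taken in voxel units with
#' replicate padding, so the last difference along each axis is zero.
#'
#' @param d a [dvf()] or `(H, W, D, 3)` array
#' @return scalar
#' @export
loss_smooth <- function(d) {
  a <- as_dvf_array(d)
  shp <- dim(a)[1:3]
  total <- 0
  for (j in 1:3) {
    comp <- array(a[, , , j], shp)
    for (ax in 1:3) {
      n <- shp[ax]
      idx <- pmin(seq_len(n) + 1L, n)
      shifted <- switch(ax,
                        comp[idx, , , drop = FALSE],
                        comp[, idx, , drop = FALSE],
                        comp[, , idx, drop = FALSE])
      total <- total + mean((shifted - comp)^2)
    }
  }
  total
}

#' Step-B combined loss
#'
#' Weighted sum `l1 * kspace + l2 * embed + l3 * smooth`.
#'
#' @param k,e,s finite scalars (k-space, embedding, smoothness terms)
#' @param w a [loss_weights()]
#' @return scalar
#' @export
loss_stepB <- function(k, e, s, w = loss_weights()) {
  stopifnot(is.finite(k), is.finite(e), is.finite(s))
  w$l1 * k + w$l2 * e + w$l3 * s
}

# --- in-graph loss builders --------------------------------------------------

# step-A loss on an (N x 3) displacement node against a constant (N x 3)
# reference; columns have equal length so the component-mean sum is three
# times the overall mean
ag_loss_stepA <- function(dvf_node, d_reg_mat) {
  ag_scale(ag_mean(ag_abs(ag_sub(dvf_node, ag_const(dvf_node$tape, d_reg_mat)))), 3)
}

# flat-index shift maps for forward differences with replicate padding
smooth_shift_idx <- function(shape) {
  g <- grid_positions(shape)
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  flat <- function(x, y, z) x + (y - 1) * H + (z - 1) * H * W
  list(flat(pmin(g$x + 1L, H), g$y, g$z),
       flat(g$x, pmin(g$y + 1L, W), g$z),
       flat(g$x, g$y, pmin(g$z + 1L, D)))
}

# smoothness loss on an (N x 3) displacement node living on `shape`
ag_loss_smooth <- function(dvf_node, shape) {
  idx <- smooth_shift_idx(shape)
  total <- NULL
  for (j in 1:3) {
    cj <- ag_cols(dvf_node, j)
    for (ax in 1:3) {
      im <- matrix(idx[[ax]], ncol = 1L)
      term <- ag_mean(ag_pow(ag_sub(ag_gather(cj, im), cj), 2))
      total <- if (is.null(total)) term else ag_add(total, term)
    }
  }
  total
}

# k-space fidelity on real/imag image nodes (N_vox x D) through the cached
# NUDFT matrix (Er + i Ei); targets are constant matrices
ag_loss_kspace <- function(xr, xi, Er, Ei, tr, ti) {
  kr <- ag_sub(ag_matmul(ag_const(xr$tape, Er), xr), ag_matmul(ag_const(xr$tape, Ei), xi))
  ki <- ag_add(ag_matmul(ag_const(xr$tape, Ei), xr), ag_matmul(ag_const(xr$tape, Er), xi))
  n_k <- length(tr)
  rr <- ag_pow(ag_sub(kr, tr), 2)
  ii <- ag_pow(ag_sub(ki, ti), 2)
  ag_scale(ag_add(ag_sum(rr), ag_sum(ii)), 1 / n_k)
}

# negated mean row-wise cosine similarity between an embedding node and a
# constant embedding matrix
ag_loss_embed <- function(E_node, E_ref, eps = 1e-12) {
  tp <- E_node$tape
  num <- ag_rowsums(ag_mul(E_node, ag_const(tp, E_ref)))
  nrm <- ag_pow(ag_add(ag_rowsums(ag_pow(E_node, 2)), eps), -0.5)
  nref <- sqrt(rowSums(E_ref^2) + eps)
  cosv <- ag_mul(ag_mul(num, nrm), matrix(1 / nref, ncol = 1L))
  ag_scale(ag_mean(cosv), -1)
}
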