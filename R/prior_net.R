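#' @title Lite population registration prior (UNet-style encoder-decoder)
#'
#' @description
#' A small volumetric encoder-decoder in the VoxelMorph mould: six input
#' planes (real/imag of the fully sampled source, the undersampled source
#' and the undersampled target), two stride-2 encoder levels to a bottleneck,
#' a mirrored decoder with skip connections, and a zero-initialised flow head
#' emitting a dense 3-component displacement field. The bottleneck features
#' double as the latent embeddings used by the embedding similarity loss.
#' Trained unsupervised across a cohort with the k-space fidelity and
#' smoothness losses; once trained it stays frozen and supplies reference
#' displacement fields and embeddings to the meta-learning loop.
#'
#' @name prior_net
NULL

# cache of im2col/upsample index maps keyed by geometry
.convmap_cache <- new.env(parent = emptyenv())

# 3x3x3 im2col voxel-index map (zero entries denote zero padding) for a given
# input shape and stride; returns the map and the output shape
conv_vox_idx <- function(shape, stride) {
  key <- paste(c(shape, stride), collapse = "_")
  hit <- .convmap_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- shape[1]; W <- shape[2]; D <- shape[3]
  out_shape <- as.integer(ceiling(shape / stride))
  g <- grid_positions(out_shape)
  cx <- (g$x - 1L) * stride + 1L
  cy <- (g$y - 1L) * stride + 1L
  cz <- (g$z - 1L) * stride + 1L
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  idx <- matrix(0L, length(cx), 27L)
  for (k in seq_len(27L)) {
    px <- cx + offs$ox[k]; py <- cy + offs$oy[k]; pz <- cz + offs$oz[k]
    ok <- px >= 1L & px <= H & py >= 1L & py <= W & pz >= 1L & pz <= D
    idx[, k] <- ifelse(ok, px + (py - 1L) * H + (pz - 1L) * H * W, 0L)
  }
  ent <- list(idx = idx, out_shape = out_shape, n_in = prod(shape))
  .convmap_cache[[key]] <- ent
  ent
}

# expand a voxel-index map across input channels of a channel-last
# (N_vox x C) matrix; zero (padding) entries stay zero
expand_channel_idx <- function(vox_idx, n_in, c_in) {
  key <- paste("ch", nrow(vox_idx), ncol(vox_idx), n_in, c_in,
               vox_idx[1L], vox_idx[length(vox_idx)], sep = "_")
  hit <- .convmap_cache[[key]]
  if (!is.null(hit)) return(hit)
  cols <- vector("list", c_in)
  for (c in seq_len(c_in)) {
    m <- vox_idx + (c - 1L) * n_in
    m[vox_idx == 0L] <- 0L
    cols[[c]] <- m
  }
  out <- do.call(cbind, cols)
  .convmap_cache[[key]] <- out
  out
}

# nearest-neighbour upsampling index (fine voxel -> coarse flat voxel)
upsample_vox_idx <- function(coarse_shape, fine_shape) {
  key <- paste(c("up", coarse_shape, fine_shape), collapse = "_")
  hit <- .convmap_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- grid_positions(fine_shape)
  f2c <- function(i, nf, nc) pmin(pmax(ceiling(i * nc / nf), 1L), nc)
  ix <- f2c(g$x, fine_shape[1], coarse_shape[1])
  iy <- f2c(g$y, fine_shape[2], coarse_shape[2])
  iz <- f2c(g$z, fine_shape[3], coarse_shape[3])
  idx <- matrix(ix + (iy - 1L) * coarse_shape[1] +
                  (iz - 1L) * coarse_shape[1] * coarse_shape[2], ncol = 1L)
  .convmap_cache[[key]] <- idx
  idx
}

# one 3x3x3 convolution inside a graph; x is an (N_vox x Cin) node
ag_conv3 <- function(x, shape, W, b, stride = 1L) {
  cv <- conv_vox_idx(shape, stride)
  c_in <- ncol(x$value)
  idx <- expand_channel_idx(cv$idx, cv$n_in, c_in)
  cols <- ag_gather(x, idx)
  list(out = ag_add(ag_matmul(cols, W), b), shape = cv$out_shape)
}

ag_upsample_nn <- function(x, coarse_shape, fine_shape) {
  vidx <- upsample_vox_idx(coarse_shape, fine_shape)
  c_in <- ncol(x$value)
  idx <- expand_channel_idx(matrix(vidx, ncol = 1L), prod(coarse_shape), c_in)
  ag_gather(x, idx)
}

conv_init <- function(c_in, c_out, gain = 1, zero = FALSE) {
  fan <- 27L * c_in
  if (zero) {
    list(W = matrix(0, fan, c_out), b = rep(0, c_out))
  } else {
    bw <- gain * sqrt(6 / fan)
    list(W = matrix(stats::runif(fan * c_out, -bw, bw), fan, c_out),
         b = rep(0, c_out))
  }
}

#' Initialise the lite prior registration network
#'
#' @param base_channels encoder width `C` at the first level; the bottleneck
#'   has `4C` channels (this is the embedding dimension `C_e`)
#' @param seed integer
#' @return object of class `prior_net` with `params`, `base_channels`,
#'   `trained` flag
#' @export
init_prior_net <- function(base_channels = 8L, seed = 1L) {
  C <- as.integer(base_channels)
  params <- with_seed(seed, list(
    enc0 = conv_init(6L, C),
    enc1 = conv_init(C, 2L * C),
    enc2 = conv_init(2L * C, 4L * C),
    dec1 = conv_init(6L * C, 2L * C),
    dec0 = conv_init(3L * C, C),
    flow = conv_init(C, 3L, zero = TRUE)
  ))
  structure(list(params = params, base_channels = C, trained = FALSE,
                 seed = as.integer(seed), loss_history = numeric(0)),
            class = "prior_net")
}

# encoder part; x is an (N_vox x 6) node, returns bottleneck node + shapes
prior_encoder_graph <- function(tp, x, pn, shape) {
  r <- function(z) ag_relu(z)
  e0 <- ag_conv3(x, shape, pn$enc0$W, pn$enc0$b, 1L); e0$out <- r(e0$out)
  e1 <- ag_conv3(e0$out, e0$shape, pn$enc1$W, pn$enc1$b, 2L); e1$out <- r(e1$out)
  e2 <- ag_conv3(e1$out, e1$shape, pn$enc2$W, pn$enc2$b, 2L); e2$out <- r(e2$out)
  list(e0 = e0, e1 = e1, bottleneck = e2)
}

# full network; returns the (N_vox x 3) flow node
prior_net_graph <- function(tp, x, pn, shape) {
  enc <- prior_encoder_graph(tp, x, pn, shape)
  u1 <- ag_upsample_nn(enc$bottleneck$out, enc$bottleneck$shape, enc$e1$shape)
  d1 <- ag_conv3(ag_cbind(u1, enc$e1$out), enc$e1$shape, pn$dec1$W, pn$dec1$b, 1L)
  d1$out <- ag_relu(d1$out)
  u0 <- ag_upsample_nn(d1$out, d1$shape, enc$e0$shape)
  d0 <- ag_conv3(ag_cbind(u0, enc$e0$out), enc$e0$shape, pn$dec0$W, pn$dec0$b, 1L)
  d0$out <- ag_relu(d0$out)
  fl <- ag_conv3(d0$out, d0$shape, pn$flow$W, pn$flow$b, 1L)
  fl$out
}

model_input_matrix <- function(X) {
  d <- dim(X)
  if (length(d) != 4L || d[4] != 6L) stop("model input must have 6 planes")
  matrix(X, prod(d[1:3]), 6L)
}

#' Predict a reference displacement field from the six-channel input
#'
#' Deterministic in evaluation mode (the network has no stochastic layers).
#'
#' @param net a [init_prior_net()]
#' @param X `(H, W, D, 6)` model input from [preprocess_case()]
#' @param spacing_mm voxel spacing carried by the returned field
#' @return a [dvf()] at full resolution in voxel units
#' @export
prior_predict <- function(net, X, spacing_mm = c(1, 1, 1)) {
  shape <- dim(X)[1:3]
  tp <- ag_tape()
  xn <- ag_const(tp, model_input_matrix(X))
  pnodes <- params_to_nodes(tp, net$params)
  flow <- prior_net_graph(tp, xn, pnodes, shape)
  dvf(array(flow$value, c(shape, 3L)), spacing_mm)
}

#' Extract latent embeddings of a complex volume with the frozen encoder
#'
#' The two-plane (real/imaginary) volume is tiled three times to match the
#' six-plane encoder input, passed through the encoder, and the bottleneck
#' features are reshaped to one embedding vector per bottleneck spatial
#' position (`N_e` vectors of dimension `4 * base_channels`).
#'
#' @param net a [init_prior_net()]
#' @param vol a [complex_volume()]
#' @return `N_e x C_e` embedding matrix
#' @export
prior_encode <- function(net, vol) {
  shape <- dim(vol$data)
  x <- cbind(Re(vol$data), Im(vol$data))
  x <- matrix(x, prod(shape), 2L)[, c(1, 2, 1, 2, 1, 2)]
  tp <- ag_tape()
  enc <- prior_encoder_graph(tp, ag_const(tp, x), params_to_nodes(tp, net$params),
                             shape)
  enc$bottleneck$out$value
}

# tile a pair of real/imag image nodes (N x 1 each) into the six-plane
# encoder input inside a graph
ag_tile_complex <- function(xr, xi) {
  ag_cbind(xr, xi, xr, xi, xr, xi)
}

#' Train the prior network across a synthetic cohort
#'
#' Unsupervised population training: per epoch and subject, a random target
#' bin and a fresh golden-angle trajectory (random initial angle) are drawn,
#' the case is preprocessed, and one Adam step minimises
#' `l1 * L_kspace + l3 * L_smooth` of the warped source against the target
#' k-space data.
#'
#' @param net a [init_prior_net()]
#' @param cohort from [generate_cohort()]
#' @param epochs passes over the cohort (>= 0; 0 returns `net` unchanged)
#' @param lr Adam learning rate
#' @param n_spokes,samples_per_spoke radial sampling used for training
#' @param weights a [loss_weights()]; only `l1` and `l3` are used
#' @param seed integer controlling bin/trajectory draws
#' @return the trained `prior_net` (with `loss_history` per step)
#' @export
train_prior <- function(net, cohort, epochs, lr = 1e-3, n_spokes = 13L,
                        samples_per_spoke = 64L, weights = loss_weights(),
                        seed = 1L) {
  stopifnot(length(cohort) >= 1L)
  if (epochs < 1L) return(net)
  opt <- adam_init(net$params, lr = lr)
  losses <- numeric(0)
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (si in seq_along(cohort)) {
      step <- step + 1L
      sseed <- derive_seed(seed, paste0("prior", ep, "_", si))
      subj <- cohort[[si]]
      nb <- length(subj$bins)
      b <- if (nb > 1L) with_seed(sseed, sample(2:nb, 1L)) else 1L
      traj <- golden_angle_trajectory(n_spokes, samples_per_spoke,
                                      seed_for_theta0 = sseed + 7L)
      S_FI <- subj$bins[[1L]]
      T_UK <- nudft_forward(subj$bins[[b]], traj)
      pc <- preprocess_case(S_FI, T_UK)
      shape <- dim(S_FI$data)
      tp <- ag_tape()
      pnodes <- params_to_nodes(tp, net$params)
      flow <- prior_net_graph(tp, ag_const(tp, model_input_matrix(pc$X)), pnodes,
                              shape)
      loss <- ag_case_stepB_loss(tp, flow, S_FI, T_UK, shape,
                                 weights = loss_weights(weights$l1, 0, weights$l3))
      ag_backward(loss$total)
      upd <- adam_step(net$params, grads_from_nodes(pnodes), opt)
      net$params <- upd$params; opt <- upd$state
      losses <- c(losses, loss$total$value)
    }
  }
  net$trained <- TRUE
  net$loss_history <- c(net$loss_history, losses)
  net
}

# Shared step-B loss graph for a full-resolution (N_vox x 3) displacement
# node: warp the source planes, project through the NUDFT, and combine
# k-space fidelity, optional embedding similarity, and smoothness.
ag_case_stepB_loss <- function(tp, flow_node, S_FI, T_UK, shape,
                               weights = loss_weights(), net = NULL,
                               E_target = NULL) {
  re <- array(Re(S_FI$data), shape); im <- array(Im(S_FI$data), shape)
  wr <- ag_warp_plane(re, flow_node)
  wi <- ag_warp_plane(im, flow_node)
  Em <- nudft_matrix(T_UK$trajectory, shape[1], shape[2])
  D <- shape[3]
  xr <- ag_reshape(wr, c(prod(shape[1:2]), D))
  xi <- ag_reshape(wi, c(prod(shape[1:2]), D))
  lk <- ag_loss_kspace(xr, xi, Em$Er, Em$Ei, Re(T_UK$values), Im(T_UK$values))
  ls <- ag_loss_smooth(flow_node, shape)
  total <- ag_add(ag_scale(lk, weights$l1), ag_scale(ls, weights$l3))
  le_val <- NA_real_
  if (weights$l2 > 0) {
    if (is.null(net) || is.null(E_target)) {
      stop("embedding loss requested but no prior net/target embedding given")
    }
    x6 <- ag_tile_complex(wr, wi)
    enc <- prior_encoder_graph(tp, x6, params_to_nodes_const(tp, net$params), shape)
    le <- ag_loss_embed(enc$bottleneck$out, E_target)
    total <- ag_add(total, ag_scale(le, weights$l2))
    le_val <- le$value
  }
  list(total = total, kspace = lk$value, smooth = ls$value, embed = le_val)
}

# constant (frozen) parameter nodes
params_to_nodes_const <- function(tp, params) {
  lapply(params, function(p) if (is.list(p)) params_to_nodes_const(tp, p)
         else ag_const(tp, p))
}
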