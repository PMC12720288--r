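#' @title Token-aware modulator
#'
#' @description
#' Conditions the shared INR template on a specific registration case. The
#' six-plane model input is cut into non-overlapping 3D patches and linearly
#' embedded into tokens; a transformer-style encoder block (multi-head
#' self-attention + MLP, both with residual connections) contextualises the
#' tokens; a second multi-head token-attention layer followed by mean pooling
#' produces one context vector; and three two-layer generators map the
#' context to per-hidden-layer modulation coefficients. Generators are
#' parameterised as `(1 + dgamma, 1 + dbeta)` with zero-initialised final
#' layers, so an untrained modulator reproduces the unmodulated template
#' exactly. A plain convolutional encoder variant (no attention) backs the
#' baseline ablation mode.
#'
#' @name modulator
NULL

# non-overlapping patch tokenisation index: one row per patch, columns run
# over (voxel within patch) x (channel); 0 entries are zero padding
patch_token_idx <- function(shape, patch, n_channels = 6L) {
  key <- paste(c("tok", shape, patch, n_channels), collapse = "_")
  hit <- .convmap_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- as.integer(rep(patch, length.out = 3L))
  np <- as.integer(ceiling(shape / p))
  n_vox <- prod(shape)
  gp <- grid_positions(np)
  off <- grid_positions(p)
  n_in_patch <- prod(p)
  idx <- matrix(0L, prod(np), n_in_patch)
  for (k in seq_len(n_in_patch)) {
    px <- (gp$x - 1L) * p[1] + off$x[k]
    py <- (gp$y - 1L) * p[2] + off$y[k]
    pz <- (gp$z - 1L) * p[3] + off$z[k]
    ok <- px <= shape[1] & py <= shape[2] & pz <= shape[3]
    idx[, k] <- ifelse(ok, px + (py - 1L) * shape[1] + (pz - 1L) * shape[1] * shape[2], 0L)
  }
  full <- expand_channel_idx(idx, n_vox, n_channels)
  ent <- list(idx = full, n_tokens = prod(np), token_dim_in = n_in_patch * n_channels)
  .convmap_cache[[key]] <- ent
  ent
}

mlp_init <- function(d_in, d_hidden, d_out, zero_out = FALSE) {
  b1 <- sqrt(6 / d_in); b2 <- sqrt(6 / d_hidden)
  list(W1 = matrix(stats::runif(d_in * d_hidden, -b1, b1), d_in, d_hidden),
       b1 = rep(0, d_hidden),
       W2 = if (zero_out) matrix(0, d_hidden, d_out)
            else matrix(stats::runif(d_hidden * d_out, -b2, b2), d_hidden, d_out),
       b2 = rep(0, d_out))
}

attn_init <- function(d) {
  b <- sqrt(6 / d)
  u <- function() matrix(stats::runif(d * d, -b, b), d, d)
  list(Wq = u(), Wk = u(), Wv = u(), Wo = u())
}

#' Initialise a modulator
#'
#' @param kind `"token"` (transformer encoder + token attention + generators)
#'   or `"conv"` (plain CNN encoder, the ablation baseline)
#' @param hidden_widths widths of the three modulated hidden layers
#' @param d_token token feature dimension (192 at acquisition scale; smaller
#'   at phantom scale)
#' @param n_heads attention heads (default 4)
#' @param patch cubic patch edge for tokenisation
#' @param base_channels encoder width for the `"conv"` kind
#' @param seed integer
#' @return object of class `modulator`
#' @export
init_modulator <- function(kind = c("token", "conv"),
                           hidden_widths = c(256L, 256L, 256L),
                           d_token = 192L, n_heads = 4L, patch = 4L,
                           base_channels = 8L, seed = 1L) {
  kind <- match.arg(kind)
  hw <- as.integer(hidden_widths)
  stopifnot(length(hw) == 3L)
  d <- as.integer(d_token)
  if (kind == "token" && d %% n_heads != 0L) stop("d_token must divide by n_heads")
  params <- with_seed(seed, {
    if (kind == "token") {
      list(
        embed = NULL,  # allocated lazily once the input patch size is known
        enc_attn = attn_init(d),
        enc_mlp = mlp_init(d, 2L * d, d),
        tok_attn = attn_init(d),
        g1 = mlp_init(d, d, 2L * hw[1], zero_out = TRUE),
        g2 = mlp_init(d, d, 2L * hw[2], zero_out = TRUE),
        g3 = mlp_init(d, d, 2L * hw[3], zero_out = TRUE)
      )
    } else {
      C <- as.integer(base_channels)
      list(
        enc0 = conv_init(6L, C),
        enc1 = conv_init(C, 2L * C),
        g1 = mlp_init(2L * C, 2L * C, 2L * hw[1], zero_out = TRUE),
        g2 = mlp_init(2L * C, 2L * C, 2L * hw[2], zero_out = TRUE),
        g3 = mlp_init(2L * C, 2L * C, 2L * hw[3], zero_out = TRUE)
      )
    }
  })
  structure(list(kind = kind, params = params, hidden_widths = hw,
                 d_token = d, n_heads = as.integer(n_heads),
                 patch = as.integer(patch),
                 base_channels = as.integer(base_channels),
                 seed = as.integer(seed)),
            class = "modulator")
}

# lazily allocate the patch embedding once the tokenised input width is known
ensure_embed <- function(m, token_dim_in) {
  if (is.null(m$params$embed)) {
    b <- sqrt(6 / token_dim_in)
    m$params$embed <- with_seed(m$seed + 101L, list(
      W = matrix(stats::runif(token_dim_in * m$d_token, -b, b),
                 token_dim_in, m$d_token),
      b = rep(0, m$d_token)))
  } else if (nrow(m$params$embed$W) != token_dim_in) {
    stop("modulator was built for a different input geometry")
  }
  m
}

# multi-head self-attention on a (n_tokens x d) node
ag_mha <- function(x, att, n_heads) {
  d <- ncol(x$value)
  dh <- d %/% n_heads
  Q <- ag_matmul(x, att$Wq); K <- ag_matmul(x, att$Wk); V <- ag_matmul(x, att$Wv)
  heads <- lapply(seq_len(n_heads), function(h) {
    j <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- ag_cols(Q, j); Kh <- ag_cols(K, j); Vh <- ag_cols(V, j)
    A <- ag_softmax_rows(ag_scale(ag_matmul(Qh, ag_t(Kh)), 1 / sqrt(dh)))
    ag_matmul(A, Vh)
  })
  ag_matmul(do.call(ag_cbind, heads), att$Wo)
}

ag_mlp2 <- function(x, p) {
  h <- ag_relu(ag_add(ag_matmul(x, p$W1), p$b1))
  ag_add(ag_matmul(h, p$W2), p$b2)
}

# column means of an (n x d) node as a (1 x d) node
ag_colmeans <- function(x) {
  n <- nrow(x$value)
  ag_matmul(ag_const(x$tape, matrix(1 / n, 1L, n)), x)
}

# modulation coefficients as graph nodes; `pn` are parameter nodes (tracked
# for the modulator update, constant during INR inner loops)
ag_modulator_forward <- function(tp, m, pn, X) {
  shape <- dim(X)[1:3]
  Xm <- model_input_matrix(X)
  if (m$kind == "token") {
    tok <- patch_token_idx(shape, m$patch)
    raw <- matrix(c(0, as.vector(Xm))[tok$idx + 1L], tok$n_tokens)
    T0 <- ag_add(ag_matmul(ag_const(tp, raw), pn$embed$W), pn$embed$b)
    T1 <- ag_add(T0, ag_mha(T0, pn$enc_attn, m$n_heads))
    T2 <- ag_add(T1, ag_mlp2(T1, pn$enc_mlp))
    T3 <- ag_mha(T2, pn$tok_attn, m$n_heads)
    ctx <- ag_colmeans(T3)
  } else {
    xn <- ag_const(tp, Xm)
    e0 <- ag_conv3(xn, shape, pn$enc0$W, pn$enc0$b, 2L); e0$out <- ag_relu(e0$out)
    e1 <- ag_conv3(e0$out, e0$shape, pn$enc1$W, pn$enc1$b, 2L); e1$out <- ag_relu(e1$out)
    ctx <- ag_colmeans(e1$out)
  }
  gens <- list(pn$g1, pn$g2, pn$g3)
  gamma <- beta <- vector("list", 3L)
  for (l in 1:3) {
    w <- m$hidden_widths[l]
    out <- ag_mlp2(ctx, gens[[l]])
    gamma[[l]] <- ag_add(ag_cols(out, seq_len(w)), 1)
    beta[[l]] <- ag_add(ag_cols(out, w + seq_len(w)), 1)
  }
  list(gamma = gamma, beta = beta)
}

#' Generate modulation coefficients for a model input
#'
#' Deterministic in evaluation mode. At initialisation the generators'
#' final layers are zero, so `gamma = beta = 1` exactly and the template is
#' unmodulated.
#'
#' @param m a [init_modulator()]
#' @param X `(H, W, D, 6)` model input
#' @return a `modulation` object (`gamma`, `beta`: three vectors matching
#'   the hidden widths)
#' @export
modulator_forward <- function(m, X) {
  shape <- dim(X)
  if (length(shape) != 4L || shape[4] != 6L) stop("model input must have 6 planes")
  if (m$kind == "token") {
    tok <- patch_token_idx(shape[1:3], m$patch)
    m <- ensure_embed(m, tok$token_dim_in)
  }
  tp <- ag_tape()
  pn <- params_to_nodes_const(tp, m$params)
  mod <- ag_modulator_forward(tp, m, pn, X)
  structure(list(gamma = lapply(mod$gamma, function(nd) as.vector(nd$value)),
                 beta = lapply(mod$beta, function(nd) as.vector(nd$value))),
            class = "modulation")
}
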