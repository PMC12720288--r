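#' Downsampled normalised coordinate grid
#'
#' Coordinates fed to the INR: per axis, `ceil(shape/downsample)` points
#' uniformly spanning `[-1, 1]` (full-grid corners map exactly to -1 and +1;
#' a single point maps to 0). Points are ordered column-major (first axis
#' fastest), matching R array flattening, so the INR output reshapes directly
#' onto the coarse grid.
#'
#' @param shape full-resolution grid shape `(H, W, D)`
#' @param downsample integer factor per axis (scalar recycled), >= 1
#' @return list with `coords` (N x 3 matrix in `[-1,1]`), `coarse_shape`,
#'   `shape`, `downsample`
#' @export
coordinate_grid <- function(shape, downsample = 2L) {
  shape <- as.integer(shape)
  ds <- as.integer(rep(downsample, length.out = 3L))
  stopifnot(all(ds >= 1L))
  cs <- as.integer(ceiling(shape / ds))
  axis <- function(n) if (n == 1L) 0 else -1 + 2 * (seq_len(n) - 1) / (n - 1)
  ax <- lapply(cs, axis)
  g <- grid_positions(cs)
  coords <- cbind(x = ax[[1]][g$x], y = ax[[2]][g$y], z = ax[[3]][g$z])
  list(coords = coords, coarse_shape = cs, shape = shape, downsample = ds)
}

#' Initialise a SIREN INR template
#'
#' A 5-layer sinusoidal MLP mapping normalised coordinates to displacement
#' vectors. Default layout `(3, 256, 256, 256, 3)`; the three hidden layers
#' are the modulated ones and the output layer has no activation. SIREN
#' initialisation: first-layer weights uniform in `+-1/fan_in`, later-layer
#' weights uniform in `+-sqrt(6/fan_in)/omega0`; biases uniform in
#' `+-1/sqrt(fan_in)`.
#'
#' @param widths layer widths, first and last must be 3
#' @param omega0 SIREN frequency scale of the first layer (default 30)
#' @param seed integer
#' @return object of class `inr_template` with fields `params`
#'   (`Wi, bi, W1, b1, W2, b2, W3, b3, Wo, bo`), `widths`, `omega0`, `seed`
#' @export
init_template <- function(widths = c(3L, 256L, 256L, 256L, 3L), omega0 = 30,
                          seed = 1L) {
  widths <- as.integer(widths)
  if (length(widths) != 5L || widths[1] != 3L || widths[5] != 3L) {
    stop("widths must be a length-5 vector starting and ending with 3")
  }
  params <- with_seed(seed, {
    u <- function(n, b) stats::runif(n, -b, b)
    lay <- function(fi, fo, first = FALSE) {
      bw <- if (first) 1 / fi else sqrt(6 / fi) / omega0
      list(W = matrix(u(fi * fo, bw), fi, fo), b = u(fo, 1 / sqrt(fi)))
    }
    # five affine layers over the width vector (3, h1, h2, h3, 3):
    # input 3->h1, hidden h1->h2, h2->h3, h3->h3, output h3->3
    l0 <- lay(widths[1], widths[2], first = TRUE)
    l1 <- lay(widths[2], widths[3]); l2 <- lay(widths[3], widths[4])
    l3 <- lay(widths[4], widths[4])
    lo <- lay(widths[4], widths[5])
    list(Wi = l0$W, bi = l0$b, W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
         W3 = l3$W, b3 = l3$b, Wo = lo$W, bo = lo$b)
  })
  structure(list(params = params, widths = widths, omega0 = omega0,
                 seed = as.integer(seed)),
            class = "inr_template")
}

#' Total parameter count of a template
#' @param template an [init_template()]
#' @export
template_n_params <- function(template) {
  sum(vapply(flatten_params(template$params), length, numeric(1)))
}

#' Identity modulation (all scales and shifts equal 1)
#'
#' With all-ones coefficients the modulated forward pass reproduces the
#' plain SIREN exactly.
#'
#' @param widths template widths
#' @return object of class `modulation`: `gamma` and `beta`, each a list of
#'   three vectors matching the hidden widths
#' @export
modulation_identity <- function(widths = c(3L, 256L, 256L, 256L, 3L)) {
  hw <- c(widths[3], widths[4], widths[4])
  structure(list(gamma = lapply(hw, function(n) rep(1, n)),
                 beta = lapply(hw, function(n) rep(1, n))),
            class = "modulation")
}

#' Modulated SIREN forward pass
#'
#' `F0 = sin(omega0 * (v Wi + bi))`; each hidden layer `l` applies
#' `F_l = sin(gamma_l * (F_{l-1} W_l) + beta_l * b_l)` — the shift
#' coefficient multiplies the layer bias — and the output layer is affine
#' with no activation. Displacements are in full-resolution voxel units.
#'
#' @param template an [init_template()]
#' @param modulation a `modulation` object (see [modulation_identity()])
#' @param coords N x 3 matrix of normalised coordinates
#' @return N x 3 matrix of displacement samples
#' @export
siren_forward <- function(template, modulation, coords) {
  p <- template$params
  stopifnot(ncol(coords) == 3L,
            length(modulation$gamma[[1]]) == ncol(p$W1))
  modrow <- function(F_, W, b, g, be) {
    pre <- sweep(F_ %*% W, 2L, g, "*")
    sin(sweep(pre, 2L, be * b, "+"))
  }
  F0 <- sin(template$omega0 * sweep(coords %*% p$Wi, 2L, p$bi, "+"))
  F1 <- modrow(F0, p$W1, p$b1, modulation$gamma[[1]], modulation$beta[[1]])
  F2 <- modrow(F1, p$W2, p$b2, modulation$gamma[[2]], modulation$beta[[2]])
  F3 <- modrow(F2, p$W3, p$b3, modulation$gamma[[3]], modulation$beta[[3]])
  sweep(F3 %*% p$Wo, 2L, p$bo, "+")
}

# nested list of arrays -> matching nested list of parameter nodes
params_to_nodes <- function(tp, params) {
  lapply(params, function(p) if (is.list(p)) params_to_nodes(tp, p) else ag_param(tp, p))
}

# matching nested list of gradients (zeros where a parameter was unused)
grads_from_nodes <- function(nodes) {
  lapply(nodes, function(n) if (is.list(n)) grads_from_nodes(n) else ag_grad(n))
}

values_from_nodes <- function(nodes) {
  lapply(nodes, function(n) if (is.list(n)) values_from_nodes(n) else ag_value(n))
}

# Modulated SIREN forward pass inside an autodiff graph.
# `pn` are template parameter nodes (params_to_nodes), `mod` either a plain
# modulation object (constants) or a list with gamma/beta nodes (row vectors),
# `coords` a constant matrix. Returns an (N x 3) node.
ag_siren_forward <- function(tp, pn, mod, coords, omega0) {
  as_vecnode <- function(x) {
    nd <- if (is_ag_node(x)) x else ag_const(tp, x)
    if (!is.null(dim(nd$value))) nd <- ag_reshape(nd, NULL)
    nd
  }
  layer <- function(F_, W, b, g, be) {
    pre <- ag_mul(ag_matmul(F_, W), as_vecnode(g))   # row-broadcast scale
    bmod <- ag_mul(as_vecnode(be), b)                # shift multiplies the bias
    ag_sin(ag_add(pre, bmod))
  }
  F0 <- ag_sin(ag_scale(ag_add(ag_matmul(ag_const(tp, coords), pn$Wi), pn$bi), omega0))
  F1 <- layer(F0, pn$W1, pn$b1, mod$gamma[[1]], mod$beta[[1]])
  F2 <- layer(F1, pn$W2, pn$b2, mod$gamma[[2]], mod$beta[[2]])
  F3 <- layer(F2, pn$W3, pn$b3, mod$gamma[[3]], mod$beta[[3]])
  ag_add(ag_matmul(F3, pn$Wo), pn$bo)
}
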