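#' @title Tape-based reverse-mode automatic differentiation
#'
#' @description
#' A minimal reverse-mode autodiff engine over dense numeric arrays. A tape
#' records nodes in forward execution order (which is a valid topological
#' order of the computation DAG), and `ag_backward()` sweeps the tape in
#' reverse, accumulating vector-Jacobian products into each node's `grad`.
#' The engine supports exactly the operations the registration networks need:
#' dense affine maps, sine/ReLU nonlinearities, broadcasted scale/shift,
#' row-wise softmax (attention), gather/scatter (convolution via im2col,
#' trilinear upsampling, finite differences), and a custom trilinear warp.
#'
#' Values are plain numeric vectors/matrices/arrays; gradients always have
#' the shape of the value. Nodes are environments; `ag_value()` and
#' `ag_grad()` read them back.
#'
#' @name autograd
#' @keywords internal
NULL

#' Create a fresh autodiff tape
#' @return an environment holding the node list
#' @keywords internal
ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_push <- function(tp, nd) {
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd$idx <- n
  nd
}

ag_new_node <- function(tp, value, parents = list(), vjps = list(), req = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjps <- vjps
  nd$tape <- tp
  if (is.null(req)) {
    req <- FALSE
    for (p in parents) if (p$req) { req <- TRUE; break }
  }
  nd$req <- req
  ag_push(tp, nd)
}

#' Constant (no gradient) and parameter (gradient-tracked) leaves
#' @keywords internal
ag_const <- function(tp, x) ag_new_node(tp, x, req = FALSE)

#' @rdname ag_const
#' @keywords internal
ag_param <- function(tp, x) ag_new_node(tp, x, req = TRUE)

is_ag_node <- function(x) is.environment(x) && !is.null(x$tape)

as_ag <- function(tp, x) if (is_ag_node(x)) x else ag_const(tp, x)

#' Read a node's value / accumulated gradient
#' @keywords internal
ag_value <- function(nd) nd$value

#' @rdname ag_value
#' @keywords internal
ag_grad <- function(nd) {
  if (is.null(nd$grad)) array(0, dim = dim(nd$value) %||% length(nd$value)) else nd$grad
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse sweep: accumulate gradients of `loss` w.r.t. every tracked leaf
#'
#' `loss` must be a scalar node on the tape. Gradients accumulate into
#' `$grad` of every node with `req = TRUE` on the path.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  tp <- loss$tape
  loss$grad <- 1
  for (i in seq.int(loss$idx, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || length(nd$vjps) == 0L) next
    g <- nd$grad
    for (k in seq_along(nd$vjps)) {
      p <- nd$parents[[k]]
      if (!p$req) next
      contrib <- nd$vjps[[k]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(loss)
}

# --- shape helpers -----------------------------------------------------------

# broadcast class of b relative to a: "same", "row" (b is a length-ncol(a)
# vector recycled over rows of matrix a), or "scalar"
ag_bclass <- function(a, b) {
  la <- length(a); lb <- length(b)
  # 1-d dim attributes (as left by array arithmetic) count as plain vectors
  da <- dim(a); if (length(da) < 2L) da <- NULL
  db <- dim(b); if (length(db) < 2L) db <- NULL
  if (lb == 1L) return("scalar")
  if (la == lb && identical(da, db)) return("same")
  if (!is.null(da) && length(da) == 2L && lb == ncol(a) && is.null(db)) {
    return("row")
  }
  stop("incompatible shapes in autograd broadcast")
}

# --- arithmetic --------------------------------------------------------------

#' Elementwise add with limited broadcasting (same shape, row vector, scalar)
#' @keywords internal
ag_add <- function(a, b) {
  tp <- a$tape; b <- as_ag(tp, b)
  bc <- ag_bclass(a$value, b$value)
  val <- switch(bc,
    same   = a$value + b$value,
    row    = sweep(a$value, 2L, b$value, "+"),
    scalar = a$value + as.numeric(b$value))
  ag_new_node(tp, val, list(a, b), list(
    function(g) g,
    switch(bc,
      same   = function(g) g,
      row    = function(g) colSums(g),
      scalar = function(g) sum(g))
  ))
}

#' @rdname ag_add
#' @keywords internal
ag_sub <- function(a, b) {
  tp <- a$tape; b <- as_ag(tp, b)
  bc <- ag_bclass(a$value, b$value)
  val <- switch(bc,
    same   = a$value - b$value,
    row    = sweep(a$value, 2L, b$value, "-"),
    scalar = a$value - as.numeric(b$value))
  ag_new_node(tp, val, list(a, b), list(
    function(g) g,
    switch(bc,
      same   = function(g) -g,
      row    = function(g) -colSums(g),
      scalar = function(g) -sum(g))
  ))
}

#' Elementwise multiply with the same broadcasting rules as [ag_add()]
#' @keywords internal
ag_mul <- function(a, b) {
  tp <- a$tape; b <- as_ag(tp, b)
  bc <- ag_bclass(a$value, b$value)
  av <- a$value; bv <- b$value
  val <- switch(bc,
    same   = av * bv,
    row    = sweep(av, 2L, bv, "*"),
    scalar = av * as.numeric(bv))
  ag_new_node(tp, val, list(a, b), list(
    switch(bc,
      same   = function(g) g * bv,
      row    = function(g) sweep(g, 2L, bv, "*"),
      scalar = function(g) g * as.numeric(bv)),
    switch(bc,
      same   = function(g) g * av,
      row    = function(g) colSums(g * av),
      scalar = function(g) sum(g * av))
  ))
}

#' Multiply by a fixed scalar
#' @keywords internal
ag_scale <- function(a, s) {
  ag_new_node(a$tape, a$value * s, list(a), list(function(g) g * s))
}

#' Matrix product; either factor may be a constant matrix
#' @keywords internal
ag_matmul <- function(a, b) {
  tp <- if (is_ag_node(a)) a$tape else b$tape
  a <- as_ag(tp, a); b <- as_ag(tp, b)
  av <- a$value; bv <- b$value
  ag_new_node(tp, av %*% bv, list(a, b), list(
    function(g) g %*% t(bv),
    function(g) crossprod(av, g)
  ))
}

# --- nonlinearities ----------------------------------------------------------

#' @keywords internal
ag_sin <- function(a) {
  av <- a$value
  ag_new_node(a$tape, sin(av), list(a), list(function(g) g * cos(av)))
}

#' @keywords internal
ag_relu <- function(a) {
  av <- a$value
  mask <- av > 0
  ag_new_node(a$tape, av * mask, list(a), list(function(g) g * mask))
}

#' @keywords internal
ag_abs <- function(a) {
  av <- a$value
  ag_new_node(a$tape, abs(av), list(a), list(function(g) g * sign(av)))
}

#' Elementwise power with fixed exponent
#' @keywords internal
ag_pow <- function(a, p) {
  av <- a$value
  ag_new_node(a$tape, av^p, list(a), list(function(g) g * p * av^(p - 1)))
}

#' Row-wise softmax (used by attention)
#' @keywords internal
ag_softmax_rows <- function(a) {
  av <- a$value
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  y <- e / rowSums(e)
  ag_new_node(a$tape, y, list(a), list(function(g) {
    y * (g - rowSums(g * y))
  }))
}

# --- reductions --------------------------------------------------------------

#' @keywords internal
ag_sum <- function(a) {
  dm <- dim(a$value) %||% length(a$value)
  ag_new_node(a$tape, sum(a$value), list(a), list(function(g) array(g, dim = dm)))
}

#' @keywords internal
ag_mean <- function(a) {
  n <- length(a$value)
  dm <- dim(a$value) %||% n
  ag_new_node(a$tape, mean(a$value), list(a), list(function(g) array(g / n, dim = dm)))
}

#' Row sums of a matrix, returned as a column matrix
#' @keywords internal
ag_rowsums <- function(a) {
  nc <- ncol(a$value)
  ag_new_node(a$tape, matrix(rowSums(a$value), ncol = 1L), list(a),
              list(function(g) matrix(g, nrow = nrow(a$value), ncol = nc)))
}

# --- structure ops -----------------------------------------------------------

#' @keywords internal
ag_reshape <- function(a, dm) {
  old <- dim(a$value) %||% length(a$value)
  v <- a$value
  dim(v) <- dm
  ag_new_node(a$tape, v, list(a), list(function(g) { dim(g) <- old; g }))
}

#' @keywords internal
ag_t <- function(a) {
  ag_new_node(a$tape, t(a$value), list(a), list(function(g) t(g)))
}

#' Column-bind matrices
#' @keywords internal
ag_cbind <- function(...) {
  args <- list(...)
  tp <- args[[1L]]$tape
  vals <- lapply(args, ag_value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  vjps <- lapply(seq_along(args), function(k) {
    s <- starts[k]; e <- ends[k]
    function(g) g[, s:e, drop = FALSE]
  })
  ag_new_node(tp, do.call(cbind, vals), args, vjps)
}

#' Select columns of a matrix
#' @keywords internal
ag_cols <- function(a, j) {
  nc <- ncol(a$value)
  ag_new_node(a$tape, a$value[, j, drop = FALSE], list(a), list(function(g) {
    out <- matrix(0, nrow(a$value), nc)
    out[, j] <- g
    out
  }))
}

#' Gather with optional zero padding
#'
#' `idx` is an integer array of 1-based indices into `as.vector(a)`; entries
#' equal to 0 read a zero (used for zero-padded convolution). The output has
#' the shape of `idx`. The backward pass scatter-adds.
#' @keywords internal
ag_gather <- function(a, idx) {
  av <- a$value
  xx <- c(0, as.vector(av))
  val <- array(xx[as.vector(idx) + 1L], dim = dim(idx) %||% length(idx))
  dma <- dim(av) %||% length(av)
  grp <- as.vector(idx)
  ag_new_node(a$tape, val, list(a), list(function(g) {
    rs <- rowsum(as.vector(g), grp)
    ids <- as.integer(rownames(rs))
    keep <- ids > 0L
    out <- array(0, dim = dma)
    out[ids[keep]] <- rs[keep]
    out
  }))
}
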