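#' Adam optimiser state for a named list of parameter arrays
#'
#' Parameters live in plain named (possibly nested) lists of numeric arrays;
#' each training step rebuilds the autodiff graph from these arrays, reads
#' gradients back, and calls [adam_step()].
#'
#' @param params named list (possibly nested) of numeric arrays
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser
#' @return an opaque optimiser state list
#' @keywords internal
adam_init <- function(params, lr = 1e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  flat <- flatten_params(params)
  list(
    m = lapply(flat, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(flat, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps
  )
}

#' One Adam update
#' @param params named list of arrays (same structure as at `adam_init`)
#' @param grads matching list of gradients
#' @param state optimiser state from [adam_init()]
#' @return list(params, state)
#' @keywords internal
adam_step <- function(params, grads, state) {
  skel <- params
  p <- flatten_params(params)
  g <- flatten_params(grads)
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (k in seq_along(p)) {
    gi <- g[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * gi
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * gi * gi
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    p[[k]] <- p[[k]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = unflatten_params(p, skel), state = state)
}

# flatten a nested named list of arrays into a flat named list (stable order)
flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- paste0(prefix, nm)
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], paste0(key, ".")))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, skel, prefix = "") {
  for (nm in names(skel)) {
    key <- paste0(prefix, nm)
    if (is.list(skel[[nm]])) {
      skel[[nm]] <- unflatten_params(flat, skel[[nm]], paste0(key, "."))
    } else {
      skel[[nm]] <- flat[[key]]
    }
  }
  skel
}

#' Derive a per-stage seed from a global seed
#'
#' A single run seed fans out to per-stage seeds through a deterministic
#' integer hash of the stage label, so each pipeline stage is independently
#' reproducible. Results stay below 2^31.
#'
#' @param seed integer global seed
#' @param label character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147482951
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147482951 + 1)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
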