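# Shared fixtures, memoised for the duration of a test run. Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a tiny single-subject cohort on an 8x8x4 grid with gentle motion
tiny_subject <- function() {
  fixture("tiny_subject", function() {
    generate_cohort(1, default_phantom_spec(c(8, 8, 4)),
                    motion = motion_model(c(0.5, 0.3, 1), 4, 3),
                    seed = 3L)[[1L]]
  })
}

# a tiny registration case and matching config (3 spokes, 16 samples)
tiny_cfg <- function() {
  meta_config("desk", widths = c(3L, 8L, 8L, 8L, 3L), d_token = 8L,
              patch = 4L, n_spokes = 3L, samples_per_spoke = 16L,
              prior_channels = 4L, seed = 1L)
}

tiny_case <- function() {
  fixture("tiny_case", function() make_case(tiny_subject(), 2L, tiny_cfg(), seed = 5L))
}

# brute-force NUDFT of one slice (independent double-loop oracle)
brute_nudft_slice <- function(slice, coords) {
  H <- nrow(slice); W <- ncol(slice)
  cx <- floor(H / 2); cy <- floor(W / 2)
  out <- complex(length(coords[, 1]))
  for (s in seq_len(nrow(coords))) {
    acc <- 0i
    for (m in seq_len(H)) for (n in seq_len(W)) {
      acc <- acc + slice[m, n] *
        exp(-1i * (coords[s, 1] * (m - 1 - cx) + coords[s, 2] * (n - 1 - cy)))
    }
    out[s] <- acc
  }
  out
}

# central finite difference of f at params[[name]][i]
fd_grad <- function(f, params, name, i, eps = 1e-5) {
  p <- params
  p[[name]][i] <- p[[name]][i] + eps
  fp <- f(p)
  p[[name]][i] <- p[[name]][i] - 2 * eps
  fm <- f(p)
  (fp - fm) / (2 * eps)
}
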