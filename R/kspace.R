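#' Complex-valued image volume
#'
#' A 3D complex array (real + imaginary parts) on a voxel grid with physical
#' spacing. Axial slices are taken along the third dimension; in-plane radial
#' k-space sampling acts on dimensions 1 and 2.
#'
#' @param data complex (or numeric, promoted) 3D array
#' @param spacing_mm positive length-3 voxel spacing in mm
#' @return an object of class `complex_volume`
#' @export
complex_volume <- function(data, spacing_mm = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L, length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (!is.complex(data)) data <- data + 0i
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)),
            class = "complex_volume")
}

#' @export
print.complex_volume <- function(x, ...) {
  cat("<complex_volume> ", paste(dim(x$data), collapse = "x"),
      " spacing ", paste(x$spacing_mm, collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Magnitude image of a complex volume
#' @param vol a [complex_volume()]
#' @return numeric 3D array
#' @export
magnitude <- function(vol) Mod(vol$data)

# golden angle as printed: 111.25 degrees
GOLDEN_ANGLE_RAD <- 111.25 * pi / 180

#' Golden-angle radial trajectory
#'
#' Generates `n_spokes` diameter spokes through the k-space centre, each
#' rotated from the previous by the golden angle (111.25 deg). Each spoke
#' carries `samples_per_spoke` uniformly spaced samples spanning the full
#' diameter, radii `linspace(-pi, pi)` in radians/voxel with the duplicate
#' `+pi` endpoint excluded by default (`include_endpoint = TRUE` keeps it).
#'
#' @param n_spokes number of spokes (>= 1)
#' @param samples_per_spoke samples per spoke (>= 2), 256 at acquisition scale
#' @param theta0_rad initial azimuthal angle (radians)
#' @param seed_for_theta0 optional seed; if given, `theta0_rad` is drawn
#'   uniformly from `[0, 2*pi)`, emulating on-the-fly resampling of the
#'   initial angle per target volume
#' @param include_endpoint keep the `+pi` edge sample (default drops it)
#' @return an object of class `radial_trajectory` with fields `angles_rad`,
#'   `radii`, and the per-sample coordinate matrix `sample_coords` (spoke-major,
#'   columns kx, ky, each in `[-pi, pi]`)
#' @export
golden_angle_trajectory <- function(n_spokes, samples_per_spoke = 256L,
                                    theta0_rad = 0, seed_for_theta0 = NULL,
                                    include_endpoint = FALSE) {
  stopifnot(n_spokes >= 1L, samples_per_spoke >= 2L)
  if (!is.null(seed_for_theta0)) {
    theta0_rad <- with_seed(seed_for_theta0, stats::runif(1, 0, 2 * pi))
  }
  angles <- (theta0_rad + (seq_len(n_spokes) - 1L) * GOLDEN_ANGLE_RAD) %% (2 * pi)
  S <- as.integer(samples_per_spoke)
  radii <- if (include_endpoint) {
    seq(-pi, pi, length.out = S)
  } else {
    -pi + (seq_len(S) - 1L) * (2 * pi / S)
  }
  kx <- as.vector(outer(radii, cos(angles)))
  ky <- as.vector(outer(radii, sin(angles)))
  structure(list(
    n_spokes = as.integer(n_spokes), samples_per_spoke = S,
    theta0_rad = theta0_rad, angles_rad = angles, radii = radii,
    sample_coords = cbind(kx = kx, ky = ky),
    include_endpoint = include_endpoint
  ), class = "radial_trajectory")
}

#' Non-Cartesian k-space samples bound to a radial trajectory
#'
#' @param values complex matrix (`n_samples_per_slice` x `n_slices`)
#' @param trajectory a [golden_angle_trajectory()]
#' @param shape grid shape `(H, W, D)` the samples refer to
#' @return object of class `kspace_data`; total sample count is
#'   `n_spokes * samples_per_spoke * D`
#' @export
kspace_data <- function(values, trajectory, shape) {
  stopifnot(inherits(trajectory, "radial_trajectory"),
            nrow(values) == nrow(trajectory$sample_coords),
            ncol(values) == shape[3], all(is.finite(Mod(values))))
  structure(list(values = values, trajectory = trajectory,
                 shape = as.integer(shape)),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat("<kspace_data> ", x$trajectory$n_spokes, " spokes x ",
      x$trajectory$samples_per_spoke, " samples x ", x$shape[3], " slices\n",
      sep = "")
  invisible(x)
}

# cache of NUDFT system matrices keyed by (trajectory geometry, grid)
.nudft_cache <- new.env(parent = emptyenv())

nudft_key <- function(traj, H, W) {
  paste(format(c(traj$theta0_rad, traj$angles_rad), digits = 17), collapse = ",") |>
    paste(traj$samples_per_spoke, traj$include_endpoint, H, W, sep = "|")
}

#' NUDFT system matrix for one axial slice (cached)
#'
#' Row s, column v holds `exp(-i (kx_s (x_v - cx) + ky_s (y_v - cy)))` with the
#' zero-frequency phase reference at voxel index `floor(N/2)` (0-based) per
#' axis and voxels flattened column-major. Also returns the real/imaginary
#' parts used when the transform sits inside an autodiff graph.
#' @keywords internal
nudft_matrix <- function(traj, H, W) {
  key <- nudft_key(traj, H, W)
  hit <- .nudft_cache[[key]]
  if (!is.null(hit)) return(hit)
  px <- (seq_len(H) - 1L) - floor(H / 2)
  py <- (seq_len(W) - 1L) - floor(W / 2)
  vx <- rep(px, times = W)
  vy <- rep(py, each = H)
  phase <- outer(traj$sample_coords[, 1L], vx) + outer(traj$sample_coords[, 2L], vy)
  E <- exp(-1i * phase)
  ent <- list(E = E, Er = Re(E), Ei = Im(E))
  .nudft_cache[[key]] <- ent
  ent
}

#' Forward non-uniform discrete Fourier transform (slice-wise)
#'
#' Projects a complex volume onto the radial trajectory, applying the same 2D
#' sampling independently to every axial slice (stack-of-stars with a shared
#' in-plane trajectory). Exact direct sum; no gridding approximation.
#'
#' @param vol a [complex_volume()]
#' @param traj a [golden_angle_trajectory()]
#' @return a [kspace_data()]
#' @export
nudft_forward <- function(vol, traj) {
  d <- dim(vol$data)
  E <- nudft_matrix(traj, d[1], d[2])$E
  X <- matrix(vol$data, d[1] * d[2], d[3])
  kspace_data(E %*% X, traj, d)
}

#' Adjoint non-uniform discrete Fourier transform (slice-wise)
#'
#' Conjugate-transposed sum of [nudft_forward()], normalised by the per-slice
#' sample count so reconstructions stay on the image intensity scale. This is
#' the operator that produces the artifact-bearing undersampled images.
#'
#' @param k a [kspace_data()]
#' @param shape grid shape `(H, W, D)`; defaults to the shape stored in `k`
#' @param spacing_mm voxel spacing for the reconstructed volume
#' @param normalize divide by the per-slice sample count (default TRUE);
#'   `FALSE` gives the bare adjoint used by the adjointness identity
#' @param density_weights `"none"` (default; the plain adjoint that produces
#'   the artifact-bearing model inputs) or `"ramp"` (radial `|r|` sample
#'   weighting, under which reconstruction quality improves with spoke count;
#'   used for convergence checks, not in the registration pipeline)
#' @return a [complex_volume()]
#' @export
nudft_adjoint <- function(k, shape = k$shape, spacing_mm = c(1, 1, 1),
                          normalize = TRUE,
                          density_weights = c("none", "ramp")) {
  stopifnot(identical(as.integer(shape), k$shape))
  density_weights <- match.arg(density_weights)
  E <- nudft_matrix(k$trajectory, shape[1], shape[2])$E
  vals <- k$values
  if (density_weights == "ramp") {
    r <- sqrt(rowSums(k$trajectory$sample_coords^2))
    w <- pmax(r, min(r[r > 0]) / 2)
    w <- w / mean(w)
    vals <- vals * w
  }
  V <- crossprod(Conj(E), vals)
  if (normalize) V <- V / nrow(vals)
  complex_volume(array(V, shape), spacing_mm)
}

#' Radial acceleration factor
#'
#' Ratio of the spoke count required by the radial Nyquist criterion
#' (`pi/2 * matrix_size`) to the number of acquired spokes.
#'
#' @param matrix_size in-plane matrix size (e.g. 256)
#' @param n_spokes acquired spokes
#' @param rounded return the rounded integer view
#' @return acceleration factor (real, or integer when `rounded = TRUE`)
#' @export
acceleration_factor <- function(matrix_size, n_spokes, rounded = FALSE) {
  stopifnot(matrix_size >= 1, n_spokes >= 1)
  af <- (pi / 2 * matrix_size) / n_spokes
  if (rounded) round(af) else af
}

#' Preprocess a registration case into the six-channel model input
#'
#' Projects the fully sampled source `S_FI` through the target's radial
#' trajectory (`S_UK`), reconstructs both k-space data sets by the adjoint
#' transform (`S_UI`, `T_UI`), and stacks real/imaginary planes of
#' `(S_FI, S_UI, T_UI)` — in that order — into the six-plane array `X`.
#'
#' @param S_FI fully sampled complex source volume
#' @param T_UK undersampled target k-space data ([kspace_data()])
#' @return list with `X` (`H x W x D x 6`), `S_UI`, `T_UI`, `S_UK`
#' @export
preprocess_case <- function(S_FI, T_UK) {
  d <- dim(S_FI$data)
  if (!identical(as.integer(d), T_UK$shape)) {
    stop("source volume shape does not match the target k-space grid")
  }
  S_UK <- nudft_forward(S_FI, T_UK$trajectory)
  S_UI <- nudft_adjoint(S_UK, spacing_mm = S_FI$spacing_mm)
  T_UI <- nudft_adjoint(T_UK, spacing_mm = S_FI$spacing_mm)
  X <- array(0, c(d, 6L))
  X[, , , 1] <- Re(S_FI$data); X[, , , 2] <- Im(S_FI$data)
  X[, , , 3] <- Re(S_UI$data); X[, , , 4] <- Im(S_UI$data)
  X[, , , 5] <- Re(T_UI$data); X[, , , 6] <- Im(T_UI$data)
  list(X = X, S_UI = S_UI, T_UI = T_UI, S_UK = S_UK)
}
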