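#' Phantom scene specification
#'
#' Describes an ellipsoid scene used to build magnitude phantoms: a uniform
#' background plus a list of ellipsoids painted in order (later structures
#' overwrite earlier ones where they overlap). A light Gaussian smoothing
#' emulates soft-tissue boundaries and keeps the scene approximately
#' band-limited, which matters when it is sampled with a handful of radial
#' spokes.
#'
#' @param grid_shape integer triple `(H, W, D)`, at least `(8, 8, 4)`
#' @param spacing_mm positive voxel spacing triple
#' @param structures list of ellipsoids, each
#'   `list(name=, center=, semi_axes=, intensity=)` with centre/semi-axes in
#'   voxel coordinates and intensity in `[0, 1]`
#' @param background_intensity real in `[0, 1)`
#' @param smooth_sigma_vox Gaussian smoothing applied to the painted
#'   magnitude (voxels; 0 disables)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid_shape, spacing_mm = c(1, 1, 1),
                         structures = list(), background_intensity = 0.1,
                         smooth_sigma_vox = 0.8) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= c(8L, 8L, 4L)),
            all(spacing_mm > 0),
            background_intensity >= 0, background_intensity < 1)
  for (s in structures) {
    stopifnot(all(s$semi_axes > 0), s$intensity >= 0, s$intensity <= 1,
              length(s$center) == 3L, length(s$semi_axes) == 3L)
  }
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 structures = structures,
                 background_intensity = background_intensity,
                 smooth_sigma_vox = smooth_sigma_vox),
            class = "phantom_spec")
}

#' A default abdomen-like ellipsoid scene for a given grid
#'
#' One large body ellipsoid, one organ, and one small bright lesion whose
#' mask is the usual target for contour metrics.
#'
#' @param grid_shape integer triple
#' @param spacing_mm voxel spacing
#' @return a [phantom_spec()]
#' @export
default_phantom_spec <- function(grid_shape, spacing_mm = c(1, 1, 1)) {
  g <- as.numeric(grid_shape)
  ctr <- (g + 1) / 2
  fit <- function(center, semi) {
    semi <- pmin(semi, (g - 1.4) / 2)
    center <- pmin(pmax(center, 1 + semi + 0.05), g - semi - 0.05)
    list(center = center, semi = semi)
  }
  body <- fit(ctr, 0.40 * g)
  organ <- fit(ctr + c(0.10, -0.08, 0) * g, c(0.20, 0.18, 0.26) * g)
  lesion <- fit(ctr + c(0.13, -0.10, 0.04) * g,
                pmax(c(0.08, 0.07, 0.11) * g, 1.2))
  phantom_spec(
    grid_shape, spacing_mm,
    structures = list(
      list(name = "body", center = body$center, semi_axes = body$semi,
           intensity = 0.45),
      list(name = "organ", center = organ$center, semi_axes = organ$semi,
           intensity = 0.8),
      list(name = "lesion", center = lesion$center, semi_axes = lesion$semi,
           intensity = 1.0)
    ),
    background_intensity = 0.05
  )
}

# separable Gaussian smoothing with replicate boundary
gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  d <- dim(arr)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    out <- array(0, d)
    idx_base <- seq_len(d[ax])
    for (k in (-r):r) {
      idx <- pmin(pmax(idx_base + k, 1L), d[ax])
      shifted <- switch(ax,
                        arr[idx, , , drop = FALSE],
                        arr[, idx, , drop = FALSE],
                        arr[, , idx, drop = FALSE])
      out <- out + w[k + r + 1L] * shifted
    }
    arr <- out
  }
  arr
}

#' Generate a magnitude phantom and its structure masks
#'
#' Paints the ellipsoids of `spec` over the background and applies the
#' configured smoothing to the magnitude (masks stay binary and unsmoothed).
#' Deterministic for fixed `(spec, seed)`; the seed matters only when the
#' spec was produced by a randomised jitter (see [generate_cohort()]).
#'
#' @param spec a [phantom_spec()]
#' @param seed integer
#' @return list with `magnitude` (values in `[0, 1]`) and `masks` (named list
#'   of 0/1 arrays, one per structure)
#' @export
generate_phantom <- function(spec, seed = 1L) {
  shp <- spec$grid_shape
  g <- grid_positions(shp)
  mag <- array(spec$background_intensity, shp)
  masks <- list()
  for (s in spec$structures) {
    if (any(s$center - s$semi_axes < 1) || any(s$center + s$semi_axes > shp)) {
      stop("structure '", s$name %||% "?", "' extends outside the grid")
    }
    inside <- ((g$x - s$center[1]) / s$semi_axes[1])^2 +
      ((g$y - s$center[2]) / s$semi_axes[2])^2 +
      ((g$z - s$center[3]) / s$semi_axes[3])^2 <= 1
    mag[inside] <- s$intensity
    masks[[s$name %||% paste0("structure", length(masks) + 1L)]] <-
      array(as.integer(inside), shp)
  }
  mag <- gauss_smooth3(mag, spec$smooth_sigma_vox)
  mag[mag < 0] <- 0; mag[mag > 1] <- 1
  list(magnitude = mag, masks = masks)
}

#' Sinusoidal phase map specification
#'
#' @param n_freqs_per_axis sinusoid count per Cartesian axis (default 4)
#' @param freq_range_per_mm spatial-frequency interval in 1/mm; the default
#'   `[1.25e-3, 2.50e-3]` corresponds to wavelengths of 800 mm down to 400 mm
#' @param amplitude amplitude of each sinusoidal component (radians)
#' @param fixed_phase_shift if non-NULL, use this phase shift for every
#'   component instead of drawing uniform shifts (used by closed-form checks)
#' @param seed integer
#' @return object of class `phase_map_spec`
#' @export
phase_map_spec <- function(n_freqs_per_axis = 4L,
                           freq_range_per_mm = c(1.25e-3, 2.50e-3),
                           amplitude = 1, fixed_phase_shift = NULL, seed = 1L) {
  stopifnot(n_freqs_per_axis >= 1L, all(freq_range_per_mm > 0),
            freq_range_per_mm[1] <= freq_range_per_mm[2])
  structure(list(n_freqs_per_axis = as.integer(n_freqs_per_axis),
                 freq_range_per_mm = as.numeric(freq_range_per_mm),
                 amplitude = amplitude, fixed_phase_shift = fixed_phase_shift,
                 seed = as.integer(seed)),
            class = "phase_map_spec")
}

#' Build a 3D sinusoidal phase map
#'
#' Sum over the three Cartesian axes of `n_freqs_per_axis` sinusoids with
#' frequencies drawn uniformly from `freq_range_per_mm` and independent
#' uniform phase shifts; the argument of each sinusoid is
#' `2*pi*f*(physical axis coordinate in mm) + shift`. Deterministic per
#' `spec$seed`.
#'
#' @param shape grid shape `(H, W, D)`
#' @param spacing_mm positive voxel spacing
#' @param spec a [phase_map_spec()]
#' @return numeric 3D phase array (radians)
#' @export
make_phase_map <- function(shape, spacing_mm, spec) {
  stopifnot(all(spacing_mm > 0), length(shape) == 3L)
  shape <- as.integer(shape)
  draws <- with_seed(spec$seed, {
    f <- matrix(stats::runif(3 * spec$n_freqs_per_axis,
                             spec$freq_range_per_mm[1], spec$freq_range_per_mm[2]),
                nrow = 3)
    ph <- matrix(stats::runif(3 * spec$n_freqs_per_axis, 0, 2 * pi), nrow = 3)
    list(f = f, ph = ph)
  })
  if (!is.null(spec$fixed_phase_shift)) draws$ph[] <- spec$fixed_phase_shift
  axis_profile <- function(a) {
    coord <- (seq_len(shape[a]) - 1) * spacing_mm[a]
    prof <- numeric(shape[a])
    for (k in seq_len(spec$n_freqs_per_axis)) {
      prof <- prof + spec$amplitude *
        sin(2 * pi * draws$f[a, k] * coord + draws$ph[a, k])
    }
    prof
  }
  px <- axis_profile(1); py <- axis_profile(2); pz <- axis_profile(3)
  g <- grid_positions(shape)
  array(px[g$x] + py[g$y] + pz[g$z], shape)
}

#' Smooth respiratory-like motion model
#'
#' Analytic surrogate for inter-bin breathing deformation: a separable
#' Gaussian spatial envelope (peak 1 at the grid centre, length scale
#' `spatial_scale` voxels) times a sinusoidal bin factor `sin(pi * f)`,
#' scaled per axis by `amplitude_vox`. Displacement magnitude is therefore
#' bounded by `amplitude_vox` and the field is smooth by construction, with
#' exactly known ground truth.
#'
#' @param amplitude_vox peak displacement per axis (voxels); make the slice
#'   axis dominant to mimic respiration
#' @param spatial_scale envelope length scale (voxels)
#' @param n_bins number of motion bins in a cycle (>= 2 for any motion)
#' @return object of class `motion_model`
#' @export
motion_model <- function(amplitude_vox = c(1, 0.5, 2), spatial_scale = 8,
                         n_bins = 4L) {
  stopifnot(length(amplitude_vox) == 3L, spatial_scale > 0, n_bins >= 1L)
  structure(list(amplitude_vox = as.numeric(amplitude_vox),
                 spatial_scale = spatial_scale, n_bins = as.integer(n_bins)),
            class = "motion_model")
}

#' Analytic ground-truth motion field for one bin
#'
#' @param shape grid shape
#' @param model a [motion_model()]
#' @param bin_fraction position in the motion cycle, in `[0, 1]`;
#'   `0` gives the identity (reference bin)
#' @param spacing_mm voxel spacing carried by the returned field
#' @return a [dvf()]
#' @export
analytic_motion_dvf <- function(shape, model, bin_fraction, spacing_mm = c(1, 1, 1)) {
  stopifnot(bin_fraction >= 0, bin_fraction <= 1)
  shape <- as.integer(shape)
  g <- grid_positions(shape)
  ctr <- (shape + 1) / 2
  env <- exp(-(((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2) /
                 (2 * model$spatial_scale^2)))
  tfac <- sin(pi * bin_fraction)
  out <- array(0, c(shape, 3L))
  for (j in 1:3) out[, , , j] <- array(model$amplitude_vox[j] * tfac * env, shape)
  dvf(out, spacing_mm)
}

#' Complex Gaussian noise specification
#' @param sd_range positive ordered interval the noise standard deviation is
#'   drawn from (default `[3.0e-3, 5.0e-3]` on images normalised to `[0, 1]`)
#' @param seed integer
#' @return object of class `noise_spec`
#' @export
noise_spec <- function(sd_range = c(3.0e-3, 5.0e-3), seed = 1L) {
  stopifnot(all(sd_range >= 0), sd_range[1] <= sd_range[2])
  structure(list(sd_range = as.numeric(sd_range), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add independent Gaussian noise to real and imaginary parts
#'
#' One standard deviation is drawn uniformly from `spec$sd_range`, then
#' zero-mean Gaussian noise with that sd is added separately to the real and
#' the imaginary plane. Deterministic per `spec$seed`.
#'
#' @param vol a [complex_volume()]
#' @param spec a [noise_spec()]
#' @return noisy [complex_volume()]
#' @export
add_complex_noise <- function(vol, spec) {
  stopifnot(all(is.finite(Mod(vol$data))))
  n <- length(vol$data)
  noisy <- with_seed(spec$seed, {
    sd <- stats::runif(1, spec$sd_range[1], spec$sd_range[2])
    if (sd == 0) vol$data
    else vol$data + complex(real = stats::rnorm(n, 0, sd),
                            imaginary = stats::rnorm(n, 0, sd))
  })
  complex_volume(array(noisy, dim(vol$data)), vol$spacing_mm)
}

# jitter an ellipsoid scene into a subject-specific variant, keeping every
# structure inside the grid
jitter_phantom_spec <- function(spec, center_vox = 1.5, axes_frac = 0.12,
                                intensity_sd = 0.04) {
  st <- spec$structures
  for (i in seq_along(st)) {
    ax <- st[[i]]$semi_axes * (1 + stats::runif(3, -axes_frac, axes_frac))
    ax <- pmax(pmin(ax, (spec$grid_shape - 1.4) / 2), 0.75)
    ctr <- st[[i]]$center + stats::runif(3, -center_vox, center_vox)
    ctr <- pmin(pmax(ctr, 1 + ax + 0.01), spec$grid_shape - ax - 0.01)
    inten <- min(max(st[[i]]$intensity + stats::rnorm(1, 0, intensity_sd), 0), 1)
    st[[i]]$semi_axes <- ax; st[[i]]$center <- ctr; st[[i]]$intensity <- inten
  }
  spec$structures <- st
  spec
}

#' Generate a synthetic cohort of motion-resolved complex phantoms
#'
#' Each subject is an independently jittered variant of `base_spec` with its
#' own motion amplitude, a sinusoidal phase map applied to the reference bin,
#' analytic ground-truth deformation fields per bin, structure masks
#' propagated by nearest-neighbour warping, and complex Gaussian noise added
#' per bin. Bin 0 is the reference (source) bin and its ground-truth field is
#' identically zero; the complex volume of bin `b` equals the bin-0 volume
#' warped by `dvfs[[b]]` before noise (phase and magnitude move together
#' because the complex image itself is warped).
#'
#' @param n_subjects number of subjects (>= 1)
#' @param base_spec a [phantom_spec()]; defaults per grid via
#'   [default_phantom_spec()]
#' @param motion a [motion_model()]
#' @param phase a [phase_map_spec()]
#' @param noise a [noise_spec()]
#' @param seed integer; all per-subject randomness derives from it
#' @param jitter logical, jitter the scene per subject (default TRUE)
#' @return list of subjects; each has `bins` (noisy complex volumes),
#'   `bins_clean` (pre-noise), `dvfs` (ground truth per bin), `masks0`
#'   (reference-bin masks), `masks_by_bin`, `spacing_mm`, `seed`
#' @export
generate_cohort <- function(n_subjects, base_spec, motion = motion_model(),
                            phase = phase_map_spec(), noise = noise_spec(),
                            seed = 1L, jitter = TRUE) {
  stopifnot(n_subjects >= 1L)
  lapply(seq_len(n_subjects), function(si) {
    sseed <- derive_seed(seed, paste0("subject", si))
    spec_s <- if (jitter) with_seed(sseed, jitter_phantom_spec(base_spec)) else base_spec
    amp_s <- if (jitter) {
      with_seed(sseed + 1L, motion$amplitude_vox * stats::runif(3, 0.7, 1.15))
    } else motion$amplitude_vox
    motion_s <- motion_model(amp_s, motion$spatial_scale, motion$n_bins)
    ph <- generate_phantom(spec_s, sseed)
    pmap <- make_phase_map(spec_s$grid_shape, spec_s$spacing_mm,
                           phase_map_spec(phase$n_freqs_per_axis,
                                          phase$freq_range_per_mm,
                                          phase$amplitude, phase$fixed_phase_shift,
                                          seed = derive_seed(sseed, "phase")))
    vol0 <- complex_volume(ph$magnitude * exp(1i * pmap), spec_s$spacing_mm)
    nb <- motion$n_bins
    bins <- bins_clean <- dvfs <- masks_by_bin <- vector("list", nb)
    for (b in seq_len(nb)) {
      frac <- (b - 1) / nb
      d_b <- analytic_motion_dvf(spec_s$grid_shape, motion_s, frac,
                                 spec_s$spacing_mm)
      vol_b <- if (b == 1L) vol0 else warp_complex(vol0, d_b)
      dvfs[[b]] <- d_b
      bins_clean[[b]] <- vol_b
      bins[[b]] <- add_complex_noise(
        vol_b, noise_spec(noise$sd_range, derive_seed(sseed, paste0("noise", b))))
      masks_by_bin[[b]] <- if (b == 1L) ph$masks else {
        lapply(ph$masks, warp_mask, d = d_b)
      }
    }
    list(bins = bins, bins_clean = bins_clean, dvfs = dvfs,
         masks0 = ph$masks, masks_by_bin = masks_by_bin,
         spacing_mm = spec_s$spacing_mm, grid_shape = spec_s$grid_shape,
         phantom_spec = spec_s, motion = motion_s, seed = sseed)
  })
}
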