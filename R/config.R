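#' Full run configuration
#'
#' One schema-validated list driving every pipeline stage. Unknown keys are
#' rejected; a resolved copy is stored with every run. A single global seed
#' fans out to per-stage seeds through [derive_seed()], so each stage is
#' independently reproducible.
#'
#' @param ... overrides of top-level sections or scalar fields
#' @return object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "runs/default",
    variant = "cmeta",
    grid_shape = c(16L, 16L, 8L),
    spacing_mm = c(1, 1, 1),
    n_subjects = 6L,
    n_bins = 4L,
    n_held_out = 1L,
    motion = list(amplitude_vox = c(1, 0.5, 2), spatial_scale = 6),
    phase = list(n_freqs_per_axis = 4L, freq_range_per_mm = c(1.25e-3, 2.50e-3),
                 amplitude = 1),
    noise = list(sd_range = c(3.0e-3, 5.0e-3)),
    prior = list(base_channels = 6L, epochs = 12L, lr = 1e-3),
    meta = list(profile = "desk"),
    export_nifti = FALSE
  )
  over <- list(...)
  # the meta section is open-ended; meta_config() validates its keys
  meta_over <- over$meta
  over$meta <- NULL
  cfg <- merge_config(cfg, over, "run_config")
  if (!is.null(meta_over)) cfg$meta <- utils::modifyList(cfg$meta, meta_over)
  structure(cfg, class = "run_config")
}

merge_config <- function(base, over, where) {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) {
    stop("unknown ", where, " keys: ", paste(unknown, collapse = ", "))
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(where, "$", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a run configuration from YAML
#' @param path YAML file; keys must match the [run_config()] schema
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Write the resolved configuration next to a run's outputs
#' @param cfg a [run_config()]
#' @param dir run directory
#' @export
save_run_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config_resolved.yaml"))
  invisible(file.path(dir, "config_resolved.yaml"))
}

# meta_config derived from a run_config (spoke settings travel via ...)
resolve_meta_config <- function(cfg, ...) {
  args <- cfg$meta
  profile <- args$profile %||% "desk"
  args$profile <- NULL
  args$variant <- cfg$variant
  args$seed <- cfg$seed
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(meta_config, c(list(profile = profile), args))
}
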