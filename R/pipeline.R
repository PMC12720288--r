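#' Simulate and persist a synthetic cohort
#'
#' Generates the cohort described by the configuration, stores it as a
#' checkpoint together with the resolved configuration and acquisition
#' metadata (spoke count and the corresponding acceleration factor at the
#' configured in-plane matrix size), and optionally exports NIfTI views.
#'
#' @param cfg a [run_config()]
#' @return list with `cohort_path` and `metadata`
#' @export
cmd_simulate <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  save_run_config(cfg, cfg$out_dir)
  mcfg <- resolve_meta_config(cfg)
  cohort <- generate_cohort(
    cfg$n_subjects,
    default_phantom_spec(cfg$grid_shape, cfg$spacing_mm),
    motion = motion_model(cfg$motion$amplitude_vox, cfg$motion$spatial_scale,
                          cfg$n_bins),
    phase = phase_map_spec(cfg$phase$n_freqs_per_axis,
                           cfg$phase$freq_range_per_mm, cfg$phase$amplitude,
                           seed = derive_seed(cfg$seed, "phase")),
    noise = noise_spec(cfg$noise$sd_range, derive_seed(cfg$seed, "noise")),
    seed = derive_seed(cfg$seed, "cohort")
  )
  metadata <- list(
    n_subjects = cfg$n_subjects, n_bins = cfg$n_bins,
    grid_shape = cfg$grid_shape, spacing_mm = cfg$spacing_mm,
    n_spokes = mcfg$n_spokes,
    acceleration_factor = acceleration_factor(cfg$grid_shape[1], mcfg$n_spokes),
    acceleration_factor_at_256 = acceleration_factor(256L, mcfg$n_spokes,
                                                     rounded = TRUE),
    seed = cfg$seed
  )
  path <- file.path(cfg$out_dir, "cohort.rds")
  save_checkpoint(cohort, path, meta = metadata)
  jsonlite::write_json(metadata, file.path(cfg$out_dir, "cohort_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$export_nifti)) {
    for (si in seq_along(cohort)) {
      write_subject_nifti(cohort[[si]],
                          file.path(cfg$out_dir, sprintf("subject%02d", si)))
    }
  }
  list(cohort_path = path, metadata = metadata)
}

#' Train the population prior on a stored cohort
#' @param cfg a [run_config()]
#' @param cohort optional in-memory cohort (loads the stored one when NULL)
#' @return list with `prior` and `prior_path`
#' @export
cmd_train_prior <- function(cfg = run_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- load_checkpoint(file.path(cfg$out_dir, "cohort.rds"))
  mcfg <- resolve_meta_config(cfg)
  train_idx <- seq_len(max(length(cohort) - cfg$n_held_out, 1L))
  net <- init_prior_net(cfg$prior$base_channels,
                        seed = derive_seed(cfg$seed, "prior_init"))
  net <- train_prior(net, cohort[train_idx], epochs = cfg$prior$epochs,
                     lr = cfg$prior$lr, n_spokes = mcfg$n_spokes,
                     samples_per_spoke = mcfg$samples_per_spoke,
                     seed = derive_seed(cfg$seed, "prior_train"))
  path <- file.path(cfg$out_dir, "prior.rds")
  save_checkpoint(net, path, meta = list(epochs = cfg$prior$epochs))
  for (i in seq_along(net$loss_history)) {
    log_jsonl(file.path(cfg$out_dir, "prior_loss.jsonl"),
              list(step = i, loss = net$loss_history[i]))
  }
  list(prior = net, prior_path = path)
}

#' Meta-train the template and modulator on a stored cohort
#' @param cfg a [run_config()]
#' @param cohort,prior optional in-memory objects
#' @return list with `template`, `modulator`, `history`, `paths`
#' @export
cmd_meta_train <- function(cfg = run_config(), cohort = NULL, prior = NULL) {
  if (is.null(cohort)) cohort <- load_checkpoint(file.path(cfg$out_dir, "cohort.rds"))
  mcfg <- resolve_meta_config(cfg)
  if (is.null(prior) && variant_uses_prior(mcfg$variant)) {
    prior <- load_checkpoint(file.path(cfg$out_dir, "prior.rds"))
  }
  train_idx <- seq_len(max(length(cohort) - cfg$n_held_out, 1L))
  template <- init_template(mcfg$widths, mcfg$omega0,
                            seed = derive_seed(cfg$seed, "template"))
  modulator <- init_modulator(variant_modulator_kind(mcfg$variant),
                              hidden_widths = mcfg$widths[c(3, 4, 4)],
                              d_token = mcfg$d_token, n_heads = mcfg$n_heads,
                              patch = mcfg$patch,
                              base_channels = mcfg$prior_channels,
                              seed = derive_seed(cfg$seed, "modulator"))
  tr <- meta_train(cohort[train_idx], template, modulator, prior, mcfg)
  tpath <- file.path(cfg$out_dir, "template.rds")
  mpath <- file.path(cfg$out_dir, "modulator.rds")
  save_checkpoint(tr$template, tpath, meta = list(variant = mcfg$variant))
  save_checkpoint(tr$modulator, mpath, meta = list(variant = mcfg$variant))
  for (i in seq_along(tr$history)) {
    log_jsonl(file.path(cfg$out_dir, "meta_loss.jsonl"),
              list(outer_iteration = i, mean_stepB_loss = tr$history[i]))
  }
  list(template = tr$template, modulator = tr$modulator, history = tr$history,
       paths = c(template = tpath, modulator = mpath))
}

#' Adapt to held-out subjects and evaluate
#' @param cfg a [run_config()]
#' @param cohort,prior,template,modulator optional in-memory objects
#' @return list of per-case results with metric reports
#' @export
cmd_adapt <- function(cfg = run_config(), cohort = NULL, prior = NULL,
                      template = NULL, modulator = NULL) {
  if (is.null(cohort)) cohort <- load_checkpoint(file.path(cfg$out_dir, "cohort.rds"))
  mcfg <- resolve_meta_config(cfg)
  needs_models <- !(mcfg$variant %in% c("ks_inr", "ks_iterative"))
  if (needs_models) {
    if (is.null(template)) template <- load_checkpoint(file.path(cfg$out_dir, "template.rds"))
    if (is.null(modulator)) modulator <- load_checkpoint(file.path(cfg$out_dir, "modulator.rds"))
  } else {
    if (is.null(template)) template <- init_template(mcfg$widths, mcfg$omega0,
                                                     seed = derive_seed(cfg$seed, "template"))
    if (is.null(modulator)) modulator <- init_modulator("token",
                                                        hidden_widths = mcfg$widths[c(3, 4, 4)],
                                                        d_token = mcfg$d_token,
                                                        patch = mcfg$patch,
                                                        seed = derive_seed(cfg$seed, "modulator"))
  }
  if (is.null(prior) && (variant_uses_prior(mcfg$variant) ||
                         variant_uses_embed(mcfg$variant))) {
    prior <- load_checkpoint(file.path(cfg$out_dir, "prior.rds"))
  }
  held <- seq.int(max(length(cohort) - cfg$n_held_out + 1L, 1L), length(cohort))
  out <- list()
  for (si in held) {
    subj <- cohort[[si]]
    for (b in seq.int(2L, length(subj$bins))) {
      case <- make_case(subj, b, mcfg,
                        seed = derive_seed(cfg$seed, sprintf("adapt%d_%d", si, b)))
      res <- adapt_case(template, modulator, prior, case, mcfg)
      rec <- c(list(subject = si, target_bin = b, variant = mcfg$variant),
               res$metrics)
      log_jsonl(file.path(cfg$out_dir, "adapt_metrics.jsonl"), rec)
      out[[length(out) + 1L]] <- c(list(case = case), res)
    }
  }
  out
}

#' Run the full pipeline: simulate, train prior, meta-train, adapt, evaluate
#'
#' Every stage derives its seed from the single configured global seed; any
#' stage failure aborts with a stage-tagged message.
#'
#' @param cfg a [run_config()]
#' @return list with `metrics` (one row per held-out case/bin), and the
#'   trained objects
#' @export
cmd_pipeline <- function(cfg = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  sim <- stage("simulate", cmd_simulate(cfg))
  cohort <- load_checkpoint(sim$cohort_path)
  mcfg <- resolve_meta_config(cfg)
  needs_prior <- variant_uses_prior(mcfg$variant) || variant_uses_embed(mcfg$variant)
  prior <- if (needs_prior) stage("train-prior", cmd_train_prior(cfg, cohort))$prior else NULL
  needs_meta <- !(mcfg$variant %in% c("ks_inr", "ks_iterative"))
  mt <- if (needs_meta) {
    stage("meta-train", cmd_meta_train(cfg, cohort, prior))
  } else list(template = NULL, modulator = NULL, history = numeric(0))
  res <- stage("adapt", cmd_adapt(cfg, cohort, prior, mt$template, mt$modulator))
  metrics <- do.call(rbind, lapply(res, function(r) {
    as.data.frame(r$metrics[c("ssim", "re_percent", "dice", "hd95_mm", "come_mm")])
  }))
  report <- list(metrics = metrics, results = res, template = mt$template,
                 modulator = mt$modulator, history = mt$history, config = cfg)
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "report_metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  report
}
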