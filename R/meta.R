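#' Meta-learning run configuration
#'
#' Collects every tunable of the meta-training and adaptation loops. The
#' `"full"` profile carries the acquisition-scale settings (outer/inner/
#' adaptation epoch counts 500/10/50, Adam learning rate 1e-5, INR widths
#' (3,256,256,256,3), 192-dimensional tokens, 13 spokes of 256 samples);
#' the `"desk"` profile is the package's scaled-down configuration for
#' phantom-sized grids, with smaller widths/tokens and learning rates chosen
#' once for that scale (see the methods vignette).
#'
#' @param profile `"desk"` or `"full"`
#' @param ... overrides of any field
#' @return object of class `meta_config`
#' @export
meta_config <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(
      variant = "cmeta", n_outer = 500L, n_inner = 10L, n_adapt = 50L,
      lr = 1e-5, lr_modulator = 1e-5, lr_iterative = 1e-5,
      optimizer = "adam", batch_size = 1L,
      weights = loss_weights(1.0, 0.5, 0.5),
      widths = c(3L, 256L, 256L, 256L, 3L), omega0 = 30,
      downsample = 2L, d_token = 192L, n_heads = 4L, patch = 8L,
      prior_channels = 16L, n_spokes = 13L, samples_per_spoke = 256L,
      seed = 1L
    )
  } else {
    list(
      variant = "cmeta", n_outer = 20L, n_inner = 5L, n_adapt = 30L,
      lr = 2e-3, lr_modulator = 1e-3, lr_iterative = 5e-2,
      optimizer = "adam", batch_size = 1L,
      weights = loss_weights(1.0, 0.5, 0.5),
      widths = c(3L, 48L, 48L, 48L, 3L), omega0 = 30,
      downsample = 2L, d_token = 24L, n_heads = 4L, patch = 4L,
      prior_channels = 6L, n_spokes = 5L, samples_per_spoke = 32L,
      seed = 1L
    )
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown meta_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_outer >= 0L, cfg$n_inner >= 0L, cfg$n_adapt >= 0L,
            cfg$lr > 0, cfg$lr_modulator > 0, cfg$lr_iterative > 0)
  cfg$variant <- match.arg(cfg$variant,
                           c("cmeta", "meta_inr", "meta_inr_a", "meta_inr_b",
                             "ks_inr", "ks_iterative"))
  structure(cfg, class = "meta_config")
}

variant_uses_prior <- function(variant) variant %in% c("cmeta", "meta_inr_b")
variant_uses_embed <- function(variant) variant == "cmeta"
variant_modulator_kind <- function(variant) {
  if (variant == "meta_inr") "conv" else "token"
}

#' Build a registration case from a cohort subject
#'
#' Source is the subject's reference bin (bin 1); the target bin's complex
#' volume is projected onto a fresh golden-angle trajectory to produce the
#' undersampled target k-space data, and the case is preprocessed into the
#' six-channel model input. Ground-truth quantities (motion field, clean
#' target magnitude, masks) are attached for *evaluation only*; no training
#' or adaptation path reads them.
#'
#' @param subject one element of [generate_cohort()]
#' @param target_bin index of the target bin (>= 2 for real motion)
#' @param cfg a [meta_config()] (spoke count and samples per spoke)
#' @param seed controls the trajectory's initial azimuthal angle
#' @return object of class `reg_case`
#' @export
make_case <- function(subject, target_bin, cfg = meta_config(), seed = 1L) {
  stopifnot(target_bin >= 1L, target_bin <= length(subject$bins))
  traj <- golden_angle_trajectory(cfg$n_spokes, cfg$samples_per_spoke,
                                  seed_for_theta0 = seed)
  S_FI <- subject$bins[[1L]]
  T_UK <- nudft_forward(subject$bins[[target_bin]], traj)
  pc <- preprocess_case(S_FI, T_UK)
  structure(list(
    S_FI = S_FI, T_UK = T_UK, X = pc$X, S_UI = pc$S_UI, T_UI = pc$T_UI,
    shape = dim(S_FI$data), spacing_mm = subject$spacing_mm,
    truth = list(dvf = subject$dvfs[[target_bin]],
                 target_mag = magnitude(subject$bins_clean[[target_bin]]),
                 masks0 = subject$masks0,
                 masks_target = subject$masks_by_bin[[target_bin]])
  ), class = "reg_case")
}

# cache the frozen prior's outputs for a case (reference DVF as a coarse-to-
# full constant, and the target embedding for the embedding loss)
case_prior_outputs <- function(case, prior, need_embed) {
  out <- list()
  if (!is.null(prior)) {
    out$d_reg <- prior_predict(prior, case$X, case$spacing_mm)
    if (need_embed) out$E_target <- prior_encode(prior, case$T_UI)
  }
  out
}

# one step-A epoch set: gradient steps on the deformation discrepancy loss
inner_loop_stepA <- function(params, template, modulation, d_reg, grid, n_epochs,
                             lr) {
  history <- numeric(0)
  if (n_epochs < 1L) return(list(params = params, history = history))
  opt <- adam_init(params, lr = lr)
  d_mat <- matrix(d_reg$data, ncol = 3L)
  for (ep in seq_len(n_epochs)) {
    tp <- ag_tape()
    pn <- params_to_nodes(tp, params)
    out <- ag_siren_forward(tp, pn, modulation, grid$coords, template$omega0)
    up <- ag_upsample_dvf(out, grid$coarse_shape, grid$shape)
    loss <- ag_loss_stepA(up, d_mat)
    ag_backward(loss)
    upd <- adam_step(params, grads_from_nodes(pn), opt)
    params <- upd$params; opt <- upd$state
    history <- c(history, loss$value)
  }
  list(params = params, history = history)
}

# one step-B epoch set: gradient steps on the combined unsupervised loss
inner_loop_stepB <- function(params, template, modulation, case, grid, n_epochs,
                             lr, weights, prior = NULL, E_target = NULL) {
  history <- history_kspace <- numeric(0)
  if (n_epochs < 1L) {
    return(list(params = params, history = history, history_kspace = history_kspace))
  }
  opt <- adam_init(params, lr = lr)
  for (ep in seq_len(n_epochs)) {
    tp <- ag_tape()
    pn <- params_to_nodes(tp, params)
    out <- ag_siren_forward(tp, pn, modulation, grid$coords, template$omega0)
    up <- ag_upsample_dvf(out, grid$coarse_shape, grid$shape)
    loss <- ag_case_stepB_loss(tp, up, case$S_FI, case$T_UK, case$shape,
                               weights = weights, net = prior,
                               E_target = E_target)
    ag_backward(loss$total)
    upd <- adam_step(params, grads_from_nodes(pn), opt)
    params <- upd$params; opt <- upd$state
    history <- c(history, loss$total$value)
    history_kspace <- c(history_kspace, loss$kspace)
  }
  list(params = params, history = history, history_kspace = history_kspace)
}

# evaluate the INR's displacement field for fixed parameters
siren_dvf <- function(params, template, modulation, grid, spacing_mm) {
  tmpl <- template; tmpl$params <- params
  coarse <- siren_forward(tmpl, modulation, grid$coords)
  up <- upsample_dvf(dvf(array(coarse, c(grid$coarse_shape, 3L)), spacing_mm),
                     grid$shape)
  up
}

#' Meta-train the INR template and modulator across a cohort (Algorithm-style
#' Reptile loop)
#'
#' Per outer iteration the template update is reset; for every subject the
#' frozen modulator generates the case's modulation, the INR is loaded from
#' the template and run through `n_inner` step-A epochs (deformation
#' discrepancy against the frozen prior, when the variant uses it) followed
#' by `n_inner` step-B epochs (k-space fidelity + optional embedding
#' similarity + smoothness); the per-subject parameter difference is
#' accumulated Reptile-style, and the modulator is then updated once by
#' backpropagating the step-B loss through the modulation with the INR
#' frozen at its post-training parameters. After all subjects the template
#' moves by the averaged difference.
#'
#' @param cohort from [generate_cohort()]
#' @param template an [init_template()]
#' @param modulator an [init_modulator()] matching the variant
#' @param prior a trained, frozen [init_prior_net()] (or NULL for variants
#'   without cohort priors)
#' @param cfg a [meta_config()]
#' @param cases optional pre-built list of `reg_case` (one per subject);
#'   built from `cohort` when NULL
#' @return list with the updated `template`, `modulator`, and `history`
#'   (per-outer-iteration mean step-B loss)
#' @export
meta_train <- function(cohort, template, modulator, prior = NULL,
                       cfg = meta_config(), cases = NULL) {
  if (length(cohort) < 1L && is.null(cases)) stop("empty cohort")
  use_prior <- variant_uses_prior(cfg$variant)
  use_embed <- variant_uses_embed(cfg$variant)
  if (use_prior && is.null(prior)) stop("variant '", cfg$variant, "' needs a prior net")
  if (is.null(cases)) {
    cases <- lapply(seq_along(cohort), function(si) {
      nb <- length(cohort[[si]]$bins)
      b <- if (nb > 1L) {
        with_seed(derive_seed(cfg$seed, paste0("pair", si)), sample(2:nb, 1L))
      } else 1L
      make_case(cohort[[si]], b, cfg, seed = derive_seed(cfg$seed, paste0("traj", si)))
    })
  }
  if (cfg$n_outer < 1L) {
    return(list(template = template, modulator = modulator, history = numeric(0)))
  }
  if (modulator$kind == "token") {
    tok <- patch_token_idx(cases[[1L]]$shape, modulator$patch)
    modulator <- ensure_embed(modulator, tok$token_dim_in)
  }
  grid <- coordinate_grid(cases[[1L]]$shape, cfg$downsample)
  pri <- lapply(cases, case_prior_outputs, prior = prior,
                need_embed = use_embed)
  w_inner <- if (use_embed) cfg$weights else
    loss_weights(cfg$weights$l1, 0, cfg$weights$l3)
  mod_opt <- adam_init(modulator$params, lr = cfg$lr_modulator)
  history <- numeric(0)
  n_x <- length(cases)
  for (it in seq_len(cfg$n_outer)) {
    delta <- NULL
    it_losses <- numeric(0)
    for (si in seq_along(cases)) {
      case <- cases[[si]]
      modv <- modulator_forward(modulator, case$X)
      params <- template$params
      if (use_prior && cfg$n_inner > 0L) {
        sa <- inner_loop_stepA(params, template, modv, pri[[si]]$d_reg, grid,
                               cfg$n_inner, cfg$lr)
        params <- sa$params
      }
      sb <- inner_loop_stepB(params, template, modv, case, grid, cfg$n_inner,
                             cfg$lr, w_inner, prior = prior,
                             E_target = pri[[si]]$E_target)
      params <- sb$params
      it_losses <- c(it_losses, utils::tail(sb$history, 1L))
      diff <- mapply(function(a, b) (a - b) / n_x,
                     flatten_params(params), flatten_params(template$params),
                     SIMPLIFY = FALSE)
      delta <- if (is.null(delta)) diff else
        mapply(`+`, delta, diff, SIMPLIFY = FALSE)
      # modulator update: freeze the INR at the post-training parameters and
      # backpropagate the step-B loss through the modulation coefficients
      tp <- ag_tape()
      mn <- params_to_nodes(tp, modulator$params)
      modn <- ag_modulator_forward(tp, modulator, mn, case$X)
      pn_inr <- params_to_nodes_const(tp, params)
      out <- ag_siren_forward(tp, pn_inr, modn, grid$coords, template$omega0)
      up <- ag_upsample_dvf(out, grid$coarse_shape, grid$shape)
      loss <- ag_case_stepB_loss(tp, up, case$S_FI, case$T_UK, case$shape,
                                 weights = w_inner, net = prior,
                                 E_target = pri[[si]]$E_target)
      ag_backward(loss$total)
      updm <- adam_step(modulator$params, grads_from_nodes(mn), mod_opt)
      modulator$params <- updm$params; mod_opt <- updm$state
    }
    template$params <- unflatten_params(
      mapply(`+`, flatten_params(template$params), delta, SIMPLIFY = FALSE),
      template$params)
    history <- c(history, mean(it_losses))
  }
  list(template = template, modulator = modulator, history = history)
}

#' Adapt to a new case (test-time adaptation) and estimate its volume
#'
#' Loads the meta-learned template under the case's modulation and runs
#' `n_adapt` step-A epochs (for variants with a cohort prior) followed by
#' `n_adapt` step-B epochs, all fully unsupervised. Baselines: `ks_inr`
#' starts from a random template with identity modulation and uses step B
#' only; `ks_iterative` optimises a voxelwise displacement array on the
#' coarse grid directly (no network) with the same upsampling path.
#'
#' @param template an [init_template()] (ignored by `ks_iterative`)
#' @param modulator an [init_modulator()] (ignored by the non-modulated
#'   baselines)
#' @param prior frozen prior net, required when the variant uses it
#' @param case a [make_case()]
#' @param cfg a [meta_config()]
#' @return list with the full-resolution `dvf`, the deformed source volume
#'   `S_DI`, `modulation`, per-epoch `history_stepA`/`history_stepB`, and
#'   `metrics` (when the case carries ground truth)
#' @export
adapt_case <- function(template, modulator, prior, case, cfg = meta_config()) {
  variant <- cfg$variant
  use_prior <- variant_uses_prior(variant)
  use_embed <- variant_uses_embed(variant)
  if (use_prior && is.null(prior)) stop("variant '", variant, "' needs a prior net")
  grid <- coordinate_grid(case$shape, cfg$downsample)
  w <- if (use_embed) cfg$weights else loss_weights(cfg$weights$l1, 0, cfg$weights$l3)
  pri <- case_prior_outputs(case, if (use_prior || use_embed) prior else NULL,
                            need_embed = use_embed)
  histA <- histB <- histK <- numeric(0)
  if (variant == "ks_iterative") {
    n_c <- prod(grid$coarse_shape)
    dpar <- list(d = matrix(0, n_c, 3L))
    opt <- adam_init(dpar, lr = cfg$lr_iterative)
    for (ep in seq_len(cfg$n_adapt)) {
      tp <- ag_tape()
      pn <- params_to_nodes(tp, dpar)
      up <- ag_upsample_dvf(pn$d, grid$coarse_shape, grid$shape)
      loss <- ag_case_stepB_loss(tp, up, case$S_FI, case$T_UK, case$shape,
                                 weights = w)
      ag_backward(loss$total)
      upd <- adam_step(dpar, grads_from_nodes(pn), opt)
      dpar <- upd$params; opt <- upd$state
      histB <- c(histB, loss$total$value)
      histK <- c(histK, loss$kspace)
    }
    d_full <- upsample_dvf(dvf(array(dpar$d, c(grid$coarse_shape, 3L)),
                               case$spacing_mm), grid$shape)
    modv <- NULL
  } else {
    modv <- if (variant %in% c("ks_inr")) {
      modulation_identity(template$widths)
    } else {
      modulator_forward(modulator, case$X)
    }
    params <- template$params
    if (use_prior && cfg$n_adapt > 0L) {
      sa <- inner_loop_stepA(params, template, modv, pri$d_reg, grid,
                             cfg$n_adapt, cfg$lr)
      params <- sa$params; histA <- sa$history
    }
    sb <- inner_loop_stepB(params, template, modv, case, grid, cfg$n_adapt,
                           cfg$lr, w, prior = prior, E_target = pri$E_target)
    params <- sb$params; histB <- sb$history; histK <- sb$history_kspace
    d_full <- siren_dvf(params, template, modv, grid, case$spacing_mm)
  }
  S_DI <- warp_complex(case$S_FI, d_full)
  res <- list(dvf = d_full, S_DI = S_DI, modulation = modv,
              history_stepA = histA, history_stepB = histB,
              history_kspace = histK, variant = variant)
  if (!is.null(case$truth)) res$metrics <- evaluate_case(res, case)
  res
}

#' Evaluate a registration result against the case's ground truth
#'
#' Warps the reference-bin lesion mask with the predicted field and compares
#' image and contour metrics against the clean target.
#'
#' @param result from [adapt_case()]
#' @param case the [make_case()] it was adapted to
#' @param mask_name which structure mask to score (default the last one,
#'   the lesion in the default scene)
#' @return a [metric_report()] list plus `mean_abs_dvf_error_vox`
#' @export
evaluate_case <- function(result, case, mask_name = NULL) {
  tr <- case$truth
  if (is.null(mask_name)) mask_name <- utils::tail(names(tr$masks0), 1L)
  pred_mask <- if (length(tr$masks0)) {
    warp_mask(tr$masks0[[mask_name]], result$dvf)
  } else NULL
  truth_mask <- if (length(tr$masks_target)) tr$masks_target[[mask_name]] else NULL
  if (!is.null(pred_mask) && (sum(pred_mask) == 0 || sum(truth_mask) == 0)) {
    # a collapsed mask: overlap is zero and distances are undefined
    rep <- metric_report(Mod(result$S_DI$data), tr$target_mag,
                         spacing_mm = case$spacing_mm)
    rep$dice <- if (sum(pred_mask) + sum(truth_mask) > 0) 0 else 1
    rep$hd95_mm <- NA_real_
    rep$come_mm <- NA_real_
  } else {
    rep <- metric_report(Mod(result$S_DI$data), tr$target_mag,
                         pred_mask, truth_mask, case$spacing_mm)
  }
  rep$mean_abs_dvf_error_vox <- mean(abs(result$dvf$data - tr$dvf$data))
  rep
}

#' Run one framework variant end to end
#'
#' Dispatcher over the ablation variants and baselines. Meta-learning
#' variants (`cmeta`, `meta_inr`, `meta_inr_a`, `meta_inr_b`) train on a
#' cohort and then adapt to each supplied held-out case; the per-case
#' baselines (`ks_inr`, `ks_iterative`) skip training. All variants emit the
#' same result schema per case.
#'
#' @param variant one of `cmeta`, `meta_inr`, `meta_inr_a`, `meta_inr_b`,
#'   `ks_inr`, `ks_iterative`
#' @param cohort training cohort (may be NULL for the per-case baselines)
#' @param cases list of held-out [make_case()] objects
#' @param cfg a [meta_config()] (its `variant` field is overridden)
#' @param prior trained prior net where the variant needs one
#' @return list with `results` (one per case), `template`, `modulator`,
#'   `history`
#' @export
run_variant <- function(variant, cohort = NULL, cases, cfg = meta_config(),
                        prior = NULL) {
  cfg$variant <- match.arg(variant, c("cmeta", "meta_inr", "meta_inr_a",
                                      "meta_inr_b", "ks_inr", "ks_iterative"))
  template <- init_template(cfg$widths, cfg$omega0,
                            seed = derive_seed(cfg$seed, "template"))
  modulator <- init_modulator(variant_modulator_kind(cfg$variant),
                              hidden_widths = cfg$widths[c(3, 4, 4)],
                              d_token = cfg$d_token, n_heads = cfg$n_heads,
                              patch = cfg$patch,
                              base_channels = cfg$prior_channels,
                              seed = derive_seed(cfg$seed, "modulator"))
  history <- numeric(0)
  if (!(cfg$variant %in% c("ks_inr", "ks_iterative"))) {
    if (is.null(cohort)) stop("variant '", cfg$variant, "' needs a training cohort")
    tr <- meta_train(cohort, template, modulator, prior, cfg)
    template <- tr$template; modulator <- tr$modulator; history <- tr$history
  }
  results <- lapply(cases, function(cs) {
    adapt_case(template, modulator, prior, cs, cfg)
  })
  list(results = results, template = template, modulator = modulator,
       history = history, variant = cfg$variant)
}

#' First epoch at which a loss history reaches a threshold
#'
#' @param history numeric per-epoch loss values
#' @param tau threshold
#' @return epoch index, or `length(history) + 1` when never reached
#' @export
epochs_to_threshold <- function(history, tau) {
  hit <- which(history <= tau)
  if (length(hit)) hit[1L] else length(history) + 1L
}
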