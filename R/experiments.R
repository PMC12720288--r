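#' @title Headline phantom experiments
#'
#' @description
#' Self-contained experiments at phantom scale: registration recovery with a
#' scratch-trained INR, convergence-speed comparison between the
#' meta-learned template and random initialisation, and the ablation ladder
#' over the framework variants. Each experiment generates its own synthetic
#' cohort, runs the method, and returns plain numeric summaries. They back
#' both the package's acceptance checks and the reproduction script.
#'
#' @name experiments
NULL

#' Registration recovery with a scratch INR (no meta-learning)
#'
#' A single subject with known smooth motion (peak below about 3.4 voxels)
#' is sampled with 13 golden-angle spokes at 32 x 32 x 8; the INR is
#' optimised from random initialisation on the k-space fidelity and
#' smoothness losses alone. Reports relative error and lesion Dice before
#' and after registration, and the residual displacement on a zero-motion
#' case.
#'
#' @param seed integer
#' @param shape grid shape
#' @param n_adapt step-B epochs for the scratch INR
#' @return list of summary numbers
#' @export
experiment_recovery <- function(seed = 1L, shape = c(32L, 32L, 8L),
                                n_adapt = 150L) {
  cfg <- meta_config("desk", variant = "ks_inr", n_spokes = 13L,
                     samples_per_spoke = 64L, n_adapt = n_adapt,
                     seed = derive_seed(seed, "recovery"))
  subj <- generate_cohort(1L, default_phantom_spec(shape),
                          motion = motion_model(c(1.5, 1, 3), 10, 4),
                          seed = derive_seed(seed, "recovery_cohort"))[[1L]]
  case <- make_case(subj, 3L, cfg, seed = derive_seed(seed, "recovery_traj"))
  re_before <- metric_re(magnitude(case$S_FI), case$truth$target_mag)
  dice_before <- metric_dice(case$truth$masks0$lesion,
                             case$truth$masks_target$lesion)
  rv <- run_variant("ks_inr", cohort = NULL, cases = list(case), cfg = cfg)
  res <- rv$results[[1L]]
  # zero-motion control: the target is the source bin itself
  case0 <- make_case(subj, 1L, cfg, seed = derive_seed(seed, "recovery_zero"))
  res0 <- adapt_case(rv$template, rv$modulator, NULL, case0, cfg)
  list(
    re_before_percent = re_before,
    re_after_percent = res$metrics$re_percent,
    re_reduction_percent = 100 * (1 - res$metrics$re_percent / re_before),
    dice_before = dice_before,
    dice_after = res$metrics$dice,
    ssim_after = res$metrics$ssim,
    hd95_after_mm = res$metrics$hd95_mm,
    come_after_mm = res$metrics$come_mm,
    zero_motion_mean_abs_d_vox = mean(abs(res0$dvf$data)),
    peak_true_displacement_vox = max(abs(case$truth$dvf$data)),
    n_spokes = cfg$n_spokes
  )
}

#' Shared setup for the meta-learning experiments
#'
#' Builds the 16 x 16 x 8 training cohort (six subjects by default) plus
#' held-out registration cases from two additional subjects (three target
#' bins each), all derived from one seed.
#'
#' @param seed integer
#' @param n_train training subjects
#' @param n_held_subjects held-out subjects (three cases each)
#' @param cfg optional [meta_config()] override
#' @return list with `cfg`, `train`, `cases`, `shape`
#' @export
meta_experiment_setup <- function(seed, n_train = 6L, n_held_subjects = 2L,
                                  cfg = NULL) {
  shape <- c(16L, 16L, 8L)
  if (is.null(cfg)) cfg <- meta_config("desk", seed = derive_seed(seed, "meta_cfg"))
  cohort <- generate_cohort(n_train + n_held_subjects,
                            default_phantom_spec(shape),
                            motion = motion_model(c(1, 0.5, 2), 6, 4),
                            seed = derive_seed(seed, "meta_cohort"))
  train <- cohort[seq_len(n_train)]
  held <- cohort[n_train + seq_len(n_held_subjects)]
  cases <- list()
  for (si in seq_along(held)) {
    for (b in 2:4) {
      cases[[length(cases) + 1L]] <-
        make_case(held[[si]], b, cfg,
                  seed = derive_seed(seed, sprintf("heldout%d_%d", si, b)))
    }
  }
  list(cfg = cfg, train = train, cases = cases, shape = shape)
}

#' Convergence advantage of the meta-learned template
#'
#' Trains the prior and meta-trains the full framework on a six-subject
#' cohort, then adapts held-out cases twice per seed with an identical pure
#' step-B objective (k-space fidelity + smoothness): once from the
#' meta-learned template under its case modulation, once from a freshly
#' initialised template. For each run the number of step-B epochs needed to
#' bring the k-space fidelity loss below `threshold_frac` times its
#' zero-displacement value is recorded; medians are compared across cases
#' and seeds.
#'
#' @param seed integer
#' @param n_seeds independent random template initialisations per case
#' @param n_cases held-out cases (capped by the available 6)
#' @param threshold_frac fraction of the unregistered k-space loss used as
#'   the convergence threshold
#' @param max_epochs step-B epoch budget per run
#' @param setup optional shared setup from a previous experiment
#' @return list with median epochs per arm and the full epoch tables
#' @export
experiment_meta_advantage <- function(seed = 1L, n_seeds = 3L, n_cases = 5L,
                                      threshold_frac = 0.25, max_epochs = 60L,
                                      setup = NULL) {
  if (is.null(setup)) setup <- meta_experiment_setup(seed)
  cfg <- setup$cfg
  cases <- setup$cases[seq_len(min(n_cases, length(setup$cases)))]
  prior <- train_prior(init_prior_net(cfg$prior_channels,
                                      seed = derive_seed(seed, "prior_init")),
                       setup$train, epochs = 12L, lr = 1e-3,
                       n_spokes = cfg$n_spokes,
                       samples_per_spoke = cfg$samples_per_spoke,
                       seed = derive_seed(seed, "prior_train"))
  trained <- run_variant("cmeta", setup$train, cases = list(), cfg = cfg,
                         prior = prior)
  pure_b <- meta_config("desk", variant = "ks_inr", n_adapt = max_epochs,
                        n_spokes = cfg$n_spokes,
                        samples_per_spoke = cfg$samples_per_spoke,
                        seed = cfg$seed)
  grid <- NULL
  epochs_meta <- epochs_scratch <- c()
  for (s in seq_len(n_seeds)) {
    for (ci in seq_along(cases)) {
      case <- cases[[ci]]
      # threshold fixed per case: fraction of the k-space loss at zero DVF
      l0 <- loss_kspace(nudft_forward(case$S_FI, case$T_UK$trajectory), case$T_UK)
      tau <- threshold_frac * l0
      modv <- modulator_forward(trained$modulator, case$X)
      grid <- coordinate_grid(case$shape, pure_b$downsample)
      w <- loss_weights(pure_b$weights$l1, 0, pure_b$weights$l3)
      run_arm <- function(params, modulation) {
        inner_loop_stepB(params, trained$template, modulation, case, grid,
                         max_epochs, pure_b$lr, w)$history_kspace
      }
      hk_meta <- run_arm(trained$template$params, modv)
      rnd <- init_template(cfg$widths, cfg$omega0,
                           seed = derive_seed(seed, sprintf("rand%d_%d", s, ci)))
      hk_scr <- run_arm(rnd$params, modulation_identity(cfg$widths))
      epochs_meta <- c(epochs_meta, epochs_to_threshold(hk_meta, tau))
      epochs_scratch <- c(epochs_scratch, epochs_to_threshold(hk_scr, tau))
    }
  }
  list(median_epochs_meta = stats::median(epochs_meta),
       median_epochs_scratch = stats::median(epochs_scratch),
       epochs_meta = epochs_meta, epochs_scratch = epochs_scratch,
       n_cases = length(cases), n_seeds = n_seeds)
}

#' Ablation ladder: held-out Dice across framework variants
#'
#' Meta-trains `meta_inr` (convolutional modulation, no priors), `meta_inr_b`
#' (token modulation + deformation discrepancy guidance) and `cmeta` (+
#' embedding similarity) on the same cohort and adapts the same held-out
#' cases with a deliberately small adaptation budget, where template quality
#' and cohort guidance matter most. Reports the median lesion Dice per
#' variant.
#'
#' @param seed integer
#' @param n_adapt adaptation epochs (small by design)
#' @param setup optional shared setup
#' @param prior optional pre-trained prior (trained here when NULL)
#' @return list with per-variant median Dice and the full tables
#' @export
experiment_ablation <- function(seed = 1L, n_adapt = 10L, setup = NULL,
                                prior = NULL) {
  if (is.null(setup)) setup <- meta_experiment_setup(seed)
  cfg <- setup$cfg
  cfg$n_adapt <- as.integer(n_adapt)
  if (is.null(prior)) {
    prior <- train_prior(init_prior_net(cfg$prior_channels,
                                        seed = derive_seed(seed, "prior_init")),
                         setup$train, epochs = 12L, lr = 1e-3,
                         n_spokes = cfg$n_spokes,
                         samples_per_spoke = cfg$samples_per_spoke,
                         seed = derive_seed(seed, "prior_train"))
  }
  variants <- c("meta_inr", "meta_inr_b", "cmeta")
  dice <- list()
  for (v in variants) {
    rv <- run_variant(v, setup$train, cases = setup$cases, cfg = cfg,
                      prior = prior)
    dice[[v]] <- vapply(rv$results, function(r) r$metrics$dice, numeric(1))
  }
  list(median_dice = vapply(dice, stats::median, numeric(1)),
       dice = dice, n_adapt = cfg$n_adapt, prior = prior)
}
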