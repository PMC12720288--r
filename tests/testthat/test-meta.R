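test_that("meta_config validates fields and rejects unknown keys", {
  cfg <- meta_config("full")
  expect_equal(cfg$n_outer, 500L)
  expect_equal(cfg$n_inner, 10L)
  expect_equal(cfg$n_adapt, 50L)
  expect_equal(cfg$lr, 1e-5)
  expect_equal(cfg$widths, c(3L, 256L, 256L, 256L, 3L))
  expect_error(meta_config("desk", not_a_field = 1), "unknown")
  expect_error(meta_config("desk", lr = 0))
  expect_error(meta_config("desk", variant = "bogus"))
})

test_that("inner loops with zero epochs leave parameters untouched", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  tmpl <- init_template(cfg$widths, seed = 3)
  grid <- coordinate_grid(case$shape, 2)
  modv <- modulation_identity(cfg$widths)
  sa <- inner_loop_stepA(tmpl$params, tmpl, modv, dvf_zero(case$shape), grid, 0, 1e-3)
  expect_identical(sa$params, tmpl$params)
  sb <- inner_loop_stepB(tmpl$params, tmpl, modv, case, grid, 0, 1e-3,
                         loss_weights(1, 0, 0.5))
  expect_identical(sb$params, tmpl$params)
})

test_that("step-A loss starts at zero when the reference equals the INR output", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  tmpl <- init_template(cfg$widths, seed = 3)
  grid <- coordinate_grid(case$shape, 2)
  modv <- modulation_identity(cfg$widths)
  self_ref <- siren_dvf(tmpl$params, tmpl, modv, grid, case$spacing_mm)
  sa <- inner_loop_stepA(tmpl$params, tmpl, modv, self_ref, grid, 1, 1e-9)
  expect_equal(sa$history[1], 0, tolerance = 1e-12)
})

test_that("inner losses decrease over a short toy optimisation", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  tmpl <- init_template(cfg$widths, seed = 3)
  grid <- coordinate_grid(case$shape, 2)
  modv <- modulation_identity(cfg$widths)
  ref <- dvf(array(0.5, c(case$shape, 3)), case$spacing_mm)
  sa <- inner_loop_stepA(tmpl$params, tmpl, modv, ref, grid, 10, 2e-3)
  expect_lt(utils::tail(sa$history, 1), sa$history[1])
  sb <- inner_loop_stepB(tmpl$params, tmpl, modv, case, grid, 10, 2e-3,
                         loss_weights(1, 0, 0.5))
  expect_lt(utils::tail(sb$history, 1), sb$history[1])
})

test_that("zero outer iterations and the single-subject Reptile identity hold", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  cfg$variant <- "meta_inr_a"  # token modulator, no prior needed
  cfg$n_outer <- 0L
  tmpl <- init_template(cfg$widths, seed = 3)
  m <- init_modulator("token", hidden_widths = cfg$widths[c(3, 4, 4)],
                      d_token = 8L, patch = 4L, seed = 4)
  same <- meta_train(list(), tmpl, m, NULL, cfg, cases = list(case))
  expect_identical(same$template$params, tmpl$params)
  expect_identical(same$modulator$params, m$params)
  # with one subject the Reptile update moves the template exactly to the
  # post-training parameters: Phi + (Phi'' - Phi) / 1
  cfg$n_outer <- 1L; cfg$n_inner <- 3L
  tok <- patch_token_idx(case$shape, m$patch)
  m2 <- ensure_embed(m, tok$token_dim_in)
  modv <- modulator_forward(m2, case$X)
  grid <- coordinate_grid(case$shape, cfg$downsample)
  manual <- inner_loop_stepB(tmpl$params, tmpl, modv, case, grid, cfg$n_inner,
                             cfg$lr, loss_weights(cfg$weights$l1, 0, cfg$weights$l3))
  got <- meta_train(list(), tmpl, m2, NULL, cfg, cases = list(case))
  expect_equal(flatten_params(got$template$params),
               flatten_params(manual$params), tolerance = 1e-12)
})

test_that("zero inner epochs leave the template fixed across outer iterations", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  cfg$variant <- "meta_inr_a"; cfg$n_outer <- 3L; cfg$n_inner <- 0L
  tmpl <- init_template(cfg$widths, seed = 3)
  m <- init_modulator("token", hidden_widths = cfg$widths[c(3, 4, 4)],
                      d_token = 8L, patch = 4L, seed = 4)
  got <- meta_train(list(), tmpl, m, NULL, cfg, cases = list(case))
  expect_equal(flatten_params(got$template$params), flatten_params(tmpl$params),
               tolerance = 1e-12)
})

test_that("zero-adaptation returns the template's zero-shot prediction", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  cfg$variant <- "meta_inr_a"; cfg$n_adapt <- 0L
  tmpl <- init_template(cfg$widths, seed = 3)
  m <- init_modulator("token", hidden_widths = cfg$widths[c(3, 4, 4)],
                      d_token = 8L, patch = 4L, seed = 4)
  res <- adapt_case(tmpl, m, NULL, case, cfg)
  grid <- coordinate_grid(case$shape, cfg$downsample)
  tok <- patch_token_idx(case$shape, m$patch)
  modv <- modulator_forward(ensure_embed(m, tok$token_dim_in), case$X)
  expect_equal(res$dvf$data,
               siren_dvf(tmpl$params, tmpl, modv, grid, case$spacing_mm)$data,
               tolerance = 1e-12)
})

test_that("adaptation is reproducible and leaves the prior bit-identical", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  cfg$variant <- "cmeta"; cfg$n_adapt <- 3L
  prior <- init_prior_net(4L, seed = 2)
  prior_before <- serialize(prior$params, NULL)
  tmpl <- init_template(cfg$widths, seed = 3)
  m <- init_modulator("token", hidden_widths = cfg$widths[c(3, 4, 4)],
                      d_token = 8L, patch = 4L, seed = 4)
  r1 <- adapt_case(tmpl, m, prior, case, cfg)
  r2 <- adapt_case(tmpl, m, prior, case, cfg)
  expect_identical(r1$history_stepB, r2$history_stepB)
  expect_identical(r1$dvf$data, r2$dvf$data)
  expect_identical(serialize(prior$params, NULL), prior_before)
  expect_error(adapt_case(tmpl, m, NULL, case, cfg), "prior")
})

test_that("all variants emit the same metrics schema and unknown flags fail", {
  case <- tiny_case()
  cfg <- tiny_cfg()
  cfg$n_adapt <- 2L; cfg$n_outer <- 1L; cfg$n_inner <- 1L
  prior <- init_prior_net(4L, seed = 2)
  subj <- tiny_subject()
  schemas <- list()
  for (v in c("ks_inr", "ks_iterative", "meta_inr", "meta_inr_a",
              "meta_inr_b", "cmeta")) {
    rv <- run_variant(v, cohort = list(subj), cases = list(case), cfg = cfg,
                      prior = prior)
    schemas[[v]] <- sort(names(rv$results[[1]]$metrics))
  }
  for (v in names(schemas)) expect_identical(schemas[[v]], schemas[[1]])
  expect_error(run_variant("nonsense", cases = list(case), cfg = cfg))
})

test_that("the iterative baseline stays near zero displacement on a zero-motion case", {
  subj <- tiny_subject()
  cfg <- tiny_cfg()
  cfg$variant <- "ks_iterative"; cfg$n_adapt <- 20L
  case0 <- make_case(subj, 1L, cfg, seed = 77)   # target is the source bin
  res <- adapt_case(NULL, NULL, NULL, case0, cfg)
  expect_lt(mean(abs(res$dvf$data)), 0.25)
})
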