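test_that("plateau schedule cuts the learning rate by 40 percent", {
  st <- list(lr = 1e-3, best = Inf, counter = 0L)
  st <- lr_plateau_step(st, 1.0)          # first epoch improves
  for (i in 1:59) st <- lr_plateau_step(st, 2.0)
  expect_equal(st$lr, 1e-3)               # 59 stagnant epochs: unchanged
  st <- lr_plateau_step(st, 2.0)          # 60th: reduce
  expect_equal(st$lr, 6e-4)
  expect_equal(st$counter, 0L)

  # improvement at epoch 59 resets the counter
  st2 <- list(lr = 1e-3, best = Inf, counter = 0L)
  st2 <- lr_plateau_step(st2, 1.0)
  for (i in 1:58) st2 <- lr_plateau_step(st2, 2.0)
  st2 <- lr_plateau_step(st2, 0.5)
  expect_equal(st2$lr, 1e-3)
  expect_equal(st2$counter, 0L)

  # two consecutive plateau windows compound to 0.36x
  st3 <- list(lr = 1e-3, best = 0.1, counter = 0L)
  for (i in 1:120) st3 <- lr_plateau_step(st3, 1.0)
  expect_equal(st3$lr, 0.36e-3)
})

test_that("metrics follow their closed forms", {
  expect_equal(prediction_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(mae = 0, rmse = 0))
  expect_equal(prediction_metrics(c(2, 3, 4), c(1, 2, 3))$mae, 1)
  m <- prediction_metrics(c(1, -1), c(0, 0))
  expect_equal(m$mae, 1)
  expect_equal(m$rmse, 1)
  # RMSE >= MAE always
  withr::local_seed(61)
  for (i in 1:5) {
    p <- stats::rnorm(20); o <- stats::rnorm(20)
    mm <- prediction_metrics(p, o)
    expect_gte(mm$rmse, mm$mae)
  }
})

test_that("training protocol: lr trace, early stop and best checkpoint", {
  # A stalled optimization (lr = 0 after warm start via zero-lr Adam) gives
  # constant validation MAE, so the full protocol runs deterministically:
  # plateau cuts at epochs 61 and 121, early stop after 150 stagnant epochs.
  withr::local_seed(62)
  synth <- make_synthetic_reactions(synthetic_spec(n_reactions = 8,
                                                   atoms_range = c(3, 4),
                                                   sigma = 0, seed = 3,
                                                   two_mol_prob = 0))
  m <- small_model("invariant", "S", "diff", "energy", n_s = 4, n_g = 4,
                   n_conv = 1)
  cfg <- train_config(lr = 1e-30, max_epochs = 512, batch_size = 8, seed = 1)
  fit <- train_model(m, synth$records, list(train = 1:6, val = 7:8), cfg)
  tr <- fit$metrics
  expect_equal(nrow(tr), 151)                      # early stop at 1 + 150
  expect_equal(fit$best_epoch, 1L)
  expect_equal(tr$lr[1:61], rep(1e-30, 61))
  expect_equal(tr$lr[62:121], rep(0.6e-30, 60))
  expect_equal(tr$lr[122:151], rep(0.36e-30, 30))
  # lr trace is non-increasing, piecewise constant with ratio 0.6
  ratios <- unique(signif(tr$lr / tr$lr[1], 6))
  expect_true(all(diff(tr$lr) <= 0))
  expect_equal(sort(ratios, decreasing = TRUE), signif(0.6^(0:2), 6))
  # best-checkpoint contract: returned model is at least as good as final
  expect_lte(min(tr$val_mae[fit$best_epoch]), tr$val_mae[nrow(tr)])
})

test_that("identical seeds give bitwise-identical metric traces", {
  withr::local_seed(63)
  synth <- make_synthetic_reactions(synthetic_spec(n_reactions = 10,
                                                   atoms_range = c(3, 4),
                                                   sigma = 0.05, seed = 4,
                                                   two_mol_prob = 0))
  run_once <- function() {
    m <- small_model("invariant", "S", "diff", "energy", n_s = 4, n_g = 4,
                     n_conv = 1)
    train_model(m, synth$records, list(train = 1:8, val = 9:10),
                train_config(max_epochs = 12, batch_size = 4, seed = 5))$metrics
  }
  expect_identical(run_once(), run_once())
})

test_that("fold aggregation reports mean and spread over k folds", {
  withr::local_seed(64)
  synth <- make_synthetic_reactions(synthetic_spec(n_reactions = 24,
                                                   atoms_range = c(3, 4),
                                                   sigma = 0.05, seed = 6,
                                                   two_mol_prob = 0))
  res <- run_folds(synth$records, split_spec("random", seed = 1), k = 2,
                   cfg = train_config(max_epochs = 8, batch_size = 8, seed = 1),
                   model_factory = function() {
                     rxn3d_model(graph_config(n_g = 4),
                                 channel_config("invariant", n_s = 4,
                                                n_conv = 1),
                                 head_config("S", "diff", "energy"))
                   })
  expect_equal(nrow(res$folds), 2)
  expect_equal(res$k, 2)
  expect_equal(res$mae_mean, mean(res$folds$mae))
  expect_equal(res$mae_sd, stats::sd(res$folds$mae))
  expect_true(all(res$folds$rmse >= res$folds$mae))
})

test_that("the sweep samples the documented hyperparameter space", {
  space <- hyperparameter_space()
  expect_setequal(space$lr, c(5e-5, 1e-4, 5e-4, 1e-3))
  expect_setequal(space$n_conv, c(2L, 3L))
  expect_setequal(space$r_max, c(2.5, 5.0, 10.0))
  expect_setequal(space$combine_mode, c("mlp", "diff", "mean", "sum"))
  withr::local_seed(65)
  synth <- make_synthetic_reactions(synthetic_spec(n_reactions = 12,
                                                   atoms_range = c(3, 4),
                                                   sigma = 0.05, seed = 8,
                                                   two_mol_prob = 0))
  sw <- sweep_random(synth$records, n_trials = 2, epochs = 3,
                     spec = split_spec("random", seed = 1), seed = 2)
  expect_equal(nrow(sw), 2)
  expect_false(is.unsorted(sw$val_mae))
  expect_true(all(sw$lr %in% space$lr))
})
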