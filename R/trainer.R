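# Training loop: Adam on a robust (Huber by default) objective over z-scored
# targets, plateau
# learning-rate schedule, early stopping, best-validation checkpointing,
# k-fold aggregation and a random hyperparameter search over the model's
# search space.

#' Training configuration
#'
#' @param lr initial learning rate (search space 5e-5 .. 1e-3).
#' @param weight_decay decoupled weight decay (search space 0 .. 1e-3).
#' @param max_epochs epoch cap (512).
#' @param lr_patience epochs of no validation-MAE improvement before the
#'   learning rate is reduced (60).
#' @param lr_factor multiplicative reduction, 0.6 (a 40 percent cut).
#' @param stop_patience epochs of no improvement before early stopping (150).
#' @param batch_size minibatch size (reactions per step).
#' @param loss training objective on z-scored targets: `"huber"` (smooth L1,
#'   quadratic within one standard deviation, L1 beyond — robust like the
#'   MAE selection criterion but optimizable near the minimum), `"l1"` or
#'   `"l2"`.
#' @param seed RNG seed for shuffling and initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 0, max_epochs = 512L,
                         lr_patience = 60L, lr_factor = 0.6,
                         stop_patience = 150L, batch_size = 8L,
                         loss = c("huber", "l1", "l2"), seed = 1L) {
  stopifnot(lr > 0, lr_factor > 0, lr_factor < 1, weight_decay >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
                 stop_patience = as.integer(stop_patience),
                 batch_size = as.integer(batch_size), loss = match.arg(loss),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Plateau learning-rate schedule step
#'
#' Any strict decrease of the validation MAE counts as improvement and
#' resets the counter; after `patience` consecutive non-improving epochs the
#' learning rate is multiplied by `factor` and the counter resets.
#'
#' @param state list with `lr`, `best` (best MAE so far, `Inf` initially) and
#'   `counter`; create with `list(lr = lr, best = Inf, counter = 0L)`.
#' @param val_mae validation MAE of the finished epoch.
#' @param patience,factor schedule constants (60 epochs, factor 0.6).
#' @return updated state.
#' @export
lr_plateau_step <- function(state, val_mae, patience = 60L, factor = 0.6) {
  if (val_mae < state$best) {
    state$best <- val_mae
    state$counter <- 0L
  } else {
    state$counter <- state$counter + 1L
    if (state$counter >= patience) {
      state$lr <- state$lr * factor
      state$counter <- 0L
    }
  }
  state
}

#' Prediction metrics
#'
#' @param pred,obs numeric vectors in original target units.
#' @return list with `mae` and `rmse`.
#' @export
prediction_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  err <- pred - obs
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Evaluate a model on reaction records
#'
#' @param model a [rxn3d_model()].
#' @param records list of [reaction_record()] or an `rxn_prep`.
#' @return list with `mae` and `rmse` in original target units.
#' @export
evaluate_model <- function(model, records) {
  obs <- if (inherits(records, "rxn_prep")) {
    vapply(records, function(p) p$target, 1)
  } else {
    vapply(records, function(r) r$target, 1)
  }
  prediction_metrics(predict_reactions(model, records), obs)
}

#' Train a model
#'
#' Minimizes a robust objective (Huber by default, see `loss`) on
#' standardized targets with Adam, reduces
#' the learning rate by `lr_factor` after `lr_patience` epochs without
#' validation improvement, stops early after `stop_patience` stagnant
#' epochs (or at `max_epochs`), and returns the parameters of the epoch with
#' the best validation MAE, not the last one.
#'
#' @param model freshly initialized [rxn3d_model()] (its standardization
#'   constants are overwritten from the training targets).
#' @param records list of [reaction_record()] or an `rxn_prep` prepared with
#'   the model's graph config.
#' @param split index partition (`train`, `val`) from [make_split()].
#' @param cfg a [train_config()].
#' @param verbose print a line every 25 epochs.
#' @return list: `model` (best checkpoint), `metrics` (per-epoch data.frame
#'   with train/val MAE and learning rate), `best_epoch`.
#' @export
train_model <- function(model, records, split, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(length(split$train) >= 1, length(split$val) >= 1)
  prep <- if (inherits(records, "rxn_prep")) records else {
    prepare_reactions(records, model$gcfg,
                      need_map = model$hcfg$mapping_variant == "M")
  }
  y <- vapply(prep, function(p) p$target, 1)
  if (any(!is.finite(y[c(split$train, split$val)]))) {
    stop("non-finite target in train/val partition")
  }
  # Difference-combined energy readouts cannot express a constant shift (it
  # cancels between the sides), so centering the targets would inject an
  # inexpressible component into the regression; scale-only standardization
  # keeps the target inside the model family (and keeps identity-reaction
  # predictions exactly zero).  Other heads carry output biases and use the
  # full z-score.
  diff_energy <- model$hcfg$graph_mode == "energy" &&
    model$hcfg$combine_mode == "diff"
  model$target_mean <- if (diff_energy) 0 else mean(y[split$train])
  model$target_sd <- stats::sd(y[split$train])
  if (!is.finite(model$target_sd) || model$target_sd < 1e-12) model$target_sd <- 1
  y_std <- (y - model$target_mean) / model$target_sd

  withr::local_seed(cfg$seed)
  theta <- params_flatten(model$params)
  opt <- adam_init(length(theta))
  val_batch <- assemble_batch(prep, split$val)
  lr_state <- list(lr = cfg$lr, best = Inf, counter = 0L)
  best <- list(val_mae = Inf, theta = theta, epoch = 0L)
  stagnant <- 0L
  hist <- vector("list", cfg$max_epochs)

  # minibatch composition is fixed by the initial seeded shuffle (batch order
  # is reshuffled every epoch); batches are assembled once and reused
  idx <- sample(split$train)
  n_batches <- ceiling(length(idx) / cfg$batch_size)
  batch_sel <- lapply(seq_len(n_batches), function(b) {
    idx[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, length(idx))]
  })
  batches <- lapply(batch_sel, function(sel) assemble_batch(prep, sel))

  for (epoch in seq_len(cfg$max_epochs)) {
    abs_err_sum <- 0
    for (b in sample(n_batches)) {
      sel <- batch_sel[[b]]
      batch <- batches[[b]]
      fw <- model_fwd(model, batch, train = TRUE)
      resid <- fw$pred - y_std[sel]
      if (any(!is.finite(resid))) stop("non-finite loss at epoch ", epoch)
      abs_err_sum <- abs_err_sum + sum(abs(resid))
      d_pred <- switch(cfg$loss,
                       l1 = sign(resid),
                       l2 = 2 * resid,
                       huber = ifelse(abs(resid) < 1, resid, sign(resid)))
      d_pred <- d_pred / length(sel)
      grads <- model_bwd(model, batch, fw, d_pred)
      gflat <- params_flatten_like(model$params, grads)
      st <- adam_step(opt, theta, gflat, lr_state$lr, cfg$weight_decay)
      opt <- st$state
      theta <- st$theta
      model$params <- params_unflatten(model$params, theta)
    }
    train_mae <- abs_err_sum / length(idx) * model$target_sd
    val_pred <- model_fwd(model, val_batch)$pred * model$target_sd + model$target_mean
    val_mae <- mean(abs(val_pred - y[split$val]))
    hist[[epoch]] <- data.frame(epoch = epoch, train_mae = train_mae,
                                val_mae = val_mae, lr = lr_state$lr)
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %4d  train MAE %.4f  val MAE %.4f  lr %.2e",
                      epoch, train_mae, val_mae, lr_state$lr))
    }
    if (val_mae < best$val_mae) {
      best <- list(val_mae = val_mae, theta = theta, epoch = epoch)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    lr_state <- lr_plateau_step(lr_state, val_mae, cfg$lr_patience, cfg$lr_factor)
    if (stagnant >= cfg$stop_patience) break
  }
  model$params <- params_unflatten(model$params, best$theta)
  list(model = model, metrics = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
       best_epoch = best$epoch)
}

#' Train and evaluate over k folds
#'
#' Runs k independent seeded splits and trainings and aggregates test
#' metrics (mean and standard deviation across folds).
#'
#' @param records list of [reaction_record()].
#' @param spec base [split_spec()]; fold f uses seed `spec$seed + f - 1`.
#' @param k number of folds.
#' @param cfg a [train_config()]; fold f trains with seed `cfg$seed + f - 1`.
#' @param model_factory zero-argument function returning a fresh
#'   [rxn3d_model()] (called under the fold's seed).
#' @return list: `folds` data.frame (fold, test MAE/RMSE, best epoch),
#'   `mae_mean`, `mae_sd`, `rmse_mean`, `rmse_sd`, `k`.
#' @export
run_folds <- function(records, spec, k = 10L, cfg = train_config(),
                      model_factory = function() rxn3d_model()) {
  rows <- lapply(seq_len(k), function(f) {
    sp <- spec; sp$seed <- spec$seed + f - 1L
    tc <- cfg; tc$seed <- cfg$seed + f - 1L
    part <- make_split(records, sp)
    model <- withr::with_seed(tc$seed, model_factory())
    fit <- train_model(model, records, part, tc)
    m <- evaluate_model(fit$model, records[part$test])
    data.frame(fold = f, mae = m$mae, rmse = m$rmse,
               best_epoch = fit$best_epoch)
  })
  folds <- do.call(rbind, rows)
  list(folds = folds, k = k,
       mae_mean = mean(folds$mae), mae_sd = stats::sd(folds$mae),
       rmse_mean = mean(folds$rmse), rmse_sd = stats::sd(folds$rmse))
}

#' The hyperparameter search space
#'
#' @return named list of admissible values per hyperparameter.
#' @export
hyperparameter_space <- function() {
  list(lr = c(5e-5, 1e-4, 5e-4, 1e-3),
       weight_decay = c(1e-5, 1e-4, 1e-3, 0),
       n_s = c(16L, 32L, 48L, 64L),
       n_v = c(16L, 32L, 48L, 64L),
       n_g = c(16L, 32L, 48L, 64L),
       n_conv = c(2L, 3L),
       r_max = c(2.5, 5.0, 10.0),
       n_neigh = c(10L, 25L, 50L),
       dropout = c(0.0, 0.05, 0.1),
       sum_mode = c("node", "both"),
       combine_mode = c("mlp", "diff", "mean", "sum"),
       graph_mode = c("energy", "vector"))
}

#' Random hyperparameter search
#'
#' Samples configurations uniformly from [hyperparameter_space()] and scores
#' each by validation MAE after training on the first fold for a reduced
#' epoch budget (the sweep stand-in for an external Bayesian service).
#'
#' @param records list of [reaction_record()].
#' @param n_trials number of sampled configurations.
#' @param epochs sweep epoch budget per trial.
#' @param variant,mapping_variant fixed model choices during the sweep.
#' @param spec split used for all trials (first fold).
#' @param seed sweep seed.
#' @return data.frame of sampled settings with their validation MAE, sorted
#'   best-first.
#' @export
sweep_random <- function(records, n_trials = 8L, epochs = 64L,
                         variant = "invariant", mapping_variant = "S",
                         spec = split_spec("random"), seed = 1L) {
  space <- hyperparameter_space()
  part <- make_split(records, spec)
  rows <- lapply(seq_len(n_trials), function(t) {
    draw <- withr::with_seed(seed + t, lapply(space, function(v) sample(v, 1)))
    gcfg <- graph_config(r_max = draw$r_max, n_neigh = draw$n_neigh,
                         n_g = draw$n_g)
    ccfg <- channel_config(variant, n_s = draw$n_s, n_v = draw$n_v,
                           n_conv = draw$n_conv, dropout = draw$dropout,
                           sum_mode = draw$sum_mode)
    hcfg <- head_config(mapping_variant, draw$combine_mode, draw$graph_mode)
    tcfg <- train_config(lr = draw$lr, weight_decay = draw$weight_decay,
                         max_epochs = epochs, seed = seed)
    model <- withr::with_seed(seed + t, rxn3d_model(gcfg, ccfg, hcfg))
    fit <- train_model(model, records, part, tcfg)
    cbind(as.data.frame(draw[c("lr", "weight_decay", "n_s", "n_v", "n_g",
                               "n_conv", "r_max", "n_neigh", "dropout",
                               "sum_mode", "combine_mode", "graph_mode")]),
          data.frame(trial = t, val_mae = min(fit$metrics$val_mae)))
  })
  out <- do.call(rbind, rows)
  out[order(out$val_mae), ]
}
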