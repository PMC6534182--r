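# Training protocol: categorical cross-entropy, RMSProp, mini-batches,
# dropout, early stopping on validation micro-F, and averaging over
# repeated seeded runs.

#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 0.001 (RMSProp),
#' mini-batch size 64, dropout 0.5 on both dropout sites, a 10% validation
#' split drawn uniformly from the training instances, and five repeated
#' runs.
#'
#' @param learning_rate RMSProp learning rate.
#' @param batch_size mini-batch size.
#' @param dropout dropout rate applied at both dropout sites (input
#'   embeddings and pooled vector).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience: training stops after this many
#'   consecutive epochs without a new best validation micro-F.
#' @param validation_fraction fraction of training instances held out for
#'   validation, in (0, 1).
#' @param seeds integer vector of seeds for repeated runs.
#' @param rho,eps RMSProp decay and epsilon.
#' @return A `cpie_train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         dropout = 0.5, max_epochs = 100L, patience = 5L,
                         validation_fraction = 0.10, seeds = 1:5,
                         rho = 0.9, eps = 1e-7) {
  stopifnot(validation_fraction > 0, validation_fraction < 1, patience >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seeds = as.integer(seeds), rho = rho, eps = eps),
            class = "cpie_train_config")
}

#' Split instances into training and validation sets
#'
#' Uniform instance-level sampling without replacement; the two sets are
#' disjoint and exhaustive, and the draw is reproducible from the seed.
#'
#' @param instances a list (or data frame) of instances.
#' @param fraction validation fraction in (0, 1).
#' @param seed integer seed.
#' @return List with `train`, `val` (same container type as the input) and
#'   the index vectors `train_idx`, `val_idx`.
#' @export
split_validation <- function(instances, fraction = 0.10, seed = 1L) {
  n <- if (is.data.frame(instances)) nrow(instances) else length(instances)
  n_val <- round(n * fraction)
  if (n_val < 1L || n_val >= n) {
    stop("validation fraction ", fraction, " yields an empty split for n = ", n)
  }
  set.seed(seed)
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  sel <- function(idx) if (is.data.frame(instances)) instances[idx, , drop = FALSE]
  else instances[idx]
  list(train = sel(train_idx), val = sel(val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

micro_f_of_predictions <- function(feats, pred_ids) {
  gold <- vapply(feats, function(f) f$label_id, 1L)
  unname(micro_metrics(confusion_from_predictions(gold, pred_ids))["f"])
}

#' Train the classifier
#'
#' Mini-batch RMSProp on the mean categorical cross-entropy, with seeded
#' epoch-level shuffling, dropout in training mode only, and early
#' stopping: after each epoch the model is scored on the validation set
#' (micro-F over the positive classes) and the checkpoint with the best
#' validation micro-F is kept (ties resolved to the earliest epoch);
#' training stops once `patience` consecutive epochs fail to improve it.
#' Fully reproducible given (data, configs, seed).
#'
#' @param train_feats,val_feats featurized instance lists.
#' @param model_cfg a [model_config()]; its dropout rates are overridden
#'   by `train_cfg$dropout`.
#' @param train_cfg a [train_config()].
#' @param provider contextual-representation provider.
#' @param seed integer seed.
#' @param class_weights optional length-6 per-class loss weight hook
#'   (default: none).
#' @param verbose print per-epoch progress.
#' @return A `cpie_run_result`: list with `params` (best checkpoint),
#'   `history` data frame (epoch, train_loss, val_micro_f), `best_epoch`,
#'   `best_val_f`, `seed`.
#' @export
train_model <- function(train_feats, val_feats, model_cfg, train_cfg,
                        provider, seed = 1L, class_weights = NULL,
                        verbose = FALSE) {
  if (length(train_feats) == 0L || length(val_feats) == 0L) {
    stop("training and validation sets must be non-empty")
  }
  model_cfg$dropout_input <- train_cfg$dropout
  model_cfg$dropout_output <- train_cfg$dropout
  set.seed(seed)
  params <- model_init(model_cfg)
  state <- NULL
  stacks_of <- function(fs) lapply(fs, function(f) provider(f$sentence_key))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_micro_f = numeric(0))
  best <- list(f = -Inf, epoch = NA_integer_, params = params)
  stale <- 0L
  n <- length(train_feats)
  for (ep in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      fs <- train_feats[batches[[bi]]]
      batch <- pad_batch(fs)
      lg <- model_loss_and_grads(batch, stacks_of(fs), params, model_cfg,
                                 dropout = train_cfg$dropout > 0,
                                 class_weights = class_weights)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d batch %d (loss = %s); aborting",
                     ep, bi, format(lg$loss)))
      }
      upd <- rmsprop_step(params, lg$grads, state, train_cfg$learning_rate,
                          train_cfg$rho, train_cfg$eps)
      params <- upd$params
      state <- upd$state
      losses[bi] <- lg$loss
    }
    val_pred <- model_predict(val_feats, params, model_cfg, provider,
                              batch_size = train_cfg$batch_size)
    vf <- micro_f_of_predictions(val_feats, val_pred$pred_ids)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         val_micro_f = vf))
    if (verbose) {
      message(sprintf("epoch %d: train loss %.4f, val micro-F %.3f",
                      ep, mean(losses), vf))
    }
    if (vf > best$f) {
      best <- list(f = vf, epoch = ep, params = params)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$patience) break
    }
  }
  structure(list(params = best$params, history = history,
                 best_epoch = best$epoch, best_val_f = best$f, seed = seed),
            class = "cpie_run_result")
}

#' @export
print.cpie_run_result <- function(x, ...) {
  cat("<cpie_run_result> seed", x$seed, "-", nrow(x$history), "epochs,",
      sprintf("best val micro-F %.3f at epoch %d\n", x$best_val_f, x$best_epoch))
  invisible(x)
}

#' Repeat training over several seeds and average the test metrics
#'
#' Each seed redraws the validation split, trains with early stopping, and
#' scores the held-out test instances; the reported micro metrics are the
#' arithmetic mean over seeds, with every per-seed report retained.
#'
#' @param all_train_feats pooled training instances (validation is
#'   resampled from them per seed).
#' @param test_feats held-out test instances.
#' @inheritParams train_model
#' @param seeds integer seeds (default from `train_cfg`).
#' @return List with `mean_micro` (precision/recall/F), `per_seed`
#'   (list of `cpie_eval_report`), `runs` (list of `cpie_run_result`).
#' @export
repeat_runs <- function(all_train_feats, test_feats, model_cfg, train_cfg,
                        provider, seeds = train_cfg$seeds, verbose = FALSE) {
  if (length(seeds) < 1L) stop("at least one seed is required")
  reports <- list(); runs <- list()
  for (s in seeds) {
    sp <- split_validation(all_train_feats, train_cfg$validation_fraction,
                           seed = s)
    run <- train_model(sp$train, sp$val, model_cfg, train_cfg, provider,
                       seed = s, verbose = verbose)
    pred <- model_predict(test_feats, run$params, model_cfg, provider,
                          batch_size = train_cfg$batch_size)
    gold <- vapply(test_feats, function(f) f$label_id, 1L)
    reports[[length(reports) + 1L]] <-
      eval_report(confusion_from_predictions(gold, pred$pred_ids))
    runs[[length(runs) + 1L]] <- run
  }
  micro <- do.call(rbind, lapply(reports, function(r) r$micro))
  list(mean_micro = colMeans(micro), per_seed = reports, runs = runs)
}
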