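# Training: volume-wise stratified splitting (no volume ever straddles a
# training set and its evaluation set), inverse-frequency class weights,
# SGD with momentum and early stopping on validation loss, and fivefold
# cross-validation orchestration.

#' Training hyperparameters
#'
#' Defaults follow the published recipe: batch size 32, SGD with learning
#' rate 0.0005 and momentum 0.9, class-weighted categorical cross-entropy,
#' and early stopping when the validation loss has not reached a new
#' minimum for 10 consecutive epochs (best-epoch weights restored).
#'
#' @param batch_size minibatch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param l2_coefficient L2 penalty on conv/dense kernels (adds
#'   `2 * l2 * w` to the kernel gradients).
#' @param patience_epochs early-stopping patience.
#' @param max_epochs epoch cap (early stopping usually ends training first).
#' @param seed master seed for shuffling, augmentation and initialization.
#' @param augment logical: augment training frames (never validation).
#' @param augment_bounds see [augment_params()].
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 5e-4,
                         momentum = 0.9, l2_coefficient = 1e-4,
                         patience_epochs = 10L, max_epochs = 200L,
                         seed = 1L, augment = TRUE,
                         augment_bounds = augment_params()) {
  if (batch_size < 1) oct_error("config_error", "batch_size must be >= 1")
  if (learning_rate <= 0) oct_error("config_error", "learning_rate must be > 0")
  if (patience_epochs < 1) oct_error("config_error", "patience_epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 l2_coefficient = l2_coefficient,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 augment = isTRUE(augment), augment_bounds = augment_bounds),
            class = "train_config")
}

#' Volume-wise stratified fold assignment
#'
#' Assigns training-pool volumes to `n_folds` folds, stratified by class so
#' per-class volume counts are balanced across folds; volumes with
#' `split_hint == "test"` form the untouched holdout. All frames of a
#' volume inherit its fold, which is what guarantees no frame-level leakage
#' across the split.
#'
#' @param manifest data frame with columns volume_id, label and optionally
#'   split_hint.
#' @param n_folds number of folds (default 5).
#' @param seed shuffling seed.
#' @return an object of class `split_plan`: `fold_of_volume` (named integer,
#'   folds 1..n_folds) and `holdout_volumes`.
#' @export
split_by_volume <- function(manifest, n_folds = 5L, seed = 1L) {
  hint <- manifest$split_hint %||% rep("train", nrow(manifest))
  train <- manifest[hint != "test", ]
  holdout <- manifest$volume_id[hint == "test"]
  fold <- integer(0)
  with_seed(seed, {
    for (cl in tissue_classes()) {
      vols <- train$volume_id[train$label == cl]
      if (length(vols) == 0) next
      if (length(vols) < n_folds)
        oct_error("split_error",
                  "class %s has %d training volumes; need at least %d for %d folds",
                  cl, length(vols), n_folds, n_folds)
      vols <- sample(vols)
      f <- rep(seq_len(n_folds), length.out = length(vols))
      fold[vols] <- f
    }
  })
  structure(list(fold_of_volume = fold, holdout_volumes = holdout,
                 n_folds = as.integer(n_folds)),
            class = "split_plan")
}

#' Assert there is no volume-level leakage
#'
#' @param train_ids,eval_ids volume ids of the training and evaluation
#'   frames.
#' @return `TRUE` invisibly; throws a leakage error otherwise.
#' @export
assert_no_leakage <- function(train_ids, eval_ids) {
  common <- intersect(unique(train_ids), unique(eval_ids))
  if (length(common))
    oct_error("leakage_error",
              "volume(s) %s appear in both a training set and its evaluation set",
              paste(common, collapse = ", "))
  invisible(TRUE)
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (n_classes * N_c)`, the "balanced" convention: the
#' weighted frame count of every class equals `N_total / n_classes`. For
#' the study's training frame counts (14,517 / 9,698 / 4,854) this gives
#' (0.667, 0.999, 1.996).
#'
#' @param frame_counts named (or class-ordered) positive counts per class.
#' @return named numeric weights.
#' @export
compute_class_weights <- function(frame_counts) {
  counts <- as.numeric(frame_counts)
  if (any(!is.finite(counts)) || any(counts <= 0))
    oct_error("degenerate_class_error",
              "all class frame counts must be > 0 (got %s)",
              paste(frame_counts, collapse = ", "))
  w <- sum(counts) / (length(counts) * counts)
  names(w) <- names(frame_counts) %||% tissue_classes()[seq_along(counts)]
  w
}

#' Early-stopping controller
#'
#' Scans a validation-loss sequence: training stops at the first epoch at
#' which the loss has not reached a new strict minimum for `patience`
#' consecutive epochs; the best epoch is the argmin seen.
#'
#' @param val_losses numeric vector of per-epoch validation losses.
#' @param patience stagnant epochs tolerated.
#' @return list with `best_epoch` and `stop_epoch` (`NA` if never
#'   triggered within the sequence).
#' @export
early_stop_epoch <- function(val_losses, patience = 10L) {
  best <- Inf; best_epoch <- NA_integer_; wait <- 0L; stop_epoch <- NA_integer_
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stop_epoch <- e; break }
    }
  }
  list(best_epoch = best_epoch, stop_epoch = stop_epoch)
}

weighted_ce <- function(probs, y_idx, w) {
  p <- pmax(probs[cbind(seq_along(y_idx), y_idx)], 1e-12)
  mean(w[y_idx] * (-log(p)))
}

snapshot_model <- function(model) {
  list(params = model$env$params, state = model$env$state)
}

restore_model <- function(model, snap) {
  model$env$params <- snap$params
  model$env$state <- snap$state
  invisible(model)
}

#' Train the classifier
#'
#' Minimizes class-weighted categorical cross-entropy by minibatch SGD with
#' momentum, augmenting training frames only, evaluating the validation set
#' each epoch, and early-stopping on stagnant validation loss with
#' best-epoch weight restoration. Training and validation volume sets must
#' be disjoint (hard leakage error otherwise).
#'
#' @param model an `oct_model` (modified in place and returned).
#' @param train_fs,val_fs [frame_set()]s.
#' @param config a [train_config()].
#' @param class_weights named weights (default: inverse-frequency weights of
#'   the training counts).
#' @param verbose print per-epoch progress.
#' @return list with `model` and `history` (data frame epoch, train_loss,
#'   val_loss, val_accuracy; attribute `best_epoch`).
#' @export
train_classifier <- function(model, train_fs, val_fs, config = train_config(),
                             class_weights = NULL, verbose = FALSE) {
  assert_no_leakage(train_fs$volume_id, val_fs$volume_id)
  n <- n_frames(train_fs)
  counts <- table(train_fs$labels)
  if (is.null(class_weights)) class_weights <- compute_class_weights(counts)
  w <- as.numeric(class_weights[tissue_classes()])
  y <- as.integer(train_fs$labels)
  yv <- as.integer(val_fs$labels)
  onehot <- diag(model$config$n_classes)

  vel <- lapply(model$env$params, function(p) p * 0)
  kernel <- stats::setNames(grepl("_w$", names(model$env$params)),
                            names(model$env$params))
  l2 <- config$l2_coefficient
  lr <- config$learning_rate; mom <- config$momentum

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  best <- Inf; best_epoch <- NA_integer_; best_snap <- NULL; wait <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    eseed <- derive_seed(config$seed, "epoch", epoch)
    batch_losses <- with_seed(eseed, {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (b0 in seq(1L, n, by = config$batch_size)) {
        idx <- perm[b0:min(n, b0 + config$batch_size - 1L)]
        nb <- length(idx)
        xb <- train_fs$x[, , idx, drop = FALSE]
        if (config$augment) {
          for (j in seq_len(nb)) {
            aseed <- sample.int(2^31 - 2, 1)
            xb[, , j] <- augment(xb[, , j], aseed, config$augment_bounds)
          }
        }
        fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
        yb <- y[idx]
        losses <- c(losses, weighted_ce(fw$probs, yb, w))
        dlogits <- (fw$probs - onehot[yb, , drop = FALSE]) * (w[yb] / nb)
        bw <- model_backward(model, fw$cache, dlogits)
        params <- model$env$params
        for (nm in names(bw$grads)) {
          g <- bw$grads[[nm]]
          if (kernel[nm] && l2 > 0) g <- g + 2 * l2 * params[[nm]]
          vel[[nm]] <- mom * vel[[nm]] - lr * g
          pnew <- params[[nm]] + vel[[nm]]
          if (grepl("_alpha$", nm)) pnew <- max(pnew, 0)
          params[[nm]] <- pnew
        }
        model$env$params <- params
      }
      losses
    })
    vp <- predict_proba(model, val_fs)
    # class weights shape the training gradients only; validation loss for
    # early stopping is plain categorical cross-entropy
    val_loss <- weighted_ce(vp, yv, rep(1, length(w)))
    val_acc <- mean(max.col(vp, ties.method = "first") == yv)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(batch_losses),
      val_loss = val_loss, val_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, mean(batch_losses), val_loss, val_acc))
    if (val_loss < best) {
      best <- val_loss; best_epoch <- epoch; wait <- 0L
      best_snap <- snapshot_model(model)
    } else {
      wait <- wait + 1L
      if (wait >= config$patience_epochs) break
    }
  }
  if (!is.null(best_snap)) restore_model(model, best_snap)
  model$env$trained <- TRUE
  attr(history, "best_epoch") <- best_epoch
  log_event("info", "train", "trained %d epochs (best %d, val loss %.4f)",
            nrow(history), best_epoch, best)
  list(model = model, history = history)
}

#' Mean and standard deviation of fold accuracies
#' @param acc numeric vector of per-fold accuracies.
#' @return named vector `c(mean, sd)` (sample standard deviation).
#' @export
fold_accuracy_summary <- function(acc) {
  c(mean = mean(acc), sd = if (length(acc) > 1) sd(acc) else 0)
}

#' Cross-validated training
#'
#' Trains one model per fold (fold `k` is the validation set), evaluates
#' each fold model on its validation fold and on the untouched holdout
#' frames, and summarizes fold accuracies as mean +/- sd. The leakage
#' guarantee is asserted for every fold and for the holdout.
#'
#' @param train_pool_fs training-pool [frame_set()].
#' @param holdout_fs holdout [frame_set()] (may have zero frames).
#' @param plan a [split_by_volume()] plan.
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param verbose print progress.
#' @return list with `folds` (per-fold model, history, val/holdout
#'   [eval_report]s) and `summary`.
#' @export
run_cross_validation <- function(train_pool_fs, holdout_fs, plan,
                                 config = model_config(),
                                 tconfig = train_config(), verbose = FALSE) {
  folds <- sort(unique(plan$fold_of_volume))
  out <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    val_vols <- names(plan$fold_of_volume)[plan$fold_of_volume == folds[k]]
    val_idx <- train_pool_fs$volume_id %in% val_vols
    train_fs <- subset_frames(train_pool_fs, !val_idx)
    val_fs <- subset_frames(train_pool_fs, val_idx)
    assert_no_leakage(train_fs$volume_id, val_fs$volume_id)
    if (n_frames(holdout_fs) > 0)
      assert_no_leakage(train_fs$volume_id, holdout_fs$volume_id)
    tc <- tconfig
    tc$seed <- derive_seed(tconfig$seed, "fold", k)
    model <- build_model(config, seed = tc$seed)
    fit <- train_classifier(model, train_fs, val_fs, tc, verbose = verbose)
    rep_val <- evaluate_frames(fit$model, val_fs)
    rep_hold <- if (n_frames(holdout_fs) > 0)
      evaluate_frames(fit$model, holdout_fs) else NULL
    out[[k]] <- list(fold = folds[k], model = fit$model,
                     history = fit$history, val_report = rep_val,
                     holdout_report = rep_hold)
  }
  val_acc <- vapply(out, function(f) f$val_report$accuracy, 1)
  hold_acc <- if (n_frames(holdout_fs) > 0)
    vapply(out, function(f) f$holdout_report$accuracy, 1) else NULL
  list(folds = out,
       summary = list(val_accuracy = fold_accuracy_summary(val_acc),
                      holdout_accuracy = if (!is.null(hold_acc))
                        fold_accuracy_summary(hold_acc)))
}
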