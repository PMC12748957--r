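# Split construction, full-batch Adam training with the gated early-stopping
# rule, repeated-seed evaluation and the cross-validation driver.

#' Leave-one-subject-out split plan
#'
#' One fold per subject: that subject's windows are the validation set, all
#' other subjects' windows the training set. With 14 subjects and 120
#' windows each this gives 1560 training / 120 validation windows per fold.
#'
#' @param ws A `window_set` (see [make_windows()]).
#' @return An object of class `split_plan` with `mode =
#'   "subject_independent"` and one fold per subject.
#' @export
loso_splits <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  subjects <- unique(ws$meta$subject)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  folds <- lapply(subjects, function(s) {
    val <- which(ws$meta$subject == s)
    list(id = s, train = which(ws$meta$subject != s), val = val)
  })
  structure(list(mode = "subject_independent", folds = folds),
            class = "split_plan")
}

#' Subject-dependent split plan
#'
#' One fold per subject: training on the windows of the subject's first six
#' trials in recorded order (which must contain three fear and three
#' non-fear trials), validation on the remaining four (two and two). With 12
#' windows per trial this is 72 training / 48 validation windows.
#'
#' @param ws A `window_set`.
#' @return A `split_plan` with `mode = "subject_dependent"`.
#' @export
subject_dependent_splits <- function(ws) {
  stopifnot(inherits(ws, "window_set"))
  subjects <- unique(ws$meta$subject)
  folds <- lapply(subjects, function(s) {
    m <- ws$meta$subject == s
    trials <- sort(unique(ws$meta$trial[m]))
    if (length(trials) < 10L)
      stop(sprintf("subject %s has %d trials; the subject-dependent split needs 10",
                   s, length(trials)))
    first6 <- trials[1:6]
    lab6 <- vapply(first6, function(tr)
      ws$meta$label[m & ws$meta$trial == tr][1], character(1))
    if (sum(lab6 == "fear") != 3L)
      stop(sprintf(
        "subject %s: first six trials are %d fear / %d non-fear; need 3/3",
        s, sum(lab6 == "fear"), sum(lab6 != "fear")))
    list(id = s,
         train = which(m & ws$meta$trial %in% first6),
         val = which(m & !(ws$meta$trial %in% first6)))
  })
  structure(list(mode = "subject_dependent", folds = folds),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  f <- x$folds[[1]]
  cat(sprintf("<split_plan %s: %d folds, %d train / %d validation windows>\n",
              x$mode, length(x$folds), length(f$train), length(f$val)))
  invisible(x)
}

#' Training configuration
#'
#' Bundles the optimization settings: full-batch Adam (standard moments
#' beta1 = 0.9, beta2 = 0.999, eps = 1e-8), cross-entropy loss, and the
#' gated early-stopping rule — stop after `patience` epochs without
#' improvement in validation loss, but only once training accuracy has
#' reached `accuracy_gate`. The default learning rate is 0.1 for the
#' subject-independent mode and 0.005 for the (much smaller) subject-
#' dependent training sets.
#'
#' @param mode `"si"` (subject-independent) or `"sd"` (subject-dependent);
#'   sets the default learning rate.
#' @param lr Learning rate override.
#' @param patience Epochs of no validation-loss improvement before stopping.
#' @param accuracy_gate Training accuracy required before early stopping may
#'   trigger.
#' @param max_epochs Hard cap guaranteeing termination when the gate is
#'   never reached.
#' @param n_seeds Number of repeated trainings per fold.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mode = c("si", "sd"), lr = NULL, patience = 5L,
                         accuracy_gate = 0.75, max_epochs = 200L,
                         n_seeds = 10L) {
  mode <- match.arg(mode)
  lr <- lr %||% if (mode == "si") 0.1 else 0.005
  stopifnot(patience >= 1L, accuracy_gate > 0, accuracy_gate < 1,
            max_epochs >= 1L)
  structure(list(mode = mode, lr = lr, patience = as.integer(patience),
                 accuracy_gate = accuracy_gate,
                 max_epochs = as.integer(max_epochs),
                 n_seeds = as.integer(n_seeds),
                 beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
            class = "train_config")
}

#' Gated early-stopping decision
#'
#' Returns `TRUE` iff the best validation loss has not improved (strictly
#' decreased) for `patience` consecutive epochs AND training accuracy has
#' reached `gate` at or before the current epoch. The gate prevents stopping
#' on a validation loss that is small by chance before the model has learned
#' anything.
#'
#' @param history Data frame with columns `train_acc` and `val_loss`, one
#'   row per completed epoch.
#' @param patience Consecutive non-improving epochs required (default 5).
#' @param gate Training-accuracy threshold (default 0.75).
#' @return Logical.
#' @export
should_stop <- function(history, patience = 5L, gate = 0.75) {
  stopifnot(nrow(history) >= 1L)
  if (max(history$train_acc) < gate) return(FALSE)
  best_at <- which.min(history$val_loss)  # first strict minimum
  (nrow(history) - best_at) >= patience
}

#' Fit a PQC classifier by full-batch Adam
#'
#' One gradient step per epoch on the entire training batch, cross-entropy
#' loss on the softmaxed class scores, exact reverse-mode gradients. All
#' randomness (the weight initialization) derives from `seed`, so a fit is
#' bit-reproducible given (seed, data, configuration). Early stopping
#' follows [should_stop()] when validation data is supplied; training
#' otherwise runs to `max_epochs`.
#'
#' @param model A [pqc_model()].
#' @param x Training windows: numeric array (n x channels x 10) of
#'   robust-arctan scaled values (see [apply_robust_arctan()]).
#' @param y Training labels: factor or character (`"fear"`/`"non-fear"`) or
#'   0/1 integers (fear = 1).
#' @param x_val,y_val Optional validation set in the same encoding.
#' @param config A [train_config()].
#' @param seed Integer seed for the weight initialization.
#' @param init Optional explicit initial weights (overrides `seed`).
#' @return An object of class `pqc_fit` with components `model`, `weights`
#'   (at the stopping epoch), `history` (per-epoch losses and accuracies),
#'   `stopped_epoch`, `best_epoch` (lowest validation loss), `seed` and
#'   `config`.
#' @seealso [predict.pqc_fit()], [cross_validate()]
#' @export
pqc_fit <- function(model, x, y, x_val = NULL, y_val = NULL,
                    config = train_config("si"), seed = 0L, init = NULL) {
  stopifnot(inherits(model, "pqc_model"), inherits(config, "train_config"))
  yi <- .encode_labels(y)
  yv <- if (!is.null(y_val)) .encode_labels(y_val) else NULL
  w <- init %||% init_weights(model, seed)
  stopifnot(length(w) == model$n_params)
  m1 <- numeric(length(w)); m2 <- numeric(length(w))
  hist_rows <- vector("list", config$max_epochs)
  stopped <- config$max_epochs
  gate_warn <- TRUE
  for (epoch in seq_len(config$max_epochs)) {
    lg <- .model_loss_grad(model, w, x, yi)
    if (!is.finite(lg$loss))
      stop(sprintf("non-finite training loss at epoch %d", epoch))
    # Adam (standard moments)
    m1 <- config$beta1 * m1 + (1 - config$beta1) * lg$grad
    m2 <- config$beta2 * m2 + (1 - config$beta2) * lg$grad^2
    mh <- m1 / (1 - config$beta1^epoch)
    vh <- m2 / (1 - config$beta2^epoch)
    w <- w - config$lr * mh / (sqrt(vh) + config$eps)
    row <- data.frame(epoch = epoch, train_loss = lg$loss,
                      train_acc = lg$acc, val_loss = NA_real_,
                      val_acc = NA_real_)
    if (!is.null(x_val)) {
      vs <- .model_scores(model, w, x_val)
      vce <- .softmax_ce(vs, yv)
      row$val_loss <- vce$loss
      row$val_acc <- vce$acc
    }
    hist_rows[[epoch]] <- row
    if (!is.null(x_val)) {
      h <- do.call(rbind, hist_rows[seq_len(epoch)])
      if (should_stop(h, config$patience, config$accuracy_gate)) {
        stopped <- epoch
        gate_warn <- FALSE
        break
      }
    }
  }
  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                              logical(1))])
  if (!is.null(x_val) && gate_warn &&
      max(history$train_acc) < config$accuracy_gate)
    warning(sprintf(
      "training stopped at the %d-epoch cap before reaching the %.0f%% accuracy gate",
      config$max_epochs, 100 * config$accuracy_gate))
  structure(list(model = model, weights = w, history = history,
                 stopped_epoch = stopped,
                 best_epoch = if (!is.null(x_val))
                   which.min(history$val_loss) else NA_integer_,
                 seed = seed, config = config,
                 levels = .label_levels(y)),
            class = "pqc_fit")
}

.encode_labels <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% 0:1))
    as.integer(y)
  } else {
    y <- as.character(y)
    stopifnot(all(y %in% c("fear", "non-fear")))
    as.integer(y == "fear")
  }
}

.label_levels <- function(y) {
  if (is.numeric(y)) c("0", "1") else c("non-fear", "fear")
}

.decode_labels <- function(idx, levels) levels[idx + 1L]

#' @export
print.pqc_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<pqc_fit %s: %d epochs, train acc %.3f%s>\n",
              if (x$model$family == "aepqc") "AEPQC"
              else sprintf("QCNN-%s/%s", toupper(x$model$kernel),
                           x$model$fusion),
              x$stopped_epoch, h$train_acc,
              if (!is.na(h$val_acc))
                sprintf(", val acc %.3f", h$val_acc) else ""))
  invisible(x)
}

#' @export
summary.pqc_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("PQC classifier fit (%s), seed %d\n",
              if (object$model$family == "aepqc") "AEPQC"
              else sprintf("QCNN-%s, %s fusion",
                           toupper(object$model$kernel),
                           object$model$fusion),
              object$seed))
  cat(sprintf("  trainable parameters: %d\n", object$model$n_params))
  cat(sprintf("  epochs run: %d (cap %d)\n", object$stopped_epoch,
              object$config$max_epochs))
  cat(sprintf("  final train loss %.4f, accuracy %.3f\n",
              h$train_loss[nrow(h)], h$train_acc[nrow(h)]))
  if (!is.na(object$best_epoch))
    cat(sprintf(
      "  validation: acc %.3f at stop, best loss %.4f at epoch %d (acc %.3f)\n",
      h$val_acc[nrow(h)], h$val_loss[object$best_epoch], object$best_epoch,
      h$val_acc[object$best_epoch]))
  invisible(object)
}

#' @export
coef.pqc_fit <- function(object, ...) object$weights

#' Predict from a fitted PQC classifier
#'
#' @param object A [pqc_fit()].
#' @param newdata Scaled window array (n x channels x 10).
#' @param type `"class"` (predicted labels), `"score"` (raw Z-expectation
#'   class scores in \eqn{[-1,1]}) or `"prob"` (softmax probabilities).
#' @param ... Unused.
#' @return Predictions of the requested type; columns of score/prob
#'   matrices follow the class order (non-fear, fear).
#' @export
predict.pqc_fit <- function(object, newdata,
                            type = c("class", "score", "prob"), ...) {
  type <- match.arg(type)
  scores <- .model_scores(object$model, object$weights, newdata)
  if (type == "score") return(scores)
  if (type == "prob") {
    e <- exp(scores - pmax(scores[, 1], scores[, 2]))
    return(e / rowSums(e))
  }
  .decode_labels(max.col(scores, ties.method = "first") - 1L,
                 object$levels)
}

#' @export
plot.pqc_fit <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = ylim, ...)
  if (!all(is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Repeat a fold's training from several seeds
#'
#' Retrains the same fold once per seed and summarizes the spread of the
#' validation accuracy (mean and standard deviation), quantifying the
#' sensitivity of small validation sets to the random initialization.
#'
#' @param model A [pqc_model()].
#' @param x,y,x_val,y_val Fold data as in [pqc_fit()].
#' @param config A [train_config()].
#' @param seeds Integer seeds (default `0:9`).
#' @return An object of class `pqc_repeats`: list of fits plus a `summary`
#'   data frame.
#' @export
run_repeats <- function(model, x, y, x_val, y_val,
                        config = train_config("si"), seeds = 0:9) {
  fits <- lapply(seeds, function(s)
    pqc_fit(model, x, y, x_val, y_val, config, seed = s))
  acc <- vapply(fits, function(f)
    f$history$val_acc[nrow(f$history)], numeric(1))
  structure(list(fits = fits,
                 summary = data.frame(seed = seeds, val_acc = acc),
                 mean = mean(acc), sd = if (length(acc) > 1) sd(acc) else 0),
            class = "pqc_repeats")
}

#' @export
print.pqc_repeats <- function(x, ...) {
  cat(sprintf("<pqc_repeats: %d seeds, val acc %.2f%% (%.2f%%)>\n",
              nrow(x$summary), 100 * x$mean, 100 * x$sd))
  invisible(x)
}

# ---- cross-validation driver ---------------------------------------------

#' Cross-validate a PQC classifier on a trial set
#'
#' Runs the full protocol: restrict trials to the 3-15 s analysis window,
#' cut 12 windows of 10 samples per trial, build the split plan
#' (leave-one-subject-out or subject-dependent), then per fold: fit the
#' robust scaler on the training windows only, scale both sides, for AEPQC
#' prune the 2 least label-correlated channels (scored on training windows
#' only), and train once per seed. Reports per-fold validation accuracies,
#' the pooled confusion matrix, and the Wilson-score chance threshold for
#' the fold's validation size.
#'
#' @param trials A [trial_set()] of full-length trials.
#' @param model A [pqc_model()].
#' @param mode `"si"` or `"sd"`.
#' @param seeds Integer seeds per fold.
#' @param config Optional [train_config()] override.
#' @param folds Optional subset of fold indices (all by default).
#' @param importance If `TRUE`, compute the occlusion channel importance of
#'   each fold's first-seed model on its validation batch.
#' @param verbose Print per-fold progress.
#' @return An object of class `pqc_cv`: `results` (fold x seed accuracy
#'   table), `table` (per-subject mean/SD plus a Mean row), `confusion`
#'   (pooled, from each fold's first seed), `threshold` (per-cent minimum
#'   significant accuracy), `importance` (subjects x channels matrix or
#'   `NULL`), and the fitted artifacts of the last fold.
#' @export
cross_validate <- function(trials, model, mode = c("si", "sd"),
                           seeds = 0:9, config = NULL, folds = NULL,
                           importance = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(trials, "trial_set"), inherits(model, "pqc_model"))
  config <- config %||% train_config(mode)
  ws <- make_windows(extract_analysis_window(trials))
  plan <- if (mode == "si") loso_splits(ws) else subject_dependent_splits(ws)
  use <- folds %||% seq_along(plan$folds)
  res <- NULL
  conf_counts <- matrix(0, 2, 2,
                        dimnames = list(true = c("fear", "non-fear"),
                                        pred = c("fear", "non-fear")))
  imp <- NULL
  n_val <- length(plan$folds[[use[1]]]$val)
  for (fi in use) {
    fold <- plan$folds[[fi]]
    tr_ws <- subset_windows(ws, fold$train)
    va_ws <- subset_windows(ws, fold$val)
    scaler <- fit_robust_scaler(tr_ws)
    tr_s <- apply_robust_arctan(tr_ws, scaler)
    va_s <- apply_robust_arctan(va_ws, scaler)
    if (model$family == "aepqc") {
      sel <- select_channels_pearson(tr_s, n_drop = 2L)
      tr_s <- select_window_channels(tr_s, sel$keep)
      va_s <- select_window_channels(va_s, sel$keep)
    }
    for (s in seeds) {
      fit <- pqc_fit(model, tr_s$x, tr_s$meta$label, va_s$x,
                     va_s$meta$label, config, seed = s)
      acc <- fit$history$val_acc[nrow(fit$history)]
      res <- rbind(res, data.frame(fold = fold$id, seed = s,
                                   val_acc = acc,
                                   epochs = fit$stopped_epoch))
      if (s == seeds[1]) {
        pred <- predict(fit, va_s$x)
        ac <- accuracy_and_confusion(pred, va_s$meta$label)
        conf_counts <- conf_counts + ac$counts
        if (importance) {
          iv <- occlusion_importance(fit, va_s$x,
                                     channels = va_s$channels)
          row <- stats::setNames(rep(NA_real_, dim(ws$x)[2]),
                                 paste0("ch", ws$channels))
          row[paste0("ch", va_s$channels)] <- iv
          imp <- rbind(imp, row)
        }
      }
      if (verbose)
        cat(sprintf("fold %s seed %d: val acc %.3f (%d epochs)\n",
                    fold$id, s, acc, fit$stopped_epoch))
    }
  }
  rownames(res) <- NULL
  if (!is.null(imp)) rownames(imp) <- vapply(plan$folds[use], `[[`,
                                             character(1), "id")
  structure(list(results = res, table = aggregate_accuracy(res),
                 confusion = .normalize_confusion(conf_counts),
                 confusion_counts = conf_counts,
                 threshold = min_significant_accuracy(n_val),
                 n_val = n_val, importance = imp, mode = mode,
                 model = model, seeds = seeds),
            class = "pqc_cv")
}

#' @export
print.pqc_cv <- function(x, ...) {
  cat(sprintf("Cross-validation (%s), %d folds x %d seeds\n", x$mode,
              length(unique(x$results$fold)), length(x$seeds)))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf(
    "Chance threshold (Wilson 95%%, n = %d): %.2f%%\n", x$n_val,
    x$threshold))
  invisible(x)
}
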