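# Accuracy, confusion matrices, the Wilson-score chance threshold and
# occlusion-based channel importance.

#' Lower bound of the Wilson score interval
#'
#' \deqn{b_l = \frac{1}{1 + z^2/n}\left(\hat p + \frac{z^2}{2n}\right) -
#'   \frac{z}{1 + z^2/n}\sqrt{\frac{\hat p (1-\hat p)}{n} +
#'   \frac{z^2}{4n^2}}}
#'
#' With a finite validation set, an accuracy above 50% is only evidence of
#' better-than-chance classification when this lower bound exceeds 0.5.
#'
#' @param p_hat Estimated accuracy in `[0, 1]` (vectorized).
#' @param n Sample count (>= 1).
#' @param z Normal critical value; default `qnorm(0.975)` = 1.959964 for
#'   95% confidence.
#' @return The lower confidence bound(s).
#' @examples
#' wilson_lower_bound(0.5895, 120)  # just above 0.5
#' @export
wilson_lower_bound <- function(p_hat, n, z = stats::qnorm(0.975)) {
  if (length(n) != 1L || n < 1) stop("n must be a single count >= 1")
  stopifnot(all(p_hat >= 0 & p_hat <= 1))
  denom <- 1 + z^2 / n
  (p_hat + z^2 / (2 * n)) / denom -
    (z / denom) * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2))
}

#' Minimum accuracy significantly better than chance
#'
#' The smallest accuracy, on a grid of 0.01 percentage points, whose Wilson
#' lower bound exceeds 50% at the given confidence level. For the two
#' validation sizes of the cross-validation protocol this evaluates to
#' 58.95% (n = 120) and 64.15% (n = 48).
#'
#' @param n Validation sample count.
#' @param confidence Confidence level (default 0.95).
#' @param grid Grid step in percentage points (default 0.01).
#' @return The threshold in percent.
#' @examples
#' min_significant_accuracy(120)  # 58.95
#' @export
min_significant_accuracy <- function(n, confidence = 0.95, grid = 0.01) {
  stopifnot(n >= 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  acc <- seq(50, 100, by = grid)
  ok <- wilson_lower_bound(acc / 100, n, z) > 0.5
  if (!any(ok)) stop("no accuracy on the grid clears the bound")
  acc[which(ok)[1]]
}

#' Accuracy and normalized confusion matrix
#'
#' @param predictions Predicted labels (`"fear"`/`"non-fear"` or 0/1,
#'   fear = 1).
#' @param labels True labels, same encoding and length.
#' @return List with `accuracy`, `counts` (2x2, rows = true class) and
#'   `normalized` (rows divided by true-class counts).
#' @export
accuracy_and_confusion <- function(predictions, labels) {
  if (length(predictions) == 0L) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  p <- .encode_labels(predictions)
  y <- .encode_labels(labels)
  lv <- c("fear", "non-fear")
  counts <- table(true = factor(ifelse(y == 1L, "fear", "non-fear"), lv),
                  pred = factor(ifelse(p == 1L, "fear", "non-fear"), lv))
  counts <- unclass(counts)
  list(accuracy = mean(p == y), counts = counts,
       normalized = .normalize_confusion(counts))
}

.normalize_confusion <- function(counts) {
  rs <- rowSums(counts)
  sweep(counts, 1, ifelse(rs == 0, 1, rs), "/")
}

#' Occlusion-based channel importance
#'
#' For each channel, zeroes that channel in every input of the batch (in the
#' scaled representation the model consumes), recomputes the model output,
#' and takes the mean over batch elements and output components of the
#' absolute difference from the baseline output; importances are normalized
#' to sum to one. If no channel changes the output the importances are
#' degenerate-uniform (with a warning).
#'
#' @param fit A [pqc_fit()] (or any object with `model` and `weights`).
#' @param x Scaled window array (n x channels x 10) — typically the
#'   validation batch of the fold the model was trained on.
#' @param channels Optional 1-based channel labels for naming.
#' @param output `"score"` uses the pre-softmax class scores (default);
#'   `"prob"` the softmax probabilities.
#' @return Named non-negative vector over channels, summing to 1.
#' @export
occlusion_importance <- function(fit, x, channels = NULL,
                                 output = c("score", "prob")) {
  output <- match.arg(output)
  stopifnot(length(dim(x)) == 3L, dim(x)[1] >= 1L)
  C <- dim(x)[2]
  channels <- channels %||% seq_len(C)
  out_of <- function(xx) {
    s <- .model_scores(fit$model, fit$weights, xx)
    if (output == "prob") {
      e <- exp(s - pmax(s[, 1], s[, 2]))
      s <- e / rowSums(e)
    }
    s
  }
  base <- out_of(x)
  diffs <- vapply(seq_len(C), function(ch) {
    xm <- x
    xm[, ch, ] <- 0
    mean(abs(base - out_of(xm)))
  }, numeric(1))
  tot <- sum(diffs)
  if (tot == 0) {
    warning("model output is insensitive to every channel; returning uniform importances")
    imp <- rep(1 / C, C)
  } else imp <- diffs / tot
  stats::setNames(imp, channels)
}

#' Per-subject accuracy table with a grand-mean row
#'
#' Aggregates fold x seed validation accuracies into the layout of the
#' cross-validation result tables: one row per subject with the mean and
#' standard deviation (in percent) over seeds, plus a final `Mean` row
#' carrying the mean and SD over the per-subject means.
#'
#' @param results Data frame with columns `fold` and `val_acc` (one row per
#'   fold x seed).
#' @return Data frame with columns `subject`, `mean_acc`, `sd_acc`.
#' @export
aggregate_accuracy <- function(results) {
  stopifnot(nrow(results) >= 1L, all(c("fold", "val_acc") %in%
                                     names(results)))
  subjects <- unique(results$fold)
  per <- do.call(rbind, lapply(subjects, function(s) {
    a <- 100 * results$val_acc[results$fold == s]
    data.frame(subject = as.character(s), mean_acc = mean(a),
               sd_acc = if (length(a) > 1) sd(a) else 0)
  }))
  rbind(per, data.frame(subject = "Mean", mean_acc = mean(per$mean_acc),
                        sd_acc = if (nrow(per) > 1) sd(per$mean_acc) else 0))
}
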