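#' ROC curve of a probability signal against truth labels
#'
#' Sweeps the classification threshold over every distinct probability
#' value plus `-Inf`/`+Inf` sentinels, using the strict rule
#' "predict motion iff probability > threshold". Sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP); the AUC is the trapezoidal area
#' under sensitivity versus 1 - specificity, which equals the
#' Mann-Whitney concordance probability (ties credited 1/2). The optimal
#' operating point maximizes the mean of sensitivity and specificity,
#' ties resolved toward the lower threshold (higher sensitivity).
#'
#' @param probs Numeric vector of per-second motion probabilities, or a
#'   `probability_signal` from [predict_proba()].
#' @param labels Integer 0/1 truth labels, same length.
#' @param id Optional clip identity, included in error messages.
#' @return An object of class `roc_result`: list with `points` (data
#'   frame of threshold, sensitivity, specificity, ordered by threshold),
#'   `auc`, `optimal` (the selected point) and `optimal_threshold`.
#' @export
roc_curve <- function(probs, labels, id = NULL) {
  if (inherits(probs, "probability_signal")) probs <- probs$probs
  if (length(probs) != length(labels))
    stop("probs and labels differ in length")
  if (length(unique(labels)) < 2)
    stop("single-class labels: ROC undefined",
         if (!is.null(id)) paste0(" (clip ", id, ")") else "")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")

  o <- order(probs, decreasing = TRUE)
  ps <- probs[o]
  ys <- labels[o]
  P <- sum(ys == 1)
  N <- sum(ys == 0)
  cum_tp <- cumsum(ys == 1)
  cum_fp <- cumsum(ys == 0)
  first <- which(!duplicated(ps))          # first occurrence, values descending
  vals <- ps[first]
  # threshold = v classifies strictly greater probabilities as motion,
  # i.e. everything before the first occurrence of v in descending order
  tp <- c(0, cum_tp)[first]
  fp <- c(0, cum_fp)[first]

  threshold <- c(-Inf, rev(vals), Inf)
  sens <- c(1, rev(tp) / P, 0)
  fpr <- c(1, rev(fp) / N, 0)
  points <- data.frame(threshold = threshold, sensitivity = sens,
                       specificity = 1 - fpr)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)

  # mean of sensitivity and specificity, scored in exact integer
  # arithmetic (tp * N + tn * P) so ties break deterministically toward
  # the lower threshold
  tp_all <- c(P, rev(tp), 0)
  tn_all <- N - c(N, rev(fp), 0)
  score <- tp_all * N + tn_all * P
  best <- which(score == max(score))[1]    # ties -> lowest threshold
  structure(
    list(points = points, auc = auc, n_pos = P, n_neg = N,
         optimal = points[best, , drop = FALSE],
         optimal_threshold = points$threshold[best]),
    class = "roc_result"
  )
}

#' Optimal operating threshold of a ROC curve
#'
#' The swept threshold maximizing the mean of sensitivity and
#' specificity, ties broken toward the lower threshold (exact tied
#' scores are resolved in integer arithmetic).
#'
#' @param roc A `roc_result` from [roc_curve()].
#' @return The selected threshold (scalar).
#' @export
optimal_threshold <- function(roc) {
  tp <- round(roc$points$sensitivity * roc$n_pos)
  tn <- round(roc$points$specificity * roc$n_neg)
  score <- tp * roc$n_neg + tn * roc$n_pos
  roc$points$threshold[which(score == max(score))[1]]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result: AUC %.4f, optimal threshold %.4f (sens %.3f, spec %.3f), %d points>\n",
    x$auc, x$optimal_threshold, x$optimal$sensitivity,
    x$optimal$specificity, nrow(x$points)))
  invisible(x)
}

# Sensitivity and specificity of `probs > threshold` against labels.
sens_spec_at <- function(probs, labels, threshold) {
  pred <- probs > threshold
  c(sensitivity = sum(pred & labels == 1) / sum(labels == 1),
    specificity = sum(!pred & labels == 0) / sum(labels == 0))
}
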