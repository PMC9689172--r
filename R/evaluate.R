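#' Aggregate per-segment votes into a frame decision
#'
#' A frame of 1024 x L signals yields L per-segment class predictions; the
#' frame-level score is the positive vote fraction and the frame is called
#' positive only under a strict majority (vote fraction greater than 0.5, so
#' an exact tie is a negative call).
#'
#' @param segment_labels Integer 0/1 vector of per-segment predictions.
#' @return List with `n_segments`, `votes_positive`, `vote_fraction`,
#'   `predicted_label`.
#' @examples
#' aggregate_votes(c(rep(1, 128), rep(0, 128)))$predicted_label  # tie -> 0
#' @export
aggregate_votes <- function(segment_labels) {
  segment_labels <- as.integer(segment_labels)
  if (length(segment_labels) == 0L) stop("no segment votes to aggregate")
  if (!all(segment_labels %in% 0:1)) stop("segment votes must be 0/1")
  n <- length(segment_labels)
  vp <- sum(segment_labels)
  frac <- vp / n
  list(n_segments = n, votes_positive = vp, vote_fraction = frac,
       predicted_label = as.integer(frac > 0.5))
}

#' Majority-vote prediction for one frame window
#'
#' Runs the network on every A-line segment of a normalized window and
#' aggregates the per-segment predictions with [aggregate_votes()]. When the
#' true label is supplied, the fraction of correct segment predictions
#' `p = nC / (nC + nW)` is also reported.
#'
#' @param object A fitted [fibrocnn()] model.
#' @param window Normalized window matrix (`input_len` x L).
#' @param true_label Optional 0/1 frame label.
#' @param case_id Optional case identifier carried into the result.
#' @param score `"vote"` (default) scores the frame by its positive vote
#'   fraction; `"mean_prob"` by the mean softmax probability of class 1.
#' @return An object of class `frame_prediction`: list with `case_id`,
#'   `n_segments`, `votes_positive`, `vote_fraction`, `score`,
#'   `predicted_label`, and `p_correct` (NA without a true label).
#' @export
predict_frame <- function(object, window, true_label = NULL, case_id = "",
                          score = c("vote", "mean_prob")) {
  score <- match.arg(score)
  stopifnot(is.matrix(window))
  if (ncol(window) == 0L) stop("window has no A-lines to predict")
  segs <- frame_to_segments(window, window_axial = object$config$input_len)
  cls <- predict(object, segs, type = "class")
  agg <- aggregate_votes(cls)
  sc <- if (score == "vote") agg$vote_fraction else
    mean(predict(object, segs, type = "prob")[, 2L])
  p_correct <- NA_real_
  if (!is.null(true_label))
    p_correct <- mean(cls == as.integer(true_label))
  structure(c(list(case_id = case_id), agg,
              list(score = sc, p_correct = p_correct)),
            class = "frame_prediction")
}

#' @export
print.frame_prediction <- function(x, ...) {
  cat(sprintf("<frame_prediction>%s %d/%d positive votes (p = %.3f) -> class %d\n",
              if (nzchar(x$case_id)) paste0(" [", x$case_id, "]") else "",
              x$votes_positive, x$n_segments, x$vote_fraction,
              x$predicted_label))
  invisible(x)
}

#' Confusion counts for binary frame predictions
#'
#' @param predicted,truth Integer 0/1 vectors of equal length; label 1 (the
#'   higher-fibrosis group) is the positive class.
#' @return Named integer vector `c(TP, TN, FP, FN)` of class
#'   `confusion_counts`.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(c(predicted, truth) %in% 0:1)) stop("labels must be 0/1")
  structure(c(TP = sum(predicted == 1L & truth == 1L),
              TN = sum(predicted == 0L & truth == 0L),
              FP = sum(predicted == 1L & truth == 0L),
              FN = sum(predicted == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity, specificity
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`,
#' `SPE = TN/(TN+FP)`.
#'
#' @param cm A [confusion_counts()] vector (or any named vector with TP, TN,
#'   FP, FN).
#' @param strict If TRUE (default) a zero denominator is an error naming the
#'   metric; if FALSE the metric is NA.
#' @return Named numeric vector `c(ACC, SEN, SPE)`.
#' @export
classification_metrics <- function(cm, strict = TRUE) {
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(cm))) stop("cm must carry TP, TN, FP, FN")
  cm <- as.numeric(cm[need]); names(cm) <- need
  ratio <- function(num, den, metric) {
    if (den == 0) {
      if (strict) stop(sprintf("%s undefined: zero denominator", metric))
      return(NA_real_)
    }
    unname(num / den)
  }
  c(ACC = ratio(cm["TP"] + cm["TN"], sum(cm), "ACC"),
    SEN = ratio(cm["TP"], cm["TP"] + cm["FN"], "SEN"),
    SPE = ratio(cm["TN"], cm["TN"] + cm["FP"], "SPE"))
}

#' ROC curve and AUC for frame scores
#'
#' Sweeps a decision threshold over the unique frame scores (a frame is
#' called positive when its score is at or above the threshold), yielding
#' the ROC from (0,0) to (1,1), and integrates the area by the trapezoidal
#' rule. This equals the Mann-Whitney two-sample statistic
#' `P(score_pos > score_neg) + 0.5 * P(equal)`. The 95% confidence interval
#' uses DeLong's method (via pROC); `ci_method = "bootstrap"` switches to a
#' stratified bootstrap.
#'
#' @param scores Numeric frame scores (e.g. vote fractions), higher =
#'   more likely positive.
#' @param labels Integer 0/1 truth; both classes must be present.
#' @param ci Compute the 95% CI (default TRUE).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @return List of class `roc_report`: `auc`, `auc_ci95` (lo/hi), and `roc`,
#'   a data.frame with `threshold`, `fpr`, `tpr` (monotone non-decreasing).
#' @examples
#' roc_auc(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0), ci = FALSE)$auc
#' @export
roc_auc <- function(scores, labels, ci = TRUE,
                    ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% 0:1)) stop("labels must be 0/1")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes in the evaluated set")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  auc_ci <- c(NA_real_, NA_real_)
  if (ci) {
    suppressMessages(suppressWarnings({
      # suppresses pROC's advisory on degenerate (AUC == 1) intervals
      r <- pROC::roc(response = labels, predictor = scores,
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      ci_obj <- pROC::ci.auc(r, method = if (ci_method == "delong")
        "delong" else "bootstrap", boot.n = 2000)
    }))
    auc_ci <- as.numeric(ci_obj)[c(1L, 3L)]
  }
  structure(list(auc = auc, auc_ci95 = auc_ci, roc = roc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("<roc_report> AUC = %.3f", x$auc))
  if (!anyNA(x$auc_ci95))
    cat(sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci95[1], x$auc_ci95[2]))
  cat(sprintf("; %d positive / %d negative frames\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate a fitted model on a set of windows
#'
#' Convenience wrapper: majority-vote prediction for each window, confusion
#' counts, ACC/SEN/SPE, and (when both classes are present) ROC/AUC over the
#' frame scores.
#'
#' @param object A fitted [fibrocnn()] model.
#' @param windows List of normalized windows.
#' @param labels Integer 0/1 frame labels.
#' @param case_ids Optional case identifiers.
#' @param score Frame score type, see [predict_frame()].
#' @param strict Passed to [classification_metrics()].
#' @return List of class `metrics_report`: `frames` (data.frame of per-frame
#'   predictions), `confusion`, `metrics`, `roc` (a `roc_report` or NULL).
#' @export
evaluate_windows <- function(object, windows, labels, case_ids = NULL,
                             score = c("vote", "mean_prob"), strict = FALSE) {
  score <- match.arg(score)
  stopifnot(length(windows) == length(labels))
  if (is.null(case_ids)) case_ids <- sprintf("w%03d", seq_along(windows))
  preds <- lapply(seq_along(windows), function(i)
    predict_frame(object, windows[[i]], true_label = labels[i],
                  case_id = case_ids[i], score = score))
  frames <- data.frame(case_id = case_ids, label = as.integer(labels),
                       score = vapply(preds, `[[`, numeric(1), "score"),
                       vote_fraction = vapply(preds, `[[`, numeric(1), "vote_fraction"),
                       predicted = vapply(preds, `[[`, integer(1), "predicted_label"),
                       p_correct = vapply(preds, `[[`, numeric(1), "p_correct"),
                       stringsAsFactors = FALSE)
  cm <- confusion_counts(frames$predicted, frames$label)
  metrics <- classification_metrics(cm, strict = strict)
  roc <- NULL
  if (length(unique(frames$label)) == 2L)
    roc <- roc_auc(frames$score, frames$label)
  structure(list(frames = frames, confusion = cm, metrics = metrics,
                 roc = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d frames: TP %d TN %d FP %d FN %d\n",
              sum(x$confusion), x$confusion["TP"], x$confusion["TN"],
              x$confusion["FP"], x$confusion["FN"]))
  m <- x$metrics
  cat(sprintf("  ACC %.4f  SEN %s  SPE %s\n", m["ACC"],
              ifelse(is.na(m["SEN"]), "NA", sprintf("%.4f", m["SEN"])),
              ifelse(is.na(m["SPE"]), "NA", sprintf("%.4f", m["SPE"]))))
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}
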