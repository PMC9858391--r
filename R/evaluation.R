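# Confusion matrices, per-class metrics and one-vs-rest ROC/AUC.
#
# Metric conventions: rows of the confusion matrix are true classes,
# columns are predictions. Per class c (one-vs-rest): TP = counts[c, c],
# FN = row sum - TP, FP = column sum - TP, TN = remainder;
# Se = TP/(TP+FN), Sp = TN/(TN+FP), Pr = TP/(TP+FP),
# F = 2TP/(2TP+FP+FN), Acc = trace/total. A zero denominator yields NA
# flagged as undefined, never a silent 0.

#' Confusion matrix
#'
#' @param true,pred equal-length label vectors with values in
#'   `class_names`.
#' @param class_names ordered class names.
#' @return a `confusion_matrix`: K x K integer matrix (rows = true,
#'   columns = predicted) with class names on both dimensions.
#' @export
confusion_matrix <- function(true, pred, class_names) {
  if (length(true) != length(pred)) stopf("label vectors differ in length")
  bad <- setdiff(unique(c(true, pred)), class_names)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  counts <- table(factor(true, levels = class_names),
                  factor(pred, levels = class_names))
  m <- matrix(as.integer(counts), nrow = length(class_names),
    dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-class classification metrics from a confusion matrix
#'
#' Computes one-vs-rest sensitivity (Se), specificity (Sp), precision
#' (Pr) and F-score for every class, plus overall accuracy
#' (trace/total). Metrics with a zero denominator are `NA` and flagged
#' in the `undefined` table.
#'
#' @param cm a [confusion_matrix].
#' @return a `metrics_report`: list with `per_class` (data.frame of
#'   class, Se, Sp, Pr, F_score), `accuracy`, `confusion` and
#'   `undefined` (logical data.frame marking zero-denominator metrics).
#' @export
classification_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  if (is.null(k) || k == 0L || total == 0L) stopf("empty confusion matrix")
  classes <- rownames(cm)
  res <- data.frame(class = classes, Se = NA_real_, Sp = NA_real_,
    Pr = NA_real_, F_score = NA_real_, stringsAsFactors = FALSE)
  und <- data.frame(class = classes, Se = FALSE, Sp = FALSE, Pr = FALSE,
    F_score = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    res$Se[i] <- safe_div(tp, tp + fn)
    res$Sp[i] <- safe_div(tn, tn + fp)
    res$Pr[i] <- safe_div(tp, tp + fp)
    res$F_score[i] <- safe_div(2 * tp, 2 * tp + fp + fn)
    und$Se[i] <- (tp + fn) == 0
    und$Sp[i] <- (tn + fp) == 0
    und$Pr[i] <- (tp + fp) == 0
    und$F_score[i] <- (2 * tp + fp + fn) == 0
  }
  structure(list(per_class = res, accuracy = sum(diag(cm)) / total,
    confusion = cm, undefined = und), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-vs-rest ROC curve and AUC
#'
#' Thresholds the given class's probability against all others. Equal
#' scores are grouped (one ROC point per distinct score), and the AUC is
#' the trapezoidal area, which equals the Mann-Whitney probability that
#' a random positive outscores a random negative (ties counted half).
#'
#' @param scores `N x K` probability matrix with class columns (a bare
#'   vector is treated as the positive-class score), columns named.
#' @param true true label vector.
#' @param class the positive class.
#' @return list with `points` (data.frame of threshold, fpr, tpr) and
#'   `auc` (`NA` with `undefined = TRUE` when the class has no positives
#'   or no negatives).
#' @export
roc_auc_ovr <- function(scores, true, class) {
  s <- if (is.matrix(scores)) {
    if (!class %in% colnames(scores)) stopf("no score column for class '%s'", class)
    scores[, class]
  } else {
    scores
  }
  if (length(s) != length(true)) stopf("scores and labels differ in length")
  pos <- true == class
  np <- sum(pos)
  nn <- sum(!pos)
  if (np == 0L || nn == 0L) {
    return(list(points = NULL, auc = NA_real_, undefined = TRUE))
  }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(s[pos] >= t) / np, numeric(1L))
  fpr <- vapply(thr, function(t) sum(s[!pos] >= t) / nn, numeric(1L))
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
    auc = auc, undefined = FALSE)
}

#' Evaluate a trained model on a labeled dataset
#'
#' Predicts with argmax (ties broken toward the lowest class index),
#' then derives the confusion matrix, the per-class metrics and the
#' one-vs-rest AUC of every class.
#'
#' @param model a trained [build_acl()] model (carrying `class_names`).
#' @param dataset a [labeled_dataset] of input-sized images.
#' @return a `metrics_report` with an `AUC` column added to `per_class`
#'   and the score matrix attached as `scores`.
#' @export
evaluate_model <- function(model, dataset) {
  class_names <- model$class_names %||% dataset$class_names
  probs <- predict_proba(model, dataset)
  colnames(probs) <- class_names
  pred <- class_names[max.col(probs, ties.method = "first")]
  true <- dataset_labels(dataset)
  cm <- confusion_matrix(true, pred, class_names)
  rep <- classification_metrics(cm)
  rep$per_class$AUC <- vapply(class_names, function(cl) {
    roc_auc_ovr(probs, true, cl)$auc
  }, numeric(1L))
  rep$scores <- probs
  rep
}

#' Tabulate evaluation reports in the ablation layout
#'
#' Produces one row per (case, ratio, class) with columns in the order
#' Se, Sp, Pr, F_score, Acc; the overall accuracy is repeated on each of
#' a report's class rows. Accepts a single `metrics_report` or an
#' [run_ablation()] result.
#'
#' @param reports a `metrics_report` or `ablation_result`.
#' @param path optional CSV output path.
#' @return a data.frame (written to `path` when given); CSV round-trips
#'   through [read.csv()] without loss.
#' @export
report_tables <- function(reports, path = NULL) {
  case_names <- c(case1 = "No Attention and LSTM Structures",
    case2 = "Only LSTM Structure", case3 = "Only Attention Structure",
    full = "Proposed Approach")
  rows <- list()
  add <- function(case, ratio, seed, rep) {
    pc <- rep$per_class
    rows[[length(rows) + 1L]] <<- data.frame(
      case = case, model = case_names[[case]] %||% case, ratio = ratio,
      seed = seed, class = pc$class, Se = pc$Se, Sp = pc$Sp, Pr = pc$Pr,
      F_score = pc$F_score, Acc = rep$accuracy, stringsAsFactors = FALSE)
  }
  if (inherits(reports, "metrics_report")) {
    add("full", NA_character_, NA_integer_, reports)
  } else if (inherits(reports, "ablation_result")) {
    for (r in reports$records) add(r$variant, r$ratio, r$seed, r$report)
  } else {
    stopf("unsupported reports object")
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
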