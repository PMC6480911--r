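#' Confusion counts for binary predictions
#'
#' @param labels True 0/1 labels.
#' @param states Predicted 0/1 states.
#' @return A list of class `confusion` with TP, TN, FP, FN.
#' @export
confusion <- function(labels, states) {
  stopifnot(length(labels) == length(states),
            all(labels %in% c(0L, 1L)), all(states %in% c(0L, 1L)))
  structure(list(TP = sum(labels == 1L & states == 1L),
                 TN = sum(labels == 0L & states == 0L),
                 FP = sum(labels == 0L & states == 1L),
                 FN = sum(labels == 1L & states == 0L)),
            class = "confusion")
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Threshold metrics from a confusion table
#'
#' Computes accuracy, precision, sensitivity (SE, recall), specificity (SP),
#' F-score and Matthews correlation coefficient:
#' \deqn{Acc = (TP+TN)/n,\quad Precision = TP/(TP+FP),\quad SE = TP/(TP+FN),}
#' \deqn{SP = TN/(TN+FP),\quad Fscore = 2\,Precision\cdot SE/(Precision+SE),}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TN+FN)(TP+FN)(TN+FP)}.}
#' Any metric whose denominator is zero is reported as 0; the affected
#' metric names are returned in the `degenerate` field so the convention is
#' visible.
#'
#' @param c A [confusion()] object.
#' @return A list of class `eval_report`.
#' @export
eval_metrics <- function(c) {
  stopifnot(inherits(c, "confusion"))
  n <- c$TP + c$TN + c$FP + c$FN
  if (n < 1L) stop("empty confusion table")
  precision <- safe_div(c$TP, c$TP + c$FP)
  se <- safe_div(c$TP, c$TP + c$FN)
  sp <- safe_div(c$TN, c$TN + c$FP)
  fscore <- safe_div(2 * precision * se, precision + se)
  mcc_den <- sqrt(as.numeric(c$TP + c$FP) * (c$TN + c$FN) *
                  (c$TP + c$FN) * (c$TN + c$FP))
  mcc <- safe_div(as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN, mcc_den)
  degenerate <- c("Precision", "SE", "SP", "Fscore", "MCC")[
    c(c$TP + c$FP, c$TP + c$FN, c$TN + c$FP, precision + se, mcc_den) == 0]
  structure(list(Acc = (c$TP + c$TN) / n, Precision = precision,
                 SE = se, SP = sp, Fscore = fscore, MCC = mcc,
                 confusion = c, degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  flds <- intersect(c("Acc", "Precision", "SE", "SP", "Fscore", "MCC",
                      "AUC", "AUPR"), names(x))
  vals <- vapply(flds, function(f) x[[f]], numeric(1))
  cat("<eval_report>\n")
  cat(paste(sprintf("  %-9s %.4f", flds, vals), collapse = "\n"), "\n")
  if (length(x$degenerate))
    cat("  (zero-denominator convention applied to:",
        paste(x$degenerate, collapse = ", "), ")\n")
  invisible(x)
}

# Score-grouped ROC/PR points: thresholds descend through the unique scores,
# all ties enter together.
roc_points <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  grp_last <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[grp_last]
  fp <- (seq_along(lab) - cumsum(lab))[grp_last]
  list(tp = c(0, tp), fp = c(0, fp), P = sum(lab), N = sum(1 - lab))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over the score-grouped threshold set (ties enter
#' a threshold together), which equals the Mann-Whitney statistic
#' P(score+ > score-) + 0.5 P(tie).
#'
#' @param labels True 0/1 labels.
#' @param scores Real-valued classifier scores.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(labels, scores) {
  r <- roc_points(labels, scores)
  if (r$P == 0L || r$N == 0L) stop("AUC needs both classes present")
  tpr <- r$tp / r$P; fpr <- r$fp / r$N
  sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}

#' Area under the precision-recall curve
#'
#' Step integration: each increment of recall contributes the precision at
#' that threshold.
#'
#' @inheritParams auc_roc
#' @return AUPR in \[0, 1\].
#' @export
auc_pr <- function(labels, scores) {
  r <- roc_points(labels, scores)
  if (r$P == 0L) stop("AUPR needs positive labels")
  tp <- r$tp[-1L]; fp <- r$fp[-1L]
  recall <- tp / r$P
  precision <- ifelse(tp + fp == 0, 1, tp / (tp + fp))
  sum(diff(c(0, recall)) * precision)
}

#' Full evaluation of probabilistic predictions
#'
#' Thresholded metrics (at `threshold`) plus AUC and AUPR.
#'
#' @param labels True 0/1 labels.
#' @param scores Predicted probabilities.
#' @param threshold State cut-off (default 0.5).
#' @return An `eval_report` with AUC and AUPR fields added.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  rep <- eval_metrics(confusion(labels, as.integer(scores > threshold)))
  rep$AUC <- auc_roc(labels, scores)
  rep$AUPR <- auc_pr(labels, scores)
  rep
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  flds <- intersect(c("Acc", "Precision", "SE", "SP", "Fscore", "MCC",
                      "AUC", "AUPR"), names(x))
  as.data.frame(setNames(lapply(flds, function(f) x[[f]]), flds))
}

#' Skip-k experiment: neighbour informativeness versus distance
#'
#' For each k, trains a classifier on the target cell's [skip_k_features()]
#' alone (2 states + 2 signed distances at rank k in `rank_pair` mode;
#' 4k features in `window` mode) and evaluates on the held-out test
#' chromosomes. Spatially correlated methylation makes close neighbours
#' informative, so the metrics are expected to decline as k grows.
#'
#' @param dataset A [multicell_dataset()].
#' @param k_values Integer vector of ranks (or window widths).
#' @param mode `"rank_pair"` (skip-k1) or `"window"` (skip-k2).
#' @param cell Target cell id; default: first cell.
#' @param split A [split_spec()].
#' @param config A [model_config()].
#' @param seed Seed for the trainer.
#' @return data.frame with one row per k and the metric columns.
#' @export
skip_k_experiment <- function(dataset, k_values, mode = c("rank_pair", "window"),
                              cell = names(dataset$cells)[1L],
                              split = split_spec(), config = model_config(),
                              seed = 1L) {
  mode <- match.arg(mode)
  prof <- dataset$cells[[cell]]
  part_sites <- function(chroms)
    prof$sites[chrom %in% chroms & !is.na(state)]
  tr <- part_sites(split$train_chroms)
  te <- part_sites(split$test_chroms)
  if (nrow(tr) == 0L || nrow(te) == 0L)
    stop("empty train or test partition for cell ", cell)
  skip_mat <- function(sites, k) {
    out <- NULL
    for (cr in unique(sites$chrom)) {
      i <- which(sites$chrom == cr)
      b <- skip_k_features(prof, cr, sites$pos[i],
                           k1 = k, k2 = k, mode = mode)
      if (is.null(out)) out <- matrix(NA_real_, nrow(sites), ncol(b),
                                      dimnames = list(NULL, colnames(b)))
      out[i, ] <- b
    }
    out
  }
  rows <- lapply(k_values, function(k) {
    cfg <- config; cfg$seed <- as.integer(seed)
    model <- train_model(list(x = skip_mat(tr, k), y = tr$state), cfg)
    pred <- predict(model, skip_mat(te, k))
    cbind(k = k, as.data.frame(evaluate_predictions(te$state, pred$prob)))
  })
  do.call(rbind, rows)
}

#' Top-k feature selection sweep
#'
#' Retrains on the `k` most important columns (by aggregated split count)
#' for each requested k and reports held-out accuracy, reproducing the
#' dimension-versus-accuracy analysis used to prune the feature set.
#'
#' @param fm_train,fm_test [build_matrix()] results sharing a manifest.
#' @param importance Importance table from [aggregate_importance()] (or a
#'   named numeric vector).
#' @param k_list Integer vector of dimensions to test.
#' @param config A [model_config()].
#' @return data.frame with columns `dimension`, `Acc`, `AUC`.
#' @export
topk_sweep <- function(fm_train, fm_test, importance, k_list,
                       config = model_config()) {
  if (is.data.frame(importance)) {
    ranked <- importance$feature
  } else {
    ranked <- names(sort(importance, decreasing = TRUE))
  }
  ranked <- ranked[ranked %in% colnames(fm_train$x)]
  rows <- lapply(k_list, function(k) {
    k <- min(k, length(ranked))
    # keep columns in their original matrix order so the full-dimension run
    # reproduces the baseline model exactly
    keep <- intersect(colnames(fm_train$x), ranked[seq_len(k)])
    model <- train_model(list(x = fm_train$x[, keep, drop = FALSE],
                              y = fm_train$y), config)
    pred <- predict(model, fm_test$x[, keep, drop = FALSE])
    data.frame(dimension = k,
               Acc = mean(pred$state == fm_test$y),
               AUC = auc_roc(fm_test$y, pred$prob))
  })
  do.call(rbind, rows)
}
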