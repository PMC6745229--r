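#' Confusion matrix against a designated positive class
#'
#' @param truth,predicted equal-length label vectors (length >= 1).
#' @param positive the label counted as positive.
#' @return an object of class `confusion_matrix` with counts `tp`,
#'   `fp`, `tn`, `fn` and the `positive` label.
#' @export
confusion <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted))
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  if (length(truth) < 1L) stop("need at least one sample", call. = FALSE)
  truth <- as.character(truth) == as.character(positive)
  predicted <- as.character(predicted) == as.character(positive)
  structure(list(tp = sum(truth & predicted),
                 fp = sum(!truth & predicted),
                 tn = sum(!truth & !predicted),
                 fn = sum(truth & !predicted),
                 positive = as.character(positive)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): tp=%d fp=%d tn=%d fn=%d\n",
              x$positive, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, positive predictive value `tp/(tp+fp)` and
#' negative predictive value `tn/(tn+fn)`, all as percentages at full
#' precision (the print method rounds to two decimals). A metric with
#' a zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion()] result, or a numeric vector/list with
#'   entries `tp`, `fp`, `tn`, `fn`.
#' @return an object of class `metric_report`: named list of the five
#'   percentages plus the input counts.
#' @examples
#' classification_metrics(c(tp = 19, fn = 1, tn = 17, fp = 3))
#' @export
classification_metrics <- function(cm) {
  cm <- as.list(cm)
  for (f in c("tp", "fp", "tn", "fn"))
    if (is.null(cm[[f]])) stop(sprintf("missing count `%s`", f), call. = FALSE)
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total < 1) stop("confusion matrix is empty", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 accuracy = ratio(tp + tn, total),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn),
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x[c("sensitivity", "specificity", "accuracy", "ppv", "npv")])
  cat(sprintf("Sens %s  Spec %s  Accu %s  PPV %s  NPV %s  (%%)\n",
              format(round(v[1], 2)), format(round(v[2], 2)),
              format(round(v[3], 2)), format(round(v[4], 2)),
              format(round(v[5], 2))))
  invisible(x)
}

#' Mean squared error
#'
#' `MSE = (1/N) * sum((T_i - O_i)^2)` between targets and obtained
#' outputs.
#'
#' @param targets,outputs equal-length numeric vectors.
#' @return scalar mean squared error.
#' @export
mse <- function(targets, outputs) {
  if (length(targets) != length(outputs))
    stop("`targets` and `outputs` must have equal length", call. = FALSE)
  if (length(targets) < 1L) stop("need at least one value", call. = FALSE)
  mean((as.numeric(targets) - as.numeric(outputs))^2)
}

#' Stratified k-fold evaluation of the selection + PNN pipeline
#'
#' Splits the samples into `k` stratified folds; for each fold a PNN
#' is trained on the other `k - 1` folds and evaluated on the held-out
#' fold. Feature selection can be disabled (`"none"`), run once on the
#' full data before the folds (`"global"`, the one-shot design), or
#' rerun inside every fold on the training portion only (`"per_fold"`,
#' the leakage-safe default when selection is wanted). Headline
#' metrics come from the confusion matrix pooled across folds
#' (micro-average); per-fold metrics are also returned. MSE uses the
#' 0/1 encoding of the positive class against predicted hard labels.
#'
#' @param X numeric feature matrix.
#' @param labels class factor; every class must have at least `k`
#'   samples.
#' @param k number of folds (default 10: 90 percent training, 10
#'   percent testing per fold).
#' @param seed integer seed (fold assignment and selection).
#' @param selection `"none"`, `"per_fold"` or `"global"`.
#' @param ccsa_cfg a [ccsa_config()] used when selection is enabled.
#' @param spread PNN smoothing parameter.
#' @param positive positive class label (default: last factor level).
#' @return an object of class `kfold_report`: pooled `metrics` and
#'   `confusion`, `mse_train` and `mse_test`, per-fold reports in
#'   `folds`, per-fold (or global) `selected` feature indices, and the
#'   evaluation settings.
#' @export
kfold_evaluate <- function(X, labels, k = 10L, seed = 1L,
                           selection = c("none", "per_fold", "global"),
                           ccsa_cfg = ccsa_config(), spread = 0.1,
                           positive = NULL) {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  if (any(table(labels) < k))
    stop(sprintf("every class needs at least k = %d samples", k),
         call. = FALSE)
  positive <- positive %||% levels(labels)[nlevels(labels)]

  folds <- with_seed(seed, make_stratified_folds(labels, k))
  global_sel <- if (selection == "global")
    select_features(X, labels, ccsa_cfg, seed = derive_seed(seed, 1L))
  else NULL

  truth_all <- character(0)
  pred_all <- character(0)
  fold_reports <- vector("list", length(folds))
  selected <- vector("list", length(folds))
  mse_train <- numeric(length(folds))

  for (i in seq_along(folds)) {
    test <- folds[[i]]
    idx <- switch(selection,
      none = seq_len(ncol(X)),
      global = global_sel$selected_idx,
      per_fold = select_features(X[-test, , drop = FALSE], labels[-test],
                                 ccsa_cfg,
                                 seed = derive_seed(seed, i + 1L))$selected_idx)
    selected[[i]] <- idx
    model <- pnn_train(X[-test, idx, drop = FALSE], labels[-test],
                       spread = spread)
    pred_test <- predict(model, X[test, idx, drop = FALSE])
    pred_train <- predict(model, X[-test, idx, drop = FALSE])
    mse_train[i] <- mse(labels[-test] == positive, pred_train == positive)
    cm <- confusion(labels[test], pred_test, positive)
    fold_reports[[i]] <- classification_metrics(cm)
    truth_all <- c(truth_all, as.character(labels[test]))
    pred_all <- c(pred_all, as.character(pred_test))
  }

  pooled_cm <- confusion(truth_all, pred_all, positive)
  structure(list(
    metrics = classification_metrics(pooled_cm),
    confusion = pooled_cm,
    mse_train = mean(mse_train),
    mse_test = mse(truth_all == positive, pred_all == positive),
    folds = fold_reports,
    fold_indices = folds,
    selected = if (selection == "global") global_sel$selected_idx else selected,
    selection = selection,
    global_selection = global_sel,
    k = as.integer(k),
    seed = as.integer(seed),
    positive = positive), class = "kfold_report")
}

#' @export
print.kfold_report <- function(x, ...) {
  cat(sprintf("%d-fold evaluation (selection = %s, positive = %s)\n",
              x$k, x$selection, x$positive))
  print(x$metrics)
  cat(sprintf("MSE: train %.4g, test %.4g\n", x$mse_train, x$mse_test))
  invisible(x)
}
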