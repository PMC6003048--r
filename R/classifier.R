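## One-feature linear threshold classifier on the mean normalized persistent
## entropy of a recording, with ROC/AUC evaluation, a stratified 70/30 split
## plus k-fold cross-validation, a Wilcoxon rank-sum comparison of the two
## classes, and a Sample Entropy baseline feature.

#' Per-recording topological feature
#'
#' For each channel of a (preprocessed) recording: sublevel-set filtration,
#' zero-dimensional persistence, normalized persistent entropy. The
#' one-dimensional feature of the recording is the arithmetic mean of the
#' per-channel values.
#'
#' @param rec A preprocessed \code{\link{recording}}.
#' @return An object of class \code{feature_vector}: list with
#'   \code{per_channel} (one normalized persistent entropy per channel) and
#'   \code{mean}.
#' @export
extract_feature <- function(rec) {
  if (!inherits(rec, "recording") || n_channels(rec) == 0L)
    ts_error("data_error", "rec must be a non-empty recording")
  vals <- vapply(seq_along(rec$channels), function(i) {
    tryCatch(
      normalized_persistent_entropy(persistence_0d(piecewise_filtration(rec$channels[[i]]))),
      toposeize_normalization_error = function(e)
        ts_error("normalization_error",
                 sprintf("channel %d: %s", i, conditionMessage(e))),
      toposeize_entropy_error = function(e)
        ts_error("entropy_error", sprintf("channel %d: %s", i, conditionMessage(e)))
    )
  }, numeric(1))
  structure(list(per_channel = vals, mean = mean(vals)), class = "feature_vector")
}

#' Per-recording Sample Entropy feature (baseline)
#'
#' Mean over channels of SampEn(m, r); the comparator feature for the
#' topological classifier.
#'
#' @param rec A preprocessed \code{\link{recording}}.
#' @param m,r See \code{\link{sample_entropy}}.
#' @return A \code{feature_vector}.
#' @export
extract_sample_entropy_feature <- function(rec, m = 2L, r = NULL) {
  if (!inherits(rec, "recording") || n_channels(rec) == 0L)
    ts_error("data_error", "rec must be a non-empty recording")
  vals <- vapply(rec$channels, sample_entropy, numeric(1), m = m, r = r)
  structure(list(per_channel = vals, mean = mean(vals)), class = "feature_vector")
}

#' Features for a whole dataset
#'
#' @param ds An \code{\link{eeg_dataset}} of labeled, preprocessed
#'   recordings.
#' @param feature \code{"persistent"} (mean normalized persistent entropy)
#'   or \code{"sample"} (mean Sample Entropy).
#' @return Data frame with columns \code{patient_id}, \code{label},
#'   \code{feature}.
#' @export
dataset_features <- function(ds, feature = c("persistent", "sample")) {
  feature <- match.arg(feature)
  if (!inherits(ds, "eeg_dataset")) ts_error("data_error", "ds must be an eeg_dataset")
  f <- switch(feature, persistent = extract_feature,
              sample = extract_sample_entropy_feature)
  data.frame(
    patient_id = vapply(ds$recordings, function(r) r$patient_id, character(1)),
    label = vapply(ds$recordings, function(r) r$label, character(1)),
    feature = vapply(ds$recordings, function(r) f(r)$mean, numeric(1))
  )
}

as_binary_labels <- function(labels, positive) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) < 2L)
    ts_error("training_error", "both classes must be present")
  if (length(cls) > 2L)
    ts_error("training_error", "more than two classes present")
  if (!positive %in% cls)
    ts_error("training_error", sprintf("positive class '%s' not present", positive))
  factor(labels, levels = c(setdiff(cls, positive), positive))
}

#' Fit the linear threshold classifier
#'
#' Chooses the decision threshold maximizing Youden's J = TPR - FPR on the
#' training ROC curve (threshold placed midway between adjacent observed
#' feature values, the ROC convention), and the decision direction from the
#' side of the threshold where the positive class mean lies. When every
#' feature value is identical the model is degenerate: it is flagged
#' (classed warning, \code{degenerate = TRUE}) and predicts the majority
#' class.
#'
#' @param features Numeric feature vector, one value per recording.
#' @param labels Class labels, two distinct values.
#' @param positive Which label is the positive class (default
#'   \code{"epileptic"}).
#' @return An object of class \code{ltc_model}: list with \code{threshold},
#'   \code{direction} (\code{"greater"} = values above the threshold are
#'   positive, else \code{"lesser"}), \code{positive}, \code{degenerate}.
#' @export
fit_ltc <- function(features, labels, positive = "epileptic") {
  y <- as_binary_labels(labels, positive)
  if (length(features) != length(y))
    ts_error("training_error", "features and labels differ in length")
  if (length(unique(features)) == 1L) {
    ts_warning("degenerate_model",
               "all feature values identical: degenerate classifier")
    maj <- names(which.max(table(y)))
    return(structure(list(threshold = features[1L], direction = "greater",
                          positive = positive, degenerate = TRUE,
                          majority = maj),
                     class = "ltc_model"))
  }
  pos_vals <- features[y == positive]
  neg_vals <- features[y != positive]
  direction <- if (mean(pos_vals) >= mean(neg_vals)) "greater" else "lesser"
  r <- pROC::roc(response = y, predictor = features,
                 direction = if (direction == "greater") "<" else ">",
                 levels = levels(y), quiet = TRUE)
  best <- pROC::coords(r, x = "best", best.method = "youden",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1L, , drop = FALSE]  # deterministic pick among J ties
  structure(list(threshold = as.numeric(best$threshold), direction = direction,
                 positive = positive, degenerate = FALSE),
            class = "ltc_model")
}

#' @export
print.ltc_model <- function(x, ...) {
  cat(sprintf("<ltc_model> predict '%s' when feature %s %.4f%s\n",
              x$positive, if (x$direction == "greater") ">" else "<",
              x$threshold, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @rdname fit_ltc
#' @param object An \code{ltc_model}.
#' @param newdata Numeric feature vector.
#' @param ... Unused.
#' @export
predict.ltc_model <- function(object, newdata, ...) {
  if (isTRUE(object$degenerate))
    return(rep(if (object$majority == object$positive) object$positive else
      paste0("not_", object$positive), length(newdata)))
  pos <- if (object$direction == "greater") newdata > object$threshold
         else newdata < object$threshold
  ifelse(pos, object$positive, paste0("not_", object$positive))
}

#' Area under the ROC curve
#'
#' AUC of the feature as a score for the positive class, by the trapezoidal
#' rule over all threshold breakpoints with half credit for ties
#' (equivalently the normalized Mann-Whitney U statistic).
#'
#' @param features Numeric scores.
#' @param labels Two-class labels.
#' @param positive Positive class label.
#' @param direction \code{"greater"} if larger scores indicate the positive
#'   class (default), \code{"lesser"} otherwise.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(features, labels, positive = "epileptic",
                      direction = "greater") {
  y <- tryCatch(as_binary_labels(labels, positive),
                toposeize_training_error = function(e)
                  ts_error("evaluation_error", conditionMessage(e)))
  r <- pROC::roc(response = y, predictor = features,
                 direction = if (direction == "greater") "<" else ">",
                 levels = levels(y), quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' ROC curve points
#'
#' @inheritParams auc_score
#' @return Data frame with columns \code{threshold}, \code{fpr}, \code{tpr},
#'   ordered with nondecreasing fpr.
#' @export
roc_points <- function(features, labels, positive = "epileptic",
                       direction = "greater") {
  y <- tryCatch(as_binary_labels(labels, positive),
                toposeize_training_error = function(e)
                  ts_error("evaluation_error", conditionMessage(e)))
  r <- pROC::roc(response = y, predictor = features,
                 direction = if (direction == "greater") "<" else ">",
                 levels = levels(y), quiet = TRUE)
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  out <- data.frame(threshold = co$threshold, fpr = 1 - co$specificity,
                    tpr = co$sensitivity)
  out[order(out$fpr, out$tpr), , drop = FALSE]
}

#' Evaluate a fitted classifier on labeled features
#'
#' @param features,labels Evaluation data (never used in fitting).
#' @param model An \code{\link{fit_ltc}} model.
#' @return An object of class \code{evaluation_report}: list with
#'   \code{roc} (FPR/TPR points), \code{auc}, \code{confusion} (tp, fp, tn,
#'   fn), \code{accuracy}, \code{model}.
#' @export
evaluate_ltc <- function(features, labels, model) {
  if (!inherits(model, "ltc_model")) ts_error("evaluation_error", "model must be an ltc_model")
  y <- tryCatch(as_binary_labels(labels, model$positive),
                toposeize_training_error = function(e)
                  ts_error("evaluation_error", conditionMessage(e)))
  pred_pos <- predict(model, features) == model$positive
  actual_pos <- y == model$positive
  conf <- c(tp = sum(pred_pos & actual_pos), fp = sum(pred_pos & !actual_pos),
            tn = sum(!pred_pos & !actual_pos), fn = sum(!pred_pos & actual_pos))
  structure(list(
    roc = roc_points(features, labels, model$positive, model$direction),
    auc = auc_score(features, labels, model$positive, model$direction),
    confusion = conf,
    accuracy = (conf[["tp"]] + conf[["tn"]]) / length(features),
    model = model
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC = %.4f, accuracy = %.3f (tp %d, fp %d, tn %d, fn %d)\n",
              x$auc, x$accuracy, x$confusion[["tp"]], x$confusion[["fp"]],
              x$confusion[["tn"]], x$confusion[["fn"]]))
  if (!is.null(x$fold_thresholds))
    cat(sprintf("  %d-fold CV thresholds: %s\n", length(x$fold_thresholds),
                paste(sprintf("%.4f", x$fold_thresholds), collapse = " ")))
  invisible(x)
}

## Seeded RNG scoped to a block, leaving the global stream untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Stratified fold assignment; remainders go to the globally least-loaded
## folds so overall fold sizes differ by at most one.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  load <- integer(k)
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    ord <- order(load, sample.int(k))
    lab <- rep_len(ord, length(idx))
    fold[idx] <- lab
    load <- load + tabulate(lab, k)
  }
  fold
}

#' Split, cross-validate and evaluate the threshold classifier
#'
#' Stratified random 70/30 train/test split (seeded); k-fold
#' cross-validation inside the training portion to gauge threshold
#' stability; a final model fitted on the full training portion and
#' evaluated on the untouched 30% test set. Test labels are never visible
#' to any fitting step.
#'
#' @param features Numeric feature vector.
#' @param labels Two-class labels.
#' @param k Number of folds (default 10).
#' @param train_frac Training fraction of the stratified split (default
#'   0.7).
#' @param seed Integer seed controlling the split and fold assignment.
#' @param positive Positive class label.
#' @return An \code{\link{evaluate_ltc}} report for the held-out test set,
#'   extended with \code{split} (train/test indices), \code{fold_assignments},
#'   \code{fold_thresholds}, \code{fold_aucs} and \code{rank_test} (Wilcoxon
#'   rank-sum on the training features by class).
#' @export
cross_validate <- function(features, labels, k = 10L, train_frac = 0.7,
                           seed = 1L, positive = "epileptic") {
  y <- as_binary_labels(labels, positive)
  n_min <- min(table(y))
  if (k > floor(train_frac * n_min) + 1L && k > n_min)
    ts_error("config_error", "k exceeds the size of the smaller class")
  with_seed(seed, {
    train_idx <- unlist(lapply(levels(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(train_frac * length(idx)))
    }), use.names = FALSE)
    train_idx <- sort(train_idx)
    test_idx <- setdiff(seq_along(y), train_idx)
    y_tr <- droplevels(y[train_idx])
    if (k > min(table(y_tr)))
      ts_error("config_error", "k exceeds the size of the smaller training class")
    fold <- stratified_folds(y_tr, k)
    fold_fit <- lapply(seq_len(k), function(f) {
      tr <- fold != f; te <- fold == f
      m <- fit_ltc(features[train_idx][tr], as.character(y_tr)[tr], positive)
      list(threshold = m$threshold,
           auc = auc_score(features[train_idx][te], as.character(y_tr)[te],
                           positive, m$direction))
    })
    model <- fit_ltc(features[train_idx], as.character(y_tr), positive)
    rep <- evaluate_ltc(features[test_idx], as.character(y[test_idx]), model)
    rep$split <- list(train = train_idx, test = test_idx)
    rep$fold_assignments <- fold
    rep$fold_thresholds <- vapply(fold_fit, `[[`, numeric(1), "threshold")
    rep$fold_aucs <- vapply(fold_fit, `[[`, numeric(1), "auc")
    rep$rank_test <- rank_test(features[train_idx][y_tr == positive],
                               features[train_idx][y_tr != positive])
    rep
  })
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test with normal
#' approximation and tie correction, plus the Hodges-Lehmann estimate of
#' the location shift A - B with its confidence interval.
#'
#' @param a,b Numeric vectors (independent groups).
#' @param conf_level Confidence level for the shift interval.
#' @return List with \code{statistic} (W), \code{p_value}, \code{shift}
#'   (Hodges-Lehmann estimate) and \code{conf_int}.
#' @export
rank_test <- function(a, b, conf_level = 0.95) {
  if (!length(a) || !length(b)) ts_error("data_error", "both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE,
                                            conf.int = TRUE, conf.level = conf_level))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       shift = unname(wt$estimate), conf_int = as.numeric(wt$conf.int))
}
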