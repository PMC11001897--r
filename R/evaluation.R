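# Evaluation: confusion counts, Sn/Sp/ACC/MCC/F1, AUROC, and the two
# assessment protocols (independent 70/30 split, stratified k-fold CV).

#' Confusion counts for binary calls
#'
#' Standard 2x2 tally with class 1 = 6mA site: TP are correctly called
#' sites, TN correctly called non-sites, FP non-sites called as sites and
#' FN sites called as non-sites.
#'
#' @param labels true binary labels (0/1).
#' @param calls predicted binary calls (0/1).
#' @return A `confusion_counts` list with TP, TN, FP, FN.
#' @export
confusion_counts <- function(labels, calls) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (length(labels) != length(calls))
    stop("labels and calls must have equal length", call. = FALSE)
  structure(list(TP = sum(labels == 1L & calls == 1L),
                 TN = sum(labels == 0L & calls == 0L),
                 FP = sum(labels == 0L & calls == 1L),
                 FN = sum(labels == 1L & calls == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/n,
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' F1 = 2TP/(2TP+FP+FN). A metric with a zero denominator is reported as NA
#' with the reason recorded in the `undefined` element, never silently 0.
#'
#' @param counts a `confusion_counts`.
#' @return A `metrics_report` list: Sn, Sp, ACC, MCC, F1, counts, undefined.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, sprintf("%s: zero denominator", name))
      return(NA_real_)
    }
    num / den
  }
  mcc_den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mcc_den == 0) {
    undefined <- c(undefined, "MCC: zero denominator")
    NA_real_
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  structure(list(
    Sn = ratio(TP, TP + FN, "Sn"),
    Sp = ratio(TN, TN + FP, "Sp"),
    ACC = ratio(TP + TN, TP + TN + FP + FN, "ACC"),
    MCC = mcc,
    F1 = ratio(2 * TP, 2 * TP + FP + FN, "F1"),
    counts = counts,
    undefined = undefined), class = "metrics_report")
}

#' AUROC and ROC curve points
#'
#' The area under the ROC curve, computed as the Mann-Whitney probability
#' that a random positive outscores a random negative, with ties counted
#' one half. Curve points (FPR, TPR) are returned for every distinct score
#' threshold.
#'
#' @param labels true binary labels (both classes required).
#' @param scores continuous class-1 scores.
#' @return List with `auc` and `curve` (data.frame fpr, tpr, threshold).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUROC", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- do.call(rbind, lapply(thresholds, function(t) {
    calls <- scores >= t
    data.frame(fpr = sum(calls & labels == 0L) / n_neg,
               tpr = sum(calls & labels == 1L) / n_pos,
               threshold = t)
  }))
  list(auc = auc, curve = curve)
}

#' Independent train/test assessment
#'
#' Splits the dataset stratified by class (default 70/30), encodes both
#' partitions, trains the configured ensemble on the training partition only
#' and reports all metrics plus AUROC on the held-out test partition.
#'
#' @param config an [ensemble_config()].
#' @param ds a `window_dataset`.
#' @param test_fraction held-out proportion (default 0.3).
#' @param seed integer seed (split and training).
#' @return A `metrics_report` with AUROC, ROC curve, protocol bookkeeping
#'   (train/test sizes, id disjointness) and the seed.
#' @export
independent_test <- function(config, ds, test_fraction = 0.3, seed = 1L) {
  parts <- stratified_split(ds, test_fraction, seed)
  train_tab <- encode_dataset(parts$train)
  test_tab <- encode_dataset(parts$test)
  model <- train_ensemble(config, train_tab, train_tab$label)
  scores <- predict_scores(model, test_tab)
  calls <- as.integer(scores >= 0.5)
  rep <- classification_metrics(confusion_counts(test_tab$label, calls))
  roc <- roc_auc(test_tab$label, scores)
  rep$AUROC <- roc$auc
  rep$roc_curve <- roc$curve
  rep$protocol <- list(type = "independent", test_fraction = test_fraction,
                       n_train = nrow(train_tab), n_test = nrow(test_tab),
                       disjoint = length(intersect(parts$train$id,
                                                   parts$test$id)) == 0L)
  rep$config <- unclass(config)
  rep$seed <- as.integer(seed)
  rep
}

#' Stratified k-fold cross-validation
#'
#' Splits the dataset into k stratified folds; each fold is scored once by a
#' model trained on the remaining k-1 folds. Headline metrics are computed
#' from the pooled (micro-averaged) confusion counts and pooled scores;
#' per-fold metrics are retained for dispersion reporting.
#'
#' @param config an [ensemble_config()].
#' @param ds a `window_dataset` with at least k members per class.
#' @param k number of folds (default 10).
#' @param seed integer seed (folds and training).
#' @return A `metrics_report` with pooled metrics, AUROC, `per_fold` metric
#'   rows and protocol bookkeeping.
#' @export
kfold_cv <- function(config, ds, k = 10L, seed = 1L) {
  tab <- encode_dataset(ds)
  folds <- stratified_folds(tab$label, k, seed)
  scores <- numeric(nrow(tab))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_ensemble(config, tab[tr, , drop = FALSE], tab$label[tr])
    sc <- predict_scores(model, tab[!tr, , drop = FALSE])
    scores[!tr] <- sc
    fold_rep <- classification_metrics(
      confusion_counts(tab$label[!tr], as.integer(sc >= 0.5)))
    per_fold[[f]] <- data.frame(fold = f, Sn = fold_rep$Sn, Sp = fold_rep$Sp,
                                ACC = fold_rep$ACC, MCC = fold_rep$MCC,
                                F1 = fold_rep$F1)
  }
  calls <- as.integer(scores >= 0.5)
  rep <- classification_metrics(confusion_counts(tab$label, calls))
  roc <- roc_auc(tab$label, scores)
  rep$AUROC <- roc$auc
  rep$roc_curve <- roc$curve
  rep$per_fold <- do.call(rbind, per_fold)
  rep$protocol <- list(type = "kfold", k = as.integer(k), n = nrow(tab))
  rep$config <- unclass(config)
  rep$seed <- as.integer(seed)
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("metrics_report (%s)\n", x$protocol$type %||% "counts-only"))
  cat(sprintf("  Sn=%s Sp=%s ACC=%s MCC=%s F1=%s%s\n",
              fmt(x$Sn), fmt(x$Sp), fmt(x$ACC), fmt(x$MCC), fmt(x$F1),
              if (!is.null(x$AUROC)) paste0(" AUROC=", fmt(x$AUROC)) else ""))
  cat(sprintf("  counts: TP=%d TN=%d FP=%d FN=%d\n", x$counts$TP, x$counts$TN,
              x$counts$FP, x$counts$FN))
  if (length(x$undefined) > 0L)
    cat("  undefined:", paste(x$undefined, collapse = "; "), "\n")
  invisible(x)
}

#' Write a metrics report as JSON (and optionally ROC points as CSV)
#'
#' @param report a `metrics_report`.
#' @param path JSON output path.
#' @param roc_csv optional CSV path for the ROC curve points.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path, roc_csv = NULL) {
  out <- list(protocol = report$protocol, config = report$config,
              seed = report$seed,
              counts = unclass(report$counts),
              metrics = list(Sn = report$Sn, Sp = report$Sp, ACC = report$ACC,
                             MCC = report$MCC, F1 = report$F1,
                             AUROC = report$AUROC),
              undefined = report$undefined)
  if (!is.null(report$per_fold)) out$per_fold <- report$per_fold
  if (!is.null(report$roc_curve)) out$roc_points <- report$roc_curve
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  if (!is.null(roc_csv) && !is.null(report$roc_curve))
    write.csv(report$roc_curve, roc_csv, row.names = FALSE)
  invisible(path)
}
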