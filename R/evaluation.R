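# Classification metrics, the random-prediction baseline and the
# cross-validation driver.

#' Matthews correlation coefficient
#'
#' Computed from the confusion matrix at the given predictions; any
#' degenerate denominator (all predictions or all labels in one class)
#' yields 0 by convention, so a random or constant predictor scores 0
#' rather than NaN.
#'
#' @param pred 0/1 predicted classes.
#' @param labels 0/1 true labels.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  if (denom == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # thresholds at unique score values (ties grouped)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - l)[!duplicated(grp, fromLast = TRUE)]
  P <- sum(l); N <- length(l) - P
  list(tpr = c(0, tp / P), fpr = c(0, fp / N),
       tp = c(0, tp), fp = c(0, fp))
}

auroc_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

aupr_step <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  tp <- pts$tp[-1]; fp <- pts$fp[-1]
  P <- sum(labels)
  precision <- tp / (tp + fp)
  recall <- tp / P
  # step integration (average-precision style): sum precision * d(recall)
  sum(precision * diff(c(0, recall)))
}

#' Classification metrics for one scored test set
#'
#' Computes accuracy, F1 and MCC at the `threshold` on the positive-class
#' score, AUROC by trapezoidal integration of the ROC curve, and AUPR by
#' step (average-precision) integration of the precision-recall curve.
#' When only one class is present in `labels`, AUROC and AUPR are `NA`
#' (flagged in `undefined`) while the threshold metrics are still
#' computed.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels 0/1 true labels.
#' @param threshold Classification threshold on the score (default 0.5).
#' @return A list of class `eval_report`: `accuracy`, `auroc`, `aupr`,
#'   `f1`, `mcc`, `n_pos`, `n_neg`, `undefined`, and `curves` (ROC and PR
#'   points).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  mcc <- mcc_score(pred, labels)
  one_class <- length(unique(labels)) < 2
  if (one_class) {
    auroc <- NA_real_; aupr <- NA_real_; curves <- NULL
  } else {
    auroc <- auroc_trapezoid(scores, labels)
    aupr <- aupr_step(scores, labels)
    pts <- roc_points(scores, labels)
    tpv <- pts$tp[-1]; fpv <- pts$fp[-1]
    curves <- list(
      roc = data.frame(fpr = pts$fpr, tpr = pts$tpr),
      pr = data.frame(recall = tpv / sum(labels),
                      precision = tpv / (tpv + fpv)))
  }
  structure(list(accuracy = acc, auroc = auroc, aupr = aupr, f1 = f1,
                 mcc = mcc, n_pos = sum(labels == 1),
                 n_neg = sum(labels == 0),
                 undefined = if (one_class) c("auroc", "aupr") else character(0),
                 curves = curves),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d (%d pos / %d neg)\n  accuracy %.4f | AUROC %s | AUPR %s | F1 %.4f | MCC %.4f\n",
    x$n_pos + x$n_neg, x$n_pos, x$n_neg, x$accuracy,
    ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc)),
    ifelse(is.na(x$aupr), "NA", sprintf("%.4f", x$aupr)),
    x$f1, x$mcc))
  invisible(x)
}

#' Random-prediction baseline
#'
#' Draws `n` labels Bernoulli(`prevalence`) and `n` scores uniform(0, 1)
#' and evaluates them: the expected AUPR of an uninformative scorer equals
#' the positive-class prevalence, and the expected MCC is 0. This is the
#' floor against which any reported model performance must be read on
#' imbalanced interaction data.
#'
#' @param n Number of simulated pairs.
#' @param prevalence Positive-class probability (0 < prevalence < 1).
#' @param seed RNG seed.
#' @return An `eval_report`.
#' @export
random_baseline <- function(n, prevalence, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  labels <- stats::rbinom(n, 1, prevalence)
  scores <- stats::runif(n)
  compute_metrics(scores, labels)
}

#' Cross-validation driver
#'
#' For each fold: fits a model on the complement, scores the held-out
#' fold, and computes metrics. Folds whose test labels contain a single
#' class are flagged and excluded from the AUROC/AUPR aggregation (their
#' threshold metrics still aggregate). Fully deterministic under fixed
#' seeds.
#'
#' @param Xc,Xt Feature matrices (rows align with `y`).
#' @param y 0/1 labels.
#' @param folds A `fold_assignment` covering all rows.
#' @param model_factory Zero-argument function returning a fresh
#'   [cti_model()].
#' @param config A [train_config()].
#' @return A list: `per_fold` (list of `eval_report`s), `aggregate` (data
#'   frame of mean and sd per metric), `flagged_folds`.
#' @export
cross_validate <- function(Xc, Xt, y, folds, model_factory,
                           config = train_config()) {
  stopifnot(length(folds$fold_of) == length(y))
  reports <- list()
  flagged <- integer(0)
  for (f in seq_len(folds$n_folds)) {
    test_idx <- which(folds$fold_of == f)
    train_idx <- setdiff(seq_along(y), test_idx)
    if (length(test_idx) == 0) next
    fit <- train_cti(model_factory(),
                     Xc[train_idx, , drop = FALSE],
                     Xt[train_idx, , drop = FALSE],
                     y[train_idx], config)
    scores <- predict_cti(fit$model, Xc[test_idx, , drop = FALSE],
                          Xt[test_idx, , drop = FALSE])
    rep <- compute_metrics(scores, y[test_idx])
    if (length(rep$undefined) > 0) flagged <- c(flagged, f)
    reports[[as.character(f)]] <- rep
  }
  metrics <- c("accuracy", "auroc", "aupr", "f1", "mcc")
  agg <- do.call(rbind, lapply(metrics, function(m) {
    v <- vapply(reports, `[[`, numeric(1), m)
    v <- v[!is.na(v)]
    data.frame(metric = m, mean = mean(v), sd = stats::sd(v))
  }))
  list(per_fold = reports, aggregate = agg, flagged_folds = flagged)
}

#' Write an evaluation report to JSON (scalars) and TSV (curves)
#'
#' @param report An `eval_report`.
#' @param stem Output path stem; writes `<stem>.json` and, when curves are
#'   defined, `<stem>_roc.tsv` / `<stem>_pr.tsv`.
#' @return `stem`, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  jsonlite::write_json(
    report[c("accuracy", "auroc", "aupr", "f1", "mcc", "n_pos", "n_neg")],
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(report$curves)) {
    utils::write.table(report$curves$roc, paste0(stem, "_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$curves$pr, paste0(stem, "_pr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(stem)
}
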