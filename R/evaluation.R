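#' Eight binary-classification test metrics
#'
#' Threshold metrics are computed from the confusion counts:
#' `Precision = TP/(TP+FP)`, `Accuracy = (TP+TN)/n`,
#' `Sensitivity = TP/(TP+FN)`, `Specificity = TN/(TN+FP)`,
#' `F1 = 2*Sens*Prec/(Sens+Prec)`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' AUROC uses the mid-rank statistic (equivalent to trapezoidal
#' integration of the ROC with tied scores shared); AUPRC is the step-wise
#' average precision. Metrics whose denominator degenerates (e.g. MCC with
#' an empty margin, or AUROC/AUPRC on a single-class sample) are reported
#' as `NA` rather than 0.
#'
#' @param y_true 0/1 reference labels.
#' @param y_pred 0/1 predicted labels.
#' @param y_score positive-class score (probability) used for the ranking
#'   metrics.
#' @return a `metrics_record`: named list of the eight metrics plus the
#'   counts `TP, TN, FP, FN` and `n`.
#' @export
compute_metrics <- function(y_true, y_pred, y_score) {
  stopifnot(length(y_true) == length(y_pred),
            length(y_true) == length(y_score))
  TP <- sum(y_true == 1 & y_pred == 1)
  TN <- sum(y_true == 0 & y_pred == 0)
  FP <- sum(y_true == 0 & y_pred == 1)
  FN <- sum(y_true == 1 & y_pred == 0)
  n <- length(y_true)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- div(TP, TP + FP)
  sensitivity <- div(TP, TP + FN)
  specificity <- div(TN, TN + FP)
  accuracy <- div(TP + TN, n)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * sensitivity * precision / (sensitivity + precision)
  mcc_den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (mcc_den == 0) NA_real_
         else (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(mcc_den)
  structure(list(precision = precision, accuracy = accuracy,
                 auprc = auprc(y_true, y_score),
                 auroc = auroc(y_true, y_score),
                 sensitivity = sensitivity, specificity = specificity,
                 f1 = f1, mcc = mcc,
                 TP = TP, TN = TN, FP = FP, FN = FN, n = n),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(paste0("<metrics_record> n=%d  acc=%.3f  auroc=%s  auprc=%s",
                     "  sens=%.3f  spec=%.3f  f1=%.3f  mcc=%s\n"),
              x$n, x$accuracy, fmt_na(x$auroc), fmt_na(x$auprc),
              x$sensitivity, x$specificity, x$f1, fmt_na(x$mcc)))
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' Area under the ROC curve (mid-rank statistic)
#' @inheritParams compute_metrics
#' @return AUROC in `[0, 1]`, or `NA` for single-class samples.
#' @export
auroc <- function(y_true, y_score) {
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(y_score)  # mid-ranks on ties
  (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (step average precision)
#'
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over the operating points obtained
#' by descending the distinct score values.
#' @inheritParams compute_metrics
#' @return AUPRC in `[0, 1]`, or `NA` for single-class samples.
#' @export
auprc <- function(y_true, y_score) {
  np <- sum(y_true == 1)
  if (np == 0 || np == length(y_true)) return(NA_real_)
  o <- order(y_score, decreasing = TRUE)
  yt <- y_true[o]
  sc <- y_score[o]
  tp <- cumsum(yt == 1)
  pp <- seq_along(yt)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  prec <- tp[keep] / pp[keep]
  rec <- tp[keep] / np
  sum(diff(c(0, rec)) * prec)
}

#' Uncertainty strata
#'
#' The default partition follows the clean/equivocal split: a right-open
#' clean bin `[0, 2)` and a closed top bin `[2, upper]` so that no record
#' is dropped at the maximum of D.
#'
#' @param upper top of the equivocal bin (defaults to `Inf`, i.e. the
#'   maximum attainable D).
#' @return data.frame with columns `label, lower, upper, upper_closed`.
#' @export
default_strata <- function(upper = Inf) {
  data.frame(label = c("clean", "equivocal"),
             lower = c(0, 2), upper = c(2, upper),
             upper_closed = c(FALSE, TRUE), stringsAsFactors = FALSE)
}

assign_stratum <- function(D, bins) {
  hit <- which(D >= bins$lower &
                 (D < bins$upper | (bins$upper_closed & D <= bins$upper)))
  if (length(hit) != 1L)
    stop("uncertainty D = ", D, " falls in ", length(hit), " bins")
  hit
}

#' Stratified evaluation of predictions by uncertainty
#'
#' Assigns each evaluated record to the unique uncertainty bin containing
#' its D and computes the eight metrics per bin. Empty strata are reported
#' with `n = 0` and `NA` metrics.
#'
#' @param results data.frame with columns `y_true, y_pred, y_score, D`
#'   (e.g. from [evaluate_model]).
#' @param bins stratum table from [default_strata].
#' @return list with `bins`, per-bin `metrics` (list of `metrics_record`
#'   or `NULL`), and `n` per bin.
#' @export
stratified_evaluate <- function(results, bins = default_strata()) {
  idx <- vapply(results$D, assign_stratum, integer(1), bins = bins)
  metrics <- vector("list", nrow(bins))
  n <- integer(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    sel <- idx == b
    n[b] <- sum(sel)
    if (n[b] > 0)
      metrics[[b]] <- compute_metrics(results$y_true[sel],
                                      results$y_pred[sel],
                                      results$y_score[sel])
  }
  structure(list(bins = bins, metrics = metrics, n = n),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  for (b in seq_len(nrow(x$bins))) {
    cat(sprintf("%s [%g, %g%s  n=%d\n", x$bins$label[b], x$bins$lower[b],
                x$bins$upper[b], if (x$bins$upper_closed[b]) "]" else ")",
                x$n[b]))
    if (!is.null(x$metrics[[b]])) print(x$metrics[[b]])
  }
  invisible(x)
}

#' Evaluate a model's base branch on a dataset
#'
#' @param model a `tram_net`.
#' @param dataset an `uncertram_dataset` with pixel data.
#' @param batch_size evaluation batch size.
#' @return data.frame with `image_id, y_true, y_pred, y_score, D`.
#' @export
evaluate_model <- function(model, dataset, batch_size = 64L) {
  lab <- label_table(dataset)
  n <- length(dataset$records)
  pred <- integer(n)
  score <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    x <- assemble_images(dataset, ix)
    p <- predict_base(model, x)
    pred[ix] <- p$pred
    score[ix] <- p$prob
  }
  data.frame(image_id = lab$image_id, y_true = lab$y, y_pred = pred,
             y_score = score, D = lab$D, stringsAsFactors = FALSE)
}

assemble_images <- function(dataset, ix) {
  first <- record_pixels(dataset, ix[1L])
  x <- array(0, c(nrow(first), ncol(first), 1L, length(ix)))
  x[, , 1L, 1L] <- first
  for (j in seq_along(ix)[-1L]) x[, , 1L, j] <- record_pixels(dataset, ix[j])
  x
}

#' Write a mean +/- sd results table as CSV
#'
#' One row per model/stratum with `mean +/- sd` per metric, mirroring the
#' usual benchmark-table layout, plus a machine-readable long-format CSV.
#'
#' @param rows list of named entries: each has `label` and `metrics`, a
#'   list of `metrics_record`s (one per fold/seed).
#' @param path output CSV path; the long-format companion gets suffix
#'   `_long.csv`.
#' @return invisibly, the formatted data.frame.
#' @export
write_report_csv <- function(rows, path) {
  keys <- c("precision", "accuracy", "auprc", "auroc", "sensitivity",
            "specificity", "f1", "mcc")
  fmt <- lapply(rows, function(r) {
    vals <- sapply(keys, function(k)
      sprintf("%.3f ± %.3f",
              mean(sapply(r$metrics, `[[`, k), na.rm = TRUE),
              stats::sd(sapply(r$metrics, `[[`, k))))
    c(model = r$label, vals)
  })
  df <- as.data.frame(do.call(rbind, fmt), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  long <- do.call(rbind, lapply(rows, function(r)
    do.call(rbind, lapply(seq_along(r$metrics), function(i)
      data.frame(model = r$label, rep = i, metric = keys,
                 value = as.numeric(unlist(r$metrics[[i]][keys])),
                 stringsAsFactors = FALSE)))))
  utils::write.csv(long, sub("\\.csv$", "_long.csv", path), row.names = FALSE)
  invisible(df)
}
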