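# Evaluation: confusion-matrix metrics at a decision threshold plus the
# ranking metrics (AUROC, AUPRC) that matter under the heavy class imbalance
# of PTM site prediction. All metrics are computed over labeled candidate
# sites only, matching the loss masking used in training.

#' Threshold (confusion-matrix) metrics
#'
#' Accuracy, precision, recall, F1 and Matthews correlation coefficient at a
#' fixed probability threshold. A degenerate denominator (e.g. no predicted
#' positives) yields 0 for the affected metric and sets the `degenerate`
#' flag rather than producing NaN, keeping reports machine-readable.
#'
#' @param scores Data.frame with columns `probability` and `label` (0/1).
#' @param threshold Decision threshold (default 0.5).
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `mcc`,
#'   `threshold`, `n_pos`, `n_neg`, and logical `degenerate`.
#' @export
threshold_metrics <- function(scores, threshold = 0.5) {
  assert_that(nrow(scores) >= 1L, "empty score table")
  assert_that(all(scores$label %in% c(0, 1)), "labels must be 0/1")
  pred <- as.integer(scores$probability >= threshold)
  y <- scores$label
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)

  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) {
    degenerate <- TRUE
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(accuracy = (tp + tn) / length(y),
       precision = precision, recall = recall, f1 = f1, mcc = mcc,
       threshold = threshold, n_pos = sum(y == 1), n_neg = sum(y == 0),
       degenerate = degenerate)
}

#' Ranking metrics: AUROC and AUPRC
#'
#' AUROC uses the Mann–Whitney formulation with midrank tie handling (tied
#' positive/negative pairs count 1/2). AUPRC is the step-wise integral of
#' the precision–recall curve over the distinct score thresholds
#' (sum of precision times recall increments), the estimator that
#' concentrates near the positive prevalence for uninformative scores.
#'
#' @param scores Data.frame with columns `probability` and `label` (0/1),
#'   both classes present.
#' @return List with `auroc` and `auprc`.
#' @export
rank_metrics <- function(scores) {
  y <- scores$label
  p <- scores$probability
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ranking metrics need both classes present", call. = FALSE)
  }
  # Mann-Whitney AUROC with midranks
  r <- rank(p, ties.method = "average")
  auroc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # step-wise PR integration over distinct thresholds, descending
  ord <- order(p, decreasing = TRUE)
  y_sorted <- y[ord]
  p_sorted <- p[ord]
  # cumulative counts at the end of each tied-score block
  ends <- cumsum(rle(p_sorted)$lengths)
  tp_cum <- cumsum(y_sorted)[ends]
  n_cum <- ends
  prec <- tp_cum / n_cum
  rec <- tp_cum / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

#' Full per-task metric report
#'
#' Bundles threshold and ranking metrics for one score table. If only one
#' class is present the ranking metrics are reported as `NA` with
#' `rank_computable = FALSE` instead of erroring (needed when stratified
#' bins are small).
#'
#' @param scores Data.frame with `probability` and `label`.
#' @param threshold Decision threshold (default 0.5).
#' @return List of class `ptm_metric_report`.
#' @export
metric_report <- function(scores, threshold = 0.5) {
  tm <- threshold_metrics(scores, threshold)
  computable <- tm$n_pos > 0 && tm$n_neg > 0
  rm_ <- if (computable) rank_metrics(scores) else
    list(auroc = NA_real_, auprc = NA_real_)
  structure(c(tm, rm_, list(rank_computable = computable,
                            n = nrow(scores))),
            class = "ptm_metric_report")
}

#' @export
print.ptm_metric_report <- function(x, digits = 3, ...) {
  cat("<ptm_metric_report> n = ", x$n, " (", x$n_pos, " pos / ", x$n_neg,
      " neg), threshold ", x$threshold, "\n", sep = "")
  vals <- c(accuracy = x$accuracy, precision = x$precision,
            recall = x$recall, f1 = x$f1, mcc = x$mcc,
            auroc = x$auroc, auprc = x$auprc)
  print(round(vals, digits))
  if (x$degenerate) cat("  (degenerate threshold metric(s) reported as 0)\n")
  if (!x$rank_computable) cat("  (ranking metrics not computable)\n")
  invisible(x)
}

#' Metric reports stratified by externally supplied similarity bins
#'
#' Splits a score table by per-protein bins (e.g. CD-HIT-2D similarity
#' strata read with [read_cluster_membership()]) and computes one metric
#' report per bin. Bins containing a single class report their ranking
#' metrics as not computable; threshold metrics are still emitted.
#'
#' @param scores Score table (see [score_sites()]).
#' @param membership Data.frame with `protein_id` and `bin`.
#' @param threshold Decision threshold.
#' @return Named list of `ptm_metric_report`, one per bin.
#' @export
stratified_report <- function(scores, membership, threshold = 0.5) {
  bin_of <- stats::setNames(membership$bin, membership$protein_id)
  unassigned <- setdiff(unique(scores$protein_id), names(bin_of))
  if (length(unassigned)) {
    stop("protein(s) without a similarity bin: ",
         paste(utils::head(unassigned, 5L), collapse = ", "), call. = FALSE)
  }
  bins <- bin_of[scores$protein_id]
  out <- lapply(split(scores, bins), metric_report, threshold = threshold)
  out[order(names(out))]
}

#' Write a metric report (or list of reports) as JSON-ready list and TSV
#'
#' @param reports A `ptm_metric_report` or named list of them.
#' @param path Output TSV path.
#' @return Invisibly, the flattened data.frame written.
#' @export
write_metric_report <- function(reports, path) {
  if (inherits(reports, "ptm_metric_report")) {
    reports <- list(all = reports)
  }
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(stratum = nm, accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1, mcc = r$mcc, auroc = r$auroc,
               auprc = r$auprc, threshold = r$threshold, n_pos = r$n_pos,
               n_neg = r$n_neg, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Precision–recall and ROC curve points for plotting
#'
#' Emits the step-wise curve points at every distinct score threshold.
#'
#' @param scores Score table with `probability` and `label`.
#' @return List of two data.frames: `pr` (`threshold`, `recall`,
#'   `precision`) and `roc` (`threshold`, `fpr`, `tpr`).
#' @export
curve_points <- function(scores) {
  ord <- order(scores$probability, decreasing = TRUE)
  y <- scores$label[ord]
  p <- scores$probability[ord]
  ends <- cumsum(rle(p)$lengths)
  tp <- cumsum(y)[ends]
  n <- ends
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  thr <- p[ends]
  list(pr = data.frame(threshold = thr, recall = tp / n_pos,
                       precision = tp / n),
       roc = data.frame(threshold = thr, fpr = (n - tp) / n_neg,
                        tpr = tp / n_pos))
}
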