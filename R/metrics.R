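#' Area under the ROC curve
#'
#' Full threshold sweep with `TPR = TP / (TP + FN)` and
#' `FPR = FP / (FP + TN)`; ties are credited one half, which makes the
#' area equal to the rank statistic
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)} (computed here via the
#' Wilcoxon rank form).
#'
#' @param labels Binary vector (both classes must be present).
#' @param scores Numeric scores, higher meaning more likely positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  check_two_classes(labels, scores)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending-score thresholds with
#' `Recall = TP / (TP + FN)` and `Precision = TP / (TP + FP)`:
#' \eqn{\sum_k (R_k - R_{k-1}) P_k}. A constant classifier yields the
#' positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(labels, scores) {
  check_two_classes(labels, scores)
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

check_two_classes <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) abort("labels must be binary (0/1)")
  if (length(unique(labels)) < 2) {
    abort("both classes must be present to compute a ranking metric")
  }
  invisible(NULL)
}

#' ROC and precision-recall curve points
#'
#' One operating point per distinct score threshold (predict positive when
#' `score >= threshold`), plus the trivial all-negative endpoint for the
#' ROC so the curve runs from (0, 0) to (1, 1).
#'
#' @inheritParams auroc
#' @return A tibble: `threshold`, `fpr`, `tpr` for `roc_points`;
#'   `threshold`, `recall`, `precision` for `pr_points`.
#' @export
roc_points <- function(labels, scores) {
  check_two_classes(labels, scores)
  sw <- threshold_sweep(labels, scores)
  tibble::tibble(
    threshold = c(Inf, sw$threshold),
    fpr = c(0, sw$fp / sum(labels == 0)),
    tpr = c(0, sw$tp / sum(labels == 1))
  )
}

#' @rdname roc_points
#' @export
pr_points <- function(labels, scores) {
  check_two_classes(labels, scores)
  sw <- threshold_sweep(labels, scores)
  tibble::tibble(
    threshold = sw$threshold,
    recall = sw$tp / sum(labels == 1),
    precision = sw$tp / (sw$tp + sw$fp)
  )
}

threshold_sweep <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)  # last index of each tie group
  tibble::tibble(
    threshold = s[keep],
    tp = cumsum(y == 1)[keep],
    fp = cumsum(y == 0)[keep]
  )
}

#' Evaluation report for one split
#'
#' @param labels,scores Binary labels and prediction scores.
#' @param split Name of the evaluated split (metadata).
#' @return Object of class `dti_metrics`: `auroc`, `aupr`, `roc_points`,
#'   `pr_points`, `n`, `n_pos`, `split`.
#' @export
metrics_report <- function(labels, scores, split = "test") {
  structure(list(
    auroc = auroc(labels, scores),
    aupr = aupr(labels, scores),
    roc_points = roc_points(labels, scores),
    pr_points = pr_points(labels, scores),
    n = length(labels),
    n_pos = sum(labels == 1),
    split = split
  ), class = "dti_metrics")
}

#' @export
print.dti_metrics <- function(x, ...) {
  cat(sprintf("<dti_metrics> split = %s, n = %d (%d positive)\n",
              x$split, x$n, x$n_pos))
  cat(sprintf("  AUROC = %.4f   AUPR = %.4f\n", x$auroc, x$aupr))
  invisible(x)
}

#' @export
tidy.dti_metrics <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$roc_points, curve = "roc", x = .data$fpr, y = .data$tpr),
    dplyr::mutate(x$pr_points, curve = "pr", x = .data$recall, y = .data$precision)
  )[, c("curve", "threshold", "x", "y")]
}

#' @export
glance.dti_metrics <- function(x, ...) {
  tibble::tibble(split = x$split, n = x$n, n_pos = x$n_pos,
                 auroc = x$auroc, aupr = x$aupr)
}

#' @export
autoplot.dti_metrics <- function(object, ...) {
  df <- tidy(object)
  df$curve <- factor(df$curve, levels = c("roc", "pr"),
                     labels = c("ROC", "Precision-recall"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$curve)) +
    ggplot2::labs(
      x = "FPR / recall", y = "TPR / precision",
      title = sprintf("AUROC = %.4f, AUPR = %.4f (%s split)",
                      object$auroc, object$aupr, object$split)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1))
}

#' Serialize a metrics report to TSV + JSON
#'
#' @param report A `dti_metrics`.
#' @param dir Output directory; writes `metrics.json` (scalar summary)
#'   and `roc_points.tsv` / `pr_points.tsv` for plotting.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(split = report$split, n = report$n, n_pos = report$n_pos,
         auroc = report$auroc, aupr = report$aupr),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  write.table(as.data.frame(report$roc_points),
              file.path(dir, "roc_points.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(report$pr_points),
              file.path(dir, "pr_points.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
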