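# Evaluation surface: confusion metrics with Wilson score intervals,
# ROC/AUC, clinical-baseline classifiers with direction inversion, and the
# signature-volume Spearman correlation test.

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' round(wilson_interval(14, 17), 2)  # 0.59 0.94
#' @export
wilson_interval <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' Confusion matrix and derived classification metrics
#'
#' Tabulates high-risk calls against binary labels and reports accuracy,
#' sensitivity and specificity, each with a 95% Wilson score interval.
#'
#' @param calls predicted classes: `"HR"`/`"LR"` or 1/0.
#' @param labels true binary labels (1 = positive / short survivor).
#' @param level confidence level for the intervals.
#' @return object of class `confusion_metrics`: list with `counts`
#'   (`TP`, `FN`, `TN`, `FP`), the three metrics and their intervals. When
#'   a class is absent the affected metric is `NA` and flagged.
#' @examples
#' cm <- confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' cm$accuracy
#' @export
confusion_metrics <- function(calls, labels, level = 0.95) {
  if (is.character(calls) || is.factor(calls))
    calls <- as.integer(as.character(calls) == "HR")
  calls <- as.integer(calls)
  labels <- as.integer(labels)
  stopifnot(length(calls) == length(labels))
  tp <- sum(calls == 1 & labels == 1)
  fn <- sum(calls == 0 & labels == 1)
  tn <- sum(calls == 0 & labels == 0)
  fp <- sum(calls == 1 & labels == 0)
  n <- length(labels)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  out <- list(
    counts = c(TP = tp, FN = fn, TN = tn, FP = fp),
    accuracy = acc, accuracy_ci = wilson_interval(tp + tn, n, level),
    sensitivity = sens,
    sensitivity_ci = if (!is.na(sens)) wilson_interval(tp, tp + fn, level)
                     else c(lower = NA_real_, upper = NA_real_),
    specificity = spec,
    specificity_ci = if (!is.na(spec)) wilson_interval(tn, tn + fp, level)
                     else c(lower = NA_real_, upper = NA_real_),
    level = level)
  if (is.na(sens) || is.na(spec))
    attr(out, "flagged") <- "a class is absent from the labels"
  structure(out, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
  cat("confusion counts: TP", x$counts["TP"], "FN", x$counts["FN"],
      "TN", x$counts["TN"], "FP", x$counts["FP"], "\n")
  cat("accuracy   ", fmt(x$accuracy, x$accuracy_ci), "\n")
  if (!is.na(x$sensitivity))
    cat("sensitivity", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  if (!is.na(x$specificity))
    cat("specificity", fmt(x$specificity, x$specificity_ci), "\n")
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Enumerates operating points at every unique score (rule: positive when
#' `score > threshold`, with sentinels at both ends) and integrates by the
#' trapezoidal rule, which equals the rank-sum (Mann-Whitney) statistic with
#' half credit for ties.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return list with `auc` and `roc` (data frame `threshold`, `sens`,
#'   `spec`, `fpr`). Constant scores give AUC 0.5 with a degeneracy flag.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, u, u[length(u)] + 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos > t), 0)
  fpr <- vapply(cand, function(t) mean(neg > t), 0)
  ord <- order(fpr, sens)
  auc_tr <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  out <- list(auc = auc_tr,
              roc = data.frame(threshold = cand, sens = sens,
                               spec = 1 - fpr, fpr = fpr))
  if (length(u) == 1) {
    out$auc <- 0.5
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Spearman correlation with t-approximation test
#'
#' Spearman's rho with average ranks for ties; the two-sided p-value uses
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` against a t distribution with
#' `n - 2` degrees of freedom. `spearman_rho_pvalue()` exposes the p-value
#' as a function of (rho, n) directly.
#'
#' @param x,y numeric vectors (no missing values, n >= 4).
#' @return list with `rho`, `p_value` and `n`.
#' @examples
#' spearman_rho_pvalue(-0.36, 17)  # ~0.156
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4) stop("need n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) stop("zero rank variance")
  rho <- cor(rx, ry)
  list(rho = rho, p_value = spearman_rho_pvalue(rho, n), n = n)
}

#' @rdname spearman_test
#' @param rho Spearman correlation coefficient.
#' @param n sample size.
#' @export
spearman_rho_pvalue <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval from a stratified bootstrap (cases and controls
#' resampled separately). Uses the caller's RNG stream.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap draws (default 2000).
#' @param level confidence level.
#' @return `c(lower, upper)`.
#' @export
auc_ci_boot <- function(scores, labels, n_boot = 2000, level = 0.95) {
  labels <- as.integer(labels)
  ip <- which(labels == 1); in_ <- which(labels == 0)
  stats_ <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(ip, length(ip), replace = TRUE),
           sample(in_, length(in_), replace = TRUE))
    rank_auc(scores[i], labels[i])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- quantile(stats_, c(alpha, 1 - alpha), names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Clinical baseline classifiers
#'
#' Scores each clinical variable as a one-dimensional classifier: its ROC is
#' computed directly, the operating threshold is chosen by the same
#' closest-to-corner rule as the radiomic signature, and when the raw AUC is
#' below 0.5 the direction of thresholding is inverted (low values called
#' high-risk) before thresholding.
#'
#' @param clinical data frame of numeric/ordinal variables (columns are
#'   evaluated independently).
#' @param labels binary labels (0/1).
#' @param variables columns to evaluate (default: all).
#' @param level confidence level for Wilson intervals.
#' @return data frame with one row per variable: `variable`, `auc`,
#'   `inverted`, `threshold`, `accuracy`/`sensitivity`/`specificity` with
#'   CI bounds, and `flag` for uninformative (constant) variables.
#' @export
clinical_baselines <- function(clinical, labels,
                               variables = colnames(clinical),
                               level = 0.95) {
  labels <- as.integer(labels)
  rows <- lapply(variables, function(v) {
    x <- as.numeric(clinical[[v]])
    if (length(unique(x)) < 2)
      return(data.frame(variable = v, auc = NA_real_, inverted = NA,
                        threshold = NA_real_, accuracy = NA_real_,
                        accuracy_lo = NA_real_, accuracy_hi = NA_real_,
                        sensitivity = NA_real_, sensitivity_lo = NA_real_,
                        sensitivity_hi = NA_real_, specificity = NA_real_,
                        specificity_lo = NA_real_, specificity_hi = NA_real_,
                        flag = "uninformative", stringsAsFactors = FALSE))
    raw_auc <- roc_auc(x, labels)$auc
    inverted <- raw_auc < 0.5
    score <- if (inverted) -x else x
    thr <- choose_threshold(score, labels)
    cm <- confusion_metrics(as.integer(score > thr), labels, level)
    data.frame(variable = v, auc = raw_auc, inverted = inverted,
               threshold = if (inverted) -thr else thr,
               accuracy = cm$accuracy,
               accuracy_lo = cm$accuracy_ci[1], accuracy_hi = cm$accuracy_ci[2],
               sensitivity = cm$sensitivity,
               sensitivity_lo = cm$sensitivity_ci[1],
               sensitivity_hi = cm$sensitivity_ci[2],
               specificity = cm$specificity,
               specificity_lo = cm$specificity_ci[1],
               specificity_hi = cm$specificity_ci[2],
               flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluation report for a set of risk calls
#'
#' Bundles the confusion metrics (with Wilson intervals), the ROC curve and
#' AUC (with a stratified-bootstrap interval) and, optionally, the
#' clinical-baseline table and the signature-volume correlation test into
#' one object that can be written as JSON/CSV.
#'
#' @param scores signature scores.
#' @param calls `"HR"`/`"LR"` calls (or 1/0).
#' @param labels binary labels.
#' @param clinical optional clinical data frame for [clinical_baselines()].
#' @param volumes optional lesion volumes for the signature-volume
#'   Spearman test.
#' @param n_boot bootstrap draws for the AUC interval.
#' @param seed seed for the bootstrap.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, calls, labels, clinical = NULL,
                              volumes = NULL, n_boot = 2000, seed = 1) {
  cm <- confusion_metrics(calls, labels)
  ra <- roc_auc(scores, labels)
  ci <- with_seed(seed, auc_ci_boot(scores, labels, n_boot))
  out <- list(confusion = cm, auc = ra$auc, auc_ci = ci, roc = ra$roc)
  if (!is.null(clinical))
    out$baselines <- clinical_baselines(clinical, labels)
  if (!is.null(volumes)) {
    if (length(volumes) >= 4) {
      out$volume_correlation <- spearman_test(volumes, scores)
    } else {
      rs_log("volume correlation skipped: fewer than 4 patients")
    }
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("AUC         %.2f (%.2f-%.2f)\n", x$auc, x$auc_ci[1],
              x$auc_ci[2]))
  if (!is.null(x$volume_correlation))
    cat(sprintf("signature~volume: rho = %.2f, p = %.2f\n",
                x$volume_correlation$rho, x$volume_correlation$p_value))
  if (!is.null(x$baselines)) {
    cat("clinical baselines:\n")
    print(x$baselines[, c("variable", "auc", "accuracy")], row.names = FALSE)
  }
  invisible(x)
}

# flatten a report for serialization; every metric is recomputable from the
# stored confusion counts, asserted here before writing
report_payload <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  cm <- report$confusion
  cnt <- as.list(cm$counts)
  n <- sum(cm$counts)
  stopifnot(abs(cm$accuracy - (cnt$TP + cnt$TN) / n) < 1e-12)
  if (!is.na(cm$sensitivity))
    stopifnot(abs(cm$sensitivity - cnt$TP / (cnt$TP + cnt$FN)) < 1e-12)
  if (!is.na(cm$specificity))
    stopifnot(abs(cm$specificity - cnt$TN / (cnt$TN + cnt$FP)) < 1e-12)
  list(counts = cnt,
       accuracy = cm$accuracy, accuracy_ci = unname(cm$accuracy_ci),
       sensitivity = cm$sensitivity,
       sensitivity_ci = unname(cm$sensitivity_ci),
       specificity = cm$specificity,
       specificity_ci = unname(cm$specificity_ci),
       auc = report$auc, auc_ci = unname(report$auc_ci),
       roc = report$roc,
       baselines = report$baselines,
       volume_correlation = report$volume_correlation)
}

#' Write an evaluation report as JSON and CSV
#'
#' `report.json` stores the full report; `report.csv` mirrors the layout of
#' a metrics table: one row for the radiomic signature and one per clinical
#' baseline with accuracy/sensitivity/specificity (each with its interval)
#' and AUC.
#'
#' @param report an [evaluation_report()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report_payload(report), jp, digits = NA,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  cm <- report$confusion
  main <- data.frame(
    variable = "Radiomics",
    accuracy = cm$accuracy, accuracy_lo = cm$accuracy_ci[1],
    accuracy_hi = cm$accuracy_ci[2], sensitivity = cm$sensitivity,
    sensitivity_lo = cm$sensitivity_ci[1],
    sensitivity_hi = cm$sensitivity_ci[2], specificity = cm$specificity,
    specificity_lo = cm$specificity_ci[1],
    specificity_hi = cm$specificity_ci[2], auc = report$auc,
    stringsAsFactors = FALSE)
  if (!is.null(report$baselines)) {
    bl <- report$baselines[, c("variable", "accuracy", "accuracy_lo",
                               "accuracy_hi", "sensitivity",
                               "sensitivity_lo", "sensitivity_hi",
                               "specificity", "specificity_lo",
                               "specificity_hi", "auc")]
    main <- rbind(main, bl)
  }
  cp <- file.path(dir, "report.csv")
  write.csv(main, cp, row.names = FALSE)
  invisible(c(jp, cp))
}
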