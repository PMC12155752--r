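## Confusion-matrix metrics with bootstrap confidence intervals, ROC/AUC
## via the rank (Mann-Whitney) formulation, and the DeLong paired test
## for correlated AUCs.  The positive class is the PD-like class "A", so
## sensitivity counts its detection rate.

#' Confusion counts
#'
#' @param tp,fn,tn,fp non-negative integers (positives = the PD-like
#'   class).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v)))
    stop_mcmae("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally confusion counts from prediction records
#'
#' @param records data.frame with `true_label` and `predicted_label`.
#' @return a [confusion_counts()].
#' @export
count_predictions <- function(records) {
  pos <- POSITIVE_CLASS
  confusion_counts(
    tp = sum(records$true_label == pos & records$predicted_label == pos),
    fn = sum(records$true_label == pos & records$predicted_label != pos),
    tn = sum(records$true_label != pos & records$predicted_label != pos),
    fp = sum(records$true_label != pos & records$predicted_label == pos))
}

#' Confusion-matrix metrics
#'
#' accuracy = (tp+tn)/total, sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp), precision = tp/(tp+fp),
#' f1 = 2 * precision * sensitivity / (precision + sensitivity).
#' Metrics are kept at full precision (round only for display); a metric
#' with a zero denominator is reported as `NA` and listed in the
#' `undefined` field rather than silently set to 0.
#'
#' @param cc a [confusion_counts()].
#' @return a `metric_report` list: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `counts`, `undefined`.
#' @export
metrics_from_counts <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  total <- cc$tp + cc$fn + cc$tn + cc$fp
  out <- list(
    accuracy    = safe_div(cc$tp + cc$tn, total),
    sensitivity = safe_div(cc$tp, cc$tp + cc$fn),
    specificity = safe_div(cc$tn, cc$tn + cc$fp),
    precision   = safe_div(cc$tp, cc$tp + cc$fp))
  out$f1 <- if (!is.na(out$precision) && !is.na(out$sensitivity) &&
                out$precision + out$sensitivity > 0)
    2 * out$precision * out$sensitivity / (out$precision + out$sensitivity)
  else NA_real_
  out$counts <- cc
  out$undefined <- names(out)[vapply(out[1:5], function(x)
    is.numeric(x) && is.na(x), logical(1))]
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1"))
    cat(sprintf("%-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.3f", x[[m]])))
  invisible(x)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  labels == POSITIVE_CLASS
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midranks for ties: equals the
#' trapezoidal area under the empirical ROC curve, and the pairwise
#' count (wins + half ties) / (n_pos * n_neg).
#'
#' @param labels class labels (`"A"`/`"B"`, or logical with `TRUE` =
#'   positive).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop_mcmae("both classes must be present to compute an AUC")
  r <- rank(scores)              # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metric_from_records <- function(records, metric_name) {
  if (metric_name == "auc")
    return(roc_auc(records$true_label, records$score))
  rep <- metrics_from_counts(count_predictions(records))
  rep[[metric_name]]
}

#' Stratified bootstrap confidence interval for a test-set metric
#'
#' Nonparametric case resampling stratified within each true class;
#' percentile 2.5/97.5 interval.  Resamples on which the metric is
#' undefined are skipped and counted in the `n_undefined` attribute.
#'
#' @param records prediction records (see [predict.mcmae_classifier()]).
#' @param metric_name one of `"accuracy"`, `"sensitivity"`,
#'   `"specificity"`, `"precision"`, `"f1"`, `"auc"`.
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param seed resampling seed.
#' @return numeric `(low, high)` with attribute `n_undefined`.
#' @export
bootstrap_ci <- function(records, metric_name, n_boot = 2000, seed = 1) {
  if (n_boot < 200) stop_mcmae("n_boot must be >= 200")
  point <- metric_from_records(records, metric_name)
  if (is.na(point))
    stop_mcmae("metric '%s' is undefined on the full sample", metric_name)
  idx_by_class <- split(seq_len(nrow(records)), records$true_label)
  vals <- with_seed(hash_seed(seed, 606L), {
    vapply(seq_len(n_boot), function(b) {
      take <- unlist(lapply(idx_by_class, function(ix)
        ix[sample.int(length(ix), replace = TRUE)]), use.names = FALSE)
      tryCatch(metric_from_records(records[take, , drop = FALSE], metric_name),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  n_und <- sum(is.na(vals))
  ci <- quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(c(low = ci[1], high = ci[2]), n_undefined = n_und)
}

#' Full evaluation report with confidence intervals
#'
#' @param records prediction records with scores.
#' @param n_boot,seed bootstrap settings.
#' @return a `metric_report` extended with `auc` and a `ci95` list per
#'   metric.
#' @export
metric_report <- function(records, n_boot = 2000, seed = 1) {
  rep <- metrics_from_counts(count_predictions(records))
  rep$auc <- roc_auc(records$true_label, records$score)
  metrics <- c("accuracy", "sensitivity", "specificity", "precision",
               "f1", "auc")
  rep$ci95 <- lapply(stats::setNames(metrics, metrics), function(m) {
    if (m != "auc" && is.na(rep[[m]])) return(c(low = NA, high = NA))
    bootstrap_ci(records, m, n_boot = n_boot, seed = hash_seed(seed, match(m, metrics)))
  })
  rep
}

# placement values (structural components) of the positive/negative scores
delong_placements <- function(pos_scores, neg_scores) {
  m <- length(pos_scores); n <- length(neg_scores)
  psi <- outer(pos_scores, neg_scores,
               function(x, y) (x > y) + 0.5 * (x == y))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two models scored on the same
#' subjects, using the placement-value (structural-component) variance
#' estimate; `z = (auc1 - auc2) / sqrt(var)` with a two-sided normal
#' p-value.  Degenerate variance (e.g. identical score vectors) returns
#' `z = 0`, `p = 1` by convention.
#'
#' @param labels shared true labels.
#' @param scores_model1,scores_model2 paired scores on the same subjects.
#' @return list: `auc1`, `auc2`, `z`, `p`, `var_diff`.
#' @export
delong_test <- function(labels, scores_model1, scores_model2) {
  pos <- as_binary_labels(labels)
  if (!any(pos) || all(pos))
    stop_mcmae("both classes must be present")
  stopifnot(length(scores_model1) == length(labels),
            length(scores_model2) == length(labels))
  p1 <- delong_placements(scores_model1[pos], scores_model1[!pos])
  p2 <- delong_placements(scores_model2[pos], scores_model2[!pos])
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(var_diff) || var_diff <= 0)
    return(list(auc1 = p1$auc, auc2 = p2$auc, z = 0, p = 1,
                var_diff = var_diff))
  z <- (p1$auc - p2$auc) / sqrt(var_diff)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z, p = 2 * pnorm(-abs(z)),
       var_diff = var_diff)
}
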