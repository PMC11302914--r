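# Confidence/accuracy statistics: ranking confidence, outcome
# classification with strict thresholds, success rate, Spearman correlation,
# ROC-AUC of confidence as a model selector, running-mean curves, and the
# score-table report.

#' Ranking confidence
#'
#' The model-selection score of multimer prediction:
#' `0.8 * iptm + 0.2 * ptm`, weighting the interface TM-score over the
#' whole-complex one. Vectorized.
#'
#' @param iptm,ptm predicted TM-scores in [0, 1].
#' @return `0.8*iptm + 0.2*ptm`, in [0, 1].
#' @export
#' @examples
#' rankingConfidence(0.9, 0.5)  # 0.82
rankingConfidence <- function(iptm, ptm) {
  if (any(iptm < 0 | iptm > 1) || any(ptm < 0 | ptm > 1))
    .stopf("rankingConfidence: iptm and ptm must lie in [0, 1]")
  0.8 * iptm + 0.2 * ptm
}

#' Classify a prediction outcome
#'
#' Strict-threshold partition of the unit square (defaults: accuracy
#' threshold MMscore > 0.75, confidence threshold RC > 0.8):
#' `success` = accurate and confidently selected; `hidden_failure` =
#' confidently selected but inaccurate (the dangerous quadrant);
#' `missed_success` = accurate but not selectable; `true_negative` =
#' neither. Boundary values (exactly at a threshold) never count as above
#' it. Vectorized.
#'
#' @param mmscore structural accuracy score in [0, 1].
#' @param rc ranking confidence in [0, 1].
#' @param mmThr,rcThr thresholds (defaults 0.75 and 0.8).
#' @return Character vector over the four outcome classes.
#' @export
classifyOutcome <- function(mmscore, rc, mmThr = 0.75, rcThr = 0.8) {
  if (any(mmscore < 0 | mmscore > 1) || any(rc < 0 | rc > 1))
    .stopf("classifyOutcome: scores must lie in [0, 1]")
  acc <- mmscore > mmThr
  conf <- rc > rcThr
  ifelse(acc & conf, "success",
         ifelse(conf, "hidden_failure",
                ifelse(acc, "missed_success", "true_negative")))
}

#' Fraction of successes in a result table
#'
#' Applies [classifyOutcome()] to (`mmscore_final`, `ranking_confidence`)
#' and returns the success fraction.
#'
#' @param results data.frame with columns `mmscore_final` and
#'   `ranking_confidence` (or `iptm` and `ptm`, from which it is derived).
#' @param mmThr,rcThr thresholds passed to [classifyOutcome()].
#' @return Fraction in [0, 1].
#' @export
successRate <- function(results, mmThr = 0.75, rcThr = 0.8) {
  if (nrow(results) == 0) .stopf("successRate: empty result table")
  rc <- if ("ranking_confidence" %in% names(results)) results$ranking_confidence
        else rankingConfidence(results$iptm, results$ptm)
  mean(classifyOutcome(results$mmscore_final, rc, mmThr, rcThr) == "success")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tied ranks. A constant input makes the
#' statistic undefined; that is reported as `NA` with a warning, never as a
#' silent zero (optimization trajectories can plateau).
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1], or `NA` when undefined.
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) .stopf("spearmanCorrelation: length mismatch")
  if (length(x) < 2) .stopf("spearmanCorrelation: need at least two points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearmanCorrelation undefined for constant input; returning NA")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' ROC-AUC of a score as a binary selector
#'
#' The Mann-Whitney statistic `P(score+ > score-) + 0.5 * P(tie)`, computed
#' from average ranks; equal to the trapezoidal area under the ROC curve.
#' Here it quantifies how well the ranking confidence selects accurate
#' models.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) .stopf("rocAUC: length mismatch")
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) .stopf("rocAUC: both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Running mean over fixed-width bins
#'
#' Averages `y` within consecutive half-open bins `[k*step, (k+1)*step)`
#' over `x`; empty bins are omitted. The smoothing used for
#' confidence-vs-accuracy and depth-vs-accuracy curves (typical steps: 0.05
#' or 0.01 in confidence, 500 in MSA depth).
#'
#' @param x,y numeric vectors of equal length.
#' @param step bin width (> 0).
#' @return data.frame with `bin_center` and `mean_y`, ordered by bin.
#' @export
runningMean <- function(x, y, step) {
  if (length(x) != length(y)) .stopf("runningMean: length mismatch")
  if (step <= 0) .stopf("runningMean: step must be > 0")
  k <- floor(x / step)
  agg <- vapply(split(y, k), mean, 0)
  ks <- as.numeric(names(agg))
  ord <- order(ks)
  data.frame(bin_center = (ks[ord] + 0.5) * step, mean_y = unname(agg[ord]))
}

#' Read a per-target score table
#'
#' TSV with columns `target_id`, `mmscore_initial`, `mmscore_final` and
#' either `ranking_confidence` or both `iptm` and `ptm` (from which it is
#' derived); optional `msa_depth`.
#'
#' @param path TSV file path.
#' @return data.frame with a `ranking_confidence` column guaranteed.
#' @export
readScores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("target_id", "mmscore_initial", "mmscore_final")
  if (!all(need %in% names(df)))
    .stopf("score table must contain columns: %s", paste(need, collapse = ", "))
  if (!"ranking_confidence" %in% names(df)) {
    if (!all(c("iptm", "ptm") %in% names(df)))
      .stopf("score table needs ranking_confidence or iptm+ptm columns")
    df$ranking_confidence <- rankingConfidence(df$iptm, df$ptm)
  }
  df
}

#' Summarize a score table
#'
#' The standard report over per-target results: outcome-class counts and
#' success rate on the final (confidence-selected) scores, ROC-AUC of the
#' ranking confidence as a selector of accurate models
#' (`mmscore_final > mmThr`), Spearman correlation between confidence and
#' final accuracy, and the median MMscore change.
#'
#' @param scores data.frame from [readScores()] (or of the same shape).
#' @param mmThr,rcThr classification thresholds.
#' @return Named list: `n`, `success_rate`, `counts` (per outcome class),
#'   `roc_auc` (`NA` when one class is absent), `spearman_rc_mmscore`,
#'   `median_delta_mmscore`.
#' @export
evaluateScores <- function(scores, mmThr = 0.75, rcThr = 0.8) {
  if (is.character(scores)) scores <- readScores(scores)
  cls <- classifyOutcome(scores$mmscore_final, scores$ranking_confidence,
                         mmThr, rcThr)
  counts <- as.list(table(factor(cls, levels = c(
    "success", "hidden_failure", "missed_success", "true_negative"))))
  acc <- scores$mmscore_final > mmThr
  auc <- if (any(acc) && any(!acc)) rocAUC(scores$ranking_confidence, acc) else NA_real_
  list(n = nrow(scores),
       success_rate = mean(cls == "success"),
       counts = lapply(counts, as.integer),
       roc_auc = auc,
       spearman_rc_mmscore = spearmanCorrelation(scores$ranking_confidence,
                                                 scores$mmscore_final),
       median_delta_mmscore = stats::median(scores$mmscore_final -
                                              scores$mmscore_initial))
}
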