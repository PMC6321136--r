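# Validation statistics: rank-sum AUC with midrank tie handling,
# Hanley/Nicholls standard error and Welch-Satterthwaite effective degrees
# of freedom, ROC curves, the Power Metric early-recognition objective,
# contingency metrics (F-score, MCC, enrichment factor), threshold sweeps
# and the AUC > 0.5 model filter.

#' Rank-sum (Mann-Whitney) AUC
#'
#' AUC computed from the rank sum of the active compounds' scores; ties
#' between an active and an inactive contribute 1/2 per pair (midrank
#' interpolation), which is exactly the Mann-Whitney U statistic divided
#' by Na*Ni.
#'
#' @param scores Numeric scores (higher = more active-like).
#' @param labels Parallel labels, "active"/"inactive" (or 1/0).
#' @return AUC in \[0, 1\].
#' @export
auc_rank_sum <- function(scores, labels) {
  labels <- normalize_labels(labels)
  stopifnot(length(scores) == length(labels))
  if (!all(is.finite(scores)))
    stop_ligfish("non-finite scores in AUC computation", "ligfish_degenerate_error")
  na <- sum(labels == "active"); ni <- sum(labels == "inactive")
  if (na == 0L || ni == 0L)
    stop_ligfish("AUC needs at least one active and one inactive", "ligfish_degenerate_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "active"]) - na * (na + 1) / 2) / (na * ni)
}

#' Standard error of an observed AUC (Hanley approximation)
#'
#' \eqn{SE = \sqrt{ w^2(1-w)/((1+w) N_a) + w(1-w)^2/((2-w)^2 N_i) }}
#' for observed AUC `w`, the "typical" smooth-ROC approximation.
#'
#' @param w Observed AUC in \[0, 1\].
#' @param na,ni Numbers of actives and inactives (>= 2).
#' @return Standard error.
#' @export
auc_se <- function(w, na, ni) {
  stopifnot(w >= 0, w <= 1, na >= 2, ni >= 2)
  sqrt(auc_var_components(w, na, ni)$va + auc_var_components(w, na, ni)$vi)
}

#' @noRd
auc_var_components <- function(w, na, ni) {
  list(va = w^2 * (1 - w) / ((1 + w) * na),
       vi = w * (1 - w)^2 / ((2 - w)^2 * ni))
}

#' Effective degrees of freedom for the AUC t-interval
#'
#' Welch-Satterthwaite combination of the two variance components of
#' [auc_se()]: \eqn{\nu = (v_a+v_i)^2 / (v_a^2/(N_a-1) + v_i^2/(N_i-1))}.
#' In the symmetric limit (equal components, Na = Ni) this reduces to
#' 2(Na - 1); when one component vanishes it reduces to the other class's
#' Na - 1 (or Ni - 1).
#'
#' @inheritParams auc_se
#' @return Effective degrees of freedom.
#' @export
auc_dof <- function(w, na, ni) {
  if (na < 2 || ni < 2)
    stop_ligfish("auc_dof needs na >= 2 and ni >= 2", "ligfish_degenerate_error")
  v <- auc_var_components(w, na, ni)
  if (v$va + v$vi == 0) return(na + ni - 2)  # w = 1: flat limit, dof immaterial
  (v$va + v$vi)^2 / (v$va^2 / (na - 1) + v$vi^2 / (ni - 1))
}

#' ROC curve points
#'
#' One operating point per distinct score threshold, scanned from the
#' highest score down, plus the (0, 0) origin. At a threshold, compounds
#' with scores >= threshold are called active.
#'
#' @inheritParams auc_rank_sum
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- normalize_labels(labels)
  na <- sum(labels == "active"); ni <- sum(labels == "inactive")
  if (na == 0L || ni == 0L)
    stop_ligfish("ROC needs both classes", "ligfish_degenerate_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == "active"), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == "inactive"), numeric(1))
  data.frame(threshold = c(Inf, thr), tpr = c(0, tp / na), fpr = c(0, fp / ni))
}

#' Power Metric at a fixed operating quota
#'
#' Early-recognition objective TPR/(TPR + FPR) evaluated where the ROC
#' walk crosses the quota chi = TPR + FPR (default 0.5). TPR and FPR are
#' linearly interpolated between the adjacent operating points to the
#' crossing, so PM = TPR*/chi there. A perfect ranker yields 1; a random
#' one about 0.5.
#'
#' @inheritParams auc_rank_sum
#' @param chi Operating quota (0 < chi < 2).
#' @return Power Metric in \[0, 1\].
#' @export
power_metric <- function(scores, labels, chi = 0.5) {
  stopifnot(chi > 0, chi < 2)
  rc <- roc_curve(scores, labels)
  s <- rc$tpr + rc$fpr
  k <- which(s >= chi)[1L]
  if (is.na(k)) k <- nrow(rc)          # cannot happen: s ends at 2
  if (k == 1L) return(rc$tpr[1L] / chi)
  f <- (chi - s[k - 1L]) / (s[k] - s[k - 1L])
  tpr_star <- rc$tpr[k - 1L] + f * (rc$tpr[k] - rc$tpr[k - 1L])
  tpr_star / chi
}

#' Contingency-table metrics: F-score, MCC, enrichment factor
#'
#' * F-score: harmonic mean of precision TP/(TP+FP) and recall TP/(TP+FN);
#' * MCC: (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN));
#' * EF: precision divided by the prevalence of actives. By default the
#'   table's own prevalence (TP+FN)/N is used; pass `prevalence_override =
#'   c(na_total, n_total)` to use the prevalence of a larger collection
#'   the table was drawn from (the convention used when a selection is
#'   validated against a full screening deck).
#'
#' Metrics whose denominator vanishes are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param tp,fp,tn,fn Non-negative contingency counts.
#' @param prevalence_override Optional numeric length-2 vector
#'   `c(actives_total, n_total)`.
#' @return List with `f_score`, `mcc`, `ef`, and the inputs echoed.
#' @export
contingency_metrics <- function(tp, fp, tn, fn, prevalence_override = NULL) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  prev <- if (is.null(prevalence_override)) {
    n <- tp + fp + tn + fn
    if (n > 0) (tp + fn) / n else NA_real_
  } else {
    stopifnot(length(prevalence_override) == 2L, prevalence_override[2L] > 0)
    prevalence_override[1L] / prevalence_override[2L]
  }
  ef <- if (!is.na(precision) && !is.na(prev) && prev > 0) precision / prev
        else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       precision = precision, recall = recall,
       f_score = f, mcc = mcc, ef = ef)
}

#' Select the best decision threshold by sweeping a grid
#'
#' Calls each compound active when its score (typically the Pa-Pi mean) is
#' at or above the candidate threshold, evaluates the chosen contingency
#' metric, and returns the grid value maximizing it. Ties are broken
#' toward the smallest threshold; undefined metric values never win.
#'
#' @param scores Numeric decision scores (e.g. Pa-Pi means).
#' @param labels Parallel activity labels.
#' @param metric One of "mcc", "f_score", "ef".
#' @param grid Threshold grid (default -1 to 1 in steps of 0.05).
#' @param prevalence_override Passed to [contingency_metrics()].
#' @return List with `threshold`, `value`, and the full sweep data frame.
#' @export
sweep_threshold <- function(scores, labels, metric = c("mcc", "f_score", "ef"),
                            grid = seq(-1, 1, by = 0.05),
                            prevalence_override = NULL) {
  metric <- match.arg(metric)
  labels <- normalize_labels(labels)
  if (length(unique(labels)) < 2L)
    stop_ligfish("threshold sweep needs both classes", "ligfish_degenerate_error")
  vals <- vapply(grid, function(t) {
    call_active <- scores >= t
    m <- contingency_metrics(
      tp = sum(call_active & labels == "active"),
      fp = sum(call_active & labels == "inactive"),
      tn = sum(!call_active & labels == "inactive"),
      fn = sum(!call_active & labels == "active"),
      prevalence_override = prevalence_override)
    m[[metric]]
  }, numeric(1))
  if (all(is.na(vals)))
    stop_ligfish("metric undefined over the whole grid", "ligfish_degenerate_error")
  best <- which(vals == max(vals, na.rm = TRUE))[1L]
  list(threshold = grid[best], value = vals[best],
       sweep = data.frame(threshold = grid, value = vals))
}

#' Filter models by validation AUC
#'
#' Retains models whose out-of-sample validation AUC is strictly greater
#' than 0.5 (a model at exactly 0.5 carries no ranking information and is
#' dropped). An empty survivor set is returned as an explicit empty
#' object, with a warning, so downstream aggregation can react.
#'
#' @param models Data frame with at least columns `dataset_id` and `auc`.
#' @param min_auc Exclusive lower bound (default 0.5).
#' @return The retained rows of `models`.
#' @export
filter_models <- function(models, min_auc = 0.5) {
  stopifnot(is.data.frame(models), all(c("dataset_id", "auc") %in% names(models)))
  keep <- models$auc > min_auc
  out <- models[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no models passed the AUC filter; downstream ranking will be empty",
            call. = FALSE)
  out
}
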