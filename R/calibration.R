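# Calibration module: convert raw ensemble scores into Pa/Pi activity
# probabilities by comparison with the out-of-sample reference score
# distribution, attach 95% confidence limits on Pa-Pi via the member
# score spread, and call compounds active/inactive. The lower Pa-Pi limit
# doubles as an applicability-domain filter: when the members disagree so
# much that the lower limit dips below zero, the compound cannot be
# called active no matter how high the mean.

#' Pa / Pi from a raw score and a reference distribution
#'
#' Pa is the fraction of reference actives scoring worse than `score`
#' (so a compound beating every active has Pa = 1); Pi is the fraction of
#' reference inactives scoring better. Ties count 1/2, consistent with
#' the midrank interpolation used for the AUC.
#'
#' @param score Raw ensemble score (finite).
#' @param ref_scores Reference scores (typically the per-compound OOF
#'   means of the training compounds).
#' @param ref_labels Parallel labels of the reference compounds.
#' @return List with `pa`, `pi` and `papi = pa - pi`.
#' @export
pa_pi <- function(score, ref_scores, ref_labels) {
  if (!is.finite(score))
    stop_ligfish("non-finite score in Pa/Pi calibration", "ligfish_degenerate_error")
  ref_labels <- normalize_labels(ref_labels)
  act <- ref_scores[ref_labels == "active"]
  ina <- ref_scores[ref_labels == "inactive"]
  if (length(act) == 0L || length(ina) == 0L)
    stop_ligfish("Pa/Pi reference needs both classes", "ligfish_degenerate_error")
  pa <- (sum(act < score) + 0.5 * sum(act == score)) / length(act)
  pi_ <- (sum(ina > score) + 0.5 * sum(ina == score)) / length(ina)
  list(pa = pa, pi = pi_, papi = pa - pi_)
}

#' 95% confidence limits of a member-score sample
#'
#' t-interval on the mean of the `n` member scores: mean +/-
#' t(0.975, n-1) * SD / sqrt(n). With a single score the limits are
#' undefined (`NA`), which downstream prediction treats as
#' low-confidence-inactive.
#'
#' @param scores Raw scores of one compound over the ensemble members.
#' @return List with `mean`, `lower`, `upper`, `sd`, `n`.
#' @export
score_limits <- function(scores) {
  n <- length(scores)
  m <- mean(scores)
  if (n < 2L)
    return(list(mean = m, lower = NA_real_, upper = NA_real_,
                sd = NA_real_, n = n))
  s <- sd(scores)
  hw <- qt(0.975, n - 1L) * s / sqrt(n)
  list(mean = m, lower = m - hw, upper = m + hw, sd = s, n = n)
}

#' Activity call from Pa-Pi mean and lower limit
#'
#' The decision rule applied to every prediction: active iff the Pa-Pi
#' mean is at or above the threshold AND the Pa-Pi lower confidence limit
#' is strictly positive. A compound whose lower limit falls to or below
#' zero is called inactive no matter how high its mean (applicability
#' domain filter); an undefined lower limit (single member) is treated
#' the same way.
#'
#' @param papi_mean,papi_lower Pa-Pi mean and lower 95% limit.
#' @param threshold Decision threshold in \[-1, 1\].
#' @return "active" or "inactive".
#' @export
papi_call <- function(papi_mean, papi_lower, threshold = 0.15) {
  stopifnot(threshold >= -1, threshold <= 1)
  ifelse(!is.na(papi_lower) & papi_mean >= threshold & papi_lower > 0,
         "active", "inactive")
}

#' Predict activity of a compound against one ensemble
#'
#' The compound's fingerprint is scored by every member; the mean score
#' gives the Pa-Pi mean, and the upper/lower 95% score limits give the
#' Pa-Pi upper limit (highest Pa minus lowest Pi) and lower limit (lowest
#' Pa minus highest Pi). The compound is called active iff the Pa-Pi mean
#' reaches `threshold` (inclusive) AND the Pa-Pi lower limit is strictly
#' positive; otherwise inactive.
#'
#' @param ensemble A fitted `ligfish_ensemble`.
#' @param keys Modal-fingerprint key vector of the query compound.
#' @param compound_id Identifier used in the output row.
#' @param threshold Pa-Pi decision threshold in \[-1, 1\] (default 0.15).
#' @return One-row data frame with columns compound_id, dataset_id,
#'   method, raw_mean, raw_sd, n_models, pa_mean, pi_mean, papi_mean,
#'   papi_lower, papi_upper, call, empty_fingerprint.
#' @export
predict_compound <- function(ensemble, keys, compound_id = "query",
                             threshold = 0.15) {
  stopifnot(threshold >= -1, threshold <= 1)
  sc <- ensemble_score(ensemble, keys)
  lim <- score_limits(sc$scores)
  ref_s <- ensemble$oof_mean
  ref_l <- ensemble$labels
  at_mean <- pa_pi(lim$mean, ref_s, ref_l)
  if (is.na(lim$lower)) {
    papi_lower <- NA_real_; papi_upper <- NA_real_
  } else {
    at_up <- pa_pi(lim$upper, ref_s, ref_l)
    at_lo <- pa_pi(lim$lower, ref_s, ref_l)
    papi_upper <- at_up$pa - at_lo$pi   # highest Pa minus lowest Pi
    papi_lower <- at_lo$pa - at_up$pi   # lowest Pa minus highest Pi
  }
  call <- papi_call(at_mean$papi, papi_lower, threshold)
  data.frame(
    compound_id = compound_id, dataset_id = ensemble$dataset_id,
    method = ensemble$method,
    raw_mean = lim$mean, raw_sd = if (is.na(lim$sd)) 0 else lim$sd,
    n_models = lim$n,
    pa_mean = at_mean$pa, pi_mean = at_mean$pi,
    papi_mean = at_mean$papi,
    papi_lower = papi_lower, papi_upper = papi_upper,
    call = call, empty_fingerprint = sc$empty_fingerprint,
    stringsAsFactors = FALSE
  )
}

#' Predict activity for a set of compounds
#'
#' @param ensemble A fitted `ligfish_ensemble`.
#' @param fps Named list of fingerprints (key vectors).
#' @param threshold Pa-Pi decision threshold.
#' @return Data frame, one [predict_compound()] row per compound.
#' @export
predict_compounds <- function(ensemble, fps, threshold = 0.15) {
  do.call(rbind, lapply(names(fps), function(id)
    predict_compound(ensemble, fps[[id]], id, threshold)))
}

#' Combine SVM and naive Bayes predictions ("Both" rule)
#'
#' A compound is predicted active if either method predicted it active.
#' Pa-Pi summary columns carry the elementwise maximum of the two
#' methods' values (informational; the call is what the rule defines).
#'
#' @param pred_svm,pred_nb Prediction data frames from
#'   [predict_compounds()] for the same compounds and dataset.
#' @return Prediction data frame with method = "both".
#' @export
combine_methods <- function(pred_svm, pred_nb) {
  if (!identical(pred_svm$compound_id, pred_nb$compound_id) ||
      !identical(pred_svm$dataset_id, pred_nb$dataset_id))
    stop_ligfish("combine_methods: compound/dataset ids do not match",
                 "ligfish_schema_error")
  out <- pred_svm
  out$method <- "both"
  for (col in c("raw_mean", "raw_sd", "pa_mean", "papi_mean",
                "papi_lower", "papi_upper"))
    out[[col]] <- pmax(pred_svm[[col]], pred_nb[[col]])
  out$pi_mean <- pmin(pred_svm$pi_mean, pred_nb$pi_mean)
  out$call <- ifelse(pred_svm$call == "active" | pred_nb$call == "active",
                     "active", "inactive")
  out
}

#' Write a prediction table to TSV
#'
#' Columns: compound_id, dataset_id, method, raw_mean, papi_mean,
#' papi_lower, papi_upper, call.
#'
#' @param pred Prediction data frame.
#' @param path Output path.
#' @export
write_prediction_tsv <- function(pred, path) {
  cols <- c("compound_id", "dataset_id", "method", "raw_mean",
            "papi_mean", "papi_lower", "papi_upper", "call")
  write.table(pred[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
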