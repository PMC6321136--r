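# Ensemble module: recurrent stratified training of SVM / naive Bayes
# member models, SVM cost selection by 5-fold cross-validated Power
# Metric, and collection of per-compound out-of-sample (OOF) score
# distributions — the reference material for Pa/Pi calibration.

#' The SVM cost grid
#'
#' Exponentially growing sequence 2^-12, 2^-11, ..., 2^6 (19 values,
#' step x2), the customary libsvm search range.
#'
#' @return Numeric vector of length 19.
#' @export
svm_cost_grid <- function() 2^(-12:6)

#' Select the SVM cost by cross-validated Power Metric
#'
#' Stratified 5-fold cross-validation over the training compounds; for
#' each candidate cost the mean fold Power Metric at chi = 0.5 is
#' computed, and the cost maximizing it is returned. Ties break toward
#' the smaller cost (stronger regularization). Deterministic given
#' `seed`.
#'
#' @param fps Named list of fingerprints (key vectors) for the training
#'   compounds.
#' @param labels Parallel activity labels.
#' @param seed Integer seed for the fold assignment.
#' @param grid Candidate costs (default [svm_cost_grid()]).
#' @param n_folds Number of CV folds (default 5).
#' @return Selected cost, with the per-cost mean Power Metric attached as
#'   attribute `"pm_by_cost"`.
#' @export
select_cost <- function(fps, labels, seed, grid = svm_cost_grid(),
                        n_folds = 5L) {
  labels <- normalize_labels(labels)
  n <- length(fps)
  stopifnot(length(labels) == n)
  vocab <- sort(unique(unlist(fps)))
  if (length(vocab) == 0L)
    stop_ligfish("degenerate feature matrix: no keys in training set",
                 "ligfish_degenerate_error")
  x <- fp_matrix(fps, vocab)
  cs <- colSums(x)
  if (all(cs == 0 | cs == n))
    stop_ligfish("degenerate feature matrix: all fingerprints identical",
                 "ligfish_degenerate_error")
  folds <- with_seed(seed, {
    f <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  xa <- cbind(x, 1)  # bias column, shared by train and held-out blocks
  pm_folds <- vapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    if (length(unique(labels[tr])) < 2L || length(unique(labels[!tr])) < 2L)
      return(rep(NA_real_, length(grid)))
    y2 <- ifelse(labels[tr] == "active", 1, -1)
    dec <- .svm_dcd_path(xa[tr, , drop = FALSE], y2,
                         xa[!tr, , drop = FALSE], grid)
    apply(dec, 2L, power_metric, labels = labels[!tr], chi = 0.5)
  }, numeric(length(grid)))
  pm <- rowMeans(pm_folds, na.rm = TRUE)
  best <- grid[which(pm == max(pm))[1L]]   # grid ascends: first max = smallest
  attr(best, "pm_by_cost") <- stats::setNames(pm, format(grid))
  best
}

#' Train an ensemble of classifiers by recurrent stratified resampling
#'
#' For every repeat of the split plan, one member model is fitted on that
#' repeat's 70% training stratum (for SVM, with the cost selected by
#' [select_cost()] on the same stratum) and scored on the 30% validation
#' stratum. Each compound's validation-set raw scores are pooled across
#' repeats into its out-of-sample (OOF) score list; the per-compound OOF
#' means are the ensemble's reference score distribution.
#'
#' @param dataset An [activity_dataset()].
#' @param fps Named list of fingerprints covering every dataset compound.
#' @param method "svm_linear" or "naive_bayes".
#' @param split_plan A [stratified_split()] plan; by default one is drawn
#'   from `seed` with 30 repeats.
#' @param seed Master seed (used for the default split plan and for
#'   per-member cost selection).
#' @param cost_grid SVM cost grid.
#' @param nb_alpha Laplace smoothing for naive Bayes.
#' @return Object of class `ligfish_ensemble`.
#' @export
train_ensemble <- function(dataset, fps, method = c("svm_linear", "naive_bayes"),
                           split_plan = NULL, seed = 1L,
                           cost_grid = svm_cost_grid(), nb_alpha = 1) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "ligfish_dataset"))
  ids <- dataset$records$compound_id
  missing_fp <- setdiff(ids, names(fps))
  if (length(missing_fp))
    stop_ligfish(sprintf("no fingerprint for compound(s): %s",
                         paste(missing_fp, collapse = ", ")),
                 "ligfish_schema_error")
  if (is.null(split_plan)) split_plan <- stratified_split(dataset, seed)
  labels <- stats::setNames(dataset$records$label, ids)

  oof <- stats::setNames(rep(list(numeric()), length(ids)), ids)
  members <- vector("list", split_plan$n_repeats)
  for (r in seq_len(split_plan$n_repeats)) {
    tr <- split_plan$assignments[[r]]
    tr_ids <- names(tr)[tr]; va_ids <- names(tr)[!tr]
    tr_fps <- fps[tr_ids]
    vocab <- sort(unique(unlist(tr_fps)))
    x_tr <- fp_matrix(tr_fps, vocab)
    if (method == "svm_linear") {
      cost <- select_cost(tr_fps, labels[tr_ids], seed = split_plan$seed + r,
                          grid = cost_grid)
      fit <- svm_fit(x_tr, labels[tr_ids], as.numeric(cost))
      fit$selected_cost <- as.numeric(cost)
    } else {
      fit <- nb_fit(x_tr, labels[tr_ids], alpha = nb_alpha)
    }
    fit$repeat_index <- r
    members[[r]] <- fit
    s_va <- member_decision(fit, fps[va_ids])
    for (k in seq_along(va_ids))
      oof[[va_ids[k]]] <- c(oof[[va_ids[k]]], s_va[k])
  }
  oof_mean <- vapply(oof, mean, numeric(1))
  oof_sd <- vapply(oof, function(v) if (length(v) > 1L) sd(v) else 0, numeric(1))
  structure(list(
    dataset_id = dataset$dataset_id, method = method,
    members = members, n_members = split_plan$n_repeats,
    split_seed = split_plan$seed,
    labels = labels, oof_scores = oof,
    oof_mean = oof_mean, oof_sd = oof_sd
  ), class = "ligfish_ensemble")
}

#' @export
print.ligfish_ensemble <- function(x, ...) {
  cat(sprintf("<%s ensemble on '%s': %d members, %d reference compounds>\n",
              x$method, x$dataset_id, x$n_members, length(x$oof_mean)))
  invisible(x)
}

#' Score a fingerprint against every member of an ensemble
#'
#' @param ensemble A fitted `ligfish_ensemble`.
#' @param keys Character vector of triplet keys (a modal fingerprint). An
#'   empty fingerprint is scored as the all-zero vector and flagged.
#' @return List with `scores` (one raw decision value per member), `mean`,
#'   `sd`, `n`, and `empty_fingerprint`.
#' @export
ensemble_score <- function(ensemble, keys) {
  stopifnot(inherits(ensemble, "ligfish_ensemble"))
  fps <- list(q = as.character(keys))
  s <- vapply(ensemble$members, function(m) member_decision(m, fps), numeric(1))
  list(scores = s, mean = mean(s),
       sd = if (length(s) > 1L) sd(s) else 0,
       n = length(s), empty_fingerprint = length(keys) == 0L)
}

#' Out-of-sample validation AUC of an ensemble
#'
#' Rank-sum AUC of the per-compound OOF mean scores against the training
#' labels — the ensemble's internal validation statistic.
#'
#' @param ensemble A fitted `ligfish_ensemble`.
#' @return List with `auc`, `se` and `dof` (Hanley/Welch-Satterthwaite).
#' @export
ensemble_validation <- function(ensemble) {
  w <- auc_rank_sum(ensemble$oof_mean, ensemble$labels)
  na <- sum(ensemble$labels == "active"); ni <- sum(ensemble$labels == "inactive")
  list(auc = w,
       se = if (na >= 2 && ni >= 2) auc_se(w, na, ni) else NA_real_,
       dof = if (na >= 2 && ni >= 2) auc_dof(w, na, ni) else NA_real_,
       na = na, ni = ni)
}
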