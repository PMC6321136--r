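# End-to-end target-fishing workflow: train one ensemble per bioassay
# dataset, validate it, drop uninformative models (AUC <= 0.5), predict
# the query compounds against the survivors, and aggregate active calls
# into a ranked activity-class table.

#' Default per-method Pa-Pi class-scoring thresholds
#'
#' 0.25 for the linear SVM and 0.30 for naive Bayes — the MCC-selected
#' operating points for class-level scoring; both sit on the standard
#' 0.05 threshold grid.
#'
#' @param method "svm_linear" or "naive_bayes".
#' @return Numeric threshold.
#' @export
default_class_threshold <- function(method = c("svm_linear", "naive_bayes")) {
  switch(match.arg(method), svm_linear = 0.25, naive_bayes = 0.30)
}

#' Run the full target-fishing pipeline for one method
#'
#' @param datasets Named list of [activity_dataset()] objects.
#' @param fps Named list of fingerprints covering all modeled compounds.
#' @param query_fps Named list of query-compound fingerprints.
#' @param class_map Data frame dataset_id/class_id.
#' @param method "svm_linear" or "naive_bayes".
#' @param threshold Pa-Pi call threshold (default: the method's
#'   [default_class_threshold()]).
#' @param n_repeats Ensemble repeats per dataset (default 30).
#' @param seed Master seed; dataset k trains with seed `seed + 1000 * k`.
#' @param auc_filter Drop models with validation AUC <= 0.5 before class
#'   scoring (default TRUE).
#' @return List with `models` (data frame dataset_id/auc/se/kept),
#'   `predictions` (per query x model), and `class_scores` (ranked).
#' @export
target_fish <- function(datasets, fps, query_fps, class_map,
                        method = c("svm_linear", "naive_bayes"),
                        threshold = NULL, n_repeats = 30L, seed = 1L,
                        auc_filter = TRUE) {
  method <- match.arg(method)
  threshold <- threshold %||% default_class_threshold(method)
  model_rows <- list(); preds <- list()
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    plan <- stratified_split(ds, seed + 1000L * k, n_repeats = n_repeats)
    ens <- train_ensemble(ds, fps, method = method, split_plan = plan)
    val <- ensemble_validation(ens)
    model_rows[[k]] <- data.frame(dataset_id = ds$dataset_id, auc = val$auc,
                                  se = val$se, stringsAsFactors = FALSE)
    preds[[k]] <- predict_compounds(ens, query_fps, threshold = threshold)
  }
  models <- do.call(rbind, model_rows)
  kept <- if (auc_filter) filter_models(models) else models
  models$kept <- models$dataset_id %in% kept$dataset_id
  predictions <- do.call(rbind, preds)
  predictions <- predictions[predictions$dataset_id %in% kept$dataset_id, ,
                             drop = FALSE]
  class_map_kept <- class_map[class_map$dataset_id %in% kept$dataset_id, ,
                              drop = FALSE]
  class_scores <- if (nrow(class_map_kept))
    score_activity_classes(predictions, class_map_kept, length(query_fps))
  else
    data.frame(class_id = character(), m = integer(), n_hits = integer(),
               score = numeric(), rank = integer())
  list(method = method, threshold = threshold, models = models,
       predictions = predictions, class_scores = class_scores)
}
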