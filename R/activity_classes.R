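# Activity-class module: group per-assay models into activity classes,
# aggregate active calls into a sqrt(M)-normalized class score, label
# classes by predominance of experimental outcomes, validate the ranking
# with a class-level ROC, and merge SVM/NB rankings into one ordered list.

#' Construct an activity class
#'
#' @param class_id Class identifier (e.g. a disease or target family).
#' @param model_ids Character vector of member dataset ids (>= 1; a model
#'   may belong to several classes).
#' @return Object of class `ligfish_activity_class`.
#' @export
activity_class <- function(class_id, model_ids) {
  model_ids <- unique(as.character(model_ids))
  if (length(model_ids) < 1L)
    stop_ligfish(sprintf("activity class '%s' has zero models", class_id),
                 "ligfish_schema_error")
  structure(list(class_id = as.character(class_id), model_ids = model_ids,
                 m = length(model_ids)),
            class = "ligfish_activity_class")
}

#' Score one activity class from per-model active calls
#'
#' The class score is the number of (compound, model) instances called
#' active among the class's models, divided by the number of query
#' compounds and by the square root of the class's model count. The
#' sqrt(M) normalization balances classes of different sizes: dividing by
#' M penalizes large classes, dividing by nothing privileges them. A
#' compound active in k of the class's models contributes k instances.
#'
#' @param predictions Data frame with columns `compound_id`, `dataset_id`,
#'   `call` (calls already made at the desired threshold with the
#'   positive-lower-limit filter).
#' @param class An [activity_class()].
#' @param n_compounds Number of query compounds submitted.
#' @return List with `class_id`, `n_hits`, `score`, `m`.
#' @export
class_score <- function(predictions, class, n_compounds) {
  stopifnot(inherits(class, "ligfish_activity_class"), n_compounds >= 1)
  in_class <- predictions$dataset_id %in% class$model_ids
  n_hits <- sum(in_class & predictions$call == "active")
  list(class_id = class$class_id, n_hits = n_hits,
       score = n_hits / (n_compounds * sqrt(class$m)), m = class$m)
}

#' Score and rank all activity classes
#'
#' @param predictions Prediction data frame (one row per compound x
#'   model) with `call` column.
#' @param class_map Data frame with columns `dataset_id`, `class_id`.
#' @param n_compounds Number of query compounds.
#' @return Data frame with columns class_id, m, n_hits, score, rank —
#'   rank 1 is the best score; ties broken by class_id for determinism.
#' @export
score_activity_classes <- function(predictions, class_map, n_compounds) {
  classes <- lapply(split(class_map$dataset_id, class_map$class_id),
                    function(ids) activity_class("x", ids))
  out <- do.call(rbind, lapply(names(classes), function(cid) {
    cl <- classes[[cid]]; cl$class_id <- cid
    s <- class_score(predictions, cl, n_compounds)
    data.frame(class_id = cid, m = s$m, n_hits = s$n_hits, score = s$score,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$score, out$class_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Label activity classes by predominance of experimental outcomes
#'
#' A class with more active than inactive experimental points is
#' "probable_active", with more inactive "probable_inactive"; equal
#' counts exclude the class from class-level validation.
#'
#' @param n_active,n_inactive Non-negative counts per class (vectors).
#' @return Character vector: probable_active / probable_inactive /
#'   excluded.
#' @export
label_classes <- function(n_active, n_inactive) {
  stopifnot(all(n_active >= 0), all(n_inactive >= 0),
            length(n_active) == length(n_inactive))
  ifelse(n_active > n_inactive, "probable_active",
         ifelse(n_inactive > n_active, "probable_inactive", "excluded"))
}

#' Class-level ROC validation of an activity-class ranking
#'
#' Rank-sum AUC of the class scores, with "probable_active" classes as
#' positives; "excluded" classes are dropped first.
#'
#' @param scores Numeric class scores.
#' @param labels Parallel labels from [label_classes()].
#' @return List with `auc`, `se`, `na`, `ni`.
#' @export
class_roc <- function(scores, labels) {
  keep <- labels != "excluded"
  scores <- scores[keep]; labels <- labels[keep]
  y <- ifelse(labels == "probable_active", "active", "inactive")
  w <- auc_rank_sum(scores, y)
  na <- sum(y == "active"); ni <- sum(y == "inactive")
  list(auc = w,
       se = if (na >= 2 && ni >= 2) auc_se(w, na, ni) else NA_real_,
       na = na, ni = ni)
}

#' Merge SVM and naive Bayes class rankings into a final ordered list
#'
#' Classes are ordered by the best (minimum) of their two ranks, then by
#' the average rank, then by class_id — a total order, so the output is
#' reproducible.
#'
#' @param rank_svm,rank_nb Named integer vectors (or data frames with
#'   columns class_id, rank) covering the same classes.
#' @return Data frame ordered by the combined key, with columns class_id,
#'   rank_svm, rank_nb, best_rank, mean_rank, final_rank.
#' @export
combine_rankings <- function(rank_svm, rank_nb) {
  as_vec <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$rank, r$class_id) else r
  }
  rs <- as_vec(rank_svm); rn <- as_vec(rank_nb)
  if (!setequal(names(rs), names(rn)))
    stop_ligfish(sprintf("rankings cover different classes: %s",
                         paste(union(setdiff(names(rs), names(rn)),
                                     setdiff(names(rn), names(rs))),
                               collapse = ", ")),
                 "ligfish_schema_error")
  rn <- rn[names(rs)]
  out <- data.frame(class_id = names(rs), rank_svm = unname(rs),
                    rank_nb = unname(rn),
                    best_rank = pmin(unname(rs), unname(rn)),
                    mean_rank = (unname(rs) + unname(rn)) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_rank, out$mean_rank, out$class_id), , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
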