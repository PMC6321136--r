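# Member classifiers: linear SVM (dual coordinate descent, compiled) and
# Bernoulli naive Bayes over present/absent triplet keys. Both operate on
# a dense 0/1 feature matrix whose columns are the triplet keys observed
# in the member's training set.

#' @noRd
fp_matrix <- function(fps, vocab) {
  m <- matrix(0, nrow = length(fps), ncol = length(vocab),
              dimnames = list(names(fps), vocab))
  for (i in seq_along(fps)) {
    j <- match(fps[[i]], vocab)
    j <- j[!is.na(j)]          # keys unseen in training are ignored
    m[i, j] <- 1
  }
  m
}

#' Fit a linear SVM on binary fingerprints
#'
#' L2-regularized L1-loss linear SVM solved by deterministic dual
#' coordinate descent; the bias is absorbed through a constant augmented
#' feature. Scores are signed distances to the separating hyperplane (up
#' to the weight norm), not probabilities.
#'
#' @param x 0/1 feature matrix (rows = compounds).
#' @param y Labels, "active"/"inactive" (actives are the +1 class).
#' @param cost Misclassification cost C (> 0).
#' @return List with weight vector `w`, bias `b`, and `vocab`.
#' @export
svm_fit <- function(x, y, cost) {
  y2 <- ifelse(normalize_labels(y) == "active", 1, -1)
  if (length(unique(y2)) < 2L)
    stop_ligfish("SVM training set lacks a class", "ligfish_degenerate_error")
  cs <- colSums(x)
  if (all(cs == 0 | cs == nrow(x)))   # every key column constant
    stop_ligfish("degenerate feature matrix: all fingerprints identical",
                 "ligfish_degenerate_error")
  xa <- cbind(x, `(bias)` = 1)
  w <- .svm_dcd_fit(xa, y2, cost)
  list(method = "svm_linear", w = w[-length(w)], b = w[length(w)],
       vocab = colnames(x), cost = cost)
}

#' @rdname svm_fit
#' @param model Fitted model.
#' @export
svm_decision <- function(model, x) {
  as.numeric(x %*% model$w + model$b)
}

#' Fit a Bernoulli naive Bayes classifier on binary fingerprints
#'
#' Per-key Bernoulli likelihoods with Laplace smoothing, restricted to
#' keys seen in training; the score is the log posterior odds
#' log P(active | x) - log P(inactive | x), additive over keys.
#'
#' @inheritParams svm_fit
#' @param alpha Laplace smoothing constant (> 0, default 1).
#' @return List with per-key log-likelihood terms and log prior odds.
#' @export
nb_fit <- function(x, y, alpha = 1) {
  stopifnot(alpha > 0)
  lab <- normalize_labels(y)
  act <- lab == "active"
  na <- sum(act); ni <- sum(!act)
  if (na == 0L || ni == 0L)
    stop_ligfish("NB training set lacks a class", "ligfish_degenerate_error")
  pa <- (colSums(x[act, , drop = FALSE]) + alpha) / (na + 2 * alpha)
  pi_ <- (colSums(x[!act, , drop = FALSE]) + alpha) / (ni + 2 * alpha)
  list(method = "naive_bayes",
       w1 = log(pa) - log(pi_),             # contribution of a present key
       w0 = log(1 - pa) - log(1 - pi_),     # contribution of an absent key
       prior = log(na) - log(ni),
       vocab = colnames(x), alpha = alpha)
}

#' @rdname nb_fit
#' @param model Fitted model.
#' @export
nb_score <- function(model, x) {
  as.numeric(model$prior + x %*% model$w1 + (1 - x) %*% model$w0)
}

#' @noRd
member_decision <- function(model, fps) {
  x <- fp_matrix(fps, model$vocab)
  if (model$method == "svm_linear") svm_decision(model, x) else nb_score(model, x)
}
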