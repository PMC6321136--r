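# Ensemble module: cost selection, recurrent training, OOF score
# collection, member scoring.

make_fp_data <- function(seed = 7, ...) {
  gen_fingerprint_dataset(fingerprint_spec(n_active = 20L, n_inactive = 20L,
                                           n_bits = 120L, seed = seed, ...))
}

test_that("the cost grid has 19 values from 2^-12 to 2^6 stepping x2", {
  g <- svm_cost_grid()
  expect_length(g, 19L)
  expect_equal(g[1], 2^-12)
  expect_equal(g[19], 2^6)
  expect_equal(unique(round(diff(log2(g)), 12)), 1)
})

test_that("cost selection maximizes CV Power Metric and is deterministic", {
  sep <- gen_fingerprint_dataset(fingerprint_spec(
    n_active = 50L, n_inactive = 50L, n_bits = 120L,
    p_signal_active = 0.9, p_signal_inactive = 0.1, seed = 13))
  labs <- setNames(sep$dataset$records$label, sep$dataset$records$compound_id)
  c1 <- select_cost(sep$fingerprints, labs, seed = 5)
  c2 <- select_cost(sep$fingerprints, labs, seed = 5)
  expect_identical(as.numeric(c1), as.numeric(c2))
  expect_true(as.numeric(c1) %in% svm_cost_grid())
  pm <- attr(c1, "pm_by_cost")
  expect_length(pm, 19L)
  # separable data: selected cost achieves near-perfect early recognition
  expect_gte(max(pm), 0.95)
  # tie-break toward the smaller cost
  expect_equal(as.numeric(c1), svm_cost_grid()[which(pm == max(pm))[1]])
  # degenerate features
  same <- list(a = c("k1", "k2"), b = c("k1", "k2"), c = c("k1", "k2"),
               d = c("k1", "k2"))
  expect_error(select_cost(same, c("active", "active", "inactive", "inactive"),
                           seed = 1),
               class = "ligfish_degenerate_error")
})

test_that("ensembles conserve the protocol: members, OOF coverage, determinism", {
  g <- make_fp_data()
  plan <- stratified_split(g$dataset, 42, n_repeats = 30)
  for (method in c("naive_bayes", "svm_linear")) {
    ens <- train_ensemble(g$dataset, g$fingerprints, method, plan)
    expect_length(ens$members, 30L)
    expect_true(all(lengths(ens$oof_scores) >= 1))
    expect_true(all(is.finite(ens$oof_mean)))
    # separable synthetic data: perfect internal validation
    expect_equal(ensemble_validation(ens)$auc, 1.0)
  }
  # determinism: same plan -> identical OOF scores
  e1 <- train_ensemble(g$dataset, g$fingerprints, "naive_bayes", plan)
  e2 <- train_ensemble(g$dataset, g$fingerprints, "naive_bayes", plan)
  expect_identical(e1$oof_scores, e2$oof_scores)
  # missing fingerprints refuse
  expect_error(train_ensemble(g$dataset, g$fingerprints[-1], "naive_bayes", plan),
               class = "ligfish_schema_error")
})

test_that("member scoring: counts, empty fingerprints, SVM antisymmetry", {
  g <- make_fp_data()
  plan <- stratified_split(g$dataset, 42, n_repeats = 30)
  ens <- train_ensemble(g$dataset, g$fingerprints, "svm_linear", plan)
  sc <- ensemble_score(ens, g$fingerprints[[1]])
  expect_equal(sc$n, 30L)
  expect_length(sc$scores, 30L)
  expect_false(sc$empty_fingerprint)
  # query identical to a strongly active training compound scores above
  # the inactive reference distribution
  expect_gt(sc$mean, median(ens$oof_mean[g$dataset$records$label == "inactive"]))
  # empty fingerprint is scored (bias only for SVM) and flagged
  sc0 <- ensemble_score(ens, character())
  expect_true(sc0$empty_fingerprint)
  m <- ens$members[[1]]
  expect_equal(sc0$scores[1], m$b)
  # decision value is linear: hand dot-product check on a constructed pair
  keys <- m$vocab[1:3]
  x1 <- as.numeric(m$vocab %in% keys)
  expect_equal(ensemble_score(ens, keys)$scores[1],
               sum(m$w * x1) + m$b, tolerance = 1e-12)
  # sign antisymmetry of the margin term: complement pair constructed so
  # that x + x_c = all-ones; decision(x) + decision(x_c) = sum(w) + 2b
  comp <- setdiff(m$vocab, keys)
  expect_equal(ensemble_score(ens, keys)$scores[1] +
                 ensemble_score(ens, comp)$scores[1],
               sum(m$w) + 2 * m$b, tolerance = 1e-10)
})

test_that("NB scores are additive over disjoint key sets", {
  g <- make_fp_data()
  plan <- stratified_split(g$dataset, 42, n_repeats = 30)
  ens <- train_ensemble(g$dataset, g$fingerprints, "naive_bayes", plan)
  m <- ens$members[[1]]
  a <- m$vocab[1:4]; b <- m$vocab[7:10]
  s <- function(k) ensemble_score(ens, k)$scores[1]
  expect_equal(s(union(a, b)), s(a) + s(b) - s(character()), tolerance = 1e-10)
})

test_that("label-shuffled data gives null validation AUC", {
  aucs <- vapply(1:6, function(s) {
    g <- gen_fingerprint_dataset(fingerprint_spec(
      n_active = 25L, n_inactive = 25L, n_bits = 120L,
      p_signal_active = 0.5, p_signal_inactive = 0.5, seed = 100 + s))
    plan <- stratified_split(g$dataset, 200 + s, n_repeats = 30)
    ensemble_validation(train_ensemble(g$dataset, g$fingerprints,
                                       "naive_bayes", plan))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("ensemble bundles survive a JSON round trip", {
  g <- make_fp_data()
  plan <- stratified_split(g$dataset, 42, n_repeats = 30)
  for (method in c("svm_linear", "naive_bayes")) {
    ens <- train_ensemble(g$dataset, g$fingerprints, method, plan)
    f <- tempfile(fileext = ".json")
    save_ensemble(ens, f)
    back <- load_ensemble(f)
    q <- g$fingerprints[[5]]
    expect_equal(ensemble_score(back, q)$scores, ensemble_score(ens, q)$scores)
    expect_equal(back$oof_mean, ens$oof_mean)
    expect_equal(back$labels, ens$labels)
  }
  expect_error(load_ensemble(tempfile()), class = "ligfish_io_error")
})
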