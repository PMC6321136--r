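# Metrics module: rank-sum AUC, Hanley SE, effective dof, Power Metric,
# contingency metrics, threshold sweep, AUC filter.

test_that("rank-sum AUC equals brute-force pair counting", {
  expect_equal(auc_rank_sum(c(3, 4, 1, 2), c("active", "active", "inactive", "inactive")), 1)
  expect_equal(auc_rank_sum(rep(2, 6), rep(c("active", "inactive"), 3)), 0.5)
  # hand-derived tie case: 6.5 of 9 pairs
  expect_equal(auc_rank_sum(c(0.9, 0.7, 0.4, 0.8, 0.4, 0.2),
                            rep(c("active", "inactive"), each = 3)), 6.5 / 9)
  # oracle equivalence on random instances with heavy ties
  set.seed(21)
  for (r in 1:200) {
    na <- sample(1:30, 1); ni <- sample(1:30, 1)
    s <- sample(seq(0, 1, by = 0.1), na + ni, replace = TRUE)
    lab <- rep(c("active", "inactive"), c(na, ni))
    expect_equal(auc_rank_sum(s, lab), oracle_auc(s, lab), tolerance = 1e-12)
  }
  # complement symmetry for tie-free data
  set.seed(4)
  s <- runif(40); lab <- rep(c("active", "inactive"), 20)
  expect_equal(auc_rank_sum(s, lab) + auc_rank_sum(-s, lab), 1)
  expect_error(auc_rank_sum(1:3, rep("active", 3)), class = "ligfish_degenerate_error")
})

test_that("AUC standard error and effective dof follow the declared formulas", {
  expect_equal(auc_se(1, 10, 20), 0)
  expect_equal(auc_se(0.8, 10, 20), 0.09067647, tolerance = 1e-7)
  # asymmetry in Na/Ni
  expect_false(isTRUE(all.equal(auc_se(0.8, 10, 20), auc_se(0.8, 20, 10))))
  # symmetric-component limit: nu = 2(Na-1) when va = vi and Na = Ni
  # va = vi (with Na = Ni) reduces to w^3 - 3w^2 + 4w - 1 = 0, root ~ 0.317
  f <- function(w) w^2 * (1 - w) / (1 + w) - w * (1 - w)^2 / (2 - w)^2
  w_star <- uniroot(f, c(0.05, 0.9))$root
  expect_equal(auc_dof(w_star, 15, 15), 2 * (15 - 1), tolerance = 1e-6)
  # single-component limit: vi -> 0 as Ni -> Inf gives nu -> Na - 1
  expect_equal(auc_dof(0.8, 10, 1e9), 10 - 1, tolerance = 1e-3)
  # regression value pinned by direct evaluation
  expect_equal(auc_dof(0.8, 10, 20), 11.89467, tolerance = 1e-5)
  expect_error(auc_dof(0.8, 1, 20), class = "ligfish_degenerate_error")
})

test_that("Power Metric behaves at the chi = 0.5 operating point", {
  lab <- rep(c("active", "inactive"), each = 10)
  # perfect ranker
  expect_equal(power_metric(c(10:1 + 100, 10:1), lab), 1)
  # anti-ranker: no active before the quota
  expect_equal(power_metric(c(10:1, 10:1 + 100), lab), 0)
  # random-ish scores stay in [0, 1]
  set.seed(8)
  for (r in 1:20) {
    pm <- power_metric(runif(20), lab)
    expect_gte(pm, 0); expect_lte(pm, 1)
  }
  # hand case: scores 4,3,2,1 labels A,I,A,I; walk: (tpr+fpr)/2 crossing
  # after first point tpr=.5 fpr=0 sum=.5 -> PM = .5/.5 = 1
  expect_equal(power_metric(4:1, c("active", "inactive", "active", "inactive")), 1)
})

test_that("contingency metrics reproduce printed validation rows", {
  # frozen from the published 2x2 tables; full-collection prevalence 128/309
  rows <- list(
    list(tp = 30, fp = 17, tn = 151, fn = 94, f = 0.35, mcc = 0.19, ef = 1.54),
    list(tp = 46, fp = 21, tn = 159, fn = 79, f = 0.48, mcc = 0.30, ef = 1.66),
    list(tp = 60, fp = 33, tn = 148, fn = 68, f = 0.54, mcc = 0.31, ef = 1.56),
    list(tp = 51, fp = 17, tn = 151, fn = 73, f = 0.53, mcc = 0.36, ef = 1.81),
    list(tp = 106, fp = 18, tn = 162, fn = 19, f = 0.85, mcc = 0.75, ef = 2.06))
  for (r in rows) {
    m <- contingency_metrics(r$tp, r$fp, r$tn, r$fn,
                             prevalence_override = c(128, 309))
    expect_equal(round(m$f_score, 2), r$f)
    expect_equal(round(m$mcc, 2), r$mcc)
    expect_equal(round(m$ef, 2), r$ef)
  }
  # perfect table
  m <- contingency_metrics(10, 0, 20, 0)
  expect_equal(m$f_score, 1); expect_equal(m$mcc, 1)
  # EF bound: EF <= 1/prevalence; MCC in [-1, 1]
  set.seed(3)
  for (r in 1:50) {
    t <- sample(0:40, 4, replace = TRUE)
    m <- contingency_metrics(t[1], t[2], t[3], t[4])
    if (!is.na(m$mcc)) { expect_gte(m$mcc, -1); expect_lte(m$mcc, 1) }
    if (!is.na(m$ef)) expect_lte(m$ef, sum(t) / (t[1] + t[4]) + 1e-12)
    if (!is.na(m$f_score)) { expect_gte(m$f_score, 0); expect_lte(m$f_score, 1) }
  }
  # undefined metrics are NA, not 0
  expect_true(is.na(contingency_metrics(0, 0, 5, 5)$f_score))
  expect_true(is.na(contingency_metrics(0, 0, 10, 0)$mcc))
})

test_that("threshold sweep maximizes the chosen metric on the grid", {
  # constructed separation: actives >= 0.3, inactives <= 0.1
  scores <- c(0.3, 0.45, 0.8, 0.35, 0.1, 0.05, -0.2, 0.0)
  labels <- rep(c("active", "inactive"), each = 4)
  sw <- sweep_threshold(scores, labels, "mcc")
  expect_gt(sw$threshold, 0.1)
  expect_lte(sw$threshold, 0.3)
  expect_equal(sw$value, 1)
  # argmax property over the whole grid
  expect_true(all(sw$value >= sw$sweep$value, na.rm = TRUE))
  # the published candidate cutoffs sit on the default grid
  expect_true(all(c(0.15, 0.25, 0.3) %in% round(sw$sweep$threshold, 10)))
  # tie -> smallest threshold
  sw2 <- sweep_threshold(c(1, 1, -1, -1), c("active", "active", "inactive", "inactive"),
                         "mcc")
  expect_equal(sw2$threshold, min(sw2$sweep$threshold[sw2$sweep$value == sw2$value],
                                  na.rm = TRUE))
  expect_error(sweep_threshold(1:4, rep("active", 4), "mcc"),
               class = "ligfish_degenerate_error")
})

test_that("the AUC model filter is strict at 0.5", {
  models <- data.frame(dataset_id = c("a", "b", "c"),
                       auc = c(0.5, 0.51, 0.49))
  kept <- filter_models(models)
  expect_equal(kept$dataset_id, "b")
  expect_warning(out <- filter_models(models[models$auc < 0.5, , drop = FALSE]),
                 "empty")
  expect_equal(nrow(out), 0L)
})

test_that("null AUC is centred at 0.5", {
  set.seed(77)
  lab <- rep(c("active", "inactive"), c(12, 18))
  aucs <- replicate(1000, auc_rank_sum(runif(30), sample(lab)))
  se <- sd(aucs) / sqrt(1000)
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})
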