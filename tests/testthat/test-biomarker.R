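make_eval_fixture <- function(seed = 47, n_edges = 30, n_planted = 5,
                              n_ref = 40, n_tumor = 30) {
  sim <- simulate_cohort(synth_config(n_ref = n_ref, n_tumor = n_tumor,
                                      n_edges = n_edges, n_planted = n_planted,
                                      seed = seed))
  ref <- build_reference(sim$panel, sim$catalog)
  dT <- delta_pcc(ref, sim$panel, "tumor")
  dC <- delta_pcc(ref, sim$panel, "non_tumor")
  list(sim = sim, dT = dT, dC = dC,
       all_edges = tibble::tibble(mirna = sim$catalog$mirna,
                                  lncrna = sim$catalog$lncrna))
}

test_that("feature table rows are sample delta-PCC columns restricted to candidates", {
  fx <- make_eval_fixture(n_ref = 10, n_tumor = 6, n_edges = 5, n_planted = 0)
  feats <- build_features(fx$dT, fx$dC, fx$all_edges)
  expect_equal(dim(feats), c(16L, 7L))          # 6 tumor + 10 control, 2 meta + 5 edges
  expect_equal(sum(feats$group == "tumor"), 6L)
  expect_identical(attr(feats, "n_imputed"), 0L)
  s <- fx$dT$sample_ids[2]
  row <- feats[feats$sample_id == s, attr(feats, "feature_cols")]
  expect_equal(unlist(row, use.names = FALSE), unname(fx$dT$delta[, s]))

  bogus <- tibble::tibble(mirna = "nope", lncrna = "nada")
  expect_error(build_features(fx$dT, fx$dC, bogus), "absent")
  expect_error(build_features(fx$dT, fx$dC, bogus[0, ]), "empty")
})

test_that("flagged-missing delta features are zero-imputed with a count", {
  fx <- make_eval_fixture(n_ref = 10, n_tumor = 6, n_edges = 5, n_planted = 0)
  fx$dT$delta[1, 2] <- NA
  expect_message(feats <- build_features(fx$dT, fx$dC, fx$all_edges), "Imputed 1")
  expect_identical(attr(feats, "n_imputed"), 1L)
  key <- rownames(fx$dT$delta)[1]
  expect_equal(feats[[key]][2], 0)
})

test_that("a perfectly separating feature ranks first across seeds", {
  for (seed in 1:10) {
    set.seed(1000 + seed)
    n <- 40
    feats <- tibble::tibble(
      sample_id = paste0("s", 1:n),
      group = rep(c("tumor", "non_tumor"), each = n / 2),
      signal = rep(c(1, -1), each = n / 2) + rnorm(n, sd = 0.05),
      noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n)
    )
    class(feats) <- c("mln_features", class(tibble::tibble()))
    imp <- rank_by_importance(feats, seed = seed, n_trees = 100)
    expect_equal(imp$feature[1], "signal")
  }
})

test_that("importance ranking is deterministic and a constant feature scores ~0", {
  fx <- make_eval_fixture(n_ref = 20, n_tumor = 15, n_edges = 10, n_planted = 2)
  feats <- build_features(fx$dT, fx$dC, fx$all_edges)
  feats$constant <- 1
  attr(feats, "feature_cols") <- c(attr(feats, "feature_cols"), "constant")
  i1 <- rank_by_importance(feats, seed = 5)
  i2 <- rank_by_importance(feats, seed = 5)
  expect_identical(i1, i2)
  expect_true(is.integer(i1$rank) || all(i1$rank == seq_len(nrow(i1))))
  expect_equal(sort(i1$rank), seq_len(nrow(i1)))
  expect_equal(i1$importance[i1$feature == "constant"], 0, tolerance = 1e-12)
  # exact duplication of the sample set preserves the ranking order
  feats2 <- dplyr::bind_rows(feats, feats)
  attr(feats2, "feature_cols") <- attr(feats, "feature_cols")
  class(feats2) <- class(feats)
  i3 <- rank_by_importance(feats2, seed = 5)
  # the strongly informative (planted) features stay on top
  planted_keys <- with(fx$sim$truth, paste(mirna, lncrna, sep = "|"))[fx$sim$truth$planted]
  expect_setequal(i1$feature[1:2], planted_keys)
  expect_setequal(i3$feature[1:2], planted_keys)
})

test_that("cross-validated AUC hits the separable and null benchmarks", {
  # perfectly separated single feature
  n <- 60
  feats <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    group = rep(c("tumor", "non_tumor"), each = n / 2),
    f = c(rnorm(n / 2, 5, 0.1), rnorm(n / 2, -5, 0.1)))
  class(feats) <- c("mln_features", class(tibble::tibble()))
  ev <- cv_auc(feats, folds = 5, seed = 1, n_trees = 100)
  expect_equal(ev$auc, 1.0)

  # label-independent feature: AUC stays near 0.5 (20 seeds, n = 500)
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    n <- 500
    f0 <- tibble::tibble(
      sample_id = paste0("s", 1:n),
      group = rep(c("tumor", "non_tumor"), each = n / 2),
      f = rnorm(n))
    class(f0) <- c("mln_features", class(tibble::tibble()))
    cv_auc(f0, folds = 5, seed = seed, n_trees = 50)$auc
  }, numeric(1))
  expect_gte(median(aucs), 0.45)
  expect_lte(median(aucs), 0.55)
})

test_that("cv_auc is deterministic and its ROC is a valid step curve", {
  fx <- make_eval_fixture(n_ref = 24, n_tumor = 20, n_edges = 8, n_planted = 3)
  feats <- build_features(fx$dT, fx$dC, fx$all_edges)
  e1 <- cv_auc(feats, folds = 4, seed = 9, n_trees = 200)
  e2 <- cv_auc(feats, folds = 4, seed = 9, n_trees = 200)
  expect_equal(e1$auc, e2$auc, tolerance = 1e-12)
  expect_identical(e1$oof$score, e2$oof$score)

  roc <- e1$roc
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(e1$auc, perturbnet:::trapezoid_auc(roc$fpr, roc$tpr), tolerance = 1e-12)

  expect_error(cv_auc(feats, folds = 1), ">= 2")
  expect_error(cv_auc(feats, folds = 21, seed = 1), "single class|lower")
})

test_that("pooled ROC/AUC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(77)
  score <- c(rnorm(40, 1), rnorm(60))
  labs <- rep(c(TRUE, FALSE), c(40, 60))
  roc <- perturbnet:::roc_points(score, labs)
  mine <- perturbnet:::trapezoid_auc(roc$fpr, roc$tpr)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = labs, predictor = score,
                                           quiet = TRUE, direction = "<")))
  expect_equal(mine, theirs, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms of the feature", {
  n <- 80
  set.seed(11)
  f0 <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    group = rep(c("tumor", "non_tumor"), each = n / 2),
    f = c(rnorm(n / 2, 1), rnorm(n / 2)))
  labs <- f0$group == "tumor"
  r1 <- perturbnet:::roc_points(f0$f, labs)
  r2 <- perturbnet:::roc_points(exp(3 * f0$f), labs)
  expect_equal(perturbnet:::trapezoid_auc(r1$fpr, r1$tpr),
               perturbnet:::trapezoid_auc(r2$fpr, r2$tpr), tolerance = 1e-12)
})

test_that("Activity Scores follow the candidate-frequency weighting", {
  catalog <- as_catalog(tibble::tibble(
    mirna = c("mA", "mA", "mA", "mA", "mB", "mC"),
    lncrna = paste0("l", 1:6)))
  scores <- tibble::tibble(
    mirna = catalog$mirna, lncrna = catalog$lncrna,
    n_significant = c(10L, 9L, 2L, 1L, 10L, 3L), n_samples = 10L,
    score = c(1, 0.9, 0.2, 0.1, 1, 0.3))
  cand <- scores[scores$score > 0.8, ]
  act <- activity_scores(cand, scores, catalog)
  # mA: 2 candidate pairs (1.0, 0.9) of 4 catalog pairs -> (1.9) * 2/4
  expect_equal(act$activity[act$mirna == "mA"], 0.95)
  expect_equal(act$c1[act$mirna == "mA"], 2L)
  expect_equal(act$c2[act$mirna == "mA"], 4L)
  # mB: its single catalog pair is a candidate with score 1 -> activity = C1
  expect_equal(act$activity[act$mirna == "mB"], 1)
  # mC: no candidate pair -> 0
  expect_equal(act$activity[act$mirna == "mC"], 0)
  # conservation: activity <= C1 always
  expect_true(all(act$activity <= act$c1 + 1e-12))

  stranger <- tibble::tibble(mirna = "mZ", lncrna = "l9", score = 1)
  expect_error(activity_scores(stranger, scores, catalog), "subset of the catalog")
})

test_that("activity C1/C2 logic is exercised end-to-end in shared-miRNA cohorts", {
  sim <- simulate_cohort(synth_config(n_ref = 40, n_tumor = 30, n_edges = 40,
                                      n_planted = 10, mode = "shared_mirna",
                                      n_mirna = 10, seed = 53))
  ref <- build_reference(sim$panel, sim$catalog)
  dT <- delta_pcc(ref, sim$panel, "tumor")
  sc <- significance_scores(dT, cutoff = fit_cutoff(dT))
  cand <- select_candidates(sc, 0.1, delta = dT)
  act <- activity_scores(cand, sc, sim$catalog)
  expect_setequal(act$mirna, unique(sim$catalog$mirna))
  expect_true(all(act$activity <= act$c1 + 1e-12))
  expect_true(all(act$c1 <= act$c2))
})

test_that("differential-expression baseline calls a constructed 4-fold shift", {
  set.seed(61)
  n <- 50
  ctrl_vals <- rexp(n, rate = 1 / 50)
  m <- rbind(shifted = c(ctrl_vals * 4 + 3, ctrl_vals),
             flat = rep(c(10, 10), each = n) + rnorm(2 * n, sd = 0.01))
  l <- rbind(lnull = rnorm(2 * n, 20))
  colnames(m) <- colnames(l) <- paste0("s", 1:(2 * n))
  ph <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("tumor", "non_tumor"), each = n))
  panel <- perturbnet:::new_panel(m, l, ph)
  de <- de_baseline(panel)
  row <- de[de$rna == "shifted", ]
  # (4 m + 3 + 1) / (m + 1) = 4 exactly, so lfc = 2 under the pseudocount
  expect_equal(row$log2_fc, 2, tolerance = 1e-12)
  expect_equal(row$status, "up")
  # independent Wilcoxon oracle on the same values
  p_oracle <- stats::wilcox.test(m["shifted", 1:n], m["shifted", -(1:n)],
                                 exact = FALSE)$p.value
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(de$status[de$rna == "flat"], "not_de")
  expect_true(all(de$p_adjusted >= de$p_value - 1e-15))
  # BH adjustment is non-decreasing in raw-p order
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[ord]) >= -1e-15))
  expect_error(de_baseline(panel, rnas = "ghost"), "absent")
})

test_that("identical group distributions yield lfc 0 and not_de", {
  vals <- rep(c(5, 7, 9, 11), 10)
  m <- rbind(same = c(vals, vals))
  l <- rbind(lsame = c(vals, vals))
  colnames(m) <- colnames(l) <- paste0("s", 1:80)
  ph <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("tumor", "non_tumor"), each = 40))
  panel <- perturbnet:::new_panel(m, l, ph)
  de <- de_baseline(panel)
  expect_equal(de$log2_fc, c(0, 0))
  expect_equal(de$status, c("not_de", "not_de"))
})
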