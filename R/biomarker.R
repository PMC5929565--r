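#' Assemble the classification feature table from delta-PCC matrices
#'
#' Rows are all tumor plus all control samples, columns are the candidate
#' edges, values are each sample's delta-PCC for that edge. Flagged-missing
#' entries are imputed as 0 (a missing edge means "no detectable
#' perturbation") and the imputation count is recorded.
#'
#' @param delta_tumor,delta_control `mln_delta` matrices for the two
#'   phenotype groups, sharing the catalog.
#' @param candidates An `mln_candidates` table (or any tibble with
#'   `mirna`/`lncrna` columns) naming the feature edges.
#' @return An `mln_features` tibble: `sample_id`, `group`, then one
#'   numeric column per candidate edge (named `"<mirna>|<lncrna>"`, in
#'   candidate order). Attribute `n_imputed` counts zero-imputed cells.
#' @export
build_features <- function(delta_tumor, delta_control, candidates) {
  if (nrow(candidates) == 0L) abort("Candidate set is empty.")
  keys <- edge_key(candidates$mirna, candidates$lncrna)
  for (d in list(delta_tumor, delta_control)) {
    missing <- setdiff(keys, rownames(d$delta))
    if (length(missing)) {
      abort(sprintf("Candidate edge(s) absent from the %s delta matrix: %s",
                    d$group, paste(utils::head(missing, 3L), collapse = ", ")))
    }
  }
  block <- function(d) {
    m <- t(d$delta[keys, , drop = FALSE])
    tibble(sample_id = d$sample_ids, group = d$group) %>%
      dplyr::bind_cols(as_tibble(m, .name_repair = "minimal"))
  }
  out <- dplyr::bind_rows(block(delta_tumor), block(delta_control))
  n_imputed <- sum(is.na(out[keys]))
  if (n_imputed > 0L) {
    message(sprintf("Imputed %d flagged-missing delta-PCC feature cells as 0.", n_imputed))
    out[keys][is.na(out[keys])] <- 0
  }
  structure(out, class = c("mln_features", class(tibble())),
            n_imputed = n_imputed, feature_cols = keys)
}

#' Node-biomarker feature table (expression values)
#'
#' The node counterpart of [build_features()]: rows are samples, columns
#' are the listed RNAs' expression values. Used for the edge-versus-node
#' biomarker comparison.
#'
#' @param panel An `mln_panel`.
#' @param rnas Character vector of feature ids (searched in the miRNA
#'   matrix first, then the lncRNA matrix).
#' @return An `mln_features` tibble (`sample_id`, `group`, one column per
#'   RNA).
#' @export
build_node_features <- function(panel, rnas) {
  if (length(rnas) == 0L) abort("`rnas` is empty.")
  rows <- lapply(rnas, function(id) {
    if (id %in% rownames(panel$mirna)) panel$mirna[id, ]
    else if (id %in% rownames(panel$lncrna)) panel$lncrna[id, ]
    else abort(sprintf("RNA '%s' is absent from the panel.", id))
  })
  m <- do.call(cbind, rows)
  colnames(m) <- rnas
  out <- tibble(sample_id = panel$phenotype$sample_id,
                group = panel$phenotype$group) %>%
    dplyr::bind_cols(as_tibble(m[panel$phenotype$sample_id, , drop = FALSE],
                               .name_repair = "minimal"))
  structure(out, class = c("mln_features", class(tibble())),
            n_imputed = 0L, feature_cols = rnas)
}

feature_matrix <- function(features, subset = NULL) {
  cols <- attr(features, "feature_cols") %||% setdiff(names(features), c("sample_id", "group"))
  if (!is.null(subset)) {
    if (is.data.frame(subset)) subset <- edge_key(subset$mirna, subset$lncrna)
    missing <- setdiff(subset, cols)
    if (length(missing)) abort(sprintf("Feature(s) not in the table: %s",
                                       paste(utils::head(missing, 3L), collapse = ", ")))
    cols <- subset
  }
  x <- as.matrix(features[cols])
  y <- factor(features$group, levels = c("non_tumor", "tumor"))
  if (nlevels(droplevels(y)) < 2L) abort("Feature table must contain both phenotype classes.")
  list(x = x, y = y)
}

#' Rank candidate edges by random-forest feature importance
#'
#' Fits a random forest (tumor vs non-tumor) on the delta-PCC feature
#' table and ranks features by mean decrease in Gini impurity,
#' descending. Ties keep the incoming feature (candidate) order, so the
#' ranking is deterministic for a fixed seed.
#'
#' @param features An `mln_features` table.
#' @param seed Integer seed controlling the forest's bootstrap draws.
#' @param n_trees Number of trees (default 500).
#' @return An `mln_importance` tibble: `feature`, `mirna`/`lncrna` (when
#'   features are edges), `importance`, `rank`.
#' @export
rank_by_importance <- function(features, seed = 1L, n_trees = 500L) {
  fm <- feature_matrix(features)
  if (min(table(fm$y)) < 2L) abort("Need >= 2 samples per class to fit the forest.")
  set.seed(seed)
  fit <- randomForest::randomForest(x = fm$x, y = fm$y, ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, seq_along(imp))
  out <- tibble(feature = colnames(fm$x)[ord],
                importance = unname(imp[ord]),
                rank = seq_along(imp))
  if (all(grepl("|", out$feature, fixed = TRUE))) {
    out <- dplyr::bind_cols(out["feature"], split_edge_key(out$feature),
                            out[c("importance", "rank")])
  }
  structure(out, class = c("mln_importance", class(tibble())),
            seed = seed, n_trees = n_trees)
}

# Pooled ROC curve from scores and binary labels (TRUE = positive class).
# One point per distinct score threshold, from (0,0) to (1,1).
roc_points <- function(score, positive) {
  ord <- order(-score)
  score <- score[ord]
  positive <- positive[ord]
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) abort("ROC needs both classes.")
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  last_of_tie <- c(score[-1] != score[-length(score)], TRUE)
  tibble(
    threshold = c(Inf, score[last_of_tie]),
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos)
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Stratified cross-validated ROC/AUC for a feature subset
#'
#' Splits the samples into stratified folds (each class spread evenly),
#' fits a random forest on each training split, scores the held-out
#' samples with the out-of-fold tumor-class probability, pools all
#' out-of-fold scores into a single ROC curve and computes the area under
#' it by the trapezoid rule. An AUC of 0.5 is the random-classifier
#' reference; 1.0 is perfect separation.
#'
#' When the evaluated feature subset was itself chosen on the full
#' cohort (the usual "top-k by importance / by differential expression"
#' protocol), the pooled AUC inherits that selection and is optimistic
#' under the null. For an unbiased estimate, pass a `selector` instead of
#' a fixed `subset`: the selector is re-run on each training fold alone,
#' so held-out samples never influence which features are used to score
#' them.
#'
#' @param features An `mln_features` table.
#' @param subset Feature columns to use: a character vector of column
#'   names or a tibble with `mirna`/`lncrna` columns; `NULL` = all.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and forest fitting.
#' @param n_trees Trees per fold forest (default 500).
#' @param selector Optional per-fold feature selection:
#'   `function(x, y) -> character` (column names), applied to each
#'   training fold's matrix and labels. Mutually exclusive with `subset`.
#'   See [importance_selector()] and [de_selector()].
#' @return An `mln_eval` object: `roc` (tibble of `threshold`, `fpr`,
#'   `tpr`), `auc`, `oof` (per-sample out-of-fold scores with fold ids),
#'   `folds`, `seed`, `features` used.
#' @export
cv_auc <- function(features, subset = NULL, folds = 10L, seed = 1L, n_trees = 500L,
                   selector = NULL) {
  if (folds < 2L) abort("`folds` must be >= 2.")
  if (!is.null(subset) && !is.null(selector)) {
    abort("Supply either a fixed `subset` or a per-fold `selector`, not both.")
  }
  fm <- feature_matrix(features, subset)
  n <- length(fm$y)
  set.seed(seed)
  fold_id <- integer(n)
  for (cl in levels(fm$y)) {
    idx <- sample(which(fm$y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  if (any(table(factor(fold_id, levels = seq_len(folds)), fm$y) == 0)) {
    abort("A fold ended up with a single class after stratification; lower `folds`.")
  }
  score <- numeric(n)
  used <- character(0)
  for (k in seq_len(folds)) {
    test <- fold_id == k
    xtr <- fm$x[!test, , drop = FALSE]
    cols <- if (is.null(selector)) colnames(fm$x) else selector(xtr, fm$y[!test])
    used <- union(used, cols)
    fit <- randomForest::randomForest(x = xtr[, cols, drop = FALSE], y = fm$y[!test],
                                      ntree = n_trees)
    score[test] <- stats::predict(fit, fm$x[test, cols, drop = FALSE],
                                  type = "prob")[, "tumor"]
  }
  roc <- roc_points(score, fm$y == "tumor")
  structure(list(
    roc = roc, auc = trapezoid_auc(roc$fpr, roc$tpr),
    oof = tibble(sample_id = features$sample_id, group = features$group,
                 score = score, fold = fold_id),
    folds = folds, seed = seed, features = used
  ), class = "mln_eval")
}

#' Per-fold feature selectors for nested cross-validation
#'
#' Factories returning `function(x, y) -> character` selectors for
#' [cv_auc()]'s `selector` argument. `importance_selector()` ranks the
#' training fold's features by random-forest Gini importance;
#' `de_selector()` ranks them by two-sided Wilcoxon rank-sum p-value
#' (the node-biomarker criterion). Both return the top `k` column names.
#'
#' @param k Number of features to keep per fold.
#' @param n_trees Trees for the selection forest.
#' @return A selector function.
#' @export
importance_selector <- function(k = 5L, n_trees = 500L) {
  function(x, y) {
    fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
    imp <- fit$importance[, "MeanDecreaseGini"]
    colnames(x)[order(-imp, seq_along(imp))][seq_len(min(k, ncol(x)))]
  }
}

#' @rdname importance_selector
#' @export
de_selector <- function(k = 5L) {
  function(x, y) {
    pos <- y == levels(y)[2]
    p <- apply(x, 2L, function(v) {
      if (stats::sd(v) == 0) 1 else
        suppressWarnings(stats::wilcox.test(v[pos], v[!pos], exact = FALSE)$p.value)
    })
    colnames(x)[order(p, seq_along(p))][seq_len(min(k, ncol(x)))]
  }
}

#' @export
print.mln_eval <- function(x, ...) {
  cat(sprintf("<mln_eval> AUC = %.4f (%d features, %d-fold stratified CV, seed %d)\n",
              x$auc, length(x$features), x$folds, x$seed))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mln_eval
#' @export
tidy.mln_eval <- function(x, ...) x$roc

#' @rdname tidiers
#' @method glance mln_eval
#' @export
glance.mln_eval <- function(x, ...) {
  tibble(auc = x$auc, n_features = length(x$features), folds = x$folds, seed = x$seed)
}

#' Per-miRNA Activity Scores
#'
#' Aggregates each miRNA's candidate edges: the sum of their significance
#' scores, weighted by `C1 / C2` where `C1` is the miRNA's frequency among
#' the candidate pairs and `C2` its frequency among all catalog pairs. The
#' weight discounts miRNAs that are catalog hubs, so a miRNA scores highly
#' only when a large share of its catalogued partners are perturbed.
#' Every catalog miRNA gets a row; miRNAs in no candidate pair score 0.
#'
#' @param candidates An `mln_candidates` table (subset of the catalog).
#' @param scores The full significance-score table (used to look up
#'   candidate edge scores; `candidates` already carries them, `scores`
#'   is accepted for symmetry and validation).
#' @param catalog The full `mln_catalog`.
#' @return An `mln_activity` tibble: `mirna`, `activity`, `c1`, `c2`,
#'   `k_terms`, sorted by descending activity.
#' @export
activity_scores <- function(candidates, scores, catalog) {
  cat_keys <- edge_key(catalog$mirna, catalog$lncrna)
  cand_keys <- edge_key(candidates$mirna, candidates$lncrna)
  if (!all(cand_keys %in% cat_keys)) abort("Candidates must be a subset of the catalog.")
  sc <- scores$score[match(cand_keys, edge_key(scores$mirna, scores$lncrna))]
  if (anyNA(sc)) abort("Candidate edge missing from the score table.")

  c2 <- table(catalog$mirna)
  per <- tibble(mirna = candidates$mirna, score = sc) %>%
    dplyr::group_by(.data$mirna) %>%
    dplyr::summarise(sum_score = sum(.data$score), c1 = dplyr::n(), .groups = "drop")
  per$c2 <- as.integer(c2[per$mirna])
  if (any(is.na(per$c2) | per$c2 == 0L)) {
    abort("Catalog inconsistency: a candidate miRNA has no catalog pairs (C2 = 0).")
  }
  rest <- setdiff(names(c2), per$mirna)
  out <- dplyr::bind_rows(
    tibble(mirna = per$mirna, activity = per$sum_score * per$c1 / per$c2,
           c1 = per$c1, c2 = per$c2, k_terms = per$c1),
    tibble(mirna = rest, activity = 0, c1 = 0L,
           c2 = as.integer(c2[rest]), k_terms = 0L)
  ) %>%
    dplyr::arrange(dplyr::desc(.data$activity), .data$mirna)
  structure(out, class = c("mln_activity", class(tibble())))
}

#' Differential-expression node baseline
#'
#' The conventional single-molecule analysis the edge statistics are
#' compared against: per RNA, the log2 fold change of tumor versus
#' non-tumor group means (pseudocount 1), a two-sided Wilcoxon rank-sum
#' p-value, Benjamini-Hochberg adjustment, and an up/down/not_de status
#' call at the stated thresholds.
#'
#' @param panel An `mln_panel` with both phenotype groups nonempty.
#' @param rnas RNAs to test; default all features of both matrices.
#' @param lfc_threshold Absolute log2-fold-change threshold (default 1).
#' @param p_threshold Adjusted-p threshold (default 0.05).
#' @return An `mln_de` tibble: `rna`, `type`, `log2_fc`, `p_value`,
#'   `p_adjusted`, `status`.
#' @export
de_baseline <- function(panel, rnas = NULL, lfc_threshold = 1, p_threshold = 0.05) {
  grp <- panel$phenotype$group
  if (!all(c("tumor", "non_tumor") %in% grp)) abort("Both phenotype groups must be nonempty.")
  if (is.null(rnas)) rnas <- c(rownames(panel$mirna), rownames(panel$lncrna))
  is_t <- grp == "tumor"

  fetch <- function(id) {
    if (id %in% rownames(panel$mirna)) list(v = panel$mirna[id, ], type = "mirna")
    else if (id %in% rownames(panel$lncrna)) list(v = panel$lncrna[id, ], type = "lncrna")
    else abort(sprintf("RNA '%s' is absent from the panel.", id))
  }
  res <- purrr::map(rnas, function(id) {
    f <- fetch(id)
    vt <- f$v[is_t]; vc <- f$v[!is_t]
    lfc <- log2((mean(vt) + 1) / (mean(vc) + 1))
    p <- if (stats::sd(f$v) == 0) 1 else
      suppressWarnings(stats::wilcox.test(vt, vc, exact = FALSE)$p.value)
    tibble(rna = id, type = f$type, log2_fc = lfc, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$status <- dplyr::case_when(
    abs(out$log2_fc) > lfc_threshold & out$p_adjusted < p_threshold & out$log2_fc > 0 ~ "up",
    abs(out$log2_fc) > lfc_threshold & out$p_adjusted < p_threshold ~ "down",
    TRUE ~ "not_de"
  )
  structure(out, class = c("mln_de", class(tibble())),
            lfc_threshold = lfc_threshold, p_threshold = p_threshold)
}
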