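#' Per-edge significance scores across a cohort
#'
#' For every catalog edge, counts the number of samples (N1) whose
#' individual-specific network contains the edge and divides by the total
#' number of samples (N): `score = N1 / N`. Ranking edges by this score
#' and keeping the high-scoring ones yields the cohort's basic
#' miRNA-lncRNA network (BMLN).
#'
#' @param x Either a list of `mln_ismln` tibbles (all derived from the
#'   same catalog and cutoff), or an `mln_delta` together with `cutoff`
#'   (the two routes are equivalent; the matrix route avoids materialising
#'   per-sample networks).
#' @param catalog The `mln_catalog` (required for the list route).
#' @param cutoff An `mln_cutoff` (required for the `mln_delta` route).
#' @return A tibble with columns `mirna`, `lncrna`, `n_significant`,
#'   `n_samples`, `score`, covering every catalog edge in catalog order.
#' @export
significance_scores <- function(x, catalog = NULL, cutoff = NULL) {
  if (inherits(x, "mln_delta")) {
    if (is.null(cutoff)) abort("Supply `cutoff` when scoring an mln_delta.")
    sig <- is_significant(x, cutoff)
    n1 <- unname(rowSums(sig))
    n <- ncol(x$delta)
    catalog <- x$catalog
  } else if (is.list(x)) {
    if (length(x) == 0L) abort("Empty list of per-sample networks.")
    if (is.null(catalog)) abort("Supply `catalog` when scoring a list of networks.")
    keys <- edge_key(catalog$mirna, catalog$lncrna)
    counts <- integer(length(keys))
    for (net in x) {
      idx <- match(edge_key(net$mirna, net$lncrna), keys)
      if (anyNA(idx)) abort("A per-sample network contains edges outside the catalog.")
      counts[idx] <- counts[idx] + 1L
    }
    n1 <- counts
    n <- length(x)
  } else {
    abort("`x` must be an mln_delta or a list of mln_ismln tibbles.")
  }
  tibble(mirna = catalog$mirna, lncrna = catalog$lncrna,
         n_significant = as.integer(n1), n_samples = as.integer(n),
         score = n1 / n)
}

# Deterministic edge ordering used everywhere a score table is ranked:
# descending score, then descending |mean tumor delta-PCC| when a delta
# matrix is available, then catalog order.
rank_edge_order <- function(scores, delta = NULL) {
  tie <- rep(0, nrow(scores))
  if (!is.null(delta)) {
    keys <- edge_key(scores$mirna, scores$lncrna)
    md <- rowMeans(delta$delta, na.rm = TRUE)
    tie <- abs(md[match(keys, rownames(delta$delta))])
    tie[is.na(tie)] <- 0
  }
  order(-scores$score, -tie, seq_len(nrow(scores)))
}

#' Select candidate edge biomarkers from a score table
#'
#' Keeps the edges whose significance score strictly exceeds the
#' threshold (default 0.8), ordered by descending score; ties are broken
#' by descending absolute mean tumor delta-PCC (when `delta` is supplied)
#' and then by catalog order, so the ordering is deterministic.
#'
#' @param scores A significance-score table from [significance_scores()].
#' @param threshold Score threshold in `[0, 1]`; strict `>` is applied.
#' @param delta Optional tumor `mln_delta` used for tie-breaking.
#' @return An `mln_candidates` tibble, a row-subset of `scores` in rank
#'   order.
#' @export
select_candidates <- function(scores, threshold = 0.8, delta = NULL) {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  ord <- rank_edge_order(scores, delta)
  out <- scores[ord, , drop = FALSE]
  out <- out[out$score > threshold, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn(sprintf("No edge has significance score > %g; returning an empty candidate set.", threshold))
  }
  structure(out, class = c("mln_candidates", class(tibble())))
}

#' Cross-cohort comparison of top-ranked edges
#'
#' Takes one significance-score table per cohort, extracts each cohort's
#' top-k edges (same deterministic tie-break as [select_candidates()]),
#' and assembles the union of those edges into an edges-by-cohorts score
#' matrix plus a per-lncRNA degree table counting in how many cohorts the
#' lncRNA appears among the top-k edges.
#'
#' @param tables A named list (>= 2) of significance-score tables.
#' @param k Number of top edges per cohort (default 200).
#' @param deltas Optional named list of tumor `mln_delta` objects for
#'   tie-breaking, matching `tables` by name.
#' @return An `mln_crosscancer` list: `matrix` (tibble: `mirna`, `lncrna`,
#'   one score column per cohort, `NA` where a cohort's catalog lacks the
#'   edge) and `degree` (tibble: `lncrna`, `degree`).
#' @export
cross_cancer <- function(tables, k = 200, deltas = NULL) {
  if (length(tables) < 2L) abort("Cross-cohort comparison needs >= 2 cohorts.")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("`tables` must be a named list (one name per cohort).")
  }
  stopifnot_scalar_number(k, "k", 1)
  key_sets <- lapply(tables, function(t) edge_key(t$mirna, t$lncrna))
  for (i in seq_along(tables)) for (j in seq_len(i - 1L)) {
    if (!length(intersect(key_sets[[i]], key_sets[[j]]))) {
      abort(sprintf("Cohorts '%s' and '%s' have disjoint catalogs.",
                    names(tables)[j], names(tables)[i]))
    }
  }
  top <- purrr::imap(tables, function(t, nm) {
    ord <- rank_edge_order(t, if (!is.null(deltas)) deltas[[nm]] else NULL)
    utils::head(t[ord, c("mirna", "lncrna", "score")], k)
  })
  union_edges <- dplyr::distinct(dplyr::bind_rows(top), .data$mirna, .data$lncrna)
  ukeys <- edge_key(union_edges$mirna, union_edges$lncrna)
  mat <- union_edges
  for (nm in names(tables)) {
    idx <- match(ukeys, key_sets[[nm]])
    mat[[nm]] <- tables[[nm]]$score[idx]
  }
  # deterministic row order: best score anywhere first, then key
  best <- do.call(pmax, c(unname(mat[names(tables)]), list(na.rm = TRUE)))
  mat <- mat[order(-best, ukeys), , drop = FALSE]

  degree <- dplyr::bind_rows(purrr::imap(top, ~ tibble(cohort = .y, lncrna = unique(.x$lncrna)))) %>%
    dplyr::count(.data$lncrna, name = "degree") %>%
    dplyr::arrange(dplyr::desc(.data$degree), .data$lncrna)

  structure(list(matrix = mat, degree = degree, k = k, cohorts = names(tables)),
            class = "mln_crosscancer")
}

#' @export
print.mln_crosscancer <- function(x, ...) {
  cat(sprintf("<mln_crosscancer> %d union edges x %d cohorts (top %d per cohort)\n",
              nrow(x$matrix), length(x$cohorts), x$k))
  invisible(x)
}
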