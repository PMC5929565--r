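# Perturbed correlations when one sample is appended to cached reference
# sums. xn / yn are centred endpoint values, one row per catalog edge,
# one column per perturbing sample (vectors are treated as one column).
append_cor <- function(ref, xn, yn) {
  xn <- as.matrix(xn)
  yn <- as.matrix(yn)
  e <- length(ref$sxy)
  n1 <- ref$n_ref + 1L
  sx <- ref$sx[ref$mi]; sy <- ref$sy[ref$lj]
  sxx <- ref$sxx[ref$mi]; syy <- ref$syy[ref$lj]

  Sx <- sx + xn;  Sy <- sy + yn
  Sxx <- sxx + xn * xn
  Syy <- syy + yn * yn
  Sxy <- ref$sxy + xn * yn

  cov <- Sxy - Sx * Sy / n1
  vx <- Sxx - Sx * Sx / n1
  vy <- Syy - Sy * Sy / n1
  tol_x <- var_floor(pmax(ref$scale_m[ref$mi], abs(xn)), n1)
  tol_y <- var_floor(pmax(ref$scale_l[ref$lj], abs(yn)), n1)
  defined <- !is.na(vx) & !is.na(vy) & vx > tol_x & vy > tol_y
  r <- matrix(NA_real_, nrow = e, ncol = ncol(xn))
  r[defined] <- pmax(-1, pmin(1, cov[defined] / sqrt(vx[defined] * vy[defined])))
  r
}

#' Perturb the reference network with a single sample
#'
#' Appends one sample's expression values to the cached reference
#' statistics and returns, for every catalog edge, the correlation over
#' the n+1 samples and its difference from the reference correlation
#' (the delta-PCC). The incremental update is algebraically identical to
#' recomputing the correlation from scratch on the extended vectors.
#'
#' Edges whose endpoint value is missing in the new sample, or whose
#' correlation is undefined before or after the perturbation, are flagged
#' `NA` rather than set to zero.
#'
#' @param ref An `mln_reference`.
#' @param sample_mirna,sample_lncrna Named numeric vectors of the new
#'   sample's expression values (names = feature ids, covering at least
#'   the catalog endpoints).
#' @return A tibble with one row per catalog edge: `mirna`, `lncrna`,
#'   `perturbed_pcc`, `delta_pcc`.
#' @export
perturb_sample <- function(ref, sample_mirna, sample_lncrna) {
  xm <- sample_mirna[names(ref$center_m)] - ref$center_m
  xl <- sample_lncrna[names(ref$center_l)] - ref$center_l
  r <- append_cor(ref, xm[ref$mi], xl[ref$lj])[, 1L]
  tibble(mirna = ref$catalog$mirna, lncrna = ref$catalog$lncrna,
         perturbed_pcc = r, delta_pcc = r - ref$pcc)
}

#' Per-sample delta-PCC matrix for a phenotype group
#'
#' Builds the edge-by-sample matrix of correlation perturbations for all
#' samples of one phenotype group.
#'
#' Tumor samples are each appended to the full reference (n controls plus
#' the one tumor sample). Control samples are, by default, handled
#' leave-one-out (`control_mode = "loo"`): the sample is first removed
#' from the reference (n-1 controls) and then appended back as the
#' perturbing sample, so that control columns have the same
#' (n samples vs n-1 reference) structure as tumor columns
#' (n+1 vs n). `control_mode = "reappend"` instead appends the control
#' sample to the full reference even though it is already inside it.
#'
#' @param ref An `mln_reference` built from the same panel.
#' @param panel The `mln_panel`.
#' @param group `"tumor"` or `"non_tumor"`.
#' @param control_mode `"loo"` (default) or `"reappend"`; only used for
#'   the non-tumor group.
#' @return An object of class `mln_delta` holding the `delta` and
#'   `perturbed_pcc` matrices (rows = catalog edges keyed
#'   `"<mirna>|<lncrna>"`, columns = samples), the group label and the
#'   reference correlations.
#' @export
delta_pcc <- function(ref, panel, group = c("tumor", "non_tumor"),
                      control_mode = c("loo", "reappend")) {
  group <- match.arg(group)
  control_mode <- match.arg(control_mode)
  ids <- panel$phenotype$sample_id[panel$phenotype$group == group]
  if (length(ids) == 0L) abort(sprintf("Panel has no '%s' samples.", group))

  Xc <- panel$mirna[, ids, drop = FALSE] - ref$center_m
  Yc <- panel$lncrna[, ids, drop = FALSE] - ref$center_l
  Xe <- Xc[ref$mi, , drop = FALSE]
  Ye <- Yc[ref$lj, , drop = FALSE]

  if (group == "tumor" || control_mode == "reappend") {
    perturbed <- append_cor(ref, Xe, Ye)
    delta <- perturbed - ref$pcc
  } else {
    # Leave-one-out: remove sample s from the cached sums (n-1 controls),
    # the reduced network is the reference for s; appending s back yields
    # the full n-control correlation, identical for every s.
    if (!all(ids %in% ref$ref_sample_ids)) {
      abort("Leave-one-out requires every non-tumor sample to be part of the reference.")
    }
    n0 <- ref$n_ref - 1L
    if (n0 < 3L) abort("Leave-one-out needs >= 4 control samples.")
    sx0 <- ref$sx[ref$mi] - Xe;  sy0 <- ref$sy[ref$lj] - Ye
    sxx0 <- ref$sxx[ref$mi] - Xe * Xe
    syy0 <- ref$syy[ref$lj] - Ye * Ye
    sxy0 <- ref$sxy - Xe * Ye
    cov <- sxy0 - sx0 * sy0 / n0
    vx <- sxx0 - sx0 * sx0 / n0
    vy <- syy0 - sy0 * sy0 / n0
    tol_x <- var_floor(ref$scale_m[ref$mi], n0)
    tol_y <- var_floor(ref$scale_l[ref$lj], n0)
    defined <- vx > tol_x & vy > tol_y
    ref_loo <- matrix(NA_real_, nrow = length(ref$sxy), ncol = length(ids))
    ref_loo[defined] <- pmax(-1, pmin(1, cov[defined] / sqrt(vx[defined] * vy[defined])))
    perturbed <- matrix(ref$pcc, nrow = length(ref$pcc), ncol = length(ids))
    delta <- perturbed - ref_loo
  }

  keys <- edge_key(ref$catalog$mirna, ref$catalog$lncrna)
  dimnames(delta) <- dimnames(perturbed) <- list(keys, ids)
  structure(list(
    delta = delta, perturbed_pcc = perturbed,
    sample_ids = ids, group = group, control_mode = control_mode,
    catalog = ref$catalog, reference_pcc = ref$pcc, n_ref = ref$n_ref
  ), class = "mln_delta")
}

#' @export
print.mln_delta <- function(x, ...) {
  cat(sprintf("<mln_delta> %d edges x %d %s samples (%d flagged-missing entries)\n",
              nrow(x$delta), ncol(x$delta), x$group, sum(is.na(x$delta))))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mln_delta
#' @export
tidy.mln_delta <- function(x, ...) {
  as_tibble(x$delta, rownames = "edge") %>%
    tidyr::pivot_longer(-"edge", names_to = "sample_id", values_to = "delta_pcc") %>%
    dplyr::mutate(split_edge_key(.data$edge), group = x$group, .after = "edge")
}
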