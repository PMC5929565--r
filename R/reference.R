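#' Pearson product-moment correlation with an explicit undefined flag
#'
#' Definitional sum-of-deviations computation. Unlike [stats::cor()], a
#' zero-variance endpoint yields `NA` (the "undefined" flag) rather than a
#' propagated `NaN`, and short or mismatched vectors are an error rather
#' than a silent answer: single-sample perturbation statistics are
#' meaningless below three reference samples.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return The correlation in `[-1, 1]`, or `NA_real_` when either vector
#'   has zero variance.
#' @examples
#' pearson_cor(c(1, 2, 3), c(3, 2, 1))   # -1
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Correlation needs at least 3 observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) return(NA_real_)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  max(-1, min(1, r))
}

#' Build the reference correlation network
#'
#' Computes one Pearson correlation per catalog edge over exactly the
#' non-tumor (control) samples of the panel, and caches the sufficient
#' statistics (per-feature sums and sums of squares, per-edge cross-product
#' sums, all on mean-centred data) so that appending a single sample later
#' costs O(edges), not O(edges x samples).
#'
#' Edges with a zero-variance endpoint among the controls get an undefined
#' (`NA`) correlation; they are flagged, carried along, and excluded from
#' cutoff fitting and network membership downstream, never imputed.
#'
#' @param panel An `mln_panel` with at least 3 non-tumor samples.
#' @param catalog An `mln_catalog` whose edges reference panel features.
#' @return An object of class `mln_reference`.
#' @export
build_reference <- function(panel, catalog) {
  controls <- panel$phenotype$sample_id[panel$phenotype$group == "non_tumor"]
  if (length(controls) < 3L) {
    abort(sprintf("Reference network needs >= 3 control samples; panel has %d.", length(controls)))
  }
  mi <- match(catalog$mirna, rownames(panel$mirna))
  lj <- match(catalog$lncrna, rownames(panel$lncrna))
  if (anyNA(mi) || anyNA(lj)) abort("Catalog references features absent from the panel.")

  n <- length(controls)
  # Centre each feature on its control mean: correlations are shift
  # invariant and centred accumulation avoids catastrophic cancellation in
  # the running-sum updates.
  center_m <- rowMeans(panel$mirna[, controls, drop = FALSE])
  center_l <- rowMeans(panel$lncrna[, controls, drop = FALSE])
  Xc <- panel$mirna[, controls, drop = FALSE] - center_m
  Yc <- panel$lncrna[, controls, drop = FALSE] - center_l

  sx <- rowSums(Xc)           # ~0 by construction, kept for exactness
  sy <- rowSums(Yc)
  sxx <- rowSums(Xc * Xc)
  syy <- rowSums(Yc * Yc)
  sxy <- rowSums(Xc[mi, , drop = FALSE] * Yc[lj, , drop = FALSE])
  scale_m <- apply(abs(Xc), 1L, max)
  scale_l <- apply(abs(Yc), 1L, max)

  st <- edge_cor_from_sums(n, sx[mi], sy[lj], sxx[mi], syy[lj], sxy,
                           tol_x = var_floor(scale_m[mi], n),
                           tol_y = var_floor(scale_l[lj], n))

  structure(list(
    catalog = catalog, mi = mi, lj = lj,
    n_ref = n, ref_sample_ids = controls,
    center_m = center_m, center_l = center_l,
    sx = sx, sy = sy, sxx = sxx, syy = syy, sxy = sxy,
    scale_m = scale_m, scale_l = scale_l,
    pcc = st$r, defined = st$defined
  ), class = "mln_reference")
}

# Numerical floor below which a sum of squared deviations is treated as a
# zero-variance (undefined-correlation) endpoint.
var_floor <- function(scale, n) pmax(scale^2 * n * 1e-24, 1e-300)

edge_cor_from_sums <- function(n, sx, sy, sxx, syy, sxy, tol_x, tol_y) {
  cov <- sxy - sx * sy / n
  vx <- sxx - sx * sx / n
  vy <- syy - sy * sy / n
  defined <- vx > tol_x & vy > tol_y
  r <- rep(NA_real_, length(sxy))
  r[defined] <- cov[defined] / sqrt(vx[defined] * vy[defined])
  r[defined] <- pmax(-1, pmin(1, r[defined]))
  list(r = r, defined = defined)
}

#' @export
print.mln_reference <- function(x, ...) {
  cat(sprintf("<mln_reference> %d edges over %d control samples (%d undefined correlations)\n",
              length(x$pcc), x$n_ref, sum(!x$defined)))
  invisible(x)
}

#' @rdname tidiers
#' @method tidy mln_reference
#' @export
tidy.mln_reference <- function(x, ...) {
  tibble(mirna = x$catalog$mirna, lncrna = x$catalog$lncrna,
         pcc = x$pcc, defined = x$defined)
}

#' @rdname tidiers
#' @method glance mln_reference
#' @export
glance.mln_reference <- function(x, ...) {
  tibble(n_edges = length(x$pcc), n_defined = sum(x$defined), n_ref = x$n_ref)
}
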