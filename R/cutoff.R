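#' Fit the significance cutoff for delta-PCC values
#'
#' Operationalises the Z-test selection of significantly perturbed edges.
#' Two constructions are available:
#'
#' * `pooled_normal` (default): fit a single normal distribution to all
#'   defined delta-PCC entries by sample mean and standard deviation; the
#'   cutoff is the exact two-sided alpha-quantile,
#'   `cutoff_abs = qnorm(1 - alpha/2) * sd`, and an entry is significant
#'   when `|delta - mean| >= cutoff_abs`. This matches thresholding a
#'   pooled delta-PCC histogram with symmetric cutoffs, and the
#'   alpha-quantile is the unique value making the two-sided tail mass
#'   equal alpha ("smaller than and as close as possible" to alpha).
#' * `ssn_z`: the per-edge asymptotic single-sample-network statistic
#'   `z = delta * (n_ref - 1) / (1 - pcc^2)` referred to the standard
#'   normal, two-sided at `alpha`. The cutoff is then edge-specific:
#'   `cutoff_abs[e] = qnorm(1 - alpha/2) * (1 - pcc[e]^2) / (n_ref - 1)`.
#'
#' Flagged-missing (undefined-correlation) entries never enter the fit.
#'
#' @param delta An `mln_delta`, or (for `pooled_normal` only) a bare
#'   numeric vector/matrix of delta-PCC values.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @param method `"pooled_normal"` or `"ssn_z"`.
#' @return An object of class `mln_cutoff` with elements `method`,
#'   `alpha`, `cutoff_abs` (scalar, or per-edge vector for `ssn_z`),
#'   `fitted_mean`, `fitted_sd` (pooled only) and bookkeeping fields.
#' @export
fit_cutoff <- function(delta, alpha = 0.05, method = c("pooled_normal", "ssn_z")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1.")
  }
  z_crit <- stats::qnorm(1 - alpha / 2)

  if (method == "pooled_normal") {
    entries <- if (inherits(delta, "mln_delta")) delta$delta else delta
    entries <- as.numeric(entries)
    entries <- entries[is.finite(entries)]
    if (length(entries) < 100L) {
      abort("pooled_normal cutoff needs >= 100 defined delta-PCC entries.")
    }
    m <- mean(entries)
    s <- stats::sd(entries)
    if (s <= 0) abort("Degenerate delta-PCC distribution: fitted sd is 0.")
    out <- list(method = method, alpha = alpha, z_crit = z_crit,
                cutoff_abs = z_crit * s, fitted_mean = m, fitted_sd = s,
                n_entries = length(entries))
  } else {
    if (!inherits(delta, "mln_delta")) {
      abort("method = 'ssn_z' needs an `mln_delta` (reference PCCs and n_ref are required).")
    }
    pcc <- delta$reference_pcc
    out <- list(method = method, alpha = alpha, z_crit = z_crit,
                cutoff_abs = z_crit * (1 - pcc^2) / (delta$n_ref - 1L),
                fitted_mean = 0, fitted_sd = NA_real_,
                n_ref = delta$n_ref, reference_pcc = pcc,
                n_entries = sum(is.finite(delta$delta)))
  }
  structure(out, class = "mln_cutoff")
}

# Significance indicator for a delta matrix/vector under a fitted cutoff.
# Flagged-missing entries are FALSE (never significant). Ties (exactly at
# the cutoff) are significant.
is_significant <- function(delta_values, cutoff) {
  if (inherits(delta_values, "mln_delta")) delta_values <- delta_values$delta
  if (cutoff$method == "pooled_normal") {
    sig <- abs(delta_values - cutoff$fitted_mean) >= cutoff$cutoff_abs
  } else {
    sig <- abs(delta_values) >= cutoff$cutoff_abs  # recycles per-edge cutoffs down columns
  }
  sig[!is.finite(delta_values) | is.na(sig)] <- FALSE
  sig
}

#' Extract one sample's individual-specific network (ISMLN)
#'
#' Thresholds one sample's delta-PCC column at the fitted cutoff: the
#' catalog edges whose correlation changed significantly when this sample
#' was appended to the reference form the sample's individual-specific
#' miRNA-lncRNA network.
#'
#' @param delta An `mln_delta`.
#' @param cutoff An `mln_cutoff` fitted on the same catalog.
#' @param sample_id A sample present in `delta`.
#' @return A tibble of class `mln_ismln` (`mirna`, `lncrna`, `delta_pcc`,
#'   `sign`), with the sample id and group as attributes.
#' @export
extract_ismln <- function(delta, cutoff, sample_id) {
  j <- match(sample_id, delta$sample_ids)
  if (is.na(j)) abort(sprintf("Sample '%s' not present in the delta matrix.", sample_id))
  col <- delta$delta[, j]
  keep <- as.logical(is_significant(col, cutoff))
  out <- tibble(
    mirna = delta$catalog$mirna[keep],
    lncrna = delta$catalog$lncrna[keep],
    delta_pcc = unname(col[keep]),
    sign = sign(unname(col[keep]))
  )
  structure(out, class = c("mln_ismln", class(out)),
            sample_id = sample_id, group = delta$group)
}

#' Extract all per-sample networks from a delta matrix
#'
#' @inheritParams extract_ismln
#' @return A named list of `mln_ismln` tibbles, one per sample.
#' @export
extract_ismlns <- function(delta, cutoff) {
  out <- lapply(delta$sample_ids, function(s) extract_ismln(delta, cutoff, s))
  names(out) <- delta$sample_ids
  out
}

#' @export
print.mln_cutoff <- function(x, ...) {
  if (x$method == "pooled_normal") {
    cat(sprintf("<mln_cutoff> pooled_normal: |delta - %.4g| >= %.4g (alpha = %g, fitted sd = %.4g, n = %d)\n",
                x$fitted_mean, x$cutoff_abs, x$alpha, x$fitted_sd, x$n_entries))
  } else {
    cat(sprintf("<mln_cutoff> ssn_z: per-edge thresholds, median %.4g (alpha = %g, n_ref = %d)\n",
                stats::median(x$cutoff_abs), x$alpha, x$n_ref))
  }
  invisible(x)
}

#' @rdname tidiers
#' @method glance mln_cutoff
#' @export
glance.mln_cutoff <- function(x, ...) {
  tibble(method = x$method, alpha = x$alpha,
         cutoff_abs = if (x$method == "pooled_normal") x$cutoff_abs else stats::median(x$cutoff_abs),
         fitted_mean = x$fitted_mean, fitted_sd = x$fitted_sd,
         n_entries = x$n_entries)
}
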