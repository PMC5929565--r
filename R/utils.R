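#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Canonical key for a miRNA-lncRNA pair. The separator never occurs in
# miRBase / LNCipedia-style identifiers.
edge_key <- function(mirna, lncrna) paste(mirna, lncrna, sep = "|")

split_edge_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  tibble(
    mirna  = vapply(parts, `[[`, character(1), 1L),
    lncrna = vapply(parts, `[[`, character(1), 2L)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
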