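#' Read an identifier alias map
#'
#' Reads a two-column delimited file mapping raw identifiers to canonical
#' identifiers (for example, harmonising miRNA names to one miRBase release,
#' or lncRNA names to one LNCipedia release). The map must be a function:
#' no raw id may map to two different canonical ids. Identifiers absent
#' from the map pass through unchanged, so applying the map twice equals
#' applying it once.
#'
#' @param path Path to a delimited text file with two columns
#'   (raw id, canonical id). A header row is expected.
#' @param delim Field delimiter, tab by default.
#' @return A named character vector: `names()` are raw ids, values are
#'   canonical ids.
#' @export
read_alias_map <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (ncol(df) < 2L) abort("Alias map must have two columns (raw, canonical).")
  raw <- df[[1]]
  canon <- df[[2]]
  dup <- unique(raw[duplicated(raw)])
  conflicting <- dup[vapply(dup, function(r) length(unique(canon[raw == r])) > 1L, logical(1))]
  if (length(conflicting)) {
    abort(sprintf("Alias map is not a function: raw id(s) %s map to multiple canonical ids.",
                  paste(utils::head(conflicting, 5L), collapse = ", ")))
  }
  map <- canon[!duplicated(raw)]
  names(map) <- raw[!duplicated(raw)]
  map
}

apply_alias <- function(ids, alias) {
  if (is.null(alias)) return(ids)
  hit <- ids %in% names(alias)
  ids[hit] <- unname(alias[ids[hit]])
  ids
}

read_expression_matrix <- function(path, delim, what) {
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (ncol(df) < 2L) abort(sprintf("%s matrix must have a feature-id column plus sample columns.", what))
  ids <- df[[1]]
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df)))
  )
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)[-1]))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "%s matrix: non-numeric or non-finite value at feature '%s', sample '%s' (row %d, column %d of %s).",
      what, ids[bad[1, 1]], colnames(num)[bad[1, 2]], bad[1, 1], bad[1, 2] + 1L, path))
  }
  rownames(num) <- ids
  num
}

new_panel <- function(mirna, lncrna, phenotype, report = list()) {
  structure(
    list(mirna = mirna, lncrna = lncrna, phenotype = phenotype, report = report),
    class = "mln_panel"
  )
}

validate_panel <- function(panel) {
  if (!identical(colnames(panel$mirna), colnames(panel$lncrna))) {
    abort("Panel invariant violated: sample columns of the two matrices differ.")
  }
  if (anyDuplicated(rownames(panel$mirna))) abort("Duplicate miRNA ids in panel.")
  if (anyDuplicated(rownames(panel$lncrna))) abort("Duplicate lncRNA ids in panel.")
  if (!all(is.finite(panel$mirna)) || !all(is.finite(panel$lncrna))) {
    abort("Panel invariant violated: non-finite expression values.")
  }
  if (!setequal(panel$phenotype$sample_id, colnames(panel$mirna))) {
    abort("Panel invariant violated: phenotype table does not cover the samples.")
  }
  if (!all(panel$phenotype$group %in% c("tumor", "non_tumor"))) {
    abort("Phenotype labels must be 'tumor' or 'non_tumor'.")
  }
  invisible(panel)
}

#' Read a paired miRNA/lncRNA expression panel
#'
#' Reads the two expression matrices (features in rows, samples in columns,
#' first column = feature id, header row = sample ids) together with a
#' sample phenotype table, and retains only the samples present in both
#' matrices and the phenotype table (the intersection rule: a sample is
#' usable only when it has miRNA and lncRNA profiles simultaneously).
#' Sample order follows the miRNA matrix. Optional alias maps canonicalise
#' feature identifiers before any matching.
#'
#' @param mirna_path,lncrna_path Paths to the delimited expression matrices.
#' @param phenotype_path Path to a two-column delimited file
#'   (sample id, label). Labels `tumor` / `non_tumor` are expected;
#'   `non-tumor` and `normal` are accepted and normalised.
#' @param mirna_alias,lncrna_alias Optional alias maps from
#'   [read_alias_map()], one per namespace.
#' @param delim Field delimiter, tab by default (comma for CSV input).
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to both matrices
#'   after reading. Off by default: expression values are used as provided.
#' @return An object of class `mln_panel`: the two aligned matrices, the
#'   phenotype tibble (`sample_id`, `group`), and a load `report` listing
#'   dropped sample counts per source.
#' @export
read_panel <- function(mirna_path, lncrna_path, phenotype_path,
                       mirna_alias = NULL, lncrna_alias = NULL,
                       delim = "\t", log2_transform = FALSE) {
  m <- read_expression_matrix(mirna_path, delim, "miRNA")
  l <- read_expression_matrix(lncrna_path, delim, "lncRNA")

  rn <- apply_alias(rownames(m), mirna_alias)
  if (anyDuplicated(rn)) {
    abort(sprintf("Duplicate miRNA id after aliasing: %s",
                  paste(unique(rn[duplicated(rn)])[1:min(5, sum(duplicated(rn)))], collapse = ", ")))
  }
  rownames(m) <- rn
  rn <- apply_alias(rownames(l), lncrna_alias)
  if (anyDuplicated(rn)) {
    abort(sprintf("Duplicate lncRNA id after aliasing: %s",
                  paste(unique(rn[duplicated(rn)])[1:min(5, sum(duplicated(rn)))], collapse = ", ")))
  }
  rownames(l) <- rn

  ph <- readr::read_delim(phenotype_path, delim = delim,
                          col_types = readr::cols(.default = "c"), progress = FALSE)
  if (ncol(ph) < 2L) abort("Phenotype table must have two columns (sample id, label).")
  labels <- tolower(ph[[2]])
  labels[labels %in% c("non-tumor", "nontumor", "normal", "control")] <- "non_tumor"
  if (!all(labels %in% c("tumor", "non_tumor"))) {
    abort(sprintf("Unrecognised phenotype label(s): %s",
                  paste(unique(ph[[2]][!labels %in% c("tumor", "non_tumor")]), collapse = ", ")))
  }
  phenotype <- tibble(sample_id = ph[[1]], group = labels)
  if (anyDuplicated(phenotype$sample_id)) abort("Duplicate sample id in phenotype table.")

  shared <- intersect(intersect(colnames(m), colnames(l)), phenotype$sample_id)
  if (length(shared) == 0L) abort("No sample is present in both matrices and the phenotype table.")
  shared <- colnames(m)[colnames(m) %in% shared]  # keep miRNA-matrix order

  report <- list(
    n_samples          = length(shared),
    dropped_mirna      = ncol(m) - length(shared),
    dropped_lncrna     = ncol(l) - length(shared),
    dropped_phenotype  = nrow(phenotype) - length(shared)
  )

  m <- m[, shared, drop = FALSE]
  l <- l[, shared, drop = FALSE]
  if (log2_transform) {
    m <- log2(m + 1)
    l <- log2(l + 1)
  }
  phenotype <- phenotype[match(shared, phenotype$sample_id), ]

  validate_panel(new_panel(m, l, phenotype, report))
}

#' @export
print.mln_panel <- function(x, ...) {
  tab <- table(x$phenotype$group)
  cat(sprintf("<mln_panel> %d miRNAs x %d lncRNAs x %d samples (%d tumor / %d non-tumor)\n",
              nrow(x$mirna), nrow(x$lncrna), ncol(x$mirna),
              tab["tumor"] %||% 0L, tab["non_tumor"] %||% 0L))
  invisible(x)
}

new_catalog <- function(edges, n_input = nrow(edges), n_dropped = 0L) {
  out <- as_tibble(edges)
  class(out) <- c("mln_catalog", class(out))
  attr(out, "n_input") <- n_input
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build an interaction catalog from an in-memory edge table
#'
#' @param edges A data frame with columns `mirna` and `lncrna` (an optional
#'   `provenance` column is carried along).
#' @param panel Optional `mln_panel`; when given, edges whose endpoints are
#'   not measured in the panel are dropped (with a recorded count).
#' @return An `mln_catalog` tibble; attributes `n_input` and `n_dropped`
#'   record the filter accounting.
#' @export
as_catalog <- function(edges, panel = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("mirna", "lncrna") %in% names(edges))) {
    abort("Catalog edges need `mirna` and `lncrna` columns.")
  }
  keep <- !duplicated(edge_key(edges$mirna, edges$lncrna))
  edges <- edges[keep, , drop = FALSE]
  n_unique <- nrow(edges)
  n_dropped <- 0L
  if (!is.null(panel)) {
    ok <- edges$mirna %in% rownames(panel$mirna) & edges$lncrna %in% rownames(panel$lncrna)
    n_dropped <- sum(!ok)
    edges <- edges[ok, , drop = FALSE]
  }
  if (nrow(edges) == 0L) abort("No catalog edge survives filtering against the panel.")
  new_catalog(edges, n_input = n_unique, n_dropped = n_dropped)
}

#' Read a miRNA-lncRNA interaction catalog
#'
#' Reads a two-column delimited edge list (miRNA id, lncRNA id; an optional
#' third column is kept as a provenance tag), canonicalises identifiers
#' through the alias maps, removes duplicate pairs keeping the first
#' occurrence, and drops pairs whose miRNA or lncRNA is not measured in the
#' panel. Dropping rather than erroring mirrors the common situation where
#' a literature-scale catalog exceeds the features actually profiled.
#'
#' @inheritParams read_panel
#' @param path Path to the edge list.
#' @param panel An `mln_panel`; edges are filtered against its feature ids.
#' @return An `mln_catalog` tibble with columns `mirna`, `lncrna` (and
#'   `provenance` when present); attributes `n_input` (unique input pairs)
#'   and `n_dropped` (pairs removed for missing endpoints).
#' @export
read_catalog <- function(path, panel, mirna_alias = NULL, lncrna_alias = NULL,
                         delim = "\t") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("Catalog file is empty.")
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  header <- fields[[1]]
  has_header <- !all(c(header[1] %in% rownames(panel$mirna),
                       length(header) >= 2 && header[2] %in% rownames(panel$lncrna))) &&
    any(tolower(header) %in% c("mirna", "mi_rna", "lncrna", "lnc_rna", "source", "target"))
  body_idx <- if (has_header) seq_along(fields)[-1] else seq_along(fields)
  bad <- body_idx[nf[body_idx] < 2L]
  if (length(bad)) abort(sprintf("Malformed catalog line %d: fewer than two fields.", bad[1]))

  mirna <- apply_alias(vapply(fields[body_idx], `[[`, character(1), 1L), mirna_alias)
  lncrna <- apply_alias(vapply(fields[body_idx], `[[`, character(1), 2L), lncrna_alias)
  prov <- vapply(fields[body_idx], function(f) if (length(f) >= 3L) f[[3]] else NA_character_,
                 character(1))
  edges <- tibble(mirna = mirna, lncrna = lncrna)
  if (any(!is.na(prov))) edges$provenance <- prov
  as_catalog(edges, panel)
}

#' @export
print.mln_catalog <- function(x, ...) {
  cat(sprintf("<mln_catalog> %d edges (%d unique input pairs, %d dropped for missing endpoints)\n",
              nrow(x), attr(x, "n_input") %||% nrow(x), attr(x, "n_dropped") %||% 0L))
  NextMethod()
}

#' Write a result table to delimited text
#'
#' Writes any score/rank/result table as delimited text with a header row.
#' Doubles are rendered with 15 significant digits so a write/read
#' round-trip is lossless well below test tolerances.
#'
#' @param x A nonempty data frame.
#' @param path Output path.
#' @param delim Field delimiter, tab by default.
#' @return Invisibly, `x`.
#' @export
write_table <- function(x, path, delim = "\t") {
  x <- as_tibble(as.data.frame(x))
  if (nrow(x) == 0L) abort("Refusing to write an empty table.")
  out <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.15g", .x))
  ))
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(x)
}

#' Read back a table written by [write_table()]
#'
#' @inheritParams write_table
#' @return A tibble with column types guessed by readr.
#' @export
read_result_table <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, col_types = readr::cols(), progress = FALSE)
}

#' Write an expression matrix in panel format
#'
#' Features in rows, samples in columns, first column `feature_id`.
#'
#' @param m A numeric matrix with row and column names.
#' @inheritParams write_table
#' @export
write_matrix <- function(m, path, delim = "\t") {
  df <- as_tibble(as.data.frame(m), rownames = "feature_id")
  write_table(df, path, delim = delim)
}
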