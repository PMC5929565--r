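#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with the statistical structure the perturbation
#' method assumes: a catalog of miRNA-lncRNA edges whose control-sample
#' correlation is `rho_ref`, a subset of "planted" edges whose correlation
#' changes to `rho_tumor` in tumor samples, and expression-like
#' non-negative marginals. Defaults mirror a breast-cancer-shaped cohort
#' scaled to desk size: 84 controls, 100 tumors, 500 catalog edges of
#' which 25 are planted with the correlation collapsing from 0.8 to 0.
#'
#' @param n_ref Number of control (non-tumor) samples.
#' @param n_tumor Number of tumor samples.
#' @param n_edges Catalog size.
#' @param n_planted Number of planted (perturbed) edges; ignored when
#'   `planted` is given. Defaults to 25, capped at `n_edges`.
#' @param planted Integer indices of the planted edges (default: the
#'   first `n_planted`; positions carry no meaning).
#' @param rho_ref Reference correlation per edge, scalar or length-
#'   `n_edges` vector, each in (-1, 1).
#' @param rho_tumor Tumor-sample correlation of planted edges.
#' @param noise_sd Marginal expression standard deviation (expression
#'   units; default 2 around a baseline mean of 10).
#' @param mean_loc Baseline expression mean (default 10; with
#'   `noise_sd = 2` values are essentially always positive).
#' @param mean_shift Additive tumor mean shift applied to every feature
#'   (expression units; default 0 — a correlation-only perturbation).
#' @param mode `"independent_pair"` (each edge has its own feature pair;
#'   exact target correlations) or `"shared_mirna"` (one miRNA serves
#'   several lncRNAs through a common latent factor, needed to exercise
#'   the C1/C2 logic of the Activity Score).
#' @param n_mirna Number of distinct miRNAs in `shared_mirna` mode
#'   (default `ceiling(n_edges / 4)`).
#' @param seed Integer seed; fully determines the output.
#' @return An `mln_synth_config` list.
#' @export
synth_config <- function(n_ref = 84L, n_tumor = 100L, n_edges = 500L,
                         n_planted = NULL, planted = NULL,
                         rho_ref = 0.8, rho_tumor = 0,
                         noise_sd = 2, mean_loc = 10, mean_shift = 0,
                         mode = c("independent_pair", "shared_mirna"),
                         n_mirna = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_planted)) n_planted <- min(25L, n_edges)
  if (is.null(planted)) planted <- seq_len(n_planted)
  if (length(planted) && (min(planted) < 1L || max(planted) > n_edges)) {
    abort("`planted` indices must lie in 1..n_edges.")
  }
  rho_ref <- rep_len(rho_ref, n_edges)
  rho_tumor <- rep_len(rho_tumor, n_edges)
  if (any(abs(rho_ref) >= 1) || any(abs(rho_tumor) >= 1)) {
    abort("Correlations must lie strictly inside (-1, 1).")
  }
  if (mode == "shared_mirna" && is.null(n_mirna)) n_mirna <- ceiling(n_edges / 4)
  structure(list(
    n_ref = as.integer(n_ref), n_tumor = as.integer(n_tumor),
    n_edges = as.integer(n_edges), planted = as.integer(planted),
    rho_ref = rho_ref, rho_tumor = rho_tumor,
    noise_sd = noise_sd, mean_loc = mean_loc, mean_shift = mean_shift,
    mode = mode, n_mirna = if (is.null(n_mirna)) NA_integer_ else as.integer(n_mirna),
    seed = as.integer(seed)
  ), class = "mln_synth_config")
}

#' A cohort preset with the full breast-cancer cohort shape
#'
#' Convenience wrapper around [synth_config()] with 84 controls and 508
#' tumor samples.
#'
#' @param ... Overrides passed to [synth_config()].
#' @export
synth_config_brca_shape <- function(...) {
  synth_config(n_ref = 84L, n_tumor = 508L, ...)
}

#' Generate a synthetic miRNA-lncRNA cohort
#'
#' Draws expression for each catalog edge from a latent bivariate normal
#' with the configured correlation: `rho_ref` for control samples
#' everywhere, and `rho_tumor` in tumor samples for the planted edges
#' (non-planted edges keep `rho_ref` in both groups, so only the planted
#' correlation structure distinguishes the groups unless `mean_shift` is
#' set). Latents are mapped affinely to expression-like values
#' (`mean_loc + noise_sd * z`, clamped at 0); the affine map leaves
#' correlations untouched. In `shared_mirna` mode each miRNA is a latent
#' factor loaded by several lncRNAs, giving the configured correlations
#' exactly in the latent model while letting one miRNA span multiple
#' catalog edges.
#'
#' @param config An `mln_synth_config`.
#' @return A list: `panel` (an `mln_panel`), `catalog` (an
#'   `mln_catalog`), and `truth` (tibble `mirna`, `lncrna`, `planted`,
#'   `rho_ref`, `rho_tumor`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mln_synth_config"))
  set.seed(config$seed)
  E <- config$n_edges
  n <- config$n_ref + config$n_tumor
  is_tumor <- c(rep(FALSE, config$n_ref), rep(TRUE, config$n_tumor))
  # per-edge, per-sample target correlation
  rho <- matrix(rep(config$rho_ref, n), nrow = E)
  if (length(config$planted)) {
    rho[config$planted, is_tumor] <- config$rho_tumor[config$planted]
  }

  if (config$mode == "independent_pair") {
    mirna_ids <- sprintf("mir-%04d", seq_len(E))
    Z1 <- matrix(stats::rnorm(E * n), nrow = E)
  } else {
    K <- config$n_mirna
    mirna_of <- ((seq_len(E) - 1L) %% K) + 1L
    mirna_ids_pool <- sprintf("mir-%04d", seq_len(K))
    mirna_ids <- mirna_ids_pool[mirna_of]
    F_lat <- matrix(stats::rnorm(K * n), nrow = K)
    Z1 <- F_lat[mirna_of, , drop = FALSE]
  }
  lncrna_ids <- sprintf("lnc-%04d", seq_len(E))
  eps <- matrix(stats::rnorm(E * n), nrow = E)
  Z2 <- rho * Z1 + sqrt(1 - rho^2) * eps

  to_expr <- function(z) pmax(config$mean_loc + config$noise_sd * z, 0)
  M <- to_expr(Z1)
  L <- to_expr(Z2)
  if (config$mean_shift != 0) {
    M[, is_tumor] <- M[, is_tumor] + config$mean_shift
    L[, is_tumor] <- L[, is_tumor] + config$mean_shift
  }

  sample_ids <- c(sprintf("ctrl-%04d", seq_len(config$n_ref)),
                  sprintf("tumor-%04d", seq_len(config$n_tumor)))
  colnames(M) <- colnames(L) <- sample_ids
  if (config$mode == "independent_pair") {
    rownames(M) <- mirna_ids
  } else {
    # collapse duplicated miRNA rows (same latent, hence identical values)
    M <- M[!duplicated(mirna_ids), , drop = FALSE]
    rownames(M) <- unique(mirna_ids)
  }
  rownames(L) <- lncrna_ids

  phenotype <- tibble(sample_id = sample_ids,
                      group = ifelse(is_tumor, "tumor", "non_tumor"))
  panel <- validate_panel(new_panel(M, L, phenotype,
                                    report = list(n_samples = n, synthetic = TRUE)))
  catalog <- new_catalog(tibble(mirna = mirna_ids, lncrna = lncrna_ids))
  truth <- tibble(mirna = mirna_ids, lncrna = lncrna_ids,
                  planted = seq_len(E) %in% config$planted,
                  rho_ref = config$rho_ref,
                  rho_tumor = ifelse(seq_len(E) %in% config$planted,
                                     config$rho_tumor, config$rho_ref))
  list(panel = panel, catalog = catalog, truth = truth)
}

#' Write a simulated cohort as the package's delimited input files
#'
#' Emits `mirna.tsv`, `lncrna.tsv`, `phenotype.tsv`, `catalog.tsv` and
#' `truth.tsv` into `dir`, in the formats [read_panel()] and
#' [read_catalog()] consume.
#'
#' @param sim A list from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mirna.tsv", "lncrna.tsv", "phenotype.tsv",
                            "catalog.tsv", "truth.tsv"))
  write_matrix(sim$panel$mirna, paths[1])
  write_matrix(sim$panel$lncrna, paths[2])
  write_table(sim$panel$phenotype, paths[3])
  write_table(as_tibble(sim$catalog), paths[4])
  write_table(sim$truth, paths[5])
  invisible(paths)
}

#' Worked-example fixture for the significance score
#'
#' A deliberately simple cohort of 508 per-sample networks over a
#' three-edge catalog: one edge significant in every sample, one in none,
#' and one in exactly half. The expected significance scores
#' (508/508 = 1, 0/508 = 0, 254/508 = 0.5) are attached, so the fixture
#' pins the score arithmetic end to end.
#'
#' @return A list: `indicator` (3 x 508 logical matrix of per-sample
#'   significance), `ismlns` (list of 508 `mln_ismln` tibbles),
#'   `catalog`, and `expected` (the score table the fixture implies).
#' @export
worked_example_fixture <- function() {
  n <- 508L
  catalog <- new_catalog(tibble(
    mirna = c("miR-200a", "miR-429", "miR-22"),
    lncrna = c("XIST", "TUG1", "H19")
  ))
  indicator <- rbind(
    rep(TRUE, n),
    rep(FALSE, n),
    c(rep(TRUE, 254L), rep(FALSE, n - 254L))
  )
  rownames(indicator) <- edge_key(catalog$mirna, catalog$lncrna)
  colnames(indicator) <- sprintf("tumor-%04d", seq_len(n))
  ismlns <- lapply(seq_len(n), function(j) {
    keep <- indicator[, j]
    structure(
      tibble(mirna = catalog$mirna[keep], lncrna = catalog$lncrna[keep],
             delta_pcc = rep(1, sum(keep)), sign = rep(1, sum(keep))),
      class = c("mln_ismln", class(tibble())),
      sample_id = colnames(indicator)[j], group = "tumor"
    )
  })
  names(ismlns) <- colnames(indicator)
  expected <- tibble(
    mirna = catalog$mirna, lncrna = catalog$lncrna,
    n_significant = c(n, 0L, 254L), n_samples = n,
    score = c(1, 0, 0.5)
  )
  list(indicator = indicator, ismlns = ismlns, catalog = catalog, expected = expected)
}
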