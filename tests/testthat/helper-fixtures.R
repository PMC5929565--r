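# Shared fixtures, built in code.

# Independent, brute-force correlation oracle: definitional sum of
# deviations via base R on the raw vectors.
oracle_cor <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# A tiny hand-built panel: 2 miRNAs, 2 lncRNAs, 4 controls + 2 tumors.
tiny_panel <- function() {
  m <- rbind(m1 = c(1, 2, 3, 4, 4, 0),
             m2 = c(2, 1, 4, 3, 1, 5))
  l <- rbind(l1 = c(1, 3, 2, 4, 0, 4),
             l2 = c(5, 4, 3, 2, 2, 2))
  colnames(m) <- colnames(l) <- c(paste0("c", 1:4), paste0("t", 1:2))
  ph <- tibble::tibble(sample_id = colnames(m),
                       group = rep(c("non_tumor", "tumor"), c(4, 2)))
  perturbnet:::new_panel(m, l, ph)
}

tiny_catalog <- function(panel = tiny_panel()) {
  as_catalog(tibble::tibble(mirna = c("m1", "m2"), lncrna = c("l1", "l2")), panel)
}

# Random panel + catalog for property tests: each edge an independent pair.
random_sim <- function(seed, n_ref = 30, n_tumor = 10, n_edges = 20,
                       rho_ref = 0.5, ...) {
  simulate_cohort(synth_config(n_ref = n_ref, n_tumor = n_tumor,
                               n_edges = n_edges, n_planted = 0,
                               rho_ref = rho_ref, seed = seed, ...))
}

# Write a panel's three input files to a temp dir; returns the paths.
write_panel_files <- function(m, l, ph, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- file.path(dir, c("mirna.tsv", "lncrna.tsv", "pheno.tsv"))
  write_matrix(m, paths[1])
  write_matrix(l, paths[2])
  write_table(ph, paths[3])
  paths
}
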