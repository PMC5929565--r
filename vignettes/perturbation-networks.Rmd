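---
title: "Single-sample miRNA-lncRNA perturbation networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample miRNA-lncRNA perturbation networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbnet)
```

## The problem and the statistic

Competing-endogenous-RNA regulation makes miRNA-lncRNA *interactions*, not
single molecules, the natural unit of dysregulation in cancer. Bulk
differential co-expression methods need many samples per group; clinical
questions are about *one* sample. perturbnet implements the single-sample
perturbation answer: hold a catalog of candidate miRNA-lncRNA pairs fixed,
estimate each pair's Pearson correlation over `n` control (non-tumor)
samples — the *reference network* — then append one case sample and
recompute. The per-edge change

\[
\Delta PCC_e(s) \;=\; PCC_e(x_1,\dots,x_n,x_s) \;-\; PCC_e(x_1,\dots,x_n)
\]

is that sample's perturbation of edge \(e\). A single conforming sample
barely moves a correlation estimated from `n` points (the shift is
\(O(1/n)\)), so edges with large \(|\Delta PCC|\) mark sample-specific
dysregulation. The edges passing a significance cutoff form the sample's
individual-specific network (ISMLN); counting, for each edge, the fraction
of tumor samples whose network contains it gives the significance score

\[
S(e) = N_1 / N \in [0, 1],
\]

and the high-scoring edges form the cohort's basic network (BMLN).
Downstream, candidate edges (score above a threshold, default 0.8 strict)
are ranked by random-forest importance of their \(\Delta PCC\) features,
evaluated by stratified cross-validated ROC/AUC against the conventional
node (expression) features, and summarised per miRNA by the Activity Score

\[
A(\text{miRNA}_i) = \Big(\sum_{j \in \text{candidates}(i)} S(i,j)\Big)
  \times \frac{C_1}{C_2},
\]

where \(C_1\) and \(C_2\) count the miRNA's pairs among the candidates and
among the whole catalog. The \(C_1/C_2\) factor discounts catalog hubs: a
miRNA with thousands of catalogued partners should not look "active" just
because a few of them are perturbed.

## Assumptions

* Expression values are used as provided (normalized RNA-seq style,
  non-negative, finite); an optional `log2(x + 1)` flag exists but is off
  by default because the statistic is built on whatever scale the
  correlations were meant to describe.
* The reference cohort is homogeneous enough that its edge correlations
  are stable; fewer than 3 controls is an error, and leave-one-out columns
  need at least 4.
* The catalog is a fixed universe: edges are never inferred from the data,
  only tested. Catalog pairs whose endpoints are not measured are dropped
  with a count (a literature catalog routinely exceeds the profiled
  features).

## The significance cutoff

The cutoff decides when a \(\Delta PCC\) is "significant". The pooled
construction (`method = "pooled_normal"`, the default) fits a single
normal by the sample mean and standard deviation of *all* defined entries
of the tumor \(\Delta PCC\) matrix and takes the exact two-sided
\(\alpha\)-quantile, \(c = z_{1-\alpha/2}\,\hat\sigma\); an entry is
significant when \(|\Delta PCC - \hat\mu| \ge c\). This mirrors
thresholding a pooled histogram with symmetric cutoffs, and the quantile
is the unique value whose tail mass equals \(\alpha\). The alternative
(`method = "ssn_z"`) is the per-edge asymptotic statistic
\(z_e = \Delta PCC_e (n-1)/(1 - PCC_e^2)\) referred to the standard
normal, which yields an edge-specific threshold vector — tighter for
strongly correlated edges, looser near \(PCC = 0\). Both are exposed
because the pooled histogram view and the per-edge asymptotic view are
genuinely different nulls; results in this package default to the pooled
one, and every function that consumes a cutoff works with either.

The fit population is the matrix you pass — conventionally the tumor
matrix; pool both groups by `rbind`-ing if you prefer. Undefined
correlations (a zero-variance endpoint) are flagged `NA` end to end:
excluded from the fit, never members of a network, never imputed —
except in the classifier feature table, where a missing perturbation is
explicitly zero-imputed (absence of evidence of perturbation) with a
logged count.

## Control samples: leave-one-out

Tumor samples are appended to the full reference. A control sample,
however, is already *inside* the reference; naively re-appending it
counts it twice and shrinks its \(\Delta PCC\) toward zero. The default
(`control_mode = "loo"`) therefore removes the sample from the cached
sums (n−1 controls), treats the reduced network as its reference, and
appends it back — giving control columns the same n-versus-(n−1)
structure tumor columns have (n+1 versus n). The naive reading is kept
as `control_mode = "reappend"` for comparability.

## Numerical choices

* All correlations run over sums of mean-centred values; appending a
  sample updates five cached sums per edge, so a whole cohort's
  \(\Delta PCC\) matrix is one vectorised pass (O(edges) per sample).
  Tests pin the incremental result to definitional recomputation at
  1e−10 over 200 random instances.
* Zero variance is detected against a relative floor
  (`scale² · n · 1e−24`, with an absolute floor of 1e−300), so exact
  constants are flagged but numerically tiny genuine variation is not.
* Comparisons against the cutoff use `>=`: ties are significant.
* Ranking ties (equal scores, equal importance) break by descending
  absolute mean tumor \(\Delta PCC\) when a delta matrix is supplied,
  then by catalog order — orderings are byte-identical across runs.
* Correlations are clamped to \([-1, 1]\) after the floating-point
  division; \(\Delta PCC\) is therefore always in \([-2, 2]\).

## Classifier evaluation and selection bias

`rank_by_importance()` uses a random forest (500 trees, Gini importance)
— the backend retained after the usual SVM/RF/ELM comparison — and
`cv_auc()` reports the pooled out-of-fold ROC of stratified k-fold
cross-validation (one curve from all held-out scores, rather than a mean
of per-fold AUCs, so the curve is a genuine step function whose
trapezoidal area is the reported AUC).

One subtlety matters when the evaluated subset was itself *chosen on the
full cohort* ("top-5 by importance", "top-5 by differential-expression
p"): the held-out samples already influenced the selection, and under a
null the best 5 of ~1000 features look genuinely discriminative
in-sample. With ~180 samples this inflates a null AUC to roughly 0.6–0.7.
`cv_auc()` therefore also accepts a `selector` — a function re-run on
each training fold alone (`importance_selector()`, `de_selector()`) —
which is the unbiased estimator of "top-k feature performance". The
package's edge-versus-node comparison uses the nested protocol
symmetrically for both feature families; the fixed-subset protocol
remains available because it is what the field's papers report.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws each catalog edge from a latent bivariate
normal: correlation `rho_ref` (default 0.8) for control samples
everywhere, and `rho_tumor` (default 0) in tumor samples for a planted
subset of edges. Latents map affinely to expression-like values
(mean 10, sd 2, clamped at zero — the clamp sits 5 sd away and is
correlation-neutral in practice). Defaults are a desk-scaled two-group
cohort: 84 controls, 100 tumors, 500 edges, 25 planted;
`synth_config_brca_shape()` keeps the full 84/508 shape. The
`shared_mirna` mode routes several lncRNAs through one miRNA latent
factor so that the \(C_1/C_2\) weighting of the Activity Score is
actually exercised; its loadings give the target correlations exactly in
the latent model (documented tolerance 0.05 on the expression scale, from
the clamp).

The generator emulates *correlation structure and its tumor-specific
perturbation* — the only thing the method consumes. It does **not**
emulate counts, library-size or batch effects, heavy-tailed expression,
miRNA-target directionality (the latent model is symmetric), or
inter-edge dependence beyond shared miRNAs. Passing tests therefore show
the statistics do what they claim under the stated model, not that any
particular biological cohort will separate as cleanly. A `mean_shift`
parameter adds a tumor mean offset for differential-expression baseline
tests; with the default 0, the simulated dysregulation is purely
relational and invisible to node-level analysis — which is exactly the
regime the edge statistics are for.

## Problem sizes used by the test suite

The suites run the full pipeline on cohorts of 500 edges and 184 samples
(10 seeds for the recovery checks, 20 for the edge-versus-node
comparison), a 200-edge, 60-sample null calibration (12,000 edge-sample
trials), a one-million-entry closed-form cutoff check, and 200 random
incremental-versus-brute-force instances. These sizes were chosen so the
estimates under test (score separation, flagging rates near 5%, AUC
medians) are stable at the asserted tolerances.

## Known limitations

* The pooled-normal null treats all edges as exchangeable; edges with
  extreme reference correlation have compressed \(\Delta PCC\) ranges
  and are relatively under-called (use `ssn_z` when this matters).
* Leave-one-out control columns use a reference of n−1, tumor columns
  one of n; the first-order size difference is negligible at n ≥ 80 but
  not at very small cohorts.
* The candidate threshold (score > 0.8) is a cohort-level convention;
  at small tumor counts the score is coarse (increments of 1/N).
* Catalog identifier harmonisation is the caller's job (an alias map is
  applied mechanically); no name unification is attempted.
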