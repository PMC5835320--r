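---
title: "Methods: COMPARE-style drug-sensitivity pharmacogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COMPARE-style drug-sensitivity pharmacogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comparetox)
```

# The analysis in one paragraph

Given a drug's half-maximal inhibitory concentration (IC50) measured across
a panel of tumor cell lines and a genes-by-lines transcriptome matrix for
the same panel, the COMPARE approach ranks every gene by the Pearson
correlation between its expression profile and the per-line log10(IC50)
profile. Genes at the positive extreme are candidate resistance factors
(more transcript, more drug needed); genes at the negative extreme are
candidate sensitivity factors. The top-k genes of each sign form a
signature on which the cell lines are clustered by the Ward method; the
resulting clusters are tested for association with a sensitive/resistant
dichotomization of the panel by a Pearson chi-square test. Downstream, the
signature's promoters can be screened for transcription-factor binding
motifs, and the signature can be intersected with curated gene sets and
functional groups. `comparetox` implements each of these stages as an
exported function plus a `run_pipeline()` orchestrator, and ships a
synthetic-data generator so that the whole chain is testable without any
external download.

# Dose-response estimation

IC50s come from viability curves (fraction of untreated control vs drug
concentration). The primary estimator is a four-parameter logistic,

$$v(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + 10^{\,h\,(\log_{10} c - e)}},$$

fit by Levenberg-Marquardt least squares on log10 concentration. Because
viability is already normalized to untreated controls, the IC50 is defined
as the *absolute* 50%-of-control crossing of the fitted curve, not the
curve's midpoint; `bottom` is constrained to `[0, 0.49]` and `top` to
`[0.5, 1.5]` so that the crossing exists whenever the data support one.
Starting values for the crossing come from log-linear interpolation of the
observed curve, with a small grid of Hill-slope starts (1 and 2) to avoid
plateau-induced singular gradients. When the nonlinear fit fails, the
estimator falls back to log-linear interpolation between the two
concentrations bracketing 50%; when observed viability never drops below
50% the estimate is censored as "greater than the highest tested
concentration" and refuses to enter ratio computations. Curves need at
least four distinct concentrations; non-monotonicity only warns, since
plate noise routinely produces local rises.

The *degree of resistance* is the ratio IC50(resistant)/IC50(parental),
rounded half-up to two decimals to match how such ratios are conventionally
printed. A ratio below 1 is flagged as collateral sensitivity — the
resistant line is hypersensitive relative to its parent.

# Correlation ranking and signature selection

`compare_correlate()` computes, for every gene with at least three
pairwise-complete observations, the Pearson correlation `r` with the
response and a two-sided p-value from the t transform with `n_used - 2`
degrees of freedom. Design choices:

* **Pearson, not Spearman.** The workflow's own statistical description
  names Pearson's correlation test; Spearman is available behind
  `method = "spearman"` for rank-robust exploration.
* **Pairwise-complete missing-value handling.** Microarray panels have
  per-gene dropouts; listwise deletion would discard whole cell lines.
* **No multiple-testing correction in the ranking.** The ranking is an
  R-ordered list by construction; an optional Benjamini-Hochberg column
  (`fdr = TRUE`) is emitted for downstream filtering and labeled as an
  extension.
* **Deterministic ordering.** Sorting is by `r` descending with
  lexicographic gene-id tie-breaks, so reruns and row permutations give
  identical output.

`select_signature()` takes the top `k_pos` genes with `r > 0` and top
`k_neg` with `r < 0` (defaults 20/20, giving the classic 40-gene
signature). If fewer genes qualify on a side, the shorter list is returned
with a warning rather than padding with wrong-signed genes.

# Ward clustering and the clustered image map

Cell lines are clustered on the signature genes after per-gene z-scoring
(`standardize_signature_matrix()`), which puts every gene on the same scale
as clustered-image-map displays do. Ward linkage is computed by the
Lance-Williams `ward.D` recurrence on **squared** Euclidean distances;
under that convention a merge height equals the Ward merge cost

$$\Delta(A, B) = \frac{2\,|A||B|}{|A|+|B|}\,\lVert \bar x_A - \bar x_B \rVert^2,$$

i.e. twice the increase in within-cluster sum of squares, and heights are
monotone non-decreasing. The test suite checks this convention against a
greedy minimal-cost agglomeration computed directly from the
sum-of-squares formula. `cut_tree()` relabels clusters 1..k by first
appearance in dendrogram leaf order, so cluster numbering is reproducible
and reading order matches the plotted tree. `k` is a user parameter
defaulting to 4; no automatic model selection is attempted.
`render_cim()` draws the heat map with both dendrograms and an optional
sensitivity annotation bar; it is purely presentational.

# Sensitivity partition and chi-square association

`partition_by_threshold()` dichotomizes the panel at a log10(IC50)
threshold: strictly below is sensitive, at-or-above is resistant (the tie
rule is documented because published descriptions rarely state one). The
default threshold is the sample median — a fixed molar threshold such as
-5.45 can be passed instead when working on an absolute scale.
`chi_square_test()` applies the Pearson statistic *without* continuity
correction (the correction is defined for 2x2 tables and would change the
reference worked example), warns when any expected count drops below 5 —
small cells are routine in 4x2 panel tables — and can report a Monte-Carlo
p-value alongside, never instead of, the asymptotic one.

# Promoter motif enrichment

`extract_promoters()` builds strand-aware windows upstream of each TSS
(default 50 kb, the full regulatory window the workflow targets), 0-based
half-open internally, truncated at contig boundaries with a warning, and
reverse-complemented on the minus strand so every sequence reads toward
its TSS. `scan_best_score()` scores a position weight matrix as summed
log2 odds against the background at every offset on both strands;
ambiguous bases contribute the background expectation (score 0).

`enrich_motifs()` ranks motifs by a shuffle-calibrated statistic: the
observed value is the mean best-hit score over promoters, and the null is
that same mean recomputed over `n_shuffles` independent
dinucleotide-preserving shuffles (Altschul-Erickson Euler-walk shuffle) of
every promoter. The z-score is `(mu0 - T)/sigma0`, *negative when
enriched* — matching the sign convention of established motif screens —
and the p-value is the one-sided normal tail. Dinucleotide (not
mononucleotide) shuffling preserves local composition, the standard null
in motif analysis. At least 20 shuffles are required because the null sd
is otherwise too noisy; the default is 100. This statistic is this
package's own open construction: tools built on proprietary or unpublished
scoring internals will produce different absolute z-scores, and no attempt
is made to reproduce any specific published motif z-score table.

# Over-representation and curated networks

`ora_fisher()` tests each gene set for overlap with the query by the right
tail of the hypergeometric distribution (the one-sided Fisher exact test),
after intersecting sets with the universe. The significance flag applies a
`-log10(p) >= 1.3` cutoff (p <= 0.05), the convention of commercial
pathway suites; a Benjamini-Hochberg column is reported alongside the raw
p that the cutoff applies to. When run inside the pipeline the universe is
all genes of the expression matrix; standalone calls must pass it
explicitly. Proprietary canonical-pathway content and activation z-score
prediction are *not* emulated: enrichment runs against whatever GMT
collection the user supplies. `functional_group_table()` ships the curated
table of published arsenic-trioxide response determinants with one primary
functional group per entry (labels preserved verbatim, including their
typographical quirks; a normalized symbol column handles matching), and
`assemble_network()` builds a group-labeled igraph network from a curated
direct/indirect edge table with self-loops and out-of-universe edges
dropped.

# The synthetic-data generator

`gen_expression_response()` emulates the statistical skeleton of a
58-line panel experiment: the response is `N(-5.45, 0.8^2)` on the
log10 molar scale (so the default median partition mirrors the absolute
threshold used in panel work), and each planted gene is
`a * response + noise` with `a` solved from

$$\rho = \frac{a\,\sigma_y}{\sqrt{a^2 \sigma_y^2 + \sigma_\varepsilon^2}}$$

so the expected Pearson correlation is exactly the configured `rho`
(default 0.6, a strength at which the published top-of-list coefficients
sit). Non-planted genes are independent noise around gene-specific
baselines. Because all planted genes in one panel share a single response
draw, their *sample* correlations co-fluctuate with the realized response
spread; recovery statistics are therefore quoted as averages over many
seeded panels. `gen_promoters()` plants exactly one PWM-sampled motif
instance in `ceiling(plant_rate * n)` uniform-background sequences — one
instance, not Poisson-many, is the simplest structure sufficient for
rank-recovery testing. `gen_dose_response()` produces replicated 4PL
viability tables with multiplicative log-normal noise clipped to
`[0, 1.2]` (default 6 replicates per concentration, grid 0.003-500 uM).
A single user seed is expanded into fixed per-component substreams so each
generator is independently reproducible.

What the generator deliberately does **not** emulate: array probe effects,
batch structure, tissue-of-origin clustering, correlated gene modules, or
non-uniform promoter composition. Passing recovery tests on this generator
demonstrates that the algorithms are implemented correctly, not that the
biological conclusions of any particular panel analysis are robust.

# Problem sizes used in validation

The packaged validation suite runs planted-panel recovery at 2000 genes x
58 lines over 50 seeds, motif rank recovery at 200 promoters x 150 bp
against 10 decoy PWMs with 100 shuffles, null motif calibration at 20
seeded runs of 30 promoters, IC50 recovery over 100 noisy curves, and
brute-force oracle comparisons at up to 6 clustered objects — sizes chosen
to exercise every code path at full statistical fidelity while keeping a
complete run on a laptop in the minutes range.

# Known limitations

* **The end-to-end association p-value is descriptive, not inferential.**
  The signature genes are selected for correlation with the very response
  that defines the sensitive/resistant partition, so clustering cell lines
  on them is biased toward response-aligned clusters even when no true
  signal exists (feature-selection circularity, or "double dipping"). We
  measured this directly: under a global null (`rho = 0`), the pipeline's
  chi-square p-value falls below 0.05 in essentially every run. The
  chi-square test is therefore reported as a description of how cleanly
  the signature separates the panel — the role it plays in the published
  workflow — and must not be read as a calibrated test of association. An
  honest inferential version would require sample splitting or a
  selection-aware null, both outside this package's scope.
* The 4PL fit assumes viability spans the 50% crossing; panels of
  near-flat curves yield censored estimates by design.
* The motif z-score's normal approximation is adequate for ranking but can
  be anticonservative in the extreme tail for small promoter sets; the
  shuffle count bounds the resolution of the null.
* Ward clustering is defined on Euclidean geometry; alternative linkages
  or distances are out of scope.
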