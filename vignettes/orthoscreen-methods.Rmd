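---
title: "Methods: concordance statistics and the substrate screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concordance statistics and the substrate screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoscreen)
```

# Scope and model

`orthoscreen` operates entirely on *differential-expression summaries*: per
feature, a log2 fold change between condition and control, a raw P and an
adjusted P, as produced upstream by DESeq2 (transcripts) or limma
(proteins). It does not touch reads, counts, or spectra. Two analyses are
supported.

**Cross-dataset concordance.** Two datasets measuring the same disease
process (e.g. a mouse model and patients) are aligned feature-by-feature —
through an ortholog map across species, or on shared ids within a study —
and their log2FC vectors are correlated (Pearson). Competing datasets are
compared against a common reference with Fisher's r-to-z test,

$$z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
          {\sqrt{1/(n_1-3) + 1/(n_2-3)}},$$

with a two-sided normal P. The test assumes independent samples; when both
correlations share the reference dataset this is violated, and the package
logs that caveat rather than pretending to fix it — reproducing the field's
standard procedure faithfully, flagged, was preferred over substituting a
dependent-correlations test the upstream literature does not use. No
multiplicity correction is applied across a comparison matrix (none is
standard here); a Bonferroni column is emitted for convenience.

**Substrate screen.** If extracellular proteases are hyperactive, substrate
proteins should sit *below* the protein level predicted from their
transcript. The screen regresses protein log2FC on mRNA log2FC by OLS
(protein is the predicted quantity, so the direction is fixed), forms
standardized residuals $e_i / \sqrt{\mathrm{RSS}/(n-2)}$, and filters in
four monotone stages:

1. $|$residual$| > 1$ in the **same direction** in the anchor dataset and
   in a comparison dataset;
2. intersection of stage-1 selections across all comparison datasets;
3. membership in a significantly enriched gene set, tested separately for
   up- and down-shifted candidates (a candidate cannot be rescued by a term
   enriched only in the other direction);
4. significant differential expression of the anchor transcript.

The funnel property $|S_1| \supseteq |S_2| \supseteq |S_3| \supseteq |S_4|$
holds by construction and is asserted in the tests.

## Choices the design left open

* **Same-direction rule at stage 1.** "Beyond ±1 in both datasets" is
  ambiguous for pairs discordant in opposite directions. Because stage 3
  analyzes up- and down-shifted sets separately, mixed-sign pairs have no
  coherent direction and are excluded.
* **Standardized vs studentized residuals.** The default divides by the
  global residual SD, matching a single ±1 threshold drawn on a regression
  plot; leverage-corrected (internally studentized) residuals are available
  via `studentized = TRUE`. At transcriptome scale the two are practically
  identical (leverage $\approx 1/n$).
* **Stage-4 thresholds** are configuration, not doctrine: defaults
  `mrna_padj_max = 0.05`, `mrna_lfc_min_abs = 1` (strict inequalities,
  mirroring the usual DEG definition), protein filter disabled. Everything
  is echoed into `config_echo` and the output headers for audit.
* **One-to-many orthology.** Ambiguous map entries are dropped entirely
  under the default `one_to_one_only` policy: duplicating one y-value
  across several x-values inflates the apparent n of every downstream
  correlation. Counts of dropped pairs are logged so users can audit the
  cost.
* **Enrichment background.** For the screen, the background is the set of
  all mRNA–protein pairs actually tested — the matched-universe default —
  rather than a genome-wide list; a genome-scale background would
  overstate enrichment of anything detected at the protein level.
* **NA fold changes.** Rows with missing or non-finite log2FC are dropped
  at load time with a logged count (upstream independent filtering produces
  such rows routinely); P-values are never imputed, and tables lacking
  adjusted P must be flagged `unadjusted`, with downstream consumers
  failing loudly instead of propagating `NA`.

# Over-representation statistics

Term enrichment uses the upper hypergeometric tail
$P(X \ge k)$ for overlap $k$, term size $K$, query size $n$, background
$N$ ("fisher"), or the conservative EASE variant that evaluates the same
tail at $k - 1$ ("ease", the default — it is what DAVID reports; $k \le 1$
gives $p = 1$). Bonferroni correction spans exactly the terms with $K \ge 1$
in the background. The properties `ease >= fisher` (for $k \ge 1$) and
monotonicity in $k$ are asserted exhaustively for all consistent tuples with
$N \le 40$ against an independent binomial-coefficient summation. GO DAG
structure and redundancy reduction (REVIGO-style) are deliberately out of
scope: the GMT is taken as flat truth.

# The simulator: a stated world

The generator emulates the statistical structure the pipeline assumes — at
the summary-statistic level, because that is what the pipeline consumes.

* Gene $g$ carries a latent disease-program effect $\theta_g$: zero with
  probability $1-\pi_{de}$, else $\mathcal N(0, \tau^2)$. Defaults
  $\pi_{de} = 0.3$, $\tau = 2$ (log2 units): a strong inflammatory skin
  phenotype where a third of the measured transcriptome moves, many genes
  several-fold.
* Dataset $d$ observes $x_{gd} = \theta_g + \mathcal N(0, \sigma_d^2)$ with
  $\sigma_d = 0.5$ by default; raw P comes from the two-sided normal test of
  $x/\sigma_d$ (the SE is known by construction) and adjusted P from
  Benjamini–Hochberg — emulating the provenance of a real `p_adj` column.
  The implied cross-dataset correlation is
  $\rho = \pi\tau^2 / (\pi\tau^2 + \sigma^2) \approx 0.83$, and the tests
  verify the empirical r against this closed form.
* Protein fold change is $y_g = 0.5\,x_g + \mathcal N(0, 1)$: a slope well
  below 1 and substantial noise, giving an mRNA–protein correlation near
  0.5, typical of proteogenomic comparisons. Substrates are additionally
  shifted by $-\delta \cdot \sigma_{noise}$ ($\delta = 3$ by default).
* **Substrate eligibility**: the `n_substrates` planted substrates (25 by
  default) are drawn from DE genes with $|\theta_g| > 2$
  (`substrate_min_effect`). This is a modeling statement, not a tuning
  knob: the screen's fourth filter admits only robust DEGs by design, so a
  "substrate" planted on a transcriptionally silent gene would not
  represent the phenomenon the screen targets (the motivating candidates
  are strongly induced secreted/membrane proteins).
* Gene sets: `n_terms` random sets with sizes uniform on
  `term_size_range`, plus one designated term covering all substrates with
  random fillers.
* Seeds: all draws derive deterministically from the single config seed via
  per-purpose sub-seeds (kept below $2^{31}$), so outputs are reproducible
  regardless of call order, and identical seeds yield byte-identical files.

**What a green test does and does not establish.** The simulator's
residuals are exactly Gaussian, independent across datasets, and
homoscedastic; its ortholog map is complete and unambiguous; its gene sets
are flat and non-overlapping with the planted term by chance only. Real
data violate all of these (heavy-tailed fold changes, shared measurement
batches, partial and many-to-many homology, nested GO terms). Green
acceptance therefore establishes *algorithmic correctness and calibration
under the stated model*, not field performance on any particular dataset.

# Numerical and formatting choices

* Pearson P: two-sided t with $n-2$ df; $|r| = 1$ reports $p = 0$ rather
  than NaN. Degenerate inputs (zero variance, $n < 4$) raise typed errors.
* `atanh` divergence at $|r| = 1$ and $n \le 3$ variance collapse are
  rejected before the r-to-z formula is evaluated.
* OLS is solved in closed form; the identities $\sum e_i = 0$ and
  $\sum (e_i/s)^2 = n-2$ are asserted to $10^{-9}$ relative.
* Output TSVs render doubles with `%.17g`, so write–read round trips are
  exact and reruns are byte-identical; rows are sorted by primary key; all
  files are UTF-8 with LF endings. Diagnostics go to stderr only.

# Known limitations

* The r-to-z comparisons against a shared reference are correlated; P
  values there are descriptive, not strictly calibrated.
* EASE/Fisher assume a well-chosen background; with DAVID's (unknown)
  implicit background, results on real data will differ from any published
  DAVID run.
* The screen's stage 2 requires candidate keys to survive one-to-one
  ortholog resolution; genes with ambiguous homology can never become
  candidates under the default policy.
* No GO hierarchy: a term and its ancestor count as independent tests.
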