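---
title: "Stage-wise testing for gene-level FDR control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise testing for gene-level FDR control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagewiseFDR)
```

## The problem

Modern transcriptome experiments rarely test a single hypothesis per gene.
A factorial differential gene expression (DGE) study tests a treatment
effect at each timepoint plus their interaction; differential transcript
expression (DTE) and differential transcript usage (DTU) analyses test one
hypothesis per isoform. When each hypothesis family is corrected
separately, the number of *genes* containing at least one false positive
grows with the number of hypotheses tested, even though each family's FDR
is controlled. Because follow-up work (validation experiments, gene set
analyses) is organised by gene, the natural error rate is the **overall
false discovery rate (OFDR)**: the expected fraction of discovered genes
that are either entirely null or contain at least one falsely rejected
hypothesis.

## The procedure

`stagewiseFDR` implements a two-stage procedure that controls the OFDR.

**Screening.** Each gene's *omnibus* null hypothesis — that none of its
$n_g$ individual nulls is false — is tested once per gene (a global F-test,
or an aggregated p-value for transcript-level analyses). The $G$ screening
p-values are corrected by Benjamini–Hochberg at the target level
$\alpha_I$; $R$ genes are retained (`screen_genes()`).

**Confirmation.** For each retained gene, the $n_g$ individual hypotheses
are tested while controlling the *within-gene* family-wise error rate at

$$\alpha_{II} = \frac{R\,\alpha_I}{G},$$

the BH-adjusted significance level carried over from the screening stage
(`confirmation_alpha()`, `confirm_genes()`).

Within a gene, the correction is Shaffer's modified sequentially rejective
Bonferroni (MSRB) procedure: the $j$-th smallest p-value is compared with
$\alpha_{II}/t(j)$, where $t(j)$ is the largest number of hypotheses that
can still be simultaneously true once the $j-1$ smaller ones are rejected.
With no logical constraints $t(j) = n_g - j + 1$ and the procedure is
Holm's method; constraints only ever shrink $t(j)$, so MSRB is uniformly at
least as powerful as Holm. `shaffer_t_sequence()` encodes the standard
contexts:

| context | design | $t$-sequence |
|---|---|---|
| `holm` | unconstrained | $n_g, n_g-1, \ldots, 1$ |
| `screened_free` | any screened family | $n_g-1$, then Holm |
| `dge_2x2` | 2×2 factorial (t1, t2, interaction) | $1, 1, 1$ |
| `dge_2x2_avg` | factorial + average-effect contrast | $1, 1, 1, 1$ |
| `dte` | per-transcript expression | $n-1$, then Holm |
| `dtu` | per-transcript usage | $n_g-2, n_g-2$, then Holm |

The reasoning: a gene that truly passes screening has at least one effect
(`screened_free`); in the 2×2 factorial at most one null can survive the
screening logic, so no within-gene correction is needed at all; a true
change in transcript *usage* must be compensated by at least one other
transcript, so DTU genes have at least two affected isoforms, and a
two-transcript DTU gene needs no confirmation test ($t = 0$, automatic
rejection). A $t(j)=0$ encodes such a vacuous threshold.

### Adjusted p-values

The procedure is defined by thresholds. For reporting we convert both
stages to adjusted p-values: within-gene adjusted p-values are the
step-down running maximum of $p_{(j)} t(j)$ (so "adjusted $p \le
\alpha_{II}$" is exactly the sequential rule), and the stage-wise adjusted
p-value on the $\alpha_I$ scale is $\min(1, \tilde p\, G/R)$ for screened
genes and 1 otherwise. A round-trip identity is enforced by tests:
thresholding the stage-wise adjusted p-values at $\alpha_I$ reproduces the
two-stage decisions exactly. Ties within a gene are broken
deterministically by hypothesis identifier; tied p-values receive equal
adjusted values through the running maximum.

### Gene-level aggregation for transcript analyses

For DTU/DTE screening, transcript-level p-values are aggregated to gene
q-values: with $\theta_g$ the smallest p-value among the $n_g$ transcripts
of gene $g$, rejecting all genes with $\theta_g \le \theta$ controls the
FDR at

$$q^*(\theta) = \frac{\sum_{g=1}^{G} 1 - (1-\theta)^{n_g}}{R(\theta)},$$

and `per_gene_qvalue()` reports, per gene, the minimum of $q^*$ over
observed thresholds $\theta \ge \theta_g$ (a running minimum from the
largest threshold down, the standard q-value convention that makes
rejection sets nested). Candidate thresholds are the observed $\theta_g$
only: between observed values $R(\theta)$ cannot change, so no other
threshold can improve $q^*$. With one transcript per gene the formula
collapses to plain BH (tested exactly). Screening then uses the rule
$q \le \alpha_I$ directly, with $R$ the number of genes so selected.

## Comparators

Two reference procedures are provided for benchmarking.
`conventional_analysis()` applies BH separately within each contrast — the
standard practice whose gene-level error the OFDR argument criticises.
`jiang_doerge()` implements the earlier two-stage proposal that splits the
level between stages (4/5 for screening, 1/5 for a single pooled BH family
of all confirmation p-values of screened genes; the split is configurable).
Because the screening level is a fraction of $\alpha$, its stage-1
discoveries are always a subset of `screen_genes()`'s at the full level —
a property the test suite checks. Stage 2 pools confirmation p-values
only, not the screening p-values.

## Simulators

The package simulates its own evaluation data; nothing is downloaded.

**Factorial DGE** (`simulate_dge_counts()`): 13,000 genes by default, in a
2×2 treatment×time design with 5 (or 3) replicates per cell. Categories:
2,000 genes with a constant fold change at both timepoints, 1,000 DE only
at timepoint 1, 1,000 only at timepoint 2, and 1,000 DE at both timepoints
with different fold changes (a true interaction); all fold changes are 3 or
1/3 with directions balanced exactly within each category (ties toward
up). Single-timepoint DE logically implies a non-null interaction and a
constant fold change implies a null one; the generated truth table
satisfies this closure by construction and tests verify it. Counts are
negative binomial with per-gene $(\mu_g, \phi_g)$ shared across timepoints
(this is how a gene's characteristics are linked over the time course) and
log-normal library-size factors (sdlog 0.25; the depth model is our
choice). The $(\mu, \phi)$ sampler is parametric — log-normal $\mu$
(median 50, sdlog 1.5) and a decreasing trend $\phi = 0.05 + 3/\mu$ with
log-normal noise (sdlog 0.4) — standing in for empirically estimated
pairs; `mean_dispersion_model(empirical = ...)` resamples a user-supplied
table instead when fidelity to a particular dataset matters.

`simulate_dge_pvalues()` is a p-value-level companion with the same truth
structure: null p-values are exactly U(0,1), alternatives Beta(0.1, 1),
and the screening p-value is drawn independently (uniform for fully-null
genes). It isolates the testing procedure from any miscalibration of a
count-level engine, which is exactly what is needed to verify OFDR
control.

**Transcript-level** (`simulate_structure()`, `assign_dtu_truth()`,
`assign_dte_truth()`, `simulate_transcript_counts()`): transcripts per
gene follow a shifted negative-binomial law (mean ≈ 2.8), expected gene
counts are log-normal, and baseline usage proportions come from a
symmetric Dirichlet (shape 0.7, favouring dominant isoforms). Per-sample
usage is Dirichlet around the baseline with concentration 100 (a
biological-variability dial; larger is tighter). DTU genes (1,000 by
default) are drawn from genes with expected count above 5 and at least two
expressed isoforms (baseline proportion > 0.01 — our operationalisation of
"expressed"); $k = \max(2, \mathrm{Binomial}(n_{tx}, 1/3))$ transcripts
are flipped, i.e. their condition-2 proportions are a uniformly random
non-identity permutation (a swap when $k = 2$) of the condition-1 values,
which conserves the gene's expected total. DTE genes (1,000, disjoint from
the DTU set) scale *all* their transcripts by a fold change whose
magnitude follows an exponential law (rate 1) truncated to [1, 3] —
parameters are configuration, not a fidelity claim — with directions
balanced across genes. Counts are NB with $\phi(\mu) = 0.05 + 5/\mu$.
Read simulation and quantification are deliberately absent: counts are
drawn directly with the same statistical structure, so quantification
uncertainty (a known driver of transcript-level FDR inflation) is not
modelled, and results on real quantified data can be expected to be
somewhat worse than on these simulations.

## The built-in test engine

`feature_tests()` fits ordinary least squares to $\log_2(\mathrm{CPM} +
0.5)$ of median-of-ratios-normalised counts, with per-contrast t-tests and
an omnibus F-test over the span of the named contrast set (logically
dependent contrast sets, e.g. t2 = t1 + interaction, are reduced to a
full-rank basis first — the global F-test is a test of the span). It
exists so the pipeline runs end-to-end without heavy dependencies; it does
no variance moderation and no NB dispersion estimation, and its p-values
on NB counts are correspondingly less calibrated than a moderated
analysis. Any fitting tool can be substituted by supplying its long-format
p-value table directly to the testing functions — the engine is
replaceable plumbing, not part of the method.

## Numerical and degenerate-case choices

* $R = 0$: the confirmation stage is vacuous ($\alpha_{II} = 0$); a message
  is emitted rather than an error.
* Missing (NA) p-values within a gene are dropped from the family with a
  warning and do not inflate $n_g$ — filtered hypotheses should not add
  correction burden.
* $G$ in $\alpha_{II} = R\alpha_I/G$ counts the genes actually screened,
  i.e. after any expression filtering.
* In `fdp_tpr_curve()`, a truth with no alternatives yields TPR 0 with an
  explicit `degenerate_tpr` flag rather than NaN, so replicate aggregation
  stays total.
* `rtruncexp()` uses inverse-CDF sampling; degenerate bounds return the
  common value exactly.

## What the tests do and do not show

The suite verifies, among other things: exact equivalence of the MSRB
adjustment with Holm's method under the unconstrained t-sequence; exact
reduction of the q-value aggregation to BH for single-transcript genes;
the round-trip identity between adjusted p-values and two-stage decisions;
the subset relation between Jiang–Doerge and full-level screening; the
simulators' truth structure (5,000 genes with a false screening null and
3,000 with a false interaction null at the default configuration; exactly
1,000 DTU and 1,000 DTE genes); and OFDR control — the mean gene-level FDP
of the procedure over 30 replicate p-value-level simulations of 13,000
genes stays within three Monte-Carlo standard errors of the nominal level
at 1%, 5% and 10%. Problem sizes in the routine suite (e.g. 400-gene OFDR
replicates in the unit tests, 2,000-gene count simulations for the method
comparisons, the full 13,000-gene structure where exact counts are the
point) were chosen to make the checks sharp while keeping the default run
fast.

Because the simulations use independent hypotheses, clean NB counts and
known truth, passing tests demonstrate correctness of the procedures and
calibration under the stated models — not performance on real data with
correlated genes, quantification uncertainty or unmodelled batch
structure.

One benchmarked claim is deliberately reported as not reproduced at desk
scale: with the plain OLS engine on the scaled-down factorial simulation,
the interaction-contrast FDP–TPR curve of the stage-wise method is
statistically indistinguishable from the conventional per-contrast
analysis at matched empirical FDP (the corresponding check in the
acceptance suite fails honestly). The screening F-statistic contains the
interaction contrast and, for OLS, shares the per-gene variance estimate
with it, so fully-null genes with accidentally small interaction p-values
pass screening at nearly the same rate as they enter the conventional
ranking; the screening stage then cannot improve the ranking at matched
FDP. The decomposition claim does hold: among gene-level false positives,
the fraction of fully-null genes is consistently lower for the stage-wise
method than for the conventional analysis, and the stage-wise method's
power advantage at its own nominal working points (larger rejection
threshold $\alpha_{II}$ versus a per-contrast BH threshold) is visible in
its higher discovery counts at equal nominal level.

## Known limitations

* Within-gene confirmation controls FWER; a within-gene FDR variant is out
  of scope.
* The t-sequence contexts cover the shipped designs; other logical
  structures require the user to derive $t(j)$ and call `msrb_adjust()`
  directly.
* OFDR control relies on the BH assumptions at the screening stage
  (independence or positive regression dependency across genes).
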