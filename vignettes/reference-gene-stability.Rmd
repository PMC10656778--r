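---
title: "Reference-gene stability: models, conventions and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, conventions and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

`refstab` evaluates candidate qRT-PCR reference genes along the standard
workflow: transcriptome-wide screening of RNA-seq FPKM values, standard-curve
validation of primer pairs, four independent expression-stability statistics
on Ct matrices, a geometric-mean consensus ranking, and 2^-ΔΔCt
quantification of target genes. This vignette explains each model, the
conventions the package fixes where the field leaves room, and what the
bundled simulator does and does not emulate.

## Ct as the working scale

The quantification cycle Ct is (approximately) linear in the log2 of
template abundance: one cycle ≈ one doubling. All dispersion statistics
below therefore operate directly on Ct, which is already a log scale.
Technical replicates are collapsed by the arithmetic mean of Ct — the
standard practice — rather than by averaging linear-scale quantities;
`collapse_technical_replicates()` offers no linear-scale variant, and
missing Ct cells are a hard error rather than being imputed, because every
downstream statistic assumes a complete matrix and there is no principled
imputation rule for qPCR dropouts.

## Candidate screening

For each gene across RNA-seq libraries: MV (mean FPKM), SD (sample standard
deviation, n − 1 denominator — libraries are a sample, not a population),
CV = SD/MV, and MFC = max/min FPKM. Defaults MV > 30, top 500 by ascending
SD, CV < 0.5, MFC < 6.3, all strict comparisons. Conventions fixed here:

* **CV is SD/MV.** Screening literature sometimes abbreviates this
  ambiguously; a per-gene scalar can only be the ratio of the gene's SD to
  its mean.
* **MV filter first, then the SD top-N.** The top-N rank is computed within
  the MV-passing subset, so weakly expressed genes cannot consume top-N
  slots. The reported `sd_rank` column, by contrast, ranks all genes so that
  ranks are unique within a report.
* **Zero FPKM voids the MFC.** max/min is undefined with a zero minimum;
  such genes never pass (a gene invisible in one library is a poor
  reference regardless).
* The final manual step practised in screening studies — curating the
  surviving list down to genes with known housekeeping annotations — is
  deliberately not automated; the package emits the post-threshold list.

## Standard curves

`fit_standard_curve()` regresses Ct on log10 relative template amount
(most concentrated point at 0; only the slope matters, so the axis
convention is internal). R² is the squared Pearson correlation of the
points. Efficiency is

$$E\% = \left(10^{1/|\text{slope}|} - 1\right) \times 100,$$

the relation implied by any published slope/efficiency table (a perfect
doubling has slope 1/log10 2 = 3.3219 and E = 100%). The bundled
`primer_curves()` compendium of 35 primer pairs reproduces this relation to
0.01 percentage points on every row, which is itself a shipped test. Note
an asymmetry the tests respect: the slope is the primary measurement and
the printed efficiency is rounded from it, so inverting a rounded
efficiency recovers the slope only to the rounding granularity
(≈ 5 × 10⁻⁴), not to full precision.

## The four stability statistics

All four return a `stability_table` with ascending ranks (lower statistic =
more stable); ties are broken by gene id, lexicographically, so reports are
deterministic.

**Comparative ΔCt.** For each ordered pair (i, k),
`sd(Ct_i − Ct_k)` across samples (n − 1 denominator); gene i's statistic is
the mean over partners k. Pairwise differences cancel any per-sample
additive offset, so the method is loading-invariant by construction.

**BestKeeper.** Descriptive dispersion of raw Ct. The default `plain_sd`
variant reports the sample SD and CV% = 100·SD/mean-Ct; the `mad_geomean`
variant reports the mean absolute deviation from the gene's geometric-mean
Ct and CV% against that geometric mean. Both are offered because published
"CV ± SD" tables are consistent with either when raw data are unavailable;
`plain_sd` is the default as the more common reading. BestKeeper is *not*
loading-invariant — deliberately so, as it mirrors the original tool's
behaviour on raw Ct; the test suite asserts this asymmetry rather than
hiding it.

**geNorm.** Ct is transformed to relative quantities
Q = E^(minCt − Ct) per gene, with E = 2 unless per-gene efficiencies are
supplied (published workflows are usually silent on which was used; perfect
doubling is the conventional default and the choice is exposed as an
argument). M_j is the mean over partners k of `sd(log2(Q_j/Q_k))`. The gene
with the largest M is removed and M recomputed until two genes remain; the
final pair is genuinely unordered by the method and is reported tied at
rank 1.5 each. When several genes tie at the maximal M, the
lexicographically last is removed first, so surviving order again favours
the global tie-break rule. V(n/n+1) is `sd(log2(NF_n/NF_(n+1)))` with NF_n
the per-sample geometric mean of the top-n genes' quantities; the customary
0.15 guidance threshold is reported (`recommended_n`) but never enforced —
it is advisory output only.

**NormFinder.** The model-based decomposition, implemented from the
published equations. Within group g (I genes, n_g samples), residuals after
double centring,

$$r_{igj} = y_{igj} - \bar y_{ig\cdot} - \bar y_{\cdot gj} + \bar y_{\cdot g\cdot},$$

give $z_{ig} = \sum_j r_{igj}^2/(n_g-1)$ and the bias-corrected intra-group
variance

$$\hat\sigma^2_{ig} = \Big(z_{ig} - \tfrac{\sum_k z_{kg}}{I(I-1)}\Big)\tfrac{I}{I-2},$$

truncated below at 0 (the estimator can go negative at small n; a negative
variance has no interpretation and would poison the square root). With
G ≥ 2 groups, the inter-group deviation d_ig (group gene mean minus gene
grand mean, centred to sum to zero across genes within each group) is
shrunk towards zero by its sampling variance
$\hat\sigma^2_{ig}/n_g$ against the empirical between-group variance
γ² = max(0, Σd²/((I−1)(G−1)) − mean(σ̂²/n)), and the stability value is the
group average of |d̃_ig| + (σ̂²_ig/n_g)^{1/2}. With a single group the
stability value is the intra-group SD alone. Because I − 2 appears in the
denominator, at least 3 genes are required; a group with a single sample is
rejected with a pointer to single-group mode rather than silently dropped.
The implementation is validated against a frozen fixture computed by an
independent explicit-loop implementation of the same equations (a synthetic
oracle; agreement to 1e−6 is a shipped test). The sample partition fed to
the method is a genuine analysis choice — treatment identity versus
treated/control — so `group_by` exposes both without privileging either.

## Consensus ranking

`aggregate_ranks()` takes 2–4 stability tables over an identical gene set
and scores each gene by the geometric mean of its ranks, final order
ascending with lexicographic tie-break. Tied input ranks enter as
fractional (average) ranks — e.g. the geNorm final pair enters as 1.5 —
which preserves the rank sum under tie splitting. The original web-based
comprehensive tools do not publish their exact tie conventions, so this
module aggregates whatever tables it is given and records the method labels
in the output rather than claiming bit-compatibility with any service.
Two consequences are guaranteed and tested: the geometric mean lies between
the extreme input ranks (strictly, unless all agree), and a gene that beats
another in every method finishes ahead of it.

## 2^-ΔΔCt normalization

Per biological sample, ΔCt = Ct_target − Ct_reference; ΔΔCt subtracts the
mean ΔCt of the control group's replicates (the published formula treats
"control" as a single quantity; averaging its replicates is the standard
reading, and it makes the control group's fold change exactly 1). With
several references the per-reference ΔΔCt values are averaged *on the Ct
scale* — the printed two-reference formula is the n = 2 case — which makes
the combined fold change the geometric mean of the per-reference fold
changes. Group-level values are the mean over biological replicates of the
per-sample ΔΔCt, again averaged before exponentiation (the output carries
the replicate SD alongside); averaging fold changes after exponentiation is
the other common convention, and the package states its choice rather than
mixing the two. Efficiency-corrected (Pfaffl-type) quantification is out of
scope: the workflow validated here uses 2^-ΔΔCt throughout.

## The simulator

`simulate_ct()` draws

$$Ct_{igj} = \mu_i + \beta_{ig} + \varphi_{gj} + \varepsilon_{igj},$$

with β ~ N(0, τ_i²) per (gene, group) — the instability to be detected —
φ ~ N(0, λ²) per sample, shared across genes (template-loading offsets),
and ε ~ N(0, σ_ε²) replicate noise. Defaults: λ = 1 cycle, σ_ε = 0.2 cycles
(typical qPCR technical noise); the pipeline's default design is 14
unordered condition groups × 3 biological replicates with 29 candidate
genes, the canonical design of multi-stress reference-gene studies. Group
effects are drawn independently per group rather than as smooth trends
because stress treatments are unordered conditions. The sharing of φ across
genes is the mechanism that makes ratio-based methods (ΔCt, geNorm) robust
where raw-Ct methods (BestKeeper) are not; this asymmetry is deliberate and
tested end-to-end.

`simulate_fpkm()` plants stable genes (log-normal, mean 40–150 FPKM,
log-SD 0.1, hence CV ≈ 0.1 and MFC well under 2 at realistic sample sizes)
among unstable genes that fail the screen on either side: low expression
(mean 1–20, failing MV > 30) or high dispersion (log-SD 1.5, CV ≈ 2.9,
failing CV and MFC). The margins are wide enough that planted and
non-planted genes cannot realistically straddle the thresholds, so
recovery tests can assert exact set equality. `simulate_dilution()` inverts
the efficiency relation exactly at zero noise; its default design is 5
ten-fold dilutions in duplicate.

What the simulator does **not** emulate: amplification curves and
fluorescence chemistry, inhibitor-driven efficiency variation between
samples, correlated co-regulation between candidate genes, heteroscedastic
noise at high Ct, or qPCR dropouts. Passing the recovery tests therefore
shows that the statistics detect additive group-level instability under
shared loading offsets and Gaussian noise — the core failure mode reference
genes are screened for — not that they are robust to every artefact of real
plates.

## Numerical conventions and test design

* Sample SDs use the n − 1 denominator everywhere.
* All stability ranks break ties lexicographically by gene id.
* NormFinder variances are truncated at 0 before square roots; shrinkage
  factors fall back to 0 when both γ² and the sampling variance vanish.
* Loading-invariance tests assert *bit identity*, not approximate equality:
  fixtures place Ct values and offsets on a dyadic grid (multiples of 2⁻⁶)
  with a power-of-two sample count, so offset addition and mean-centring
  are exact in IEEE double arithmetic and the invariance is exact rather
  than approximate.
* Deterministic problem sizes used by the shipped tests: the 3-gene × 3-sample
  worked fixture for brute-force oracle equivalence; an 8-gene ×
  (4 groups × 6 samples) NormFinder oracle fixture; 20 seeded runs of a
  10-gene, 5-group × 3-replicate planted-gene design; a 500-gene ×
  42-sample screening recovery at seed 1; and 1000 random rank tables for
  the consensus properties.
* `run_pipeline()` is byte-deterministic at a fixed seed: CSV outputs are
  written atomically (a stage that fails leaves only `.partial` files), and
  only the manifest carries timestamps.

## Known limitations

* BestKeeper's published tool also reports correlations against a
  BestKeeper index and significance tests; only the SD/CV% stability core
  is implemented here, in the two variants above.
* geNorm ranks below the final pair reflect the exclusion path, not a full
  re-ranking at every step; this matches the original algorithm but means
  mid-table ranks can differ from a single-pass M ranking
  (`genorm_m()` exposes the single-pass values).
* NormFinder's inter/intra decomposition assumes roughly balanced groups of
  at least two samples; wildly unbalanced designs are better analysed in
  single-group mode.
* The consensus is the unweighted geometric mean; no weighting scheme is
  offered.
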