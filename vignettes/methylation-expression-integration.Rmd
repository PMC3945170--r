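---
title: "Linking differential CpG methylation to gene expression: models and design choices"
author: "methyLink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking differential CpG methylation to gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyLink)
```

# The analysis model

methyLink implements an integrated two-platform analysis for
case–control array studies: genome-scale CpG methylation measured as
β-values (β = M/(M + U + α), the methylated fraction of signal at one
CpG) and transcript expression measured as bead intensities, on the
same samples. The pipeline's end point is a per-gene prioritization:
genes whose expression difference between phenotypes is accompanied by
differential methylation that is *strong and heterogeneously
distributed across genomic contexts* — the pattern most suggestive of
methylation-driven regulation — rise to the top.

## Probe annotation

Every CpG probe carries two context labels, both on 1-based inclusive
coordinates (the array-manifest MAPINFO convention):

* **Gene context** relative to each linked transcript: `TSS200`
  (within 200 bp upstream of the TSS), `TSS1500` (201–1500 bp
  upstream), `FirstExon`, `UTR5`, `UTR3`, `Body`. Upstream distance is
  measured against the transcript's strand. When a position sits in
  several classes at once the package applies the fixed precedence
  TSS200 > TSS1500 > FirstExon > UTR5 > UTR3 > Body; the class system
  itself does not define a tie-break, so an explicit, documented order
  is preferable to manifest-dependent behavior. A probe may link to
  several transcripts; all links are kept and treated independently
  downstream, since collapsing them would require an arbitrary choice
  of "primary" transcript.
* **Island context** relative to the CpG-island (CGI) set: `Island`
  inside a CGI (boundaries inclusive), `Shore` when the distance to
  the nearest CGI boundary is 1–4000 bp, `OpenSea` beyond. The 4-kb
  band merges the manufacturer's north/south shores *and* shelves into
  one flank category; the boundary case (exactly 4000 bp) counts as
  shore, reading "within 4 kb" inclusively. Around an isolated CGI the
  shore therefore spans exactly 8000 positions, a property the test
  suite checks directly.

## Preprocessing

Expression intensities are variance-stabilized per sample —
`log2(x + offset)` with offset 1 by default, or `asinh(x)` — and then
quantile-normalized across samples (every column is forced onto the
mean of the sorted columns, ties averaged). Cross-sample quantile
normalization stands behind the named normalization step so that
alternatives can be plugged in; a spline-based between-chip
normalization would need knot and robustness parameters that have no
canonical defaults, whereas quantile normalization is parameter-free
and idempotent (to 1e-12, which the suite asserts).

Methylation probes on chrX/chrY and probes not interrogating a CpG
dinucleotide are excluded up front. Presence filtering uses the
detection p-value: a probe is *present* in a sample when detection
p < 0.01 (we read the detectability rule as a p-value threshold — the
alternative reading as a ratio statistic has no defined reference
distribution — and expose the threshold as `det_p`); a probe is
retained only when present in at least ⌈5/6 · group size⌉ samples in
*each* phenotype. Requiring the quorum per phenotype rather than
overall prevents a probe that dropped out of one whole group from
producing a one-sided group mean. Non-present cells stay in the matrix
but are masked out of every group mean and correlation.

## Differential calls

**Expression.** Per probe, a two-group linear fit gives the
case-minus-control effect, the pooled residual variance s² and its
df d = n₁ + n₂ − 2. Variances are shrunk toward a common prior by
empirical Bayes: under the scaled-inverse-χ² hierarchical model, the
marginal moments of log s² identify the prior df d₀ and prior variance
s₀² in closed form (digamma/trigamma inversion); the posterior
variance is s̃² = (d₀s₀² + d·s²)/(d₀ + d) and the moderated
t = effect / (s̃·√(1/n₁ + 1/n₂)) is referred to t on d₀ + d df. Two
limits are exposed for verification: d₀ = 0 recovers the ordinary
pooled t, d₀ = ∞ a z-statistic with the common variance. When the
observed variances are more concordant than any finite d₀ allows (the
trigamma moment equation has no positive solution) the estimator falls
back to d₀ = ∞ with a warning. P-values are BH-adjusted; probes map to
transcripts and only the probe with the smallest adjusted p represents
each transcript (ties broken by raw p, then probe id); transcripts at
p_adj < 0.05 are called differentially expressed.

**Methylation.** A CpG is differentially methylated when the absolute
difference of its phenotype-mean β-values (present samples only)
exceeds Δβ = 0.15 *strictly*. The comparison uses a 1e-12 guard so
that a difference that is exactly the threshold up to floating-point
dust is not emitted. No p-value is attached: with 6 + 6 samples and
array-scale β noise, the fixed effect-size rule is the intended
deliberately simple caller, and its false-call rate under the null is
checked by simulation instead.

## Integration and the proportion tests

Differentially methylated CpGs are matched to differentially expressed
transcripts through the manifest links; each (CpG, transcript) link is
one analysis unit. The Spearman ρ between the CpG's β-values and the
transcript's expression across all samples (average ranks for ties,
non-present samples dropped pairwise) classifies the pair: positive
(hypermethylation with overexpression, or hypomethylation with
underexpression), negative (the converse), or excluded when ρ is 0 or
undefined (constant series, fewer than 3 complete pairs). Excluded
pairs leave the cross-tables entirely.

Per context stratum, the package tests whether the stratum's fraction
of negatively correlated pairs equals the overall fraction p₀, with
the plain one-sample two-tailed z (no continuity correction):
z = (p̂ − p₀)/√(p₀(1 − p₀)/n), p = 2Φ(−|z|). A Wald variant (p̂ in the
standard error) and the exact binomial test are available behind
`method=`; no single standard formulation reproduces every published
p-value in this family of tables, so the package standardizes on the
score form and treats the neg/pos *ratios*, not the p-values, as the
reproducible arithmetic.

## The status × location interaction

The prioritization statistic treats each (CpG, sample) β-value of a
gene's matched differentially methylated CpGs as one observation, with
two crossed factors: the CpG's **status** (hypo-/hypermethylated, the
sign of its Δβ) and its **location** (gene context, and in a second
pass island context). The full model
`β ~ status + location + status:location` is compared with the
additive model by extra sum of squares; Δdf is the *rank* difference
of the two design matrices, so unbalanced and empty-cell designs get
the correct df or are declared untestable, rather than silently
producing a named-type ANOVA that depends on factor order. F is
referred to F(Δdf, n − rank_full). A saturated zero-residual fit with
interaction signal reports F = ∞, p = 0.

Design decisions worth spelling out:

* **Observation unit.** Replication comes from both CpGs and samples.
  The alternative — summarizing each CpG to one mean — discards the
  sample dimension and leaves many genes with too few observations to
  test. The cost is that observations within a CpG and within a sample
  are not independent: the group-structured part of β inflates the
  residual and makes the pipeline-level test conservative. The
  engine's own calibration is therefore verified under an iid null
  (randomized labels, iid noise), where the F p-values are uniform;
  on pipeline-level no-interaction plantings the suite checks the
  conservative direction (at most a trickle of BH-significant genes).
* **Only differentially methylated CpGs enter.** Status is undefined
  for the others; including them would force an arbitrary third
  status level.
* **Estimability.** A gene whose every location carries a single
  status has cell means explained by location alone — the interaction
  is rank-inestimable, and the gene is reported untestable
  (`interaction_inestimable`) rather than given a meaningless p. The
  same applies to equal hyper-vs-hypo gaps in every location, which
  carry no interaction signal even when estimable. Real interaction
  genes mix statuses within at least two locations with unequal gaps.
* **Two BH families.** The two location taxonomies are adjusted
  separately over their testable genes and combined by "either
  adjusted p < 0.05". A pooled family would mix tests with very
  different testability patterns; the per-taxonomy choice is exposed
  in the result columns so users can recombine at will. The reported
  `p_min` is the smaller raw p, the quantity displayed when annotating
  single genes.

## Over-representation

The enrichment step is a generic hypergeometric ORA against a
user-supplied gene → category map (no ontology or commercial database
is bundled): expected = nK/N, ratio = actual/expected,
z = (actual − expected)/√(n·(K/N)(1 − K/N)·(N − n)/(N − 1)), exact
upper-tail p by summation, plus a directional p (lower tail when z is
negative) matching the usual ORA-table convention. The published
worked example this reproduces uses the mapped-query size (n = 426)
rather than the nominal list size in the expectation — the printed
expected counts back-compute to the mapped size, and the package
reports n and N explicitly so either convention is auditable.
`intersectRank()` ranks the category terms shared by two query lists
by the worse of their two enrichment p-values.

# The synthetic-data generator

`simulateDataset()` builds the whole study from a seed: a manifest of
~2,200 probes over 200 one-transcript genes (10 linked CpGs each, plus
~10% unlinked intergenic probes and small chrX/Y and non-CpG
contingents for the exclusion rules), each gene with a promoter CGI so
both context labels derive from genuine coordinates; β-values from
beta distributions with precision 50 (variance m(1 − m)/51) around
per-CpG baselines at the two array modes (0.10 unmethylated, 0.85
methylated — island CpGs unmethylated, other CpGs methylated with
probability 0.75, giving the characteristic bimodal pooled density);
detection p-values with a 1% dropout rate; expression as 2^latent with
per-gene baselines N(8, 1.2) and residual sd 0.5 on the log2 scale;
6 + 6 samples.

Planted effects are declared per gene: context-wise β shifts with a
transcript log-fold-change whose sign enforces the requested Spearman
direction, and interaction genes via `plantInteractionGene()`, which
populates promoter (TSS1500) and body with CpGs of *both* statuses and
unequal gaps — the estimable form of the "promoter and body disagree"
pattern discussed above. Planted CpGs start from direction-appropriate
baselines (0.3 when gaining, 0.7 when losing methylation); an effect
that would push a group mean outside (0.02, 0.98) errors before any
sampling. A truth table records every planted direction, fold change
and interaction flag. All randomness flows from one master seed
through fixed per-stage substreams, so outputs are bit-identical given
the seed.

What the generator deliberately does **not** emulate: batch/chip
effects, Infinium I/II probe-type differences, cross-hybridizing or
SNP-affected probes, cell-type mixtures, and correlated probe noise
along the genome. Passing tests therefore demonstrate the pipeline's
statistical behavior under clean array-like data, not robustness to
those artifacts — on real arrays the usual upstream QC still applies.

# Numerical choices and test problem sizes

* Quantile-normalization idempotence is asserted to 1e-12; the
  balanced-design interaction F is checked against the classical
  cell-means closed form to 1e-10; BH, Spearman-with-ties,
  hypergeometric tails and average-linkage heights are checked against
  brute-force definitional oracles (step-up scan, counting ranks, pmf
  summation with binomial coefficients, naive agglomeration).
* Null calibration runs 200 simulated null datasets of 2,000 linked
  probes / 200 genes at 6 + 6: the raw moderated-t p < 0.05 fraction
  must sit in 0.05 ± 0.01, the Δβ > 0.15 false-call rate below 0.1%,
  and the interaction engine's null p-values pass a KS uniformity
  check. Recovery runs plant 20 interaction genes (gaps 0.25 vs 0.6)
  and 20 single-context correlation genes (|Δβ| = 0.35, |log2FC| = 2)
  among 200: at least 16/20 interaction genes at adjusted p < 0.05 and
  at least 95% of pairs with the planted correlation sign. These sizes
  are the package's standing reference conditions; they run in well
  under a minute each on a laptop-class core.
* The pipeline writes every stage artifact as CSV/TSV/JSON and a run
  log with input/output counts per stage; rerunning a config/seed
  reproduces every artifact byte-for-byte except the run log, whose
  wall-time column is the single sanctioned use of the clock.

# Known limitations

* The Δβ caller carries no uncertainty; near-threshold CpGs flip
  in/out between replications of a real experiment.
* The interaction test's per-(CpG, sample) pooling ignores within-CpG
  and within-sample correlation; its pipeline-level p-values are
  conservative, and the BH threshold should be read as a ranking
  device more than a strict error rate.
* Matching relies entirely on manifest links; CpGs regulating a gene
  from outside the annotated windows (distal enhancers) are invisible.
* The proportion tests treat each (CpG, transcript) link as
  independent, which overstates n when one CpG links to several
  transcripts of the same locus.
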