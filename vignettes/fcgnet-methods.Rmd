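---
title: "Methods: factorial expression analysis and co-expression networks for Four Core Genotypes studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial expression analysis and co-expression networks for Four Core Genotypes studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgnet)
```

fcgnet analyses 2×2×2 factorial gene-expression studies in the Four Core
Genotypes (FCG) mouse model, where sex chromosome complement (XX vs XY⁻),
developmental gonadal sex (ovaries vs testes), and adult testosterone
(blank vs testosterone capsule) vary independently. This vignette is the
package's account of the statistical machinery, the choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## qPCR quantification

Quadruplicate CT wells are collapsed by the **arithmetic mean of CT**, and
relative expression is

$$\mathrm{signal} = 2^{-(CT_g - \overline{CT}_{\mathrm{ref}})} \times 10{,}000,$$

with $\overline{CT}_{\mathrm{ref}}$ the mean CT of the two reference genes
(β-actin and Gapdh). Because $2^{-(a - (b+c)/2)} = \sqrt{2^{-(a-b)}\,2^{-(a-c)}}$,
this mean-CT form is algebraically the geometric mean of the two
per-control relative intensities; the test suite asserts the identity to
1e-9 relative error on random tables. Whether replicate wells should be
averaged on the CT scale or the intensity scale is not determined by the
procedure we mirror; we average CT, which is the geometric mean in
intensity space and therefore consistent with the geometric-mean
convention throughout. Reference-gene stability is not re-estimated, but
`check_reference_stability()` warns when a reference gene's group-mean CT
range exceeds 0.5 cycles (≈1.4-fold on the intensity scale).

Degenerate inputs are surfaced, not hidden: sample×gene cells with no
wells become flagged-missing rows, and samples missing either reference
gene are excluded with a logged message.

## Per-gene three-way ANOVA

Each gene is fitted with the full factorial linear model
`expression ~ chr * gon * act` under **sum-to-zero (effect) coding**, and
terms are tested with **Type-III** F statistics (via `car::Anova`). In a
2×2×2 design every term has numerator df = 1. The choice of sums-of-squares
type only matters under imbalance; real FCG group sizes are rarely equal,
and Type-III with effect coding reduces exactly to the classical balanced
factorial decomposition when cells are equal — the suite checks both that
identity (sequential ≡ Type-III on balanced data, 1e-9) and agreement with
a textbook sums-of-squares oracle. Factors with a single observed level are
dropped with a message, so the same surface covers reduced designs; the
two-group reduction satisfies F = t² against the pooled t-test.

Tukey follow-ups use the **Tukey–Kramer** studentized-range test among the
four gonadal×hormone cells (or all eight cells), with the mean-square error
and residual df taken from the *full* three-way model rather than a
refitted one-way model. Contrasts are gated on the omnibus model: they are
only computed when some term is significant at α = 0.05, mirroring the
follow-up logic of the analysis we reimplement. With k = 2 cells the
studentized-range p equals the pooled t-test p (q = t√2), which the suite
asserts at 1e-6.

Multiple testing is controlled by **Benjamini–Hochberg** at 5% FDR within
gene categories, with a *declared* family size `m` that may exceed the
number of p-values supplied — the convention of counting all genes in a
category as tests even if some are reported elsewhere. `bh_adjust()`
implements the step-up rule through `stats::p.adjust(method = "BH", n = m)`
and is verified against a literal brute-force step-up on random vectors.
Whether the three main-effect p-values of one gene belong to one family or
three is ambiguous in the source convention; the package defaults to
per-term families within category (`bh_family = "per_term"`) and exposes
`"pooled"` as the alternative. Zero-variance genes are reported as
degenerate rows, never dropped silently. A trend flag marks p < 0.1.

## Behavioral emotionality Z-scores

For each measure, $z = d\,(X - \mu)/\sigma$ where $\mu,\sigma$ come from
the **comparison group only** (default XX + blank, configurable) and the
direction $d = \pm 1$ orients every measure so that larger z means more
anxiety-like emotionality (e.g. time in open arms carries $d = -1$).
$\sigma$ is the sample SD (n−1 denominator); the population/sample choice
is not documented in the source convention and the n−1 form is the
standard estimator. Scores are then averaged in **two enforced levels** —
measures within a behavior test, then test scores within animal — rather
than pooling all measures, so a test with four measures does not outweigh
one with two. Consequences verified in the suite: comparison-group means
are 0 to 1e-12 per measure, overall scores are invariant to affine
rescaling of any raw measure, and the composite of an unbalanced fixture
equals the hand computation.

## Stratified gene–behavior correlation

Each gene is correlated (Pearson; two-sided p from the t transform on
n−2 df) with the overall emotionality score in all mice and within the six
single-factor strata (XX, XY⁻, gonadal female/male, blank, testosterone).
Two-sidedness is the conservative default since the source convention
reports signed correlations without stating sidedness. BH is applied per
gene category *within each stratum* (declared sizes default to the genes
present, e.g. 16 GABA-related and 14 serotonin/dopamine-related), and a
+/− sign class is assigned only to BH-significant entries; `sign_summary()`
collapses the table to the per-stratum gene listings with "None"
fallbacks. Strata with n < 3 or zero variance are flagged missing.
Aggregation across strata can disagree with every stratum
(Simpson-style reversals); the package makes no claim that the pooled r is
bounded by stratum r's and the suite includes an adversarial fixture.

## Dimorphism ratio matrix

For each gene and factor the ratio of **unweighted marginal cell means**,
male phenotype over female phenotype (XY⁻/XX, testes/ovaries,
testosterone/blank). Unweighted cell means equal pooled sample means under
balance but are robust to unequal group sizes, which is why they are the
default here (the original rendering choice is not recoverable).
Annotations copied from the ANOVA table mark a significant main effect of
the factor (`*`) and a significant interaction involving it (`+`).
Nonpositive female-phenotype means make a cell undefined, flagged rather
than coerced. `autoplot()` renders the blue–white–red log2 tile map.

## Co-expression networks

Within each group, all gene pairs get a signed Pearson correlation
$r_{ij}$ and an edge weight $w_{ij} = |r_{ij}|^3$. Cubing boosts strong
correlations and shrinks the small ones that sampling noise produces; the
sign is retained only for edge annotation (every statistic uses $|r|^3$).

Global properties, all implemented in the package and cross-checked
against independent oracles:

- **Density** $= \operatorname{mean}_i(k_i)/(n-1)$ with weighted degree
  $k_i = \sum_j w_{ij}$; equals 1 for a complete unit-weight graph.
- **Clustering**: per node,
  $\sum_{j \ne i}\sum_{k \ne i,j} w_{ij} w_{jk} w_{ki} \big/
  \big[(\sum_{j \ne i} w_{ij})^2 - \sum_{j \ne i} w_{ij}^2\big]$; the
  ordered double sum counts each triangle twice, matching the symmetric
  denominator. The global value averages nodes with a nonzero denominator;
  denominator-zero nodes (fewer than two weighted neighbours) are 0/0 and
  are excluded from the mean with their count logged, rather than scored 0.
- **Assortativity**: Newman's degree-correlation coefficient in its M-edge
  moment form, over the edge list $\{(i,j): w_{ij} > \tau\}$ with endpoint
  values taken as the *weighted* degrees $k_i$. The formula is written for
  discrete edges while the other measures are weighted; this hybrid is a
  declared convention, for two reasons. A binary-degree reading at
  $\tau = 0$ makes every node's degree identical (n−1) and assortativity
  universally undefined; and with weighted degrees over the *complete*
  edge list the statistic is identically $-1/(n-1)$ for any degree vector
  (each node is paired equally often with all others). Finite, varying
  assortativity values therefore imply a thresholded edge list: choose
  $\tau > 0$ (τ is a weight threshold; `tau = 0.05` corresponds to
  $|r| \approx 0.37$) when assortativity is of interest. The default stays
  $\tau = 0$ so that density and clustering operate on the complete
  weighted graph. A regular graph (all endpoint degrees equal) has a zero
  denominator and is reported *undefined*, not 0.

Paired male/female networks are compared by **label permutation**: pooled
sample labels are shuffled preserving group sizes, both networks rebuilt,
and the property difference recomputed; the two-sided p-value is
$(1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(n_{valid} + 1)$. Add-one
smoothing avoids p = 0 from finite permutations (sidedness is unstated in
the source convention; two-sided is conservative). Permutations yielding an
undefined property are excluded with an adjusted denominator, and results
are flagged unreliable when over 20% are lost. The default is 1,000
permutations.

`project_reference()` fixes the edge set from a reference network (the
male phenotype, whose differential-expression effect is the more robust)
and recomputes weights from the other group's samples. Whether published
group statistics for female phenotypes derive from their own networks or
from such projections is ambiguous; the pipeline computes *statistics*
from each group's own full network and uses projection only for the
exported/visualised female networks when `projection = "male-reference"`.

## The synthetic-data generator

`simulate_study()` emulates the study's structure so every stage is
testable: 8 design cells crossing the three binary factors
(`n_per_group = 8` by default, typical of FCG behavior cohorts); latent
log2 expression per gene as baseline + additive effects of XY⁻, testes,
testosterone, and a gonadal×hormone interaction; a single per-sample
latent factor shared by a module of signal-transduction genes (Akt1/2/3,
Adcy2, Adcy5, Pdyn, Cdk5, App) active only in chosen groups
(gonadal-male groups by default), giving a controllable within-module
correlation $\rho = \lambda^2/(\lambda^2 + \sigma^2)$ for loading
$\lambda$ and residual SD $\sigma$; and behavior measures linearly coupled
to chosen genes. Defaults plant the direction of the reported biology:
−0.35 log2 XY⁻ effects on the chromosome-sensitive genes, −0.4 log2
testosterone-in-males interactions, module loading 0.8, residual SD 0.5
log2 (≈40% CV, typical for frontal-cortex qPCR), reference CT 20,
replicate SD 0.15 cycles.

CT construction is defined to make quantification the exact inverse of
simulation at zero noise ($CT = \overline{CT}_{ref} - \text{latent} +
\log_2 10{,}000$), giving a round-trip identity the suite asserts at 1e-9.
Additivity is on the log2 scale so planted betas carry fold-change
semantics through $2^{-\Delta Ct}$. One top-level seed drives deterministic
per-stage sub-seeds; identical (config, seed) gives bit-identical outputs,
including the full pipeline's files.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: amplification-efficiency differences and
other non-log-linear qPCR artefacts; heavy-tailed or count-like expression
noise; correlated residuals beyond the single module factor; litter,
batch, and cage effects; stressor-schedule dynamics; and behavior–gene
relations beyond linear coupling. Tests verify the machinery under the
stated generative model, not the biology.

## Numerical conventions and test scale

Zero-variance inputs raise classed degenerate errors naming the offending
gene/measure. Clustering and assortativity denominators are compared
against zero at 1e-12 (relative for assortativity). Exactly-zero p-values
(possible with numerically perfect correlations) are clamped to the
smallest positive double before BH. Tie-breaks in the permutation p use
`>=`, which is conservative.

Simulation-based checks in the suite run at deliberately modest sizes
chosen to make their statistical targets sharp while keeping the default
test run quick: permutation-size calibration uses 500 replicates of
10 + 10 samples × 12 genes at 200 permutations (rejection rate within
[0.03, 0.07] at α = 0.05); module-detection power uses 100 replicates at
the generator's stated module parameters; ANOVA type-I error uses 1,000
null datasets of 4 mice/cell; end-to-end planted-effect recovery uses 200
replicates at 5 mice/group. All are fixed-seed and reproducible.

## Limitations

Mixed-effects structure (litters, cohorts) is out of scope, as are
amplification-efficiency correction, module *discovery* (the gene set is
fixed), partial-correlation or directed networks, and any interpretation
of which biological factor "explains" an observed difference. The
assortativity convention above is a documented package choice — alternative
readings of the formula are possible and τ is exposed precisely so users
can state theirs.
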