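---
title: "Quantifying gradual inverse drug resistance: models and design choices"
author: "invresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gradual inverse drug resistance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invresist)
```

## The setting

When a cancer cell line is cultured under stepwise-increasing doses of a
selecting drug, a series of isogenic sublines emerges whose resistance to
that drug grows gradually — and whose sensitivity to a second, bystander
drug may simultaneously *increase* ("inverse resistance" or collateral
sensitivity). The canonical example modelled throughout this package is an
A2780 ovarian-cancer series selected with paclitaxel (PTX, resistance
index rising from 1 to about 59) while becoming collaterally sensitive to
cisplatin (CDDP, sensitivity index rising to about 11 before relapsing).

`invresist` implements the full in-silico side of such a study: the
cytotoxicity arithmetic that quantifies resistance, two statistical
comparisons of dose-response relationships, ordered-series differential
expression with kinetic trend classification, scaffold-gene selection, and
protein-interaction network analysis — each stage exercised end-to-end on
synthetic data with known ground truth.

## Cytotoxicity: from absorbance to indices

**Viability.** The alamarBlue assay reports cell viability through the
reduction of resazurin. Per well, percent dye reduction uses the standard
two-wavelength formula with published molar extinction coefficients
(oxidised: 80586 at 570 nm, 117216 at 600 nm; reduced: 155677 and 14652),

$$\%\mathrm{red} = \frac{\varepsilon^{ox}_{600} A_{570} -
\varepsilon^{ox}_{570} A_{600}}
{\varepsilon^{red}_{570} A'_{600} - \varepsilon^{red}_{600} A'_{570}}
\times 100,$$

where primed absorbances come from cell-free blank wells. Percent
viability is the treated wells' reduction relative to the mean of the
drug-free control wells. The plate layout follows assay convention:
columns 1/12 blanks, 2/11 drug-free controls, 3–10 an eight-point
concentration series with four wells per concentration.

**IC50 by interpolation, not curve fitting.** Because each line is
assayed on its own dilution series, curves are transformed to a common
grid of eight viability levels (90%…20%). For a level $y$ bracketed by
observed points $(x_1, y_1)$ and $(x_2, y_2)$,

$$x = x_1 + (x_2 - x_1)\,\frac{y - y_1}{y_2 - y_1}.$$

The IC50 is the 50% entry of this grid. Scanning proceeds from the lowest
concentration; the first crossing wins and multiple crossings are
flagged. Levels outside the observed range are undefined by default — the
per-line dilution series is designed to avoid extrapolation — but an
`extrapolate` flag extends the terminal segment. On any piecewise-linear
curve this interpolation is exact: re-evaluating the interpolant at the
returned concentration reproduces the level to machine precision, which
the test suite asserts on randomly generated curves.

**Indices.** For the selecting drug, the resistance index is
RI = IC50(subline)/IC50(parent); for the bystander drug the sensitivity
index is SI = IC50(parent)/IC50(subline). Consecutive fold changes use
the same ratios between neighbouring lines of the derivation series, so
the unrounded folds telescope exactly to the end-to-end index. Reported
values round to two decimals *half away from zero* — the commercial
convention that reproduces every published table entry, where R's default
half-to-even rounding does not. pIC50 is $-\log_{10}$ of the molar IC50;
it is close to normally distributed where raw IC50s are log-normal, so
replicate-level comparisons operate on that scale.

## Comparing dose-response relationships

Two complementary tests are provided.

`compare_ttest_pic50()` is the classical unpaired Student t-test (pooled
variance, not Welch) on replicate pIC50 values. Degenerate inputs follow
explicit conventions: both groups constant gives p = 1 at equal means and
p = 0 otherwise.

`compare_lmm()` uses the whole curve rather than its 50% point. Well-level
viability is modelled linearly in concentration (raw scale) with
line-specific fixed intercepts and slopes and a Gaussian random slope
deviation per replicate plate; the slope difference (the
line-by-concentration interaction) measures how differently survival
decays with dose. Inference was a genuinely open design choice. A Wald z
on the interaction is badly anti-conservative with two or three plates
per line, and even Satterthwaite-style approximations tend to run
slightly liberal when the slope variance component rests on so few
grouping units. For the
balanced assay design, however, the slope contrast lies entirely in the
between-plate stratum, so the pooled two-sample t-test on per-plate
least-squares slopes — with plates-minus-two degrees of freedom — is
*exactly* calibrated under the model. That stratum test is the default;
`df_method = "satterthwaite"` or `"wald"` remain available for unbalanced
data. The mixed model is always fitted and returned, and boundary
variance estimates are flagged. `simulate_dose_response()` generates data
from exactly this model for the type-I-error and power studies in the
test suite (1000 null data sets; power is assessed at a slope separation
of five between-plate slope standard deviations with six plates per
line).

## Ordered-series differential expression

The pipeline starts at a gene-by-sample count matrix with an ordered
`cell_line` factor (parent first) and at least two replicates per line.

**Filtering.** Genes need more than 5 counts-per-million in at least two
samples. The filter is applied once, globally, so all contrasts share one
gene universe.

**Normalisation.** Expression is
$\log_2\!\big((\mathrm{count}+0.5)/(\mathrm{libsize}+1)\times 10^6\big)$.
The library size is, by default, the TMM *effective* size (column sum
times a trimmed-mean-of-M-values scaling factor). This departs
deliberately from plain total-count scaling: when a substantial fraction
of genes moves in one direction — exactly the regime of a resistance
series, and of this package's planted simulations — total-count CPM
shifts every unchanged gene by the compositional offset, wrecking
false-discovery control.
Trimmed-mean scaling centres fold changes on the non-changing majority.
`norm_method = "total"` restores plain column sums.

**Moderated tests.** Per contrast, the log2 fold change is the mean
difference of log-CPM; the per-gene pooled residual variance is shrunk
toward a common prior estimated by the method of moments on the log
variances (a scaled inverse-chi-square prior: prior df $d_0$ from the
trigamma-inverse of the excess log-variance dispersion, prior variance
$s_0^2$ from the corrected mean; when the moment estimate of $d_0$ is
infinite the prior variance is the arithmetic mean of the gene
variances). The moderated t uses the posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$ with $d + d_0$ degrees of freedom. The
construction is cross-checked in the test suite against an independent
empirical-Bayes implementation, and its two analytic limits — ordinary
two-sample t at $d_0 = 0$, pooled z at $d_0 = \infty$ — are asserted
exactly. Observation-level precision weights (a mean-variance trend) are
deliberately omitted: with two replicates per line the trend is unstable,
and the package's validation surface is synthetic-data recovery rather
than numeric identity with any particular reference implementation.

**FDR.** q-values are Benjamini-Hochberg by default (the reading most
consistent with "FDR-adjusted p-value"); a conservative Storey-style
rescaling by $\hat\pi_0$ at $\lambda = 0.5$ sits behind
`adjust_fdr(..., method = "storey")`. DEG sets are genes with
q below a threshold (0.05 and 0.01 are the conventional working points),
optionally with an absolute log2FC bound, split by sign.

## Kinetic trend classes and the scaffold

Across the ordered subline-vs-parent contrasts, each gene's log2FC
trajectory reduces to a sign pattern and one of five classes:
consistently up, consistently down, rising (one switch, minus to plus),
descending (the mirror), and variable (two or more switches). Two rules
deserve comment:

* **Dead zone.** $|\log_2 FC| < 0.1$ counts as sign zero and inherits the
  neighbouring nonzero sign. The published pattern assignment was made
  visually from heat maps; a small dead zone prevents noise-level wobbles
  from relabelling an otherwise consistent gene as "variable". An
  all-zero trajectory is labelled variable with an explicit flag.
* **Signs only.** Classification ignores per-contrast significance,
  matching how heat maps colour all selected genes in all contrasts.

The five classes partition any input list — an identity the tests assert
— and on planted simulations (effect 3, dispersion 0.05) class recovery
exceeds 90% over non-null genes and 99% over the consistent classes.

**Scaffold genes** satisfy q < 0.001 *and* |log2FC| > 2 in every contrast
— the genes strongly and significantly changed at each stage, the
"scaffold" of the resistance process. Being a conjunction, the selection
is order-invariant. Shared-DEG matrices count pairwise intersections of
up- (upper triangle) and downregulated (lower triangle) DEG sets, with
aggregate totals for an early/late partition of the series (the stage
structure in which early sublines share predominantly downregulated genes
and late sublines predominantly upregulated ones).

**Ordination and clustering.** PCA is the centred, unscaled SVD of
samples (no unit-variance scaling: fold-change magnitude is the signal);
hierarchical clustering defaults to Euclidean distance with average
linkage, recorded in the output and configurable. Both choices are
unstated in typical reports; these defaults are the most common
conventions for log-expression data.

## The scaffold network

From a supplied scored edge list (combined scores in [0, 1]),
`build_network()` induces the subgraph on the scaffold genes at a minimum
score of 0.4 — the widespread "medium confidence" convention, since
retrieval thresholds are rarely reported. Nodes carry the trend-summary
direction (up, down, nonconsistent). Hubs are nodes of degree at least 7,
matching the convention that scaffold hubs carry on the order of 7–11
partners. Gene-set over-representation is the one-sided hypergeometric
upper tail with BH control across terms at q < 0.05; the default
background is the expressed-gene universe (everything surviving the
low-expression filter) rather than the whole genome — the standard choice
when the annotation's universe is unknown — and is configurable.

## What the synthetic data emulate — and what they do not

`sim_config()` fixes the study conditions once: 7 lines x 2 replicates;
negative-binomial counts (dispersion 0.05, library sizes ~2x10^7 with
±15% uniform jitter, baseline log2 CPM ~ N(5, 2) clipped to [1, 12]);
planted |log2FC| of 3 at full effect; pattern proportions 6% consistently
up, 9% rising, 4% variable, 5% descending, 6% consistently down, 70%
null (the non-null mix mirrors the relative pattern frequencies observed
in such series, scaled by a conventional null majority); rising/descending
switch positions uniform over interior contrasts 2..(k-1), so rule
generality is tested rather than one fixed switch stage; plates built on
a 4-parameter logistic through each line's measured IC50 (asymptotes
100/0, Hill slope 1) with additive Gaussian viability noise (SD 3%,
truncated to [-5, 120], the scale loosely calibrated to published
replicate SDs); concentration grids geometric from IC50/10 to 10xIC50,
emulating per-line serial dilutions. Every generator draws from a single
RNG stream derived deterministically from the configuration seed, so all
outputs are bit-reproducible.

The generators deliberately do *not* emulate: batch or flow-cell effects,
gene length and GC bias, a mean-variance trend, correlated gene modules,
outlier samples, or plate edge effects. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated model,
not that it is robust to every artefact of real data.

## Numerical conventions and degenerate inputs

* Rounding of reported indices: two decimals, half away from zero.
* Interpolation ties: scanning from the lowest concentration, first
  crossing wins; equality with an observed level returns that observed
  concentration exactly.
* Zero variance in both t-test groups: p = 1 at equal means, else 0.
* A gene with degenerate (non-finite) moderated statistic is excluded
  from testing with a warning; exact-zero variances are offset to
  10^-5 times the median before the prior fit.
* The trigamma inverse uses Newton iteration with analytic derivatives
  (50-iteration cap, relative tolerance 10^-10).
* Mixed-model variance components at the boundary are flagged
  (`singular = TRUE`) and a warning is raised.

## Problem sizes

The validation suite uses 2000-gene simulations for recovery metrics,
1000 null data sets for each calibration study, 200 simulations for
power, exhaustive enumeration up to universes of 12 genes for the
hypergeometric oracle, and all 720 permutations of six p-values for the
BH oracle — sizes chosen so that every stochastic bound sits well inside
its tolerance while the whole suite stays quick to run.

## Limitations

The IC50 is interpolation-based by design; no 4PL regression is exposed
for estimation (the logistic lives only in the simulator). The mixed
model treats concentration linearly on the raw scale (a log-concentration
option exists) — adequate for comparing slopes, not for mechanistic
dose-response modelling. The exact post-hoc procedure behind published
mixed-model p-values for such series is typically unreported; our
stratum-exact test is calibrated under the balanced design but is our own
choice, validated by its own simulations. Enrichment takes annotations as
given and performs no ontology-graph propagation.
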