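---
title: "Models and methods behind serpinscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serpinscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinscreen)
```

## The experiment this package models

Plasminogen activator inhibitor-1 (PAI-1) is a metastable serpin: its
active conformation sits in a local energy minimum and spontaneously
converts to an inactive *latent* conformation with a half-life of only
1–2 h at 37 °C. A two-timepoint phage-display deep mutational scanning
(DMS) screen probes both of PAI-1's phenotypes at once. A site-saturation
variant library (19 substitutions at each of 379 mature-protein positions,
7201 candidate variants) is selected for urokinase-type plasminogen
activator (uPA) inhibition either immediately (**0 h**) or after a **48 h**
incubation at 37 °C. Variants captured at 0 h are functional inhibitors;
variants still captured at 48 h additionally resisted the latency
transition. Sequencing the input and selected libraries yields per-variant
read counts; log2 enrichment of a variant in the 0 h selection is its
*inhibition score*, and in the 48 h selection its *functional stability
score*.

`serpinscreen` implements the full downstream analysis — enrichment
scoring, positional aggregation and region calling, comparison against
variant-effect and protein-stability predictors, and the
purifying-selection analysis against per-position conservation scores —
together with a synthetic screen generator so that every stage is testable
end to end without external data.

## The synthetic screen generator

### Ground truth

Each variant *i* carries two latent properties:

* an inhibitory activity $a_i \in [0, 1]$, the probability of capture by
  the uPA selection while in the active conformation, and
* a latency half-life $h_i > 0$ hours.

Per-position tolerances organise these draws. `tol0`, drawn from a
Beta(2, 2) distribution, is the fraction of substitutions at a position
that remain functional; functional variants draw
$a_i \sim U(0.3, 1)$ and nonfunctional variants draw $a_i$ below a floor
of 0.02 (near zero but not exactly zero, so their read counts are finite
and depleted rather than absent). All variants start with a wild-type-like
half-life $h_i \sim U(1, 2)$ h. Inside *planted stabilizing regions*
(default: five intervals, residues 40–45, 72–93, 158–178, 216–237 and
320–347, mirroring the flexible elements of the serpin fold where
substitutions can slow reactive-center-loop insertion), a per-position
stabilization tolerance `tol48` $\sim U(0.6, 0.95)$ gives each variant
that probability of being *stabilized*, multiplying its half-life by 20.
Outside the planted regions `tol48` is 0.

### Selection model

Selection after $t$ hours of incubation captures variant $i$ with
probability

$$p_i(t) = a_i \, 2^{-t/h_i} + b_i,$$

the product of activity and the first-order exponential survival of the
active conformation, plus a nonspecific background $b_i$. Post-selection
frequencies are the renormalised products $f_i\,p_i(t)$. The decay factor
makes selection memoryless: selecting at $t_1$ then $t_2$ (with $a = 1$)
equals selecting once at $t_1 + t_2$, a property the test suite checks.

The background term matters. At $t = 48$ h and $h \approx 1.5$ h the
surviving active fraction is $2^{-32} \approx 10^{-10}$: without a
background floor every non-stabilized variant would vanish entirely and
the zero line of the downstream region-calling rule would be meaningless.
Phage immunoprecipitations have real nonspecific background, and it is not
uniform: misfolded protein exposes hydrophobic surface and adsorbs to
beads and antibody more than natively folded protein. The generator
therefore uses $b_i = 10^{-3}$ for natively folded (functional) variants
and three times that for misfolded (nonfunctional) variants
(`misfolded_background_multiplier = 3`). Because nonfunctional variants
are the largest class at 48 h, the median-of-ratios normalisation anchors
on them, which places latent wild-type-like functional variants at a
systematically negative log2 fold change (~ −1.6) and stabilized variants
strongly positive — the qualitative structure a real 48 h screen shows,
with both positive and negative refined classes populated.

### Counts, predictors, conservation

Read counts are negative-binomial with mean `depth * f` and variance
$\mu + \alpha\mu^2$ (default depth $2\times10^6$ per sample, dispersion
$\alpha = 0.05$, three replicate libraries per condition; with
$\alpha = 0$ the draw is multinomial). The input library has near-equal
representation with log-normal jitter (sd 0.1) and two default spike-ins,
I91L at 2.6% and E242T at 1.4%, emulating cloning artifacts.

The synthetic variant-effect predictor (VEP) score is a monotone
decreasing function of activity plus Gaussian noise, clipped to [0, 1]
(higher = more pathogenic). The synthetic ΔΔG tables (kcal/mol) carry a
constant baseline per conformation, a misfolding penalty of 2.5 kcal/mol
for nonfunctional variants, and Gaussian noise (sd 0.8) — and, by
construction, **no** dependence on the half-life. This encodes the
hypothesis the predictor comparison is designed to expose: equilibrium
stability predictions see misfolding but are blind to the kinetic barrier
that controls the latency transition.

Per-position conservation scores follow

$$s_p = \alpha\,\mathrm{tol0}_p - \beta\,\mathrm{tol48}_p + \varepsilon_p,
\qquad \alpha = 2,\ \beta = 0.75,\ \varepsilon_p \sim N(0, 0.25^2),$$

with higher scores meaning more evolutionary lability. Positions tolerant
of substitution (high `tol0`) are labile; positions harbouring stabilizing
substitutions (high `tol48`) are under extra purifying selection against a
slowed latency transition, hence less labile.

### What the generator does not emulate

Amplicon tiling and read-level artifacts (including the amplicon-wise
wild-type background created by an I91L cloning vector), codon-level
library structure, position-correlated count noise, continuous half-life
distributions, predictor error that correlates across neighbouring
positions, and phylogenetic non-independence of conservation scores. Tests
passing on synthetic screens therefore validate the *analysis machinery*
and its statistical calibration, not the biological accuracy of any real
screen.

One structural property deserves emphasis. Because the conservation model
is linear in the tolerances and the tolerances are drawn independently
across positions, the quadrant analysis (below) has a *fixed* expected
ordering: among inhibition-constrained positions, those with stabilizing
substitutions (Q2) are strictly more conserved than those without (Q3), by
exactly $\beta\,E[\mathrm{tol48}]$. Real data need not behave this way —
empirically Q2 and Q3 are often statistically indistinguishable and the
dominant axis is inhibition tolerance — and no choice of $\alpha, \beta$
or tolerance coupling can make Q3 the strict minimum while keeping the
48 h conservation slope negative, since both quantities measure the same
monotone dependence on `tol48`. The generator documents this as a known
property rather than hiding it.

## The enrichment engine

The engine is a deliberately small, fully specified negative-binomial
procedure — *not* a DESeq2 port, although its output columns follow the
DESeq2 naming convention so real exported results can be ingested
interchangeably.

1. **Size factors** per sample by median-of-ratios: the median over
   variants (with positive counts in every sample) of the ratio of the
   sample's count to the variant's geometric mean count, rescaled to
   geometric mean 1. The median is taken on the log scale; for an odd
   number of variants this is identical to the ratio-scale median, and for
   an even number the two interpolation conventions differ negligibly.
2. **Dispersions** by method of moments on normalised counts within each
   condition, $\hat\alpha = \max(0, (s^2-\bar\mu)/\bar\mu^2)$, pooled
   across conditions by residual degrees of freedom, then shrunk 50/50
   toward a fitted mean–dispersion trend $a_0 + a_1/\mu$ and floored at
   $10^{-8}$. Unreplicated designs fall back to a configured prior
   dispersion (default 0.1) with a warning.
3. **Log fold change** $\log_2\frac{\bar q_{sel} + 0.5}{\bar q_{in} + 0.5}$
   of pseudocounted normalised condition means. The pseudocount of 0.5
   keeps fully depleted variants — the screen's strongest signal class —
   finite, at the cost of compressing extreme fold changes.
4. **Wald test**: a delta-method standard error from
   $\mathrm{Var}(K_{ij}/s_j) = q_i/s_j + \alpha_i q_i^2$, $z =$
   log2FC / SE, two-sided normal $p$.
5. **baseMean filter and FDR**: baseMean is the mean normalised count over
   the contrast's samples; only variants with baseMean ≥ 50 enter the
   Benjamini–Hochberg adjustment (others carry `padj = NA`), matching the
   thresholding order of the screen this models.

Known divergences from DESeq2, by design: no log-fold-change shrinkage, no
Cox–Reid dispersion estimation, no independent-filtering optimisation of
the threshold, and no amplicon-wise wild-type correction. Sample-level QC
uses PCA of $\log_2(\text{normalised count}+1)$ with samples as
observations, centred per variant.

## Refinement, mutational acceptance, regions

The 48 h depleted class mixes variants that lost inhibition outright with
variants that merely transitioned faster, so the functional stability
table is refined by removing variants whose 0 h inhibition score is below
zero. A score of exactly 0 is **retained** here (the filter removes
"less than zero"), while classification elsewhere folds 0 into the lower
class; the asymmetry is intentional and documented at both sites.

Refined scores are aggregated per position into a *mutational acceptance
score* — mean by default, sum available (`aggregate = "sum"`), since both
conventions appear in practice and the choice is a genuine free parameter.
The positional series is smoothed with a fixed LOWESS dialect: for each
position, the 20 nearest scored positions are fit by weighted least
squares with tricube weights and local degree 1, with **no** robustness
iterations; positions without refined variants are gaps and never enter a
neighbourhood. Regions are called from the smoothed series: destabilizing
where the value is below zero, stabilizing where it reaches the 75th
percentile of the series (linear-interpolation quantile, type 7; a
mean-of-series threshold is available via `upper_type = "mean"`), neutral
otherwise, with contiguous runs merged into 1-based inclusive intervals.
When every value is negative, the destabilizing rule wins everywhere and
no stabilizing region is called. Positional coordinates are 1-based
throughout; the BED export is the single 0-based half-open surface.

## Predictor stratification

Variants are stratified at a score boundary of 0 — strictly positive
scores form the "maintained/stabilized" stratum, zero and negative scores
the "reduced/destabilized" stratum. Each stratum is summarised by its mean
and a normal-approximation 95% CI (mean ± 1.96 SE). The group comparison
fits `value ~ stratum + (1 | position)` by REML: the 19 substitutions at a
site share structural context, so positions contribute random intercepts
rather than 19 pseudo-independent observations. The stratum coefficient is
reported with its Wald SE and two-sided normal $p$; a positive coefficient
means the reduced/destabilized stratum has the higher predictor value.
When the random-effect variance estimates to zero the model falls back to
ordinary least squares with a warning — the degenerate case in which both
estimators agree. ΔΔG tables are analysed twice, once per conformation
(active, latent), for side-by-side reporting.

## Purifying-selection analysis

The *normalized position count* (npc) at a position is the fraction of its
scored substitutions with score > 0 — for 0 h over all passed-filter
variants, for 48 h over the refined table. Conservation is regressed on
npc by OLS with a two-sided slope $t$ test; a positive 0 h slope and a
negative 48 h slope are the signatures of purifying selection on
inhibition and against slowed latency, respectively.

Positions are segmented at the medians of the two npc axes
($x$ = 0 h, $y$ = 48 h) into Cartesian quadrants: Q1 $(x>m_x, y>m_y)$,
Q2 $(x\le m_x, y>m_y)$, Q3 $(x\le m_x, y\le m_y)$, Q4 $(x>m_x, y\le m_y)$.
Ties go to the low half — npc values are discrete fractions, so ties at
the median are real and the rule must be deterministic. The naming makes
Q4 inhibition-permissive/stability-constrained and Q3 constrained for
both. Conservation is compared across quadrants by one-way ANOVA with
Tukey's HSD (Tukey–Kramer for the inevitably unequal quadrant sizes), and
the interdependence of the two median-split classes is tested by two-way
ANOVA with type-II sums of squares (the splits are unbalanced by
construction; denominator df $= n - 4$). Conservation scores are consumed
as-is under the convention higher = more labile; re-scaling or sign flips
are the caller's responsibility.

## Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; zero-SE Wald statistics get $p = 1$
  (all-zero variants) and zero-SE mixed-model contrasts get `p = NA`.
* Constant conservation gives a one-way F of 0 (not 0/0) and a regression
  with slope 0, $R^2 = 0$.
* Quadrants with fewer than 2 positions, confounded ANOVA factors,
  contrasts with a missing condition, and count tables with negative or
  non-integer entries raise immediate, named errors.
* The percentile in region calling uses R's default type-7 quantile.
* All stochastic steps of a simulation draw from a single generator seeded
  with `config$seed`, in a fixed documented order, so every artifact is
  byte-reproducible from the config alone.

## Problem sizes used by the test suite

Unit tests run on a 60-position library at depth $2\times10^5$; the
end-to-end checks use the full default conditions (7201 candidate
variants, three replicates, depth $2\times10^6$, dispersion 0.05), with 10
null screens for FDR calibration, 5 screens for region recovery, and 20
replicate fits for mixed-model recovery. These sizes were chosen so the
whole suite exercises full-scale screens while remaining quick to run on a
single core.
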