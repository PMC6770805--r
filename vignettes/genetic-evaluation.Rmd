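---
title: "Methods: the repeated-records animal model behind caprigen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the repeated-records animal model behind caprigen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

caprigen re-implements, as a tested pipeline, the genetic evaluation of
210-day standardized lactation yields (milk, fat, protein, dry matter, all
in kg) in Murciano-Granadina dairy goats, with and without the αS1-casein
(*CSN1S1*) genotype as a fixed effect. This vignette is the package's own
account of the model, the estimation machinery, the synthetic-data
generator, and the numerical and design choices a maintainer would want
spelled out.

## The model and its assumptions

Record $q$ of doe $p$ is modelled as

$$ y = \mu + \mathrm{Far}_i + \mathrm{Yea}_j + \mathrm{Mon}_k +
       \mathrm{Sea}_l + \mathrm{Typ}_m\; [+\, \mathrm{Gen}_n] +
       b_1 A + b_2 A^2 + a_p + pe_p + e $$

with farm ($i = 1..59$ by default), parturition year (2005–2016), month
(May–December), season (four meteorological quarters), birth type (1–5
kids) and optionally the observed *CSN1S1* genotype class as cross-
classified fixed effects; age at parturition in months enters as a linear
and quadratic covariate, centred at the sample mean before squaring (pure
conditioning — predictions are unaffected). The random terms are the
additive genetic effect $a \sim N(0, A\sigma^2_a)$, with $A$ the numerator
relationship matrix from the full pedigree, a permanent-environment effect
$pe \sim N(0, I\sigma^2_{pe})$ shared by all lactations of a doe, and the
residual $e \sim N(0, I\sigma^2_e)$. Assumptions worth stating: additive
gene action only (no dominance, no maternal effects), homogeneous residual
variance across farms and parities, and records connected to the pedigree
through at least one known ancestor (enforced by `connect_to_pedigree()`).

Identifiability of the fixed part uses the reference-level (first level)
constraint. Because season is a deterministic function of month, the season
dummies are aliased whenever both are fitted; `build_design_matrices()`
detects rank deficiency by QR, drops the aliased columns and reports them,
mirroring how both terms can coexist in the field's model statements.

## Pedigree algebra

Inbreeding uses the Meuwissen–Luo recursion ($F_i = \sum_j L_{ij}^2 d_j -
1$, ancestors traced per animal), which scales to tens of thousands of
animals; the tabular method is kept as the dense cross-check and for
relationship submatrices. Henderson's sparse $A^{-1}$ uses the
inbreeding-aware Mendelian-sampling variance $d_i = 0.5 - 0.25(F_s + F_d)$
(0.75 − 0.25F with one known parent, 1 for founders), consistent with the
recursion. Unknown parents are founder contributions; no genetic groups are
fitted, matching the evaluation being emulated. For pedigrees beyond 2000
animals the summary's pairwise-relationship range is estimated from a
seeded random sample of 100,000 pairs (the full matrix is $O(n^2)$).

## REML estimation

Variance components are estimated by EM-REML with safeguarded average-
information (AI) acceleration, for one or two traits sharing the design:

- The mixed-model equations are assembled with the residual-precision
  scaling, so the inverse coefficient matrix directly yields prediction
  error (co)variances; systems here stay below a few thousand equations and
  a dense Cholesky inverse is both simplest and fast.
- EM updates are the textbook conditional expectations; the EM map never
  decreases the restricted likelihood, and the test suite asserts this
  trace property on every run.
- After three EM burn-in steps, AI-Newton proposals are tried. The score is
  computed from trace identities on the MME inverse (verified against
  finite differences of the likelihood during development) and the AI
  matrix from working vectors $f_i = V_i P y$. Proposals are damped (max
  5-fold relative change), treated with an active set — variance components
  pushed below the floor are pinned there and the step re-solved for the
  free parameters — and step-halved, then abandoned for EM, whenever the
  likelihood would decrease. After four abandoned proposals the fit stays
  with EM. This combination converges in ~10 iterations on well-posed
  problems and degrades gracefully to monotone EM elsewhere.
- Convergence is declared on the squared relative change of the stacked
  parameter vector, $\|\Delta\theta\|^2 / \|\theta\|^2 < 10^{-12}$ by
  default. The norm form matters: near-zero components (a PE variance
  collapsing to its floor) would otherwise dominate a per-component
  criterion and convergence would never be declared.
- Components are floored at $10^{-8}\,\mathrm{var}(y)$; covariance blocks
  are projected to the nearest positive semi-definite matrix when an update
  leaves the cone (logged through the likelihood safeguard rather than
  silently).

Standard errors come from the inverse AI matrix at the optimum; the SE of
$h^2$ (and of $r_G$, $r_P$ in bivariate fits) uses the delta method.
Following the evaluation being emulated, multi-trait analysis is univariate
per trait for variances and bivariate per pair for correlations, not one
four-trait fit.

A caveat found while validating: when the true PE covariance of a trait
pair is nearly singular (the fat–protein pair under the default components
has PE correlation 0.97 with a tiny protein PE variance), the REML surface
has a flat ridge and reaching $10^{-12}$ can take many iterations even with
AI; estimates of $G_0$ and $r_G$ stabilise long before. `max_iter` caps the
cost and the convergence flag and final criterion are always reported.

## Breeding values, SEP, reliability

At converged components, the MME give BLUEs and PBVs for every pedigree
animal, bucks included (predicted through relatives). The prediction error
variance is the additive diagonal of the inverse coefficient matrix;
$\mathrm{SEP} = \sqrt{\mathrm{PEV}}$. Reliability is implemented as
$R_{AP} = 1 - \mathrm{SEP}^2/\sigma^2_a$ and accuracy as its square root.
The corresponding printed formula in the source literature squares the
whole expression, which is inconsistent with its own tabulated values
(e.g. $1 - 2.21^2/16.87 = 0.71$ is the printed reliability *without* the
outer square); the package implements the internally consistent reading and
the tests pin it to those tabulated values. For an animal with no records
and no informative relatives, PEV reaches $\sigma^2_a(1+F)$; the clipped
reliability is 0, as it should be.

Confidence ranges are $\mathrm{PBV} \pm k\,\mathrm{SEP}$ with nominal
normal coverage ($k=2 \to 95\%$), and the package validates empirically —
on model-true simulations solved at the true components — that the realised
TBV coverage matches (`sep_coverage_simulation()`; 95.3% and 68.3% at the
default seed). Accuracy and reliability bands use lower-inclusive
boundaries (0.50/0.75/0.90 for RTi; 0.30/0.55/0.65/0.75/0.90 for R_AP) —
the boundary convention had to be fixed somewhere to be testable.

## The synthetic-data generator

`sim_config()` fixes the study conditions the package is exercised under:

| parameter | default | why |
| --- | --- | --- |
| variance components | milk 11511.83/1689.51/15578.23; fat 16.87/16.22/25.74; protein 9.45/0.36/8.14; dm 57.45/82.03/211.58 (kg²) | the genotype-inclusive component set used as simulation truth |
| trait means | 416.0/19.54/13.25/52.33 kg | breed reference 210-day yields |
| trait correlations | weak milk–component, fat–protein 0.97 | the reported correlation structure |
| fixed-effect levels | 59 farms, years 2005–2016, months 5–12, 4 seasons, birth types 1–5 | the evaluation's level sets |
| fixed-effect spreads | 0.4/0.25/0.15/0.10/0.10 × phenotypic SD | plausible herd>year>month ordering; unpublished, hence configurable |
| allele frequencies | uniform over A, B, E, F, N | the real class-frequency table is in an unavailable appendix; flagged placeholder |
| genotype effects | protein & dry matter shift of 0.2 kg per g/L of summed allelic αS1 output (strong 3.6, medium 1.6, weak 0.6, null 0) | scaled from the per-allele protein outputs; magnitude configurable |
| lactations per doe | 1–6; ages 14–40 months at first parturition, +12/parity | the repeated-records structure and observed age bounds |
| lactation curve | Wood $t^b e^{-ct}$, $b=0.15$, $c=0.004$ | standard dairy shape with a computable integral |

Pedigrees are produced by seeded random mating with a doe-biased sex ratio;
genotypes drop founder alleles at Hardy–Weinberg and inherit uniformly
(Mendelian by construction); TBVs use recursive gene flow (founder draws
plus Mendelian-sampling deviations scaled by $d_i$), which is exactly
$MVN(0, A \otimes G_0)$. Everything is deterministic given the config seed.

What the generator does *not* emulate: selection (matings are random, where
the real population is under directional selection, which deflates
variances and biases relationship structure), heterogeneous farm recording
intensity, seasonal lactation-curve shape differences, genotyping error,
and missing pedigree links beyond unknown founders. Passing tests therefore
show the *machinery* is correct under the stated model; they do not certify
that the real population satisfies that model.

## What a genotype fixed effect can and cannot do

Under this generator the locus acts additively through allele content, so
its variance is part of the additive genetic variance. Excluding the
genotype from the model then folds the locus variance into **both**
$\sigma^2_a$ and $\sigma^2_p$ of the fit, so the genotype-exclusive $h^2$
is, in expectation, slightly *above* the inclusive one. A large positive
inclusive-minus-exclusive contrast — as reported for protein on the real
data (+0.23) — cannot arise from a purely additive locus in a correctly
specified model; it requires something the simulation deliberately does not
build in (non-additive action, genotype–environment structure, or
estimation interplay in the real data, where the exclusive protein fit also
shows a much larger phenotypic variance). The tests therefore assert the
model-consistent invariants — zero genotype effect implies near-identical
fits and PBV correlation above 0.99, and an additive locus yields a bounded
contrast with a larger exclusive-model phenotypic variance — and the
printed +0.23 contrast is checked where it is well-defined: as arithmetic
on the published component table.

## Lactation standardization and screening choices

- **Fleischmann test-interval accumulation** with back-extension of the
  first test to day 0 and carry of the last test to day 210 (tests past 210
  are truncated by interpolation). The upstream method citation gives no
  detail, so the choice is documented and isolated in one function;
  the accumulation is exactly numeric integration of the implied
  piecewise-linear yield curve, and the test suite checks that identity.
- Component percentages are milk-weighted means, so `fat_kg =
  milk_kg × fat_pct/100` holds to machine precision.
- **Depuration ranges** default to mean ± 4 SD of the breed reference
  values (e.g. milk 416.0 ± 197.9 kg), configurable; the study's exact
  ranges are unpublished.
- **Season** is derived from month by Northern-hemisphere meteorological
  quarters — unstated upstream, fixed here for reproducibility.
- The screen reproduces the published table's arithmetic with
  $F = H/\mathrm{dfn}$ and $\eta^2_p = F\,\mathrm{dfn}/(F\,\mathrm{dfn} +
  \mathrm{dfd})$, a reconstruction verified on the parturition-year and
  genotype rows (one published farm-row value, 0.206 vs 0.209, is
  inconsistent with its own table and left as-is). Kruskal–Wallis is the
  tie-corrected base-R test; Dunn's z and the independent-samples median
  test are implemented in-package (no installed package provides them);
  Shapiro–Francia wraps the standard implementation (valid for
  5 ≤ n ≤ 5000); Levene uses median centring; moments use the adjusted
  sample formulas.

## Selection index and sampling

ICO is a weighted sum of standardized milk, fat and protein PBVs (dry
matter excluded as an indirect fat+protein measure). The true economic
weights are external to the available sources, so equal weights on the
standardized scale are the documented placeholder and the weight vector is
a mandatory configuration surface. The genotyping sample takes the lowest
`n_low`, the highest `n_high`, and `n_mid` consecutive ranks centred on the
median rank ("around percentile 50" made precise); ties break by animal id
so the selection is order-invariant.

## Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to run
comfortably on a single core: coverage checks use ten replicates of a
~600-animal, three-generation pedigree solved at true components;
parameter-recovery fits use ~1500–2000 records (h² recovered within ±0.10
of 0.40); bivariate recovery uses ~900 records with tolerance ±0.15 on
$r_G$; the 12-record toy is checked against a dense grid-search oracle, and
the MME likelihood is checked to equal the dense-V REML likelihood exactly.
The analysis drivers use a ~2000-record herdbook, matching the scale of the
records the evaluation emulates.

## Known limitations

- Single-locus, single-gene treatment: no multi-locus LD, no genomic
  relationships, no genetic groups, no maternal effects.
- PE is separable from the additive effect only through pedigree structure;
  with founder-only pedigrees or single records the split is unidentified,
  and estimates near that regime carry large standard errors.
- The AI acceleration assumes the dense inverse of the MME is affordable;
  beyond ~5000 equations a sparse selected-inversion strategy would be
  needed.
- Bivariate fits with nearly singular PE covariance converge slowly to the
  strict criterion (estimates stabilise early; flags are reported).
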