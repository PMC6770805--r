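# caprigen

Pedigree-based genetic evaluation of dairy goat milk traits, built around the
question of whether acknowledging the αS1-casein (*CSN1S1*) genotype as a
fixed effect changes the genetic parameters and predicted breeding values of
210-day standardized milk, fat, protein and dry-matter yields in
Murciano-Granadina goats.

The package is aimed at animal breeders and quantitative geneticists who want
a transparent, fully testable re-implementation of the classical
repeated-records evaluation workflow: pedigree algebra, REML variance
components, BLUP breeding values with their prediction errors, a combined
selection index, and the two-model (genotype in / genotype out) comparison —
exercisable end to end on synthetic data with the same structure as the
breeding-program records, so no proprietary herdbook data are required.

## The model

Each 210-day lactation record is modelled with a repeated-records animal
model,

```
y = μ + farm + year + month + season + birth type [+ genotype]
      + b1·age + b2·age² + animal + pe + e
```

where `animal ~ N(0, A σ²a)` is the additive genetic effect with `A` the
numerator relationship matrix, `pe ~ N(0, I σ²pe)` the permanent-environment
effect common to a doe's lactations, and `e ~ N(0, I σ²e)` the residual.
The genotype term is the observed *CSN1S1* class (AA, BA, BB, AE, BE, EF, …),
and the evaluation is run once including and once excluding it.

Components are estimated by REML: monotone EM steps safeguarded with
average-information (AI) Newton acceleration under an active-set treatment of
variance components pinned at the boundary, with the convergence criterion
being the squared relative change of the parameter vector (default `1e-12`).
At the estimates, Henderson's mixed-model equations give BLUEs for fixed
effects and BLUP predicted breeding values (PBV) for every pedigree animal.
From the inverse coefficient matrix the package reports, per animal:

- `SEP = sqrt(PEV)` — standard error of prediction,
- reliability `R_AP = 1 − SEP²/σ²a` and accuracy `RTi = sqrt(R_AP)`,
- confidence ranges `PBV ± k·SEP` (k = 1 → 68%, k = 2 → 95% nominal
  coverage of the true breeding value).

Derived parameters follow the standard definitions: `h² = σ²a/σ²p`,
repeatability `(σ²a + σ²pe)/σ²p`, and for trait pairs (bivariate fits)
`r_G = σ_a12/√(σ²a1 σ²a2)` with `σ_p12 = σ_a12 + σ_pe12 + σ_e12`.

Supporting modules implement the Meuwissen–Luo inbreeding recursion,
the tabular relationship matrix, Henderson's sparse A⁻¹ with inbreeding
accommodation, Fleischmann 210-day standardization of monthly test-day
records, the nonparametric pre-model battery (Kruskal–Wallis with
`F = H/dfn` and `η²p = F·dfn/(F·dfn + dfd)`, Dunn–Bonferroni, Shapiro–
Francia, Levene), the ICO selection index with the low / percentile-50 /
high genotyping strata, and a gene-dropping simulator for pedigrees,
*CSN1S1* genotypes and correlated multi-trait lactation records.

## Worked example

```r
library(caprigen)

cfg  <- sim_config(seed = 42, n_founder_bucks = 8, n_founder_does = 40,
                   n_generations = 3, kids_per_doe = 3,
                   lactation_range = c(1L, 3L))
ped  <- simulate_pedigree(cfg)
herd <- simulate_lactation_dataset(ped, NULL, cfg)
print(ped)
#> <goat_pedigree> 462 animals; 48 founders; generation depth 1-3
#>   mean F = 0.01055

rec  <- connect_to_pedigree(depurate_records(herd$records)$records, ped)$records
Ainv <- a_inverse_sparse(ped)
dm   <- build_design_matrices(rec, model_spec("milk"), ped)
fit  <- reml_fit(dm, Ainv)
print(fit)
#> <reml_fit> 1 trait(s): milk
#>   iterations: 10 (converged)  criterion: 8.78e-15
#>   sigma_a2: 10430.5  sigma_pe2: 0.000319908  sigma_e2: 15734
#>   h2: 0.3987 +/- 0.111  repeatability: 0.3987

sol <- solve_blup(dm, Ainv, fit$vc)
ev  <- evaluation_table(sol, ped, rec)
head(ev[order(-ev$PBV), c("animal_id", "sex", "PBV", "SEP", "RTi", "R_AP")], 3)
#>     animal_id sex      PBV      SEP       RTi      R_AP
#> 19     A00019 doe 199.8730 74.70859 0.6818365 0.4649010
#> 254    A00188 doe 177.2715 71.54919 0.7135841 0.5092023
#> 45     A00045 doe 175.7104 69.08131 0.7365295 0.5424757
```

The simulation truth for milk has `σ²a = 11511.83`, `σ²pe = 1689.51`,
`σ²e = 15578.23` (h² = 0.40): the 708-record fit recovers h² = 0.399 with a
delta-method standard error of 0.11. The top-ranked does carry PBVs of
+175–200 kg of 210-day milk with medium accuracy — with ~700 records most
information comes from own performance plus a shallow pedigree.

## The analysis workflow

The numbered drivers under `analysis/` run the full study sequence on the
synthetic herdbook (~800 pedigree animals, ~2000 lactation records) and
write their tables under `results/analysis/`:

| script | stage |
| --- | --- |
| `01_simulate.R` | pedigree, genotypes, lactation records, depuration |
| `02_lactation.R` | test-day expansion and Fleischmann re-standardization |
| `03_screen.R` | nonparametric battery and effect sizes |
| `04_reml.R` | variance components for both model variants, bivariate fit |
| `05_breeding_values.R` | BLUP evaluations, SEP/RTi/R_AP, by-sex descriptives |
| `06_selection_index.R` | ICO ranking and the three genotyping strata |
| `07_model_comparison.R` | PBV correlations and regressions between variants |

`run_pipeline()` wires the same stages into a single call with a manifest.

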