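#!/usr/bin/env Rscript
# Stage 3: the nonparametric pre-model battery -- Shapiro-Francia normality,
# Levene homoscedasticity, Kruskal-Wallis per factor with the F conversion
# and partial eta squared, and Dunn-Bonferroni post hocs for the genotype.
source(file.path("analysis", "00_common.R"))

d <- get_dataset()
rec <- d$records

sf <- shapiro_francia(sample(rec$milk_kg, min(nrow(rec), 5000)))
message(sprintf("Shapiro-Francia on milk: W' = %.4f, p = %.3g", sf$W,
                sf$p_value))
sup <- supporting_tests(rec$milk_kg, rec$farm,
                        extra = rec[c("milk_kg", "fat_kg", "protein_kg",
                                      "dm_kg")])
message(sprintf("Levene across farms: F = %.2f, p = %.3g; skewness %.2f, kurtosis %.2f",
                sup$levene$F, sup$levene$p_value, sup$skewness, sup$kurtosis))

screen <- factor_screen(rec,
                        traits = c("milk_kg", "fat_kg", "protein_kg", "dm_kg"),
                        factors = c("farm", "year", "month", "season",
                                    "birth_type", "genotype_class"))
message("largest effect sizes:")
top <- screen[order(-screen$partial_eta_squared), ][1:5, ]
for (i in seq_len(5)) {
  message(sprintf("  %s x %s: H = %.2f, F = %.2f, eta_p2 = %.3f",
                  top$factor[i], top$trait[i], top$H[i], top$F[i],
                  top$partial_eta_squared[i]))
}

dunn <- dunn_bonferroni(rec$protein_kg, rec$genotype_class)
message(sprintf("Dunn-Bonferroni genotype pairs with adjusted p < 0.05: %d of %d",
                sum(dunn$p_adjusted < 0.05), nrow(dunn)))

write_tsv(screen, "03_factor_screen")
write_tsv(dunn, "03_dunn_genotype_protein")
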