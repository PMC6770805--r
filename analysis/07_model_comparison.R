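#!/usr/bin/env Rscript
# Stage 7: compare the two evaluations -- Pearson correlation and OLS
# regression between the genotype-inclusive and -exclusive PBVs per trait,
# over all pedigree animals and over phenotyped does.
source(file.path("analysis", "00_common.R"))

d <- get_dataset()
ev <- utils::read.delim(file.path(RESULTS, "05_evaluations.tsv"))

rows <- list()
for (tr in c("milk", "fat", "protein", "dm")) {
  a <- ev[ev$trait == tr & ev$model_variant == "incl_genotype", ]
  b <- ev[ev$trait == tr & ev$model_variant == "excl_genotype", ]
  pa <- stats::setNames(a$PBV, a$animal_id)
  pb <- stats::setNames(b$PBV, b$animal_id)
  for (pop in c("all", "phenotyped_does")) {
    ids <- if (pop == "all") names(pa)
           else intersect(names(pa), unique(d$records$doe_id))
    ct <- pbv_correlation(pa[ids], pb[ids])
    rg <- pbv_regression(pa[ids], pb[ids])
    message(sprintf("%s (%s): r = %.3f (p = %.2g), slope %.3f, R2 = %.3f",
                    tr, pop, ct$r, ct$p_value, rg$slope, rg$r_squared))
    rows[[paste(tr, pop)]] <- data.frame(
      trait = tr, population = pop, n = ct$n, r = ct$r, p_value = ct$p_value,
      slope = rg$slope, intercept = rg$intercept, r_squared = rg$r_squared)
  }
}
write_tsv(do.call(rbind, rows), "07_model_comparison")
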