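#!/usr/bin/env Rscript
# Stage 6: combine milk, fat and protein PBVs of the genotype-inclusive
# evaluation into the ICO selection index, rank the does, and draw the
# low / percentile-50 / high genotyping strata.
source(file.path("analysis", "00_common.R"))

d <- get_dataset()
ev <- utils::read.delim(file.path(RESULTS, "05_evaluations.tsv"))
ev <- ev[ev$model_variant == "incl_genotype", ]

pbv_tab <- data.frame(animal_id = d$ped$ped$animal_id,
                      sex = d$ped$ped$sex)
for (tr in c("milk", "fat", "protein")) {
  sub <- ev[ev$trait == tr, c("animal_id", "PBV")]
  pbv_tab[[tr]] <- sub$PBV[match(pbv_tab$animal_id, sub$animal_id)]
}
does <- pbv_tab[pbv_tab$sex == "doe", c("animal_id", "milk", "fat", "protein")]
sc <- ico_scores(does)
message(sprintf("scored %d does; top animal %s (ICO %.2f)", nrow(sc),
                sc$animal_id[sc$rank == 1], max(sc$ico)))

n_low <- n_high <- min(236L, floor(nrow(sc) / 3))
n_mid <- min(238L, nrow(sc) - n_low - n_high)
strata <- rank_stratified_sample(sc, n_low, n_mid, n_high)
message(sprintf("strata sizes: low %d, mid %d, high %d, unselected %d",
                sum(strata$stratum == "low"), sum(strata$stratum == "mid"),
                sum(strata$stratum == "high"),
                sum(strata$stratum == "unselected")))
write_tsv(strata, "06_ico_strata")
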