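#!/usr/bin/env Rscript
# Stage 1: generate the synthetic herdbook -- pedigree, CSN1S1 genotypes and
# repeated 210-day lactation records -- and summarize its structure.
source(file.path("analysis", "00_common.R"))

d <- get_dataset()

message(sprintf("pedigree: %d animals (%d does, %d bucks), depth %s",
                d$ped$n, sum(d$ped$ped$sex == "doe"),
                sum(d$ped$ped$sex == "buck"),
                paste(range(d$ped$depth), collapse = "-")))
ps <- pedigree_summary(d$ped)
message(sprintf("mean inbreeding %.3f%%; pairwise relationship range %.3f-%.3f",
                100 * ps$mean_inbreeding, ps$relatedness_range[1],
                ps$relatedness_range[2]))
message(sprintf("%d lactation records on %d does (%d rejected in depuration)",
                nrow(d$records), length(unique(d$records$doe_id)),
                nrow(d$rejections)))
message(sprintf("genotype classes: %s",
                paste(names(table(d$sim$genotypes$genotype_class)),
                      collapse = " ")))

write_tsv(d$ped$ped, "01_pedigree")
write_tsv(d$sim$genotypes, "01_genotypes")
write_tsv(d$records, "01_records")
write_tsv(d$rejections, "01_depuration_log")
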