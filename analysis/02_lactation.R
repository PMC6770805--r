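#!/usr/bin/env Rscript
# Stage 2: demonstrate the test-day layer -- expand standardized lactations
# into seven 30-day controls along a Wood curve and re-standardize with the
# Fleischmann test-interval method; the round trip should agree within the
# curve-discretization tolerance (~2%).
source(file.path("analysis", "00_common.R"))

d <- get_dataset()
rec <- utils::head(d$records, 200L)

tds <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
  simulate_test_day_records(rec[i, ], d$cfg)))
std <- standardize_lactation_210(tds)

m <- merge(rec[c("doe_id", "parity", "milk_kg")], std,
           by = c("doe_id", "parity"), suffixes = c("_true", "_std"))
rel_err <- abs(m$milk_kg_std - m$milk_kg_true) / m$milk_kg_true
message(sprintf("round-trip relative error: median %.2f%%, max %.2f%% (n = %d)",
                100 * stats::median(rel_err), 100 * max(rel_err), nrow(m)))

write_tsv(tds, "02_test_days")
write_tsv(std, "02_standardized")
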