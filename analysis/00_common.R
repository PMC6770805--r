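# Shared setup for the numbered analysis drivers. Each script is a thin
# narrative layer over the package; all computation lives in R/.
library(caprigen)

RESULTS <- file.path("results", "analysis")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

# The study conditions emulated throughout: a three-generation pedigree of
# ~800 animals, 1-6 standardized lactations per doe, 59 farms, parturition
# years 2005-2016 and months May-December, six observed CSN1S1 genotype
# classes, and the milk/fat/protein/dry-matter variance components used as
# simulation truth.
get_config <- function(seed = 2026L) {
  sim_config(seed = seed, n_founder_bucks = 14L, n_founder_does = 70L,
             n_generations = 3L, kids_per_doe = 3L,
             lactation_range = c(1L, 6L))
}

get_dataset <- function(cfg = get_config()) {
  ped <- simulate_pedigree(cfg)
  sim <- simulate_lactation_dataset(ped, NULL, cfg)
  dep <- depurate_records(sim$records)
  conn <- connect_to_pedigree(dep$records, ped)
  list(cfg = cfg, ped = ped, sim = sim, records = conn$records,
       rejections = dep$rejections, Ainv = a_inverse_sparse(ped))
}

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
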