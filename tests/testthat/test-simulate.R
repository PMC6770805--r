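test_that("pedigree simulation is reproducible and respects the config", {
  cfg <- sim_config(seed = 3, n_founder_bucks = 4, n_founder_does = 12,
                    n_generations = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(ped$n, 16L)
  expect_true(all(ped$inbreeding == 0))
  expect_true(all(ped$depth == 1L))

  cfg2 <- sim_config(seed = 9, n_founder_bucks = 4, n_founder_does = 10,
                     n_generations = 3, kids_per_doe = 2)
  p1 <- simulate_pedigree(cfg2)
  p2 <- simulate_pedigree(cfg2)
  expect_identical(p1$ped, p2$ped)
  expect_error(simulate_pedigree(sim_config(n_founder_bucks = 0)),
               "founder")
})

test_that("simulated mean inbreeding agrees with gene-dropping on the same pedigrees", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_founder_bucks = 3, n_founder_does = 8,
                      n_generations = 3, kids_per_doe = 2)
    ped <- simulate_pedigree(cfg)
    gd <- gene_drop_estimates(ped, n_drops = 2e4, seed = seed + 50)
    se <- sqrt(mean(gd$F) * (1 - mean(gd$F)) / (gd$n_drops)) + 1e-4
    expect_lt(abs(mean(ped$inbreeding) - mean(gd$F)),
              3 * se + 3 * stats::sd(gd$F) / sqrt(ped$n))
  }
})

test_that("genotype dropping is Mendelian and Hardy-Weinberg at the founders", {
  cfg <- sim_config(seed = 5, n_founder_bucks = 3, n_founder_does = 10,
                    n_generations = 3, kids_per_doe = 2)
  ped <- simulate_pedigree(cfg)
  mono <- drop_genotypes(ped, c(B = 1), seed = 2)
  expect_true(all(mono$allele1 == "B" & mono$allele2 == "B"))
  expect_true(all(mono$genotype_class == "BB"))

  gt <- drop_genotypes(ped, c(A = 0.2, B = 0.2, E = 0.2, F = 0.2, N = 0.2),
                       seed = 7)
  idx <- stats::setNames(seq_len(ped$n), ped$ped$animal_id)
  for (i in which(ped$ped$sire > 0L)) {
    s <- ped$ped$sire[i]
    expect_true(gt$allele1[i] %in% c(gt$allele1[s], gt$allele2[s]))
  }
  for (i in which(ped$ped$dam > 0L)) {
    d <- ped$ped$dam[i]
    expect_true(gt$allele2[i] %in% c(gt$allele1[d], gt$allele2[d]))
  }
  # the observed class labels follow the field convention (BA, not AB)
  expect_true(all(!grepl("^AB$", gt$genotype_class)))
  expect_error(drop_genotypes(ped, c(A = 0.5, B = 0.4)), "sum to 1")

  # Hardy-Weinberg proportions in a large founder-only population
  freqs <- c(A = 0.4, B = 0.3, E = 0.2, F = 0.05, N = 0.05)
  big <- simulate_pedigree(sim_config(seed = 8, n_founder_bucks = 2000,
                                      n_founder_does = 8000,
                                      n_generations = 1))
  g <- drop_genotypes(big, freqs, seed = 3)
  counts <- table(g$genotype_class)
  classes <- names(counts)
  expected <- vapply(classes, function(cl) {
    a <- strsplit(cl, "")[[1]]
    if (a[1] == a[2]) freqs[[a[1]]]^2 else 2 * freqs[[a[1]]] * freqs[[a[2]]]
  }, numeric(1))
  chi <- sum((as.vector(counts) - 1e4 * expected)^2 / (1e4 * expected))
  p <- stats::pchisq(chi, df = length(classes) - 1, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("polymorphism percentage counts monomorphic markers", {
  m <- cbind(matrix(rep_len(c(0, 1, 2), 5 * 43), 5, 43), matrix(2, 5, 5))
  expect_equal(polymorphism_summary(m), 100 * 43 / 48)
  expect_equal(polymorphism_summary(matrix(0, 4, 6)), 0)
  expect_equal(polymorphism_summary(matrix(c(0, 1), 4, 6)), 100)
  chr <- cbind(c("AA", "AB", "BB"), c("AA", "AA", "AA"))
  expect_equal(polymorphism_summary(chr), 50)
  expect_error(polymorphism_summary(matrix(0, 0, 0)), "empty")
})

test_that("gene-flow TBVs have the additive covariance structure", {
  cfg <- sim_config(seed = 2, n_founder_bucks = 1000, n_founder_does = 4000,
                    n_generations = 1)
  ped <- simulate_pedigree(cfg)
  expect_true(all(simulate_breeding_values(ped, matrix(0, 1, 1), seed = 1) == 0))
  tbv <- simulate_breeding_values(ped, matrix(100, 1, 1), seed = 4)
  se <- 100 * sqrt(2 / ped$n)
  expect_lt(abs(stats::var(tbv[, 1]) - 100), 3 * se)

  # offspring on parent-average regression has slope ~ 1
  cfg2 <- sim_config(seed = 6, n_founder_bucks = 100, n_founder_does = 900,
                     n_generations = 2, kids_per_doe = 2)
  ped2 <- simulate_pedigree(cfg2)
  tbv2 <- simulate_breeding_values(ped2, matrix(50, 1, 1), seed = 9)[, 1]
  kids <- which(ped2$ped$sire > 0L)
  pa <- (tbv2[ped2$ped$sire[kids]] + tbv2[ped2$ped$dam[kids]]) / 2
  fit <- stats::lm(tbv2[kids] ~ pa)
  slope_se <- summary(fit)$coefficients["pa", "Std. Error"]
  expect_lt(abs(stats::coef(fit)[["pa"]] - 1), 3 * slope_se)
})

test_that("lactation records follow the generating model", {
  zero_vc <- lapply(default_variance_components(), function(x) x * 0)
  cfg <- sim_config(seed = 4, n_founder_bucks = 3, n_founder_does = 10,
                    n_generations = 2, kids_per_doe = 2,
                    variance_components = zero_vc,
                    genotype_effect_kg_per_gl = 0,
                    fixed_effect_sd = c(farm = 0, year = 0, month = 0,
                                        season = 0, birth_type = 0),
                    age_coeffs = c(b1 = 0, b2 = 0))
  ped <- simulate_pedigree(cfg)
  sim <- simulate_lactation_dataset(ped, NULL, cfg)
  expect_true(all(abs(sim$records$milk_kg - 416.0) < 1e-9))
  expect_true(all(abs(sim$records$dm_kg - 52.33) < 1e-9))

  cfg2 <- sim_config(seed = 4, n_founder_bucks = 3, n_founder_does = 30,
                     n_generations = 2, kids_per_doe = 2,
                     lactation_range = c(2L, 5L))
  sim2 <- simulate_lactation_dataset(simulate_pedigree(cfg2), NULL, cfg2)
  per_doe <- table(sim2$records$doe_id)
  expect_true(all(per_doe >= 2 & per_doe <= 5))
  expect_true(all(sim2$records$month %in% 5:12))
  expect_true(all(sim2$records$season ==
                    c("winter", "winter", "spring", "spring", "spring",
                      "summer", "summer", "summer", "autumn", "autumn",
                      "autumn", "winter")[sim2$records$month]))

  # with all systematic effects off, phenotypic variance ~ sa + spe + se
  cfg3 <- sim_config(seed = 12, n_founder_bucks = 200, n_founder_does = 2500,
                     n_generations = 1, lactation_range = c(1L, 1L),
                     genotype_effect_kg_per_gl = 0,
                     fixed_effect_sd = c(farm = 0, year = 0, month = 0,
                                         season = 0, birth_type = 0),
                     age_coeffs = c(b1 = 0, b2 = 0))
  sim3 <- simulate_lactation_dataset(simulate_pedigree(cfg3), NULL, cfg3)
  sp2 <- sum(default_variance_components()$milk)
  v <- stats::var(sim3$records$milk_kg)
  expect_lt(abs(v - sp2), 3 * sp2 * sqrt(2 / nrow(sim3$records)))
})

test_that("test-day expansion integrates back to the lactation total", {
  lac <- data.frame(doe_id = "a", parity = 1, milk_kg = 420, fat_kg = 21,
                    protein_kg = 14.7, dm_kg = 58.8)
  flat <- simulate_test_day_records(lac, sim_config(wood_shape = c(b = 0, c = 0)))
  expect_equal(nrow(flat), 7L)
  expect_true(all(abs(flat$daily_milk_kg - 2) < 1e-9))

  wood <- simulate_test_day_records(lac)
  rt <- standardize_lactation_210(wood)
  expect_lt(abs(rt$milk_kg - 420) / 420, 0.02)
  expect_equal(rt$fat_kg / rt$milk_kg, 21 / 420, tolerance = 1e-9)
})
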