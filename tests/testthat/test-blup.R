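test_that("single-record prediction follows the regression identity", {
  # one animal, known mean (no fixed effects), no permanent environment:
  # PBV = h2 * (y - mu)
  ped <- validate_pedigree(data.frame(animal_id = "d1", sire_id = "",
                                      dam_id = "", sex = "doe"))
  vc <- c(sigma_a2 = 4, sigma_pe2 = 0, sigma_e2 = 6)
  dm <- list(X = matrix(0, 1, 0), Za = Matrix::Matrix(1, 1, 1, sparse = TRUE),
             Zpe = Matrix::Matrix(1, 1, 1, sparse = TRUE),
             Y = matrix(10, 1, 1), animal_ids = "d1", pe_ids = "d1")
  sol <- solve_blup(dm, a_inverse_sparse(ped), vc)
  expect_equal(unname(sol$pbv), 0.4 * 10, tolerance = 1e-12)
})

test_that("MME solutions and PEV match the dense GLS oracle", {
  toy <- toy_design(seed = 13)
  sol <- solve_blup(toy$dm, a_inverse_sparse(toy$ped), toy$vc)
  oracle <- dense_gls_oracle(toy$dm$X, toy$dm$Za, toy$dm$Zpe, toy$dm$Y[, 1],
                             toy$A, toy$vc)
  expect_equal(sol$blue$estimate, oracle$b, tolerance = 1e-8)
  expect_equal(unname(sol$pbv), oracle$u, tolerance = 1e-8)
  expect_equal(unname(sol$pev), oracle$pev, tolerance = 1e-8)
})

test_that("no-information animals have PEV = sigma_a2 (1+F) and zero reliability", {
  # add an isolated founder to a pedigree with records on others
  raw <- rbind(trio_raw(),
               data.frame(animal_id = "iso", sire_id = "", dam_id = "",
                          sex = "doe", birth_year = 2001))
  ped <- validate_pedigree(raw)
  vc <- c(sigma_a2 = 5, sigma_pe2 = 0, sigma_e2 = 10)
  ids <- ped$ped$animal_id
  rec_does <- c("d1", "o1")
  n <- 4L
  doe_id <- rep(rec_does, each = 2)
  dm <- list(X = matrix(1, n, 1),
             Za = Matrix::sparseMatrix(i = seq_len(n),
                                       j = match(doe_id, ids), x = 1,
                                       dims = c(n, ped$n)),
             Zpe = Matrix::sparseMatrix(i = seq_len(n),
                                        j = match(doe_id, rec_does), x = 1,
                                        dims = c(n, 2L)),
             Y = matrix(c(12, 14, 9, 11), ncol = 1),
             animal_ids = ids, pe_ids = rec_does)
  sol <- solve_blup(dm, a_inverse_sparse(ped), vc)
  expect_equal(sol$pev[["iso"]], 5, tolerance = 1e-9)
  ra <- reliability_accuracy(sol$sep[["iso"]], 5)
  expect_equal(ra$R_AP, 0)
  expect_equal(ra$RTi, 0)
})

test_that("SEP decreases monotonically with the number of own records", {
  # single animal, known mean (no fixed effects): each extra record adds
  # information, PEV = (n/sigma_e2 + 1/sigma_a2)^-1
  ped <- validate_pedigree(data.frame(animal_id = "d1", sire_id = "",
                                      dam_id = "", sex = "doe"))
  Ainv <- a_inverse_sparse(ped)
  vc <- c(sigma_a2 = 4, sigma_pe2 = 0, sigma_e2 = 6)
  seps <- sapply(1:10, function(n) {
    dm <- list(X = matrix(0, n, 0),
               Za = Matrix::Matrix(1, n, 1, sparse = TRUE),
               Zpe = Matrix::Matrix(1, n, 1, sparse = TRUE),
               Y = matrix(rnorm(n, 10), ncol = 1),
               animal_ids = "d1", pe_ids = "d1")
    solve_blup(dm, Ainv, vc)$sep
  })
  expect_true(all(diff(seps) < 0))
  expect_equal(unname(seps), sqrt(1 / (1:10 / 6 + 1 / 4)), tolerance = 1e-9)
})

test_that("reliability and accuracy algebra reproduces the printed ranges", {
  buck_fat <- reliability_accuracy(2.21, 16.87)
  expect_equal(round(buck_fat$R_AP, 2), 0.71)
  expect_equal(round(buck_fat$RTi, 2), 0.84)
  doe_fat <- reliability_accuracy(1.55, 16.87)
  expect_equal(round(doe_fat$R_AP, 2), 0.86)
  perfect <- reliability_accuracy(0, 16.87)
  expect_equal(perfect$R_AP, 1)
  expect_equal(perfect$RTi, 1)
  expect_warning(reliability_accuracy(10, 4), "clipping")
})

test_that("confidence ranges carry the nominal normal coverage", {
  cr <- confidence_range(0, 1, k = 2)
  expect_equal(cr$lower, -2)
  expect_equal(cr$upper, 2)
  expect_equal(attr(cr, "coverage"), 2 * stats::pnorm(2) - 1)
  deg <- confidence_range(3.5, 0, k = 2)
  expect_equal(deg$lower, deg$upper)
  expect_error(confidence_range(0, 1, k = 0))
})

test_that("accuracy and reliability bands use lower-inclusive boundaries", {
  expect_equal(as.character(accuracy_band(0.84)), "medium/high")
  expect_equal(as.character(accuracy_band(0.50)), "medium")
  expect_equal(as.character(accuracy_band(c(0.2, 0.75, 0.90, 0.95))),
               c("preliminary", "medium/high", "true-BV-grade",
                 "true-BV-grade"))
  expect_equal(as.character(reliability_band(0.71)), "more than sufficient")
  expect_equal(as.character(reliability_band(0.30)), "poor")
  expect_equal(as.character(reliability_band(c(0.1, 0.55, 0.90))),
               c("unreliable", "sufficient", "very reliable"))
  sc <- interpret_scores(data.frame(RTi = 0.84, R_AP = 0.71))
  expect_equal(sc$accuracy_band, "medium/high")
  expect_equal(sc$reliability_band, "more than sufficient")
})

test_that("predictions are unbiased and accuracies match realized correlations", {
  cfg <- sim_config(seed = 17, n_founder_bucks = 11, n_founder_does = 52,
                    n_generations = 3, kids_per_doe = 3,
                    lactation_range = c(1L, 3L))
  ped <- simulate_pedigree(cfg)
  vc <- default_variance_components()$milk
  tbv <- simulate_breeding_values(ped, matrix(vc[["sigma_a2"]], 1, 1),
                                  seed = 18)
  ids <- ped$ped$animal_id
  does <- which(ped$ped$sex == "doe")
  set.seed(19)
  nlac <- sample(1:3, length(does), replace = TRUE)
  doe_id <- rep(ids[does], nlac)
  pe <- rep(rnorm(length(does), 0, sqrt(vc[["sigma_pe2"]])), nlac)
  y <- 416 + rep(tbv[does, 1], nlac) + pe +
    rnorm(length(doe_id), 0, sqrt(vc[["sigma_e2"]]))
  n <- length(y)
  dm <- list(X = matrix(1, n, 1),
             Za = Matrix::sparseMatrix(i = seq_len(n),
                                       j = match(doe_id, ids), x = 1,
                                       dims = c(n, ped$n)),
             Zpe = Matrix::sparseMatrix(i = seq_len(n),
                                        j = match(doe_id, unique(doe_id)),
                                        x = 1,
                                        dims = c(n, length(unique(doe_id)))),
             Y = matrix(y, ncol = 1), animal_ids = ids,
             pe_ids = unique(doe_id))
  sol <- solve_blup(dm, a_inverse_sparse(ped), vc)

  fit <- stats::lm(tbv[, 1] ~ sol$pbv)
  slope_se <- summary(fit)$coefficients[2, "Std. Error"]
  expect_lt(abs(stats::coef(fit)[[2]] - 1), 3 * slope_se)

  ra <- reliability_accuracy(sol$sep, vc[["sigma_a2"]], F = ped$inbreeding)
  expect_lt(abs(stats::cor(tbv[, 1], sol$pbv) - mean(ra$RTi)), 0.1)

  ev <- evaluation_table(sol, ped)
  expect_setequal(names(ev)[1:8],
                  c("animal_id", "sex", "PBV", "SEP", "RTi", "R_AP",
                    "n_records", "n_offspring"))
  expect_true(all(ev$R_AP >= 0 & ev$R_AP <= 1))
  expect_equal(ev$R_AP, ev$RTi^2, tolerance = 1e-9)
})

test_that("empirical coverage of PBV +/- k SEP is nominal", {
  cv <- sep_coverage_simulation(seed = 3, n_replicates = 4)
  expect_lt(abs(cv[["k2"]] - 95), 3)
  expect_lt(abs(cv[["k1"]] - 68), 4)
})
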