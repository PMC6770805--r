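test_that("design matrices encode the model with reference-level constraints", {
  ped <- validate_pedigree(data.frame(animal_id = c("d1", "d2"),
                                      sire_id = "", dam_id = "",
                                      sex = "doe"))
  one <- data.frame(doe_id = "d1", farm = 1, year = 2010, month = 6,
                    season = "summer", birth_type = 1, genotype_class = "AA",
                    age_months = 30, milk_kg = 400)
  dm <- build_design_matrices(one, model_spec("milk"), ped)
  expect_equal(ncol(dm$X), 1L)           # intercept only after aliasing
  expect_equal(dim(dm$Za), c(1L, 2L))

  set.seed(8)
  rec <- data.frame(doe_id = rep(c("d1", "d2"), 6),
                    farm = 1, year = 2010, month = 6, season = "summer",
                    birth_type = 1,
                    genotype_class = rep(c("AA", "BA", "BB"), 4),
                    age_months = stats::runif(12, 20, 60),
                    milk_kg = stats::rnorm(12, 400, 30))
  dm_in <- build_design_matrices(rec, model_spec("milk"), ped)
  dm_ex <- build_design_matrices(rec, model_spec("milk", include_genotype = FALSE),
                                 ped)
  expect_equal(ncol(dm_in$X) - ncol(dm_ex$X), 2L)  # 3 observed classes - 1

  # hand-built toy: one factor with 2 levels + centred age + age^2
  toy <- data.frame(doe_id = c("d1", "d1", "d2", "d2", "d1", "d2"),
                    grp = c("u", "u", "v", "v", "u", "v"),
                    age_months = c(20, 30, 40, 50, 60, 70),
                    milk_kg = 1:6)
  spc <- model_spec("milk", include_genotype = FALSE, fixed_factors = "grp")
  dmt <- build_design_matrices(toy, spc, ped)
  ac <- toy$age_months - mean(toy$age_months)
  Xhand <- cbind(1, c(0, 0, 1, 1, 0, 1), ac, ac^2)
  expect_equal(unname(dmt$X), Xhand, ignore_attr = TRUE)
  expect_error(build_design_matrices(toy[0, ], spc, ped), "no records")
})

test_that("MME-based REML log-likelihood equals the dense-V form", {
  toy <- toy_design(seed = 5)
  dm <- toy$dm
  for (pars in list(c(4, 2, 6), c(8, 1, 3), c(2, 5, 9))) {
    mine <- with(list(), {
      fit0 <- reml_fit(dm, a_inverse_sparse(toy$ped),
                       start = list(G0 = pars[1], P0 = pars[2], R0 = pars[3]),
                       max_iter = 1L, tol = Inf, method = "em")
      fit0$loglik_trace[1]
    })
    oracle <- dense_reml_ll(dm$X, dm$Za, dm$Zpe, dm$Y[, 1], toy$A,
                            pars[1], pars[2], pars[3])
    expect_equal(mine, as.numeric(oracle), tolerance = 1e-8)
  }
})

test_that("REML maximum agrees with a dense grid search on a tiny dataset", {
  toy <- toy_design(seed = 7)
  dm <- toy$dm
  Ainv <- a_inverse_sparse(toy$ped)
  fit <- reml_fit(dm, Ainv, tol = 1e-12, max_iter = 300)
  ll_fit <- dense_reml_ll(dm$X, dm$Za, dm$Zpe, dm$Y[, 1], toy$A,
                          fit$vc[["sigma_a2"]], max(fit$vc[["sigma_pe2"]], 1e-8),
                          fit$vc[["sigma_e2"]])
  grid <- expand.grid(sa = seq(0.5, 12, length.out = 9),
                      sp = seq(0.2, 8, length.out = 9),
                      se = seq(0.5, 12, length.out = 9))
  lls <- mapply(function(sa, sp, se)
    dense_reml_ll(dm$X, dm$Za, dm$Zpe, dm$Y[, 1], toy$A, sa, sp, se),
    grid$sa, grid$sp, grid$se)
  expect_gte(as.numeric(ll_fit), max(lls) - 1e-6)
  # and the fitted point is within one grid cell of the grid argmax
  best <- grid[which.max(lls), ]
  expect_lt(abs(fit$vc[["sigma_a2"]] - best$sa), diff(range(grid$sa)) / 8 + 1e-6)
  expect_lt(abs(fit$vc[["sigma_e2"]] - best$se), diff(range(grid$se)) / 8 + 1e-6)
})

test_that("EM iterations never decrease the restricted likelihood", {
  d <- sim_dataset(seed = 21, n_founder_bucks = 5, n_founder_does = 25,
                   n_generations = 2, kids_per_doe = 2)
  dm <- build_design_matrices(d$records,
                              model_spec("milk", include_genotype = FALSE),
                              d$ped)
  fit <- reml_fit(dm, d$Ainv, method = "em", max_iter = 60, tol = 1e-12)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # the AI-accelerated path is safeguarded to the same property
  fit2 <- reml_fit(dm, d$Ainv, max_iter = 120, tol = 1e-10)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-6))
  expect_true(fit2$converged)
})

test_that("a zero permanent-environment truth is recovered as near-zero", {
  # PE is separable from the additive effect only through the pedigree, so
  # the check uses related does with repeated records; the estimate should
  # collapse to a small fraction of the phenotypic variance
  vc0 <- default_variance_components()
  vc0$milk["sigma_pe2"] <- 0
  frac <- sapply(31:33, function(s) {
    d <- sim_dataset(seed = s, n_founder_bucks = 8, n_founder_does = 50,
                     n_generations = 3, kids_per_doe = 3,
                     lactation_range = c(2L, 5L),
                     variance_components = vc0)
    dm <- suppressMessages(build_design_matrices(
      d$records, model_spec("milk", include_genotype = FALSE), d$ped))
    fit <- reml_fit(dm, d$Ainv, max_iter = 80)
    fit$vc[["sigma_pe2"]] / fit$vc[["sigma_p2"]]
  })
  expect_lt(mean(frac), 0.05)
})

test_that("estimates are invariant to record order", {
  d <- sim_dataset(seed = 41, n_founder_bucks = 4, n_founder_does = 20,
                   n_generations = 2, kids_per_doe = 2)
  spc <- model_spec("milk", include_genotype = FALSE)
  dm1 <- build_design_matrices(d$records, spc, d$ped)
  set.seed(1)
  perm <- sample(nrow(d$records))
  dm2 <- build_design_matrices(d$records[perm, ], spc, d$ped)
  f1 <- reml_fit(dm1, d$Ainv, max_iter = 50, tol = 1e-10)
  f2 <- reml_fit(dm2, d$Ainv, max_iter = 50, tol = 1e-10)
  expect_equal(f1$vc, f2$vc, tolerance = 1e-6)
})

test_that("bivariate REML recovers genetic correlations", {
  # construct a well-identified truth: r_G = 0.9, moderate PE, r_E = 0.3
  vc <- list(milk = c(sigma_a2 = 100, sigma_pe2 = 40, sigma_e2 = 120),
             fat = c(sigma_a2 = 80, sigma_pe2 = 30, sigma_e2 = 100),
             protein = c(sigma_a2 = 60, sigma_pe2 = 25, sigma_e2 = 90),
             dm = c(sigma_a2 = 50, sigma_pe2 = 20, sigma_e2 = 80))
  Rg <- default_trait_correlations()
  Rg[] <- diag(4); Rg["fat", "protein"] <- Rg["protein", "fat"] <- 0.9
  Re <- default_trait_correlations()
  Re[] <- diag(4); Re["fat", "protein"] <- Re["protein", "fat"] <- 0.3
  Rp <- Re
  d <- sim_dataset(seed = 51, n_founder_bucks = 8, n_founder_does = 45,
                   n_generations = 3, kids_per_doe = 3,
                   lactation_range = c(1L, 3L),
                   variance_components = vc, genetic_correlations = Rg,
                   pe_correlations = Rp, residual_correlations = Re)
  dm <- suppressMessages(build_design_matrices(
    d$records, model_spec(c("fat", "protein"), include_genotype = FALSE),
    d$ped))
  fit <- reml_fit(dm, d$Ainv, max_iter = 80, tol = 1e-9)
  cr <- correlations(fit)
  expect_lt(abs(cr$r_G - 0.9), 0.15)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))

  # independent traits come back near zero
  Rg0 <- Rg; Rg0["fat", "protein"] <- Rg0["protein", "fat"] <- 0
  Re0 <- Re; Re0["fat", "protein"] <- Re0["protein", "fat"] <- 0
  d0 <- sim_dataset(seed = 61, n_founder_bucks = 8, n_founder_does = 45,
                    n_generations = 3, kids_per_doe = 3,
                    lactation_range = c(1L, 3L),
                    variance_components = vc, genetic_correlations = Rg0,
                    pe_correlations = Re0, residual_correlations = Re0)
  dm0 <- suppressMessages(build_design_matrices(
    d0$records, model_spec(c("fat", "protein"), include_genotype = FALSE),
    d0$ped))
  fit0 <- reml_fit(dm0, d0$Ainv, max_iter = 80, tol = 1e-9)
  expect_lt(abs(correlations(fit0)$r_G), 0.15)
})

test_that("derived genetic parameters follow their defining ratios", {
  expect_equal(round(heritability(c(sigma_a2 = 11511.83, sigma_pe2 = 1689.51,
                                    sigma_e2 = 15578.23)), 2), 0.40)
  expect_equal(round(heritability(c(sigma_a2 = 9.45, sigma_pe2 = 0.36,
                                    sigma_e2 = 8.14)), 2), 0.53)
  expect_equal(heritability(c(sigma_a2 = 0, sigma_pe2 = 1, sigma_e2 = 1)), 0)
  expect_error(heritability(c(sigma_a2 = 0, sigma_pe2 = 0, sigma_e2 = 0)),
               "phenotypic")

  vc <- c(sigma_a2 = 11511.83, sigma_pe2 = 1689.51, sigma_e2 = 15578.23)
  expect_equal(repeatability(vc), (11511.83 + 1689.51) / 28779.57,
               tolerance = 1e-6)
  expect_equal(repeatability(c(sigma_a2 = 2, sigma_pe2 = 0, sigma_e2 = 3)),
               heritability(c(sigma_a2 = 2, sigma_pe2 = 0, sigma_e2 = 3)))
  expect_equal(repeatability(c(sigma_a2 = 2, sigma_pe2 = 3, sigma_e2 = 0)), 1)

  # correlation algebra on random PSD blocks vs the direct formula
  set.seed(9)
  for (i in 1:5) {
    L <- matrix(rnorm(4), 2); G0 <- crossprod(L) + diag(0.1, 2)
    L2 <- matrix(rnorm(4), 2); P0 <- crossprod(L2) + diag(0.1, 2)
    L3 <- matrix(rnorm(4), 2); R0 <- crossprod(L3) + diag(0.1, 2)
    cr <- correlations(list(G0 = G0, P0 = P0, R0 = R0))
    expect_equal(cr$r_G, G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2]))
    S <- G0 + P0 + R0
    expect_equal(cr$r_P, S[1, 2] / sqrt(S[1, 1] * S[2, 2]))
  }
  z <- correlations(list(G0 = matrix(c(2, 0, 0, 3), 2),
                         P0 = diag(0, 2), R0 = diag(1, 2)))
  expect_equal(z$r_G, 0)
  o <- correlations(list(G0 = matrix(c(2, sqrt(6), sqrt(6), 3), 2),
                         P0 = diag(0, 2), R0 = diag(0, 2)))
  expect_equal(o$r_G, 1)
})

test_that("information-based standard errors shrink with sample size", {
  h2se <- sapply(c(25, 80), function(nd) {
    d <- sim_dataset(seed = 71, n_founder_bucks = 5, n_founder_does = nd,
                     n_generations = 2, kids_per_doe = 2,
                     lactation_range = c(2L, 3L))
    dm <- build_design_matrices(d$records,
                                model_spec("milk", include_genotype = FALSE),
                                d$ped)
    fit <- reml_fit(dm, d$Ainv, max_iter = 60, tol = 1e-9)
    fit$h2_se
  })
  expect_true(is.finite(h2se[1]) && is.finite(h2se[2]))
  expect_lt(h2se[2], h2se[1])
})
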