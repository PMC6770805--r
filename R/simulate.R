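#' Default per-trait variance components
#'
#' Additive, permanent-environment and residual variances (kg^2) for the four
#' lactation traits, at the values used throughout the package as the
#' simulation truth for 210-day milk, fat, protein and dry-matter yields of
#' Murciano-Granadina goats under the genotype-inclusive evaluation.
#'
#' @return Named list; each element is `c(sigma_a2, sigma_pe2, sigma_e2)`.
#' @export
default_variance_components <- function() {
  list(milk    = c(sigma_a2 = 11511.83, sigma_pe2 = 1689.51, sigma_e2 = 15578.23),
       fat     = c(sigma_a2 = 16.87,    sigma_pe2 = 16.22,   sigma_e2 = 25.74),
       protein = c(sigma_a2 = 9.45,     sigma_pe2 = 0.36,    sigma_e2 = 8.14),
       dm      = c(sigma_a2 = 57.45,    sigma_pe2 = 82.03,   sigma_e2 = 211.58))
}

#' Default trait correlation matrix
#'
#' Weak correlations between milk and the component yields and a strong
#' fat-protein correlation, as is typical for dairy goat 210-day yields.
#' Used as the default for the genetic, permanent-environment and residual
#' correlation structure of the simulator.
#'
#' @return 4x4 correlation matrix over (milk, fat, protein, dm).
#' @export
default_trait_correlations <- function() {
  tr <- c("milk", "fat", "protein", "dm")
  R <- diag(4)
  dimnames(R) <- list(tr, tr)
  R["milk", "fat"] <- R["fat", "milk"] <- 0.01
  R["milk", "protein"] <- R["protein", "milk"] <- -0.02
  R["milk", "dm"] <- R["dm", "milk"] <- 0.01
  R["fat", "protein"] <- R["protein", "fat"] <- 0.97
  R["fat", "dm"] <- R["dm", "fat"] <- -0.09
  R["protein", "dm"] <- R["dm", "protein"] <- 0.14
  R
}

# alpha-S1 casein output (g per litre of milk) contributed by one allele:
# strong 3.6, medium 1.6, weak 0.6, null 0.
casein_allele_output <- c(A = 3.6, B = 3.6, E = 1.6, F = 0.6, N = 0)

#' Default CSN1S1 genotype effects on the four traits
#'
#' Additive per-class shifts (kg per 210-day lactation) scaled from the
#' strong/medium/weak/null alpha-S1 casein protein outputs (3.6/1.6/0.6/0 g
#' per litre per allele): the protein and dry-matter shifts are proportional
#' to the summed allelic output, milk and fat are unaffected by default.
#' The scale is configurable; these defaults are placeholders in the absence
#' of published per-class estimates.
#'
#' @param classes Character vector of genotype class labels.
#' @param kg_per_gl Shift in protein kg per g/L of summed allelic output.
#' @return Matrix `length(classes) x 4` (milk, fat, protein, dm), rownames =
#'   classes.
#' @export
casein_genotype_effects <- function(classes, kg_per_gl = 0.2) {
  alle <- strsplit(classes, "")
  content <- vapply(alle, function(a) sum(casein_allele_output[a]), numeric(1))
  eff <- cbind(milk = 0 * content, fat = 0 * content,
               protein = kg_per_gl * content, dm = kg_per_gl * content)
  rownames(eff) <- classes
  eff
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' structure of the Murciano-Granadina breeding-program data the package is
#' designed around: 59 farms, parturition years 2005-2016, parturition months
#' May-December, four seasons, birth types 1-5 kids, one to six lactations
#' per doe, five CSN1S1 alleles, and trait means/variances at the breed
#' reference values.
#'
#' @param n_founder_bucks,n_founder_does Founder counts.
#' @param n_generations Total generations including founders (>= 1).
#' @param kids_per_doe Offspring per dam per generation.
#' @param prop_male Probability an offspring is a buck.
#' @param lactation_range Integer range of repeated lactations per doe.
#' @param allele_freqs Named frequencies over alleles A, B, E, F, N (sum 1).
#' @param genotype_effect_kg_per_gl Scale of the genotype class effects; see
#'   [casein_genotype_effects()]. Set 0 for a null genotype effect.
#' @param mu Named per-trait overall means (kg).
#' @param variance_components Named list per trait,
#'   `c(sigma_a2, sigma_pe2, sigma_e2)`.
#' @param genetic_correlations,pe_correlations,residual_correlations 4x4
#'   correlation matrices over (milk, fat, protein, dm).
#' @param n_farms,years,months,birth_types Fixed-effect level sets.
#' @param fixed_effect_sd Named fractions of the phenotypic SD used as the
#'   spread of the farm, year, month, season and birth-type effects.
#' @param age_coeffs `c(b1, b2)`: linear and quadratic regression on age in
#'   months (centred at `age_center`), as kg per month (per month^2).
#' @param age_center Centring constant for the age covariate (months).
#' @param age_first_range Range of the age at first parturition (months).
#' @param wood_shape `c(b, c)` of the Wood lactation curve t^b exp(-c t).
#' @param seed Integer seed; every downstream draw is reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founder_bucks = 14L,
                       n_founder_does = 70L,
                       n_generations = 3L,
                       kids_per_doe = 3L,
                       prop_male = 0.2,
                       lactation_range = c(1L, 6L),
                       allele_freqs = c(A = 0.2, B = 0.2, E = 0.2, F = 0.2, N = 0.2),
                       genotype_effect_kg_per_gl = 0.2,
                       mu = c(milk = 416.0, fat = 19.54, protein = 13.25, dm = 52.33),
                       variance_components = default_variance_components(),
                       genetic_correlations = default_trait_correlations(),
                       pe_correlations = default_trait_correlations(),
                       residual_correlations = default_trait_correlations(),
                       n_farms = 59L,
                       years = 2005:2016,
                       months = 5:12,
                       birth_types = 1:5,
                       fixed_effect_sd = c(farm = 0.4, year = 0.25, month = 0.15,
                                           season = 0.10, birth_type = 0.10),
                       age_coeffs = c(b1 = 0.8, b2 = -0.01),
                       age_center = 35,
                       age_first_range = c(14, 40),
                       wood_shape = c(b = 0.15, c = 0.004),
                       seed = 1L) {
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1")
  }
  for (R in list(genetic_correlations, pe_correlations, residual_correlations)) {
    if (!isSymmetric(unname(R)) || min(eigen(R, symmetric = TRUE,
                                             only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrices must be symmetric positive semi-definite")
    }
  }
  if (any(unlist(variance_components) < 0)) stop("variances must be >= 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

traits4 <- c("milk", "fat", "protein", "dm")

# trait x trait covariance block from per-trait variances (index 1..3 picks
# sigma_a2 / sigma_pe2 / sigma_e2) and a correlation matrix
vc_block <- function(variance_components, corr, which) {
  sd <- sqrt(vapply(variance_components[traits4], `[[`, numeric(1), which))
  S <- outer(sd, sd) * corr[traits4, traits4]
  dimnames(S) <- list(traits4, traits4)
  S
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders are unrelated; each later generation is produced by mating every
#' dam of the previous generation to a randomly drawn buck from any earlier
#' generation. Offspring sex is Bernoulli(`prop_male`). Fully reproducible
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return A validated `goat_pedigree`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_founder_bucks < 1L || config$n_founder_does < 1L) {
    stop("need at least one founder of each sex")
  }
  local_seed(config$seed, {
    id <- function(k) sprintf("A%05d", k)
    nb <- config$n_founder_bucks; nd <- config$n_founder_does
    base_year <- min(config$years) - 2L
    rows <- data.frame(
      animal_id = id(seq_len(nb + nd)),
      sire_id = "", dam_id = "",
      sex = c(rep("buck", nb), rep("doe", nd)),
      birth_year = base_year,
      stringsAsFactors = FALSE)
    bucks <- rows$animal_id[rows$sex == "buck"]
    dams <- rows$animal_id[rows$sex == "doe"]
    nxt <- nb + nd + 1L
    if (config$n_generations > 1L) {
      for (g in 2:config$n_generations) {
        yr <- base_year + 2L * (g - 1L)
        kid_rows <- vector("list", length(dams))
        for (j in seq_along(dams)) {
          s <- sample(bucks, 1L)
          nk <- config$kids_per_doe
          sexes <- ifelse(stats::runif(nk) < config$prop_male, "buck", "doe")
          kid_rows[[j]] <- data.frame(
            animal_id = id(seq.int(nxt, length.out = nk)),
            sire_id = s, dam_id = dams[j], sex = sexes, birth_year = yr,
            stringsAsFactors = FALSE)
          nxt <- nxt + nk
        }
        kids <- do.call(rbind, kid_rows)
        if (!any(kids$sex == "buck")) {  # keep the line breedable
          kids$sex[1L] <- "buck"
        }
        rows <- rbind(rows, kids)
        bucks <- c(bucks, kids$animal_id[kids$sex == "buck"])
        dams <- kids$animal_id[kids$sex == "doe"]
      }
    }
    validate_pedigree(rows)
  })
}

# fixed lookup from unordered allele pairs to the class labels used in the
# field (note BA, not AB)
genotype_class_label <- function(a1, a2) {
  p <- ifelse(a1 <= a2, paste0(a1, a2), paste0(a2, a1))
  ifelse(p == "AB", "BA", p)
}

#' Drop single-locus genotypes through a pedigree
#'
#' Founders are drawn from Hardy-Weinberg proportions at the supplied allele
#' frequencies; every non-founder inherits one allele from each parent
#' uniformly at random, so Mendelian consistency is guaranteed by
#' construction.
#'
#' @param pedigree A `goat_pedigree`.
#' @param allele_freqs Named allele frequencies summing to 1.
#' @param seed Integer seed.
#' @return Data frame: `animal_id`, `allele1`, `allele2`, `genotype_class`.
#' @export
drop_genotypes <- function(pedigree, allele_freqs, seed = 1L) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  if (abs(sum(allele_freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1")
  }
  n <- pedigree$n
  ped <- pedigree$ped
  alleles <- names(allele_freqs)
  local_seed(seed, {
    a1 <- character(n); a2 <- character(n)
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      a1[i] <- if (s > 0L) {
        if (stats::runif(1) < 0.5) a1[s] else a2[s]
      } else sample(alleles, 1L, prob = allele_freqs)
      a2[i] <- if (d > 0L) {
        if (stats::runif(1) < 0.5) a1[d] else a2[d]
      } else sample(alleles, 1L, prob = allele_freqs)
    }
    data.frame(animal_id = ped$animal_id, allele1 = a1, allele2 = a2,
               genotype_class = genotype_class_label(a1, a2),
               stringsAsFactors = FALSE)
  })
}

#' Percentage of polymorphic markers
#'
#' A marker is monomorphic when only a single allele is observed across all
#' animals. Returns `100 * (n_markers - n_monomorphic) / n_markers`.
#'
#' @param marker_matrix Animals x markers matrix. Character entries are
#'   two-letter genotype calls (e.g. `"AB"`); numeric entries are biallelic
#'   dosages 0/1/2 (monomorphic = every call the same homozygote).
#' @return Percentage of polymorphic markers.
#' @export
polymorphism_summary <- function(marker_matrix) {
  if (is.null(dim(marker_matrix)) || ncol(marker_matrix) == 0L ||
      nrow(marker_matrix) == 0L) {
    stop("empty marker matrix")
  }
  mono <- apply(marker_matrix, 2L, function(col) {
    col <- col[!is.na(col)]
    if (is.numeric(col)) {
      length(unique(col)) == 1L && col[1L] %in% c(0, 2)
    } else {
      length(unique(unlist(strsplit(as.character(col), "")))) == 1L
    }
  })
  100 * (length(mono) - sum(mono)) / length(mono)
}

#' Simulate true breeding values by recursive gene flow
#'
#' Founders are drawn from N(0, G0); every non-founder receives the parent
#' average plus a Mendelian-sampling deviation with covariance d_i * G0,
#' where d_i accounts for parental inbreeding (and for unknown parents).
#' The resulting vectors are exactly MVN(0, A kron G0).
#'
#' @param pedigree A `goat_pedigree`.
#' @param G0 Additive covariance matrix between traits (a scalar is treated
#'   as a 1x1 matrix).
#' @param seed Integer seed.
#' @return Matrix animals x traits of true breeding values, rownames =
#'   animal ids.
#' @export
simulate_breeding_values <- function(pedigree, G0, seed = 1L) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  G0 <- as.matrix(G0)
  ev <- eigen(G0, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("G0 must be positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(G0)) # G0 = L L'
  n <- pedigree$n
  t_ <- nrow(G0)
  ped <- pedigree$ped
  d <- mendelian_d(ped$sire, ped$dam, pedigree$inbreeding)
  local_seed(seed, {
    Z <- matrix(stats::rnorm(n * t_), n, t_)
    tbv <- matrix(0, n, t_)
    for (i in seq_len(n)) {
      pa <- numeric(t_)
      if (ped$sire[i] > 0L) pa <- pa + 0.5 * tbv[ped$sire[i], ]
      if (ped$dam[i] > 0L)  pa <- pa + 0.5 * tbv[ped$dam[i], ]
      tbv[i, ] <- pa + sqrt(d[i]) * as.vector(L %*% Z[i, ])
    }
    rownames(tbv) <- ped$animal_id
    colnames(tbv) <- colnames(G0)
    tbv
  })
}

month_to_season <- function(month) {
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}

#' Simulate a repeated-records lactation dataset
#'
#' Generates, for every doe in the pedigree, 1-6 (configurable) standardized
#' 210-day lactation records for the four traits jointly under the animal
#' model: overall mean + farm + year + month + season + birth-type +
#' genotype-class effect + linear and quadratic age + true breeding value +
#' a permanent-environment effect constant across the doe's lactations +
#' a fresh residual per record.
#'
#' @param pedigree A `goat_pedigree`.
#' @param genotypes Output of [drop_genotypes()] (or `NULL` to drop them
#'   with the config seed).
#' @param config A [sim_config()].
#' @return A list of class `goat_simulation`: `records` (one row per doe x
#'   parity with trait yields in kg and all fixed-effect labels), `tbv`
#'   (animals x traits), `pe` (does x traits), `genotypes`, `pedigree`,
#'   `effects` (the drawn fixed-effect level values).
#' @export
simulate_lactation_dataset <- function(pedigree, genotypes = NULL, config) {
  stopifnot(inherits(pedigree, "goat_pedigree"), inherits(config, "sim_config"))
  vc <- config$variance_components
  Ga <- vc_block(vc, config$genetic_correlations, "sigma_a2")
  Gp <- vc_block(vc, config$pe_correlations, "sigma_pe2")
  Re <- vc_block(vc, config$residual_correlations, "sigma_e2")
  if (is.null(genotypes)) {
    genotypes <- drop_genotypes(pedigree, config$allele_freqs,
                                seed = config$seed + 1L)
  }
  tbv <- simulate_breeding_values(pedigree, Ga, seed = config$seed + 2L)
  colnames(tbv) <- traits4
  ped <- pedigree$ped
  does <- which(ped$sex == "doe")
  if (length(does) == 0L) stop("no does in pedigree")
  gmap <- stats::setNames(genotypes$genotype_class, genotypes$animal_id)
  if (anyNA(gmap[ped$animal_id[does]])) stop("missing genotype for a doe")
  eff_classes <- sort(unique(genotypes$genotype_class))
  gen_eff <- casein_genotype_effects(eff_classes,
                                     config$genotype_effect_kg_per_gl)
  sd_p <- sqrt(vapply(vc[traits4], sum, numeric(1)))  # phenotypic SD

  local_seed(config$seed + 3L, {
    draw_levels <- function(levels, frac) {
      m <- matrix(stats::rnorm(length(levels) * 4), length(levels), 4)
      m <- sweep(m, 2L, frac * sd_p, `*`)
      dimnames(m) <- list(as.character(levels), traits4)
      m
    }
    fsd <- config$fixed_effect_sd
    effects <- list(
      farm = draw_levels(seq_len(config$n_farms), fsd[["farm"]]),
      year = draw_levels(config$years, fsd[["year"]]),
      month = draw_levels(config$months, fsd[["month"]]),
      season = draw_levels(c("winter", "spring", "summer", "autumn"),
                           fsd[["season"]]),
      birth_type = draw_levels(config$birth_types, fsd[["birth_type"]]))

    pe_chol <- chol_psd(Gp)
    re_chol <- chol_psd(Re)
    nd <- length(does)
    pe <- matrix(stats::rnorm(nd * 4), nd, 4) %*% pe_chol
    rownames(pe) <- ped$animal_id[does]
    colnames(pe) <- traits4

    rows <- vector("list", nd)
    for (j in seq_len(nd)) {
      i <- does[j]
      n_lac <- sample(seq.int(config$lactation_range[1L],
                              config$lactation_range[2L]), 1L)
      farm <- sample.int(config$n_farms, 1L)
      btype <- sample(config$birth_types, 1L)
      age1 <- stats::runif(1, config$age_first_range[1L],
                           config$age_first_range[2L])
      ages <- age1 + 12 * (seq_len(n_lac) - 1L)
      mon <- sample(config$months, n_lac, replace = TRUE)
      yr0 <- if (is.na(ped$birth_year[i])) min(config$years) else ped$birth_year[i]
      yrs <- pmin(max(config$years), pmax(min(config$years),
                                          yr0 + floor(ages / 12)))
      e <- matrix(stats::rnorm(n_lac * 4), n_lac, 4) %*% re_chol
      ac <- ages - config$age_center
      agev <- outer(config$age_coeffs[["b1"]] * ac +
                    config$age_coeffs[["b2"]] * ac^2,
                    config$mu[traits4] / config$mu[["milk"]])
      gcl <- gmap[[ped$animal_id[i]]]
      y <- matrix(rep(config$mu[traits4], each = n_lac), n_lac, 4) + e
      y <- sweep(y, 2L, effects$farm[farm, ], `+`)
      y <- y + effects$year[as.character(yrs), , drop = FALSE]
      y <- y + effects$month[as.character(mon), , drop = FALSE]
      y <- y + effects$season[month_to_season(mon), , drop = FALSE]
      y <- sweep(y, 2L, effects$birth_type[as.character(btype), ], `+`)
      y <- sweep(y, 2L, gen_eff[gcl, ], `+`)
      y <- y + agev
      y <- sweep(y, 2L, tbv[i, ] + pe[j, ], `+`)
      rows[[j]] <- data.frame(
        doe_id = ped$animal_id[i], parity = seq_len(n_lac),
        milk_kg = y[, 1L], fat_kg = y[, 2L], protein_kg = y[, 3L],
        dm_kg = y[, 4L],
        farm = farm, year = yrs, month = mon,
        season = month_to_season(mon), birth_type = btype,
        genotype_class = gcl, age_months = ages,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    out <- list(records = records, tbv = tbv, pe = pe, genotypes = genotypes,
                pedigree = pedigree, effects = effects, config = config)
    class(out) <- "goat_simulation"
    out
  })
}

#' @export
print.goat_simulation <- function(x, ...) {
  cat("<goat_simulation>", nrow(x$records), "lactation records on",
      length(unique(x$records$doe_id)), "does;",
      x$pedigree$n, "pedigree animals\n")
  invisible(x)
}

# upper-triangular factor of a PSD matrix (chol with eigen fallback for
# semi-definite blocks)
chol_psd <- function(S) {
  ok <- try(chol(S), silent = TRUE)
  if (!inherits(ok, "try-error")) return(ok)
  ev <- eigen(S, symmetric = TRUE)
  t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)))
}

#' Expand a standardized lactation into seven test-day measurements
#'
#' Emits daily-yield observations at days 30, 60, ..., 210 following a Wood
#' incomplete-gamma lactation curve `t^b exp(-c t)` scaled so that its
#' 210-day integral equals the record's total milk. Component percentages
#' are constant across the lactation at the record's milk-weighted values.
#'
#' @param lactation One-row data frame (or list) with `doe_id`, `parity`,
#'   `milk_kg`, `fat_kg`, `protein_kg`, `dm_kg`.
#' @param config A [sim_config()] (for the curve shape), or `NULL` for the
#'   default shape.
#' @return Data frame of 7 rows: `doe_id`, `parity`, `day_in_milk`,
#'   `daily_milk_kg`, `fat_pct`, `protein_pct`, `dm_pct`.
#' @export
simulate_test_day_records <- function(lactation, config = NULL) {
  shape <- if (is.null(config)) c(b = 0.15, c = 0.004) else config$wood_shape
  b <- shape[[1L]]; cc <- shape[[2L]]
  wood <- function(t) t^b * exp(-cc * t)
  days <- seq(30, 210, by = 30)
  total <- lactation$milk_kg
  integral <- stats::integrate(wood, 0, 210, rel.tol = 1e-10)$value
  a <- total / integral
  daily <- a * wood(days)
  data.frame(doe_id = lactation$doe_id, parity = lactation$parity,
             day_in_milk = days, daily_milk_kg = daily,
             fat_pct = 100 * lactation$fat_kg / total,
             protein_pct = 100 * lactation$protein_kg / total,
             dm_pct = 100 * lactation$dm_kg / total,
             stringsAsFactors = FALSE)
}
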