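#' Descriptive statistics of PBVs (and scores) by sex
#'
#' Min, max, median, adjusted sample skewness and kurtosis of each numeric
#' parameter column, split by sex — the layout of the standard two-model
#' evaluation report.
#'
#' @param evaluation An [evaluation_table()] data frame (columns `sex` plus
#'   numeric parameters such as `PBV`, `SEP`, `RTi`, `R_AP`).
#' @param params Parameter columns to summarise.
#' @return Data frame: `sex`, `parameter`, `min`, `max`, `median`,
#'   `skewness`, `kurtosis`, `n`.
#' @export
pbv_descriptives_by_sex <- function(evaluation,
                                    params = c("PBV", "SEP", "RTi", "R_AP")) {
  params <- intersect(params, names(evaluation))
  sexes <- unique(evaluation$sex)
  if (any(is.na(sexes))) stop("missing sex labels")
  rows <- list()
  for (s in sexes) {
    sub <- evaluation[evaluation$sex == s, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty sex stratum: ", s)
    for (pcol in params) {
      v <- sub[[pcol]]
      rows[[length(rows) + 1L]] <- data.frame(
        sex = s, parameter = pcol,
        min = min(v), max = max(v), median = stats::median(v),
        skewness = if (length(v) > 2L) e1071::skewness(v, type = 2) else NA_real_,
        kurtosis = if (length(v) > 3L) e1071::kurtosis(v, type = 2) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two models' PBVs
#'
#' @param pbv_a,pbv_b PBV vectors over the same animal set (names, when
#'   present, are used to align them).
#' @return List: `r`, `p_value`, `n`.
#' @export
pbv_correlation <- function(pbv_a, pbv_b) {
  if (!is.null(names(pbv_a)) && !is.null(names(pbv_b))) {
    pbv_b <- pbv_b[names(pbv_a)]
  }
  stopifnot(length(pbv_a) == length(pbv_b))
  if (stats::sd(pbv_a) == 0 || stats::sd(pbv_b) == 0) {
    stop("zero-variance PBV vector")
  }
  ct <- stats::cor.test(pbv_a, pbv_b)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(pbv_a))
}

#' OLS regression of one model's PBVs on the other's
#'
#' @inheritParams pbv_correlation
#' @return List: `slope`, `intercept`, `r_squared`.
#' @export
pbv_regression <- function(pbv_a, pbv_b) {
  if (!is.null(names(pbv_a)) && !is.null(names(pbv_b))) {
    pbv_b <- pbv_b[names(pbv_a)]
  }
  if (stats::sd(pbv_a) == 0) stop("zero-variance predictor")
  fit <- stats::lm(pbv_b ~ pbv_a)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Heritability difference between the genotype-inclusive and -exclusive fits
#'
#' `h2(incl) - h2(excl)` with the SE propagated as the root sum of squares
#' of the two delta-method SEs (the fits share data, so this is an upper
#' bound on the SE of the difference).
#'
#' @param fit_incl,fit_excl Univariate `reml_fit` objects on the same data.
#' @return List: `delta_h2`, `se`, `h2_incl`, `h2_excl`.
#' @export
heritability_delta <- function(fit_incl, fit_excl) {
  d <- fit_incl$h2 - fit_excl$h2
  se <- sqrt(sum(c(fit_incl$h2_se, fit_excl$h2_se)^2))
  list(delta_h2 = d, se = se, h2_incl = fit_incl$h2, h2_excl = fit_excl$h2)
}

#' Two-model comparison report
#'
#' Pearson correlation, OLS regression and R-squared between the PBVs of the
#' genotype-inclusive and genotype-exclusive evaluations, over all pedigree
#' animals and separately over phenotyped does.
#'
#' @param sol_incl,sol_excl `blup_solution` objects for the same trait.
#' @param pedigree The shared `goat_pedigree`.
#' @param doe_ids Ids of phenotyped does (for the restricted comparison).
#' @return Data frame with one row per population (`all`, `phenotyped_does`):
#'   correlation, p-value, slope, intercept, R-squared.
#' @export
compare_models <- function(sol_incl, sol_excl, pedigree, doe_ids = NULL) {
  sets <- list(all = names(sol_incl$pbv))
  if (!is.null(doe_ids)) sets$phenotyped_does <- intersect(names(sol_incl$pbv),
                                                           unique(doe_ids))
  rows <- lapply(names(sets), function(nm) {
    ids <- sets[[nm]]
    a <- sol_incl$pbv[ids]; b <- sol_excl$pbv[ids]
    ct <- pbv_correlation(a, b)
    rg <- pbv_regression(a, b)
    data.frame(population = nm, n = ct$n, r = ct$r, p_value = ct$p_value,
               slope = rg$slope, intercept = rg$intercept,
               r_squared = rg$r_squared, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
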