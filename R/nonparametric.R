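#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value, plus the
#' numerator/denominator degrees of freedom used by the effect-size
#' reconstruction (`dfn = levels - 1`, `dfd = n - levels`).
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 non-empty levels).
#' @return List: `H`, `p_value`, `dfn`, `dfd`, `n`, `levels`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L) {
    k <- nlevels(groups)
    return(list(H = 0, p_value = 1, dfn = k - 1L,
                dfd = length(values) - k, n = length(values), levels = k))
  }
  kt <- stats::kruskal.test(values, groups)
  k <- nlevels(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       dfn = k - 1L, dfd = length(values) - k,
       n = length(values), levels = k)
}

#' Convert a Kruskal-Wallis H into an F-scale statistic
#'
#' The screen reports `F = H / dfn`, the reconstruction of the F column the
#' effect-size computation is based on.
#'
#' @param H Kruskal-Wallis statistic.
#' @param dfn Numerator degrees of freedom (levels - 1), >= 1.
#' @return F value.
#' @export
h_to_f <- function(H, dfn) {
  if (any(dfn < 1)) stop("dfn must be >= 1")
  H / dfn
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * dfn / (F * dfn + dfd)`: the proportion of variance in the
#' response attributable to the factor, partialling out the other factors.
#'
#' @param F F statistic.
#' @param dfn,dfd Numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared in `[0, 1]`.
#' @export
partial_eta_squared <- function(F, dfn, dfd) {
  if (any(dfn < 1) || any(dfd < 1)) stop("degrees of freedom must be >= 1")
  F * dfn / (F * dfn + dfd)
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise rank-based z statistics with tie correction; the Bonferroni
#' family is the number of level pairs `k (k - 1) / 2`.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @return Data frame: `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_bonferroni <- function(values, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("every group needs at least one observation")
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(levels(groups), 2L)
  m <- ncol(pairs)
  z <- numeric(m); praw <- numeric(m)
  for (j in seq_len(m)) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z[j] <- if (se == 0) 0 else (rbar[[g1]] - rbar[[g2]]) / se
    praw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_raw = praw, p_adjusted = pmin(1, praw * m),
             stringsAsFactors = FALSE)
}

#' Shapiro-Francia normality test
#'
#' Squared correlation of the ordered sample with expected normal order
#' scores, with the standard log-transform normal approximation for the
#' p-value; valid for 5 <= n <= 5000.
#'
#' @param values Numeric sample.
#' @return List: `W`, `p_value`, `n`.
#' @export
shapiro_francia <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5L || n > 5000L) stop("sample size must be between 5 and 5000")
  sf <- nortest::sf.test(values)
  list(W = unname(sf$statistic), p_value = sf$p.value, n = n)
}

#' Supporting pre-model tests
#'
#' Levene's homoscedasticity test with group-median centring
#' (Brown-Forsythe), an independent-samples median test, adjusted sample
#' skewness and kurtosis, and (when `extra` columns are supplied) a Spearman
#' correlation matrix.
#'
#' @param values Numeric response.
#' @param groups Grouping factor.
#' @param extra Optional numeric data frame/matrix for the Spearman matrix.
#' @return List: `levene` (`F`, `p_value`), `median_test` (`chisq`, `df`,
#'   `p_value`), `skewness`, `kurtosis`, `spearman` (or `NULL`).
#' @export
supporting_tests <- function(values, groups, extra = NULL) {
  groups <- droplevels(factor(groups))
  if (any(table(groups) < 2L)) stop("degenerate groups for Levene's test")
  lev <- car::leveneTest(values, groups, center = stats::median)
  med <- stats::median(values)
  above <- values > med
  tab <- table(above, groups)
  mt <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  sp <- if (!is.null(extra)) stats::cor(as.matrix(extra),
                                        method = "spearman") else NULL
  list(levene = list(F = lev[1, "F value"], p_value = lev[1, "Pr(>F)"]),
       median_test = list(chisq = unname(mt$statistic),
                          df = unname(mt$parameter),
                          p_value = mt$p.value),
       skewness = e1071::skewness(values, type = 2),
       kurtosis = e1071::kurtosis(values, type = 2),
       spearman = sp)
}

#' Full factor screen over traits
#'
#' Runs the Kruskal-Wallis battery for every trait x factor combination and
#' assembles the screen table: H (as a chi-square), p, dfn, dfd, the derived
#' F and partial eta squared.
#'
#' @param data Data frame of records.
#' @param traits Character vector of trait column names.
#' @param factors Character vector of factor column names.
#' @return Data frame with one row per factor x trait.
#' @export
factor_screen <- function(data, traits, factors) {
  rows <- list()
  for (f in factors) {
    for (tr in traits) {
      kw <- kruskal_wallis(data[[tr]], data[[f]])
      Fv <- h_to_f(kw$H, kw$dfn)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, trait = tr, H = kw$H, p_value = kw$p_value,
        dfn = kw$dfn, dfd = kw$dfd, F = Fv,
        partial_eta_squared = partial_eta_squared(Fv, kw$dfn, kw$dfd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
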