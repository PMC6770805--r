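#' Empirical SEP coverage on model-true simulations
#'
#' Validation utility for the prediction-error machinery: simulates a
#' three-generation pedigree (about 600 animals), draws true breeding
#' values from the additive model, generates 1-3 repeated records per doe
#' around an overall mean only, solves the mixed-model equations at the
#' true variance components, and reports the percentage of animals whose
#' TBV falls inside PBV +/- k SEP, averaged over seeded replicates. Under a
#' correctly computed SEP these coverages match the nominal normal values
#' (about 95% at k = 2 and 68% at k = 1).
#'
#' @param seed Base seed; replicate r uses `seed * 100 + r` offsets.
#' @param n_replicates Number of replicates to average over.
#' @param k Multipliers of SEP to evaluate.
#' @param vc Named true variance components (defaults: the milk-yield
#'   components used throughout the package).
#' @param mu Overall mean of the records.
#' @return Named numeric vector of coverages in percent (one per `k`),
#'   with attribute `n_animals` (mean pedigree size).
#' @export
sep_coverage_simulation <- function(seed = 1L, n_replicates = 10L,
                                    k = c(1, 2),
                                    vc = c(sigma_a2 = 11511.83,
                                           sigma_pe2 = 1689.51,
                                           sigma_e2 = 15578.23),
                                    mu = 416) {
  one_rep <- function(rs) {
    cfg <- sim_config(seed = rs, n_founder_bucks = 11L, n_founder_does = 52L,
                      n_generations = 3L, kids_per_doe = 3L,
                      lactation_range = c(1L, 3L))
    ped <- simulate_pedigree(cfg)
    tbv <- simulate_breeding_values(ped, matrix(vc[["sigma_a2"]], 1, 1),
                                    seed = rs + 500L)
    does <- which(ped$ped$sex == "doe")
    ids <- ped$ped$animal_id
    rec <- local_seed(rs + 900L, {
      nlac <- sample(1:3, length(does), replace = TRUE)
      pe <- stats::rnorm(length(does), 0, sqrt(vc[["sigma_pe2"]]))
      doe_id <- rep(ids[does], nlac)
      y <- mu + rep(tbv[does, 1L] + pe, nlac) +
        stats::rnorm(sum(nlac), 0, sqrt(vc[["sigma_e2"]]))
      data.frame(doe_id = doe_id, y = y, stringsAsFactors = FALSE)
    })
    n <- nrow(rec)
    dm <- list(X = matrix(1, n, 1),
               Za = Matrix::sparseMatrix(i = seq_len(n),
                                         j = match(rec$doe_id, ids), x = 1,
                                         dims = c(n, ped$n)),
               Zpe = Matrix::sparseMatrix(i = seq_len(n),
                                          j = match(rec$doe_id,
                                                    unique(rec$doe_id)), x = 1,
                                          dims = c(n, length(unique(rec$doe_id)))),
               Y = matrix(rec$y, ncol = 1),
               animal_ids = ids, pe_ids = unique(rec$doe_id))
    sol <- solve_blup(dm, a_inverse_sparse(ped), vc)
    err <- tbv[, 1L] - sol$pbv
    c(vapply(k, function(kk) 100 * mean(abs(err) <= kk * sol$sep), numeric(1)),
      ped$n)
  }
  res <- vapply(seq_len(n_replicates),
                function(r) one_rep(seed * 100L + r), numeric(length(k) + 1L))
  out <- rowMeans(res)[seq_along(k)]
  names(out) <- paste0("k", k)
  attr(out, "n_animals") <- mean(res[length(k) + 1L, ])
  out
}
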