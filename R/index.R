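#' Combined selection index (ICO) over milk, fat and protein PBVs
#'
#' `ICO = sum_t w_t z(PBV_t)` when `standardize` is on (the default), else
#' the raw weighted sum. Dry matter is excluded by construction: as an
#' indirect measure of fat and protein it would be redundant in the index.
#' Default weights are equal on the standardized scale; the breeding
#' program's true economic weights are a mandatory configuration surface.
#'
#' @param pbv_table Data frame with `animal_id` and columns `milk`, `fat`,
#'   `protein` holding per-trait PBVs.
#' @param weights Named per-trait weights; finite, at least one non-zero.
#' @param standardize Z-score each trait's PBVs before weighting?
#' @return Data frame: `animal_id`, `ico`, `rank` (1 = best, ties broken by
#'   animal id).
#' @export
ico_scores <- function(pbv_table,
                       weights = c(milk = 1, fat = 1, protein = 1),
                       standardize = TRUE) {
  traits <- names(weights)
  if (!all(traits %in% names(pbv_table))) {
    stop("missing trait PBV column(s): ",
         paste(setdiff(traits, names(pbv_table)), collapse = ", "))
  }
  if (any(!is.finite(weights)) || all(weights == 0)) {
    stop("weights must be finite with at least one non-zero")
  }
  Z <- as.matrix(pbv_table[traits])
  if (anyNA(Z)) stop("missing trait PBV for some animals")
  if (standardize) {
    Z <- scale(Z)
    Z[is.nan(Z)] <- 0   # zero-variance trait contributes nothing
  }
  ico <- as.vector(Z %*% weights)
  ord <- order(-ico, pbv_table$animal_id)
  rank <- integer(length(ico)); rank[ord] <- seq_along(ico)
  data.frame(animal_id = pbv_table$animal_id, ico = ico, rank = rank,
             stringsAsFactors = FALSE)
}

#' Three-stratum sample from an index ranking
#'
#' Selects the `n_low` lowest-scoring animals, the `n_high` highest, and an
#' `n_mid` window of consecutive ranks centred on the median rank (the
#' study's design: 236 low, 238 around percentile 50, 236 high out of 710
#' does). Ties are broken deterministically by animal id, so the selection
#' is invariant to input order. Overlapping strata are an error.
#'
#' @param scores Output of [ico_scores()] (needs `animal_id`, `ico`).
#' @param n_low,n_mid,n_high Stratum sizes.
#' @return Data frame: `animal_id`, `ico`, `rank`, `stratum` in
#'   `{low, mid, high, unselected}`.
#' @export
rank_stratified_sample <- function(scores, n_low = 236L, n_mid = 238L,
                                   n_high = 236L) {
  N <- nrow(scores)
  if (n_low + n_mid + n_high > N) stop("strata exceed the number of scored animals")
  ord <- order(scores$ico, scores$animal_id)   # ascending: rank 1 = lowest ICO
  asc_rank <- integer(N); asc_rank[ord] <- seq_len(N)
  stratum <- rep("unselected", N)
  low_set <- asc_rank <= n_low
  high_set <- asc_rank > N - n_high
  mid_start <- floor((N - n_mid) / 2) + 1L
  mid_set <- asc_rank >= mid_start & asc_rank < mid_start + n_mid
  if (any(mid_set & (low_set | high_set))) {
    stop("strata overlap: population too small for the requested sizes")
  }
  stratum[low_set] <- "low"
  stratum[mid_set] <- "mid"
  stratum[high_set] <- "high"
  out <- scores[c("animal_id", "ico")]
  out$rank <- N - asc_rank + 1L     # 1 = best, as in ico_scores
  out$stratum <- stratum
  out
}
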