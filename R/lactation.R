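#' Standardize test-day measurements to a 210-day lactation
#'
#' Fleischmann test-interval accumulation: the first test's daily yield is
#' back-extended to day 0, each interval between consecutive tests
#' contributes the mean of its two daily yields times the interval length,
#' and the last test's daily yield is carried forward to day 210 (tests past
#' day 210 are truncated at 210 by linear interpolation). Component
#' percentages are milk-weighted means over the same intervals.
#'
#' @param test_days Data frame with columns `doe_id`, `parity`,
#'   `day_in_milk`, `daily_milk_kg`, `fat_pct`, `protein_pct`, `dm_pct`
#'   (one or more lactations; grouped by doe x parity internally).
#' @return Data frame with one row per doe x parity: `doe_id`, `parity`,
#'   `milk_kg`, `fat_pct`, `protein_pct`, `dm_pct`, `fat_kg`, `protein_kg`,
#'   `dm_kg`, `n_tests`.
#' @export
standardize_lactation_210 <- function(test_days) {
  stopifnot(all(c("doe_id", "parity", "day_in_milk", "daily_milk_kg")
                %in% names(test_days)))
  pcts <- intersect(c("fat_pct", "protein_pct", "dm_pct"), names(test_days))
  key <- interaction(test_days$doe_id, test_days$parity, drop = TRUE)
  groups <- split(test_days, key)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$day_in_milk), , drop = FALSE]
    res <- fleischmann_210(g$day_in_milk, g$daily_milk_kg,
                           as.matrix(g[pcts]))
    out <- data.frame(doe_id = g$doe_id[1L], parity = g$parity[1L],
                      milk_kg = res$milk_kg, stringsAsFactors = FALSE)
    for (p in pcts) out[[p]] <- res$pct[[p]]
    out$n_tests <- nrow(g)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("fat_pct" %in% pcts) out$fat_kg <- out$milk_kg * out$fat_pct / 100
  if ("protein_pct" %in% pcts) out$protein_kg <- out$milk_kg * out$protein_pct / 100
  if ("dm_pct" %in% pcts) out$dm_kg <- out$milk_kg * out$dm_pct / 100
  out
}

# Fleischmann accumulation for a single lactation. days sorted ascending.
fleischmann_210 <- function(days, yields, pct_matrix = NULL) {
  stopifnot(length(days) >= 1L, !is.unsorted(days))
  horizon <- 210
  if (any(days > horizon)) {
    # truncate: interpolate the yield at day 210 and drop later tests
    keep <- days <= horizon
    if (!any(keep)) {
      days2 <- horizon; yields2 <- yields[1L]
      pm <- if (!is.null(pct_matrix)) pct_matrix[1L, , drop = FALSE]
    } else {
      last_in <- max(which(keep))
      if (last_in < length(days)) {
        t1 <- days[last_in]; t2 <- days[last_in + 1L]
        w <- (horizon - t1) / (t2 - t1)
        y210 <- (1 - w) * yields[last_in] + w * yields[last_in + 1L]
        days2 <- c(days[keep], horizon)
        yields2 <- c(yields[keep], y210)
        pm <- if (!is.null(pct_matrix))
          rbind(pct_matrix[keep, , drop = FALSE],
                pct_matrix[last_in, , drop = FALSE])
      } else {
        days2 <- days[keep]; yields2 <- yields[keep]
        pm <- if (!is.null(pct_matrix)) pct_matrix[keep, , drop = FALSE]
      }
    }
    days <- days2; yields <- yields2
    if (!is.null(pct_matrix)) pct_matrix <- pm
  }
  m <- length(days)
  # interval milk: back-extension, trapezoid mid intervals, carry to 210
  seg_milk <- numeric(m)
  seg_milk[1L] <- yields[1L] * days[1L]
  if (m > 1L) {
    for (k in 2:m) {
      seg_milk[k] <- (yields[k - 1L] + yields[k]) / 2 * (days[k] - days[k - 1L])
    }
  }
  carry <- yields[m] * (horizon - days[m])
  milk <- sum(seg_milk) + carry
  pct <- NULL
  if (!is.null(pct_matrix) && ncol(pct_matrix) > 0L) {
    # milk-weighted mean percentage: each segment carries the percentage of
    # the test closing it (the first segment and the carry use their own test)
    seg_all <- c(seg_milk, carry)
    wts <- seg_all / sum(seg_all)
    pct <- lapply(seq_len(ncol(pct_matrix)), function(j) {
      v <- c(pct_matrix[, j], pct_matrix[m, j])
      sum(v * wts)
    })
    names(pct) <- colnames(pct_matrix)
  }
  list(milk_kg = milk, pct = pct)
}

#' Component yield in kg from total milk and a percentage
#'
#' @param milk_kg Total 210-day milk yield (kg).
#' @param component_pct Component percentage (0-100).
#' @return `milk_kg * component_pct / 100`.
#' @export
component_yield_kg <- function(milk_kg, component_pct) {
  if (any(milk_kg < 0) || any(component_pct < 0)) {
    stop("milk and percentage must be non-negative")
  }
  milk_kg * component_pct / 100
}

#' Filter lactation records against per-trait reference ranges
#'
#' Keeps records whose trait values all fall inside the configured
#' `[min, max]` ranges; each rejection is logged with the rule that fired.
#' The default ranges are mean +/- 4 SD of the breed reference values
#' (416.0 +/- 197.9 kg milk, 19.54 +/- 7.12 fat, 13.25 +/- 5.31 protein,
#' 52.33 +/- 17.16 dry matter).
#'
#' @param records Lactation records with `milk_kg`, `fat_kg`, `protein_kg`,
#'   `dm_kg`.
#' @param reference_ranges Named list of `c(min, max)` per trait column.
#' @return List: `records` (survivors), `rejections` (data frame `row`,
#'   `doe_id`, `rule`), `n_kept`.
#' @export
depurate_records <- function(records, reference_ranges = default_depuration_ranges()) {
  bad <- list()
  keep <- rep(TRUE, nrow(records))
  for (trait in names(reference_ranges)) {
    rng <- reference_ranges[[trait]]
    v <- records[[trait]]
    if (is.null(v)) next
    lo <- which(v < rng[1L]); hi <- which(v > rng[2L])
    for (r in lo) bad[[length(bad) + 1L]] <-
      data.frame(row = r, doe_id = records$doe_id[r],
                 rule = paste0(trait, "_below_", signif(rng[1L], 6)))
    for (r in hi) bad[[length(bad) + 1L]] <-
      data.frame(row = r, doe_id = records$doe_id[r],
                 rule = paste0(trait, "_above_", signif(rng[2L], 6)))
    keep[c(lo, hi)] <- FALSE
  }
  rejections <- if (length(bad)) do.call(rbind, bad) else
    data.frame(row = integer(), doe_id = character(), rule = character())
  list(records = records[keep, , drop = FALSE],
       rejections = rejections, n_kept = sum(keep))
}

#' @rdname depurate_records
#' @export
default_depuration_ranges <- function() {
  mk <- function(mu, sd) c(max(0, mu - 4 * sd), mu + 4 * sd)
  list(milk_kg = mk(416.0, 197.9), fat_kg = mk(19.54, 7.12),
       protein_kg = mk(13.25, 5.31), dm_kg = mk(52.33, 17.16))
}

#' Connect lactation records to the pedigree
#'
#' Drops records whose doe is absent from the pedigree or has no known
#' ancestor link (both parents unknown and never used as a parent herself),
#' mirroring the requirement that evaluated animals have direct records and
#' are connected to the relationship matrix via at least one known ancestor.
#'
#' @param records Lactation records with a `doe_id` column.
#' @param pedigree A `goat_pedigree`.
#' @return List: `records` (retained, with an `animal_idx` column giving the
#'   pedigree position), `dropped` (data frame `doe_id`, `reason`).
#' @export
connect_to_pedigree <- function(records, pedigree) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  ped <- pedigree$ped
  idx <- match(records$doe_id, ped$animal_id)
  used_as_parent <- seq_len(pedigree$n) %in% c(ped$sire, ped$dam)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(idx)] <- "not_in_pedigree"
  isolated <- !is.na(idx) & ped$sire[idx] == 0L & ped$dam[idx] == 0L &
    !used_as_parent[pmax(idx, 1L)]
  reason[isolated] <- "no_known_ancestor_link"
  keep <- is.na(reason)
  dropped <- unique(data.frame(doe_id = records$doe_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
  out <- records[keep, , drop = FALSE]
  out$animal_idx <- idx[keep]
  list(records = out, dropped = dropped)
}
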