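#' Validate and order a raw pedigree
#'
#' Builds a `goat_pedigree` object from raw parentage records: parents that
#' never appear as animals are added as founders, records are sorted so that
#' every ancestor precedes its descendants, per-animal generation depth is
#' computed (founders have depth 1) and inbreeding coefficients are obtained
#' with the Meuwissen-Luo recursion.
#'
#' @param raw A data frame with columns `animal_id`, `sire_id`, `dam_id` and
#'   optionally `sex` (`"buck"`/`"doe"`) and `birth_year`. Unknown parents are
#'   encoded as `NA`, the empty string or `"0"`.
#' @return An object of class `goat_pedigree`: a list with elements
#'   `ped` (data frame in topological order with integer parent indices
#'   `sire`/`dam`, 0 = unknown), `inbreeding` (per-animal F), `depth`
#'   (per-animal generation depth) and `n`.
#' @details Hard errors are raised for duplicated animal ids, for cycles
#'   (an animal that is its own ancestor) and for sex conflicts (an id used
#'   both as a sire and as a dam, or a recorded sex contradicting parental
#'   use). Sexes missing from the input are imputed from parental use where
#'   possible.
#' @export
validate_pedigree <- function(raw) {
  if (is.null(raw) || nrow(as.data.frame(raw)) == 0L) {
    ped <- data.frame(animal_id = character(), sire = integer(),
                      dam = integer(), sex = character(),
                      birth_year = integer(), stringsAsFactors = FALSE)
    out <- list(ped = ped, inbreeding = numeric(0), depth = integer(0), n = 0L)
    class(out) <- "goat_pedigree"
    return(out)
  }
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(raw)))
  norm_id <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA_character_
    x
  }
  aid <- norm_id(raw$animal_id)
  if (anyNA(aid)) stop("missing animal_id")
  if (anyDuplicated(aid)) {
    stop("duplicate animal_id: ", aid[duplicated(aid)][1L])
  }
  sid <- norm_id(raw$sire_id)
  did <- norm_id(raw$dam_id)

  both <- intersect(stats::na.omit(sid), stats::na.omit(did))
  if (length(both) > 0L) {
    stop("sex conflict: animal used as both sire and dam: ", both[1L])
  }

  sex <- if ("sex" %in% names(raw)) as.character(raw$sex) else rep(NA_character_, length(aid))
  by  <- if ("birth_year" %in% names(raw)) as.integer(raw$birth_year) else rep(NA_integer_, length(aid))

  # add parents that never occur as animals: treated as founders
  extra <- setdiff(unique(c(stats::na.omit(sid), stats::na.omit(did))), aid)
  if (length(extra) > 0L) {
    aid <- c(aid, extra)
    sid <- c(sid, rep(NA_character_, length(extra)))
    did <- c(did, rep(NA_character_, length(extra)))
    sex <- c(sex, rep(NA_character_, length(extra)))
    by  <- c(by, rep(NA_integer_, length(extra)))
  }
  n <- length(aid)
  idx <- stats::setNames(seq_len(n), aid)
  si <- ifelse(is.na(sid), 0L, idx[sid])
  di <- ifelse(is.na(did), 0L, idx[did])

  # sex consistency with parental use
  used_sire <- aid %in% sid
  used_dam  <- aid %in% did
  bad <- which((used_sire & !is.na(sex) & sex == "doe") |
               (used_dam  & !is.na(sex) & sex == "buck"))
  if (length(bad) > 0L) {
    stop("sex conflict for animal ", aid[bad[1L]],
         ": recorded sex contradicts use as parent")
  }
  sex[is.na(sex) & used_sire] <- "buck"
  sex[is.na(sex) & used_dam]  <- "doe"

  # Kahn toposort on parent -> offspring edges; also yields generation depth
  depth <- rep(NA_integer_, n)
  indeg <- (si > 0L) + (di > 0L)
  order_out <- integer(n)
  queue <- which(indeg == 0L)
  depth[queue] <- 1L
  k <- 0L
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L
    order_out[k] <- v
    for (ch in children[[v]]) {
      pd <- max(depth[c(si[ch], di[ch])[c(si[ch], di[ch]) > 0L]], na.rm = FALSE)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        pp <- c(si[ch], di[ch]); pp <- pp[pp > 0L]
        depth[ch] <- max(depth[pp]) + 1L
        queue <- c(queue, ch)
      }
    }
  }
  if (k < n) {
    on_cycle <- aid[which(indeg > 0L)][1L]
    stop("pedigree cycle detected involving animal ", on_cycle)
  }
  perm <- order_out
  newpos <- integer(n); newpos[perm] <- seq_len(n)
  remap <- function(p) {
    out <- integer(length(p))
    out[p > 0L] <- newpos[p[p > 0L]]
    out
  }
  ped <- data.frame(animal_id = aid[perm],
                    sire = remap(si)[perm],
                    dam = remap(di)[perm],
                    sex = sex[perm],
                    birth_year = by[perm],
                    stringsAsFactors = FALSE)
  out <- list(ped = ped, depth = depth[perm], n = n)
  out$inbreeding <- ml_inbreeding(ped$sire, ped$dam)
  class(out) <- "goat_pedigree"
  out
}

#' @export
print.goat_pedigree <- function(x, ...) {
  cat("<goat_pedigree>", x$n, "animals;",
      sum(x$ped$sire == 0L & x$ped$dam == 0L), "founders;",
      "generation depth", if (x$n) paste(range(x$depth), collapse = "-") else "NA",
      "\n  mean F =", if (x$n) format(mean(x$inbreeding), digits = 4) else "NA", "\n")
  invisible(x)
}

# Mendelian-sampling variance multiplier for animal i given parental F values.
# Both parents known: 0.5 - 0.25 (F_s + F_d); one known: 0.75 - 0.25 F_p;
# none: 1.  This is the d_i of the L D L' decomposition of A.
mendelian_d <- function(sire, dam, F) {
  n <- length(sire)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dm <- dam[i]
    d[i] <- if (s > 0L && dm > 0L) 0.5 - 0.25 * (F[s] + F[dm])
            else if (s > 0L) 0.75 - 0.25 * F[s]
            else if (dm > 0L) 0.75 - 0.25 * F[dm]
            else 1
  }
  d
}

# Meuwissen & Luo (1992) recursion: F_i = sum_j L_ij^2 d_j - 1, where the
# L-row of animal i is generated by tracing ancestors downward.  Parents are
# assumed to precede offspring (validate_pedigree guarantees this).
ml_inbreeding <- function(sire, dam) {
  n <- length(sire)
  F <- numeric(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; dm <- dam[i]
    d[i] <- if (s > 0L && dm > 0L) 0.5 - 0.25 * (F[s] + F[dm])
            else if (s > 0L) 0.75 - 0.25 * F[s]
            else if (dm > 0L) 0.75 - 0.25 * F[dm]
            else 1
    if (s == 0L || dm == 0L) { F[i] <- 0; next }
    r <- numeric(i)
    r[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (r[j] == 0) next
      aii <- aii + r[j]^2 * d[j]
      if (sire[j] > 0L) r[sire[j]] <- r[sire[j]] + 0.5 * r[j]
      if (dam[j] > 0L)  r[dam[j]]  <- r[dam[j]]  + 0.5 * r[j]
    }
    F[i] <- aii - 1
  }
  F
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F (probability that the two alleles at
#' a locus are identical by descent), as computed by the Meuwissen-Luo
#' recursion during pedigree validation. Founders have F = 0.
#'
#' @param pedigree A `goat_pedigree`.
#' @return Named numeric vector of F values in pedigree order.
#' @export
inbreeding_coefficients <- function(pedigree) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  stats::setNames(pedigree$inbreeding, pedigree$ped$animal_id)
}

#' Additive (numerator) relationship matrix for a subset of animals
#'
#' Tabular-method A for the requested animals and all their ancestors,
#' returned restricted to the subset. The diagonal equals 1 + F.
#'
#' @param pedigree A `goat_pedigree`.
#' @param subset Character vector of animal ids (default: all animals).
#' @return Dense symmetric matrix with dimnames = animal ids.
#' @export
additive_relationship <- function(pedigree, subset = NULL) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  ped <- pedigree$ped
  if (is.null(subset)) {
    keep <- seq_len(pedigree$n)
  } else {
    keep <- match(as.character(subset), ped$animal_id)
    if (anyNA(keep)) {
      stop("unknown animal ids in subset: ",
           paste(subset[is.na(keep)][seq_len(min(3, sum(is.na(keep))))],
                 collapse = ", "))
    }
  }
  # close the subset over ancestors
  need <- logical(pedigree$n)
  need[keep] <- TRUE
  for (i in rev(seq_len(pedigree$n))) {
    if (need[i]) {
      if (ped$sire[i] > 0L) need[ped$sire[i]] <- TRUE
      if (ped$dam[i] > 0L)  need[ped$dam[i]]  <- TRUE
    }
  }
  act <- which(need)                    # ascending => parents first
  m <- length(act)
  pos <- integer(pedigree$n); pos[act] <- seq_len(m)
  A <- matrix(0, m, m)
  for (k in seq_len(m)) {
    i <- act[k]
    s <- pos[ped$sire[i]][ped$sire[i] > 0L]; s <- if (length(s)) s else 0L
    d <- pos[ped$dam[i]][ped$dam[i] > 0L];  d <- if (length(d)) d else 0L
    A[k, k] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        v <- 0
        if (s > 0L) v <- v + 0.5 * A[j, s]
        if (d > 0L) v <- v + 0.5 * A[j, d]
        A[j, k] <- A[k, j] <- v
      }
    }
  }
  dimnames(A) <- list(ped$animal_id[act], ped$animal_id[act])
  A[pos[keep], pos[keep], drop = FALSE]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accommodation: each animal contributes
#' 1/d_i to its own diagonal and the usual -1/2, 1/4 patterns to parental
#' entries, with d_i = 0.5 - 0.25 (F_s + F_d) when both parents are known
#' (0.75 - 0.25 F_p with one known parent, 1 for founders).
#'
#' @param pedigree A `goat_pedigree`.
#' @return Sparse symmetric `dsCMatrix` (Matrix package) in pedigree order.
#' @export
a_inverse_sparse <- function(pedigree) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  ped <- pedigree$ped
  n <- pedigree$n
  if (n == 0L) return(Matrix::Matrix(0, 0, 0, sparse = TRUE))
  d <- mendelian_d(ped$sire, ped$dam, pedigree$inbreeding)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    a <- 1 / d[i]
    s <- ped$sire[i]; dm <- ped$dam[i]
    add(i, i, a)
    for (p in c(s, dm)) {
      if (p > 0L) {
        add(i, p, -a / 2); add(p, i, -a / 2)
        add(p, p, a / 4)
      }
    }
    if (s > 0L && dm > 0L) {
      add(s, dm, a / 4); add(dm, s, a / 4)
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal_id, ped$animal_id))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationship summary
#'
#' Mean inbreeding, the range of pairwise additive relationships, per-animal
#' offspring counts and the generation-depth range. For pedigrees larger than
#' `max_exact` animals the relationship range is estimated from a seeded
#' random sample of `n_pairs` pairs rather than the full pairwise matrix.
#'
#' @param pedigree A `goat_pedigree`.
#' @param max_exact Largest pedigree for which all pairs are scanned.
#' @param n_pairs Number of sampled pairs beyond that size.
#' @param seed Seed for the pair sample.
#' @return A list with `mean_inbreeding`, `relatedness_range` (min, max over
#'   off-diagonal pairs), `offspring_counts` (named), `depth_range`.
#' @export
pedigree_summary <- function(pedigree, max_exact = 2000L, n_pairs = 1e5L,
                             seed = 1L) {
  stopifnot(inherits(pedigree, "goat_pedigree"))
  ped <- pedigree$ped
  n <- pedigree$n
  offs <- tabulate(c(ped$sire[ped$sire > 0L], ped$dam[ped$dam > 0L]), nbins = n)
  names(offs) <- ped$animal_id
  if (n < 2L) {
    rel <- c(NA_real_, NA_real_)
  } else if (n <= max_exact) {
    A <- additive_relationship(pedigree)
    off <- A[upper.tri(A)]
    rel <- range(off)
  } else {
    pairs <- local_seed(seed, {
      cbind(sample.int(n, n_pairs, replace = TRUE),
            sample.int(n, n_pairs, replace = TRUE))
    })
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    u <- sort(unique(as.vector(pairs)))
    A <- additive_relationship(pedigree, ped$animal_id[u])
    pos <- integer(n); pos[u] <- seq_along(u)
    vals <- A[cbind(pos[pairs[, 1]], pos[pairs[, 2]])]
    rel <- range(vals)
  }
  list(mean_inbreeding = if (n) mean(pedigree$inbreeding) else NA_real_,
       relatedness_range = rel,
       offspring_counts = offs,
       depth_range = if (n) range(pedigree$depth) else c(NA_integer_, NA_integer_))
}

#' Read a pedigree CSV
#'
#' Columns `animal_id, sire_id, dam_id, sex, birth_year`; empty string or 0
#' marks an unknown parent.
#'
#' @param path File path.
#' @return A validated `goat_pedigree`.
#' @export
read_pedigree_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  if ("birth_year" %in% names(raw)) raw$birth_year <- as.integer(raw$birth_year)
  validate_pedigree(raw)
}

#' Export a sparse matrix as 1-based coordinate triplets
#'
#' @param M A sparse (or dense) matrix.
#' @param path Output path; tab-separated columns i, j, value.
#' @export
write_triplets <- function(M, path) {
  T <- methods::as(methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
                   "TsparseMatrix")
  df <- data.frame(i = T@i + 1L, j = T@j + 1L, value = T@x)
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
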