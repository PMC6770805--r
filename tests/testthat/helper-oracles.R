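# Shared fixtures and independent oracles for the test suite.

# -- pedigree fixtures -------------------------------------------------------

# trio: sire, dam, offspring (non-inbred)
trio_raw <- function() {
  data.frame(animal_id = c("s1", "d1", "o1"),
             sire_id = c("", "", "s1"), dam_id = c("", "", "d1"),
             sex = c("buck", "doe", "doe"), birth_year = c(2000, 2000, 2002),
             stringsAsFactors = FALSE)
}

# a 10-animal pedigree with deliberate inbreeding (full-sib and
# parent-offspring matings)
inbred10_raw <- function() {
  data.frame(
    animal_id = c("f1", "f2", "f3", "f4", "a", "b", "c", "d", "e", "g"),
    sire_id = c("", "", "", "", "f1", "f1", "a", "a", "c", "e"),
    dam_id = c("", "", "", "", "f2", "f2", "b", "f3", "d", "d"),
    stringsAsFactors = FALSE)
}

# random pedigree generator: n animals, founders first, random earlier
# parents with the right sexes
random_pedigree_raw <- function(n, n_founders = 10L, seed = 1L) {
  set.seed(seed)
  id <- sprintf("R%03d", seq_len(n))
  sex <- sample(c("buck", "doe"), n, replace = TRUE, prob = c(0.3, 0.7))
  sex[1:2] <- c("buck", "doe")
  sire <- dam <- rep("", n)
  for (i in seq.int(n_founders + 1L, n)) {
    prev <- seq_len(i - 1L)
    bucks <- prev[sex[prev] == "buck"]
    does <- prev[sex[prev] == "doe"]
    sire[i] <- id[sample(bucks, 1L)]
    dam[i] <- id[sample(does, 1L)]
  }
  data.frame(animal_id = id, sire_id = sire, dam_id = dam, sex = sex,
             stringsAsFactors = FALSE)
}

# -- gene-dropping oracle ----------------------------------------------------

# Monte-Carlo estimate of additive relationships (2 x kinship) and
# inbreeding by dropping unique founder alleles through the pedigree.
gene_drop_estimates <- function(ped, n_drops = 1e4L, seed = 1L) {
  set.seed(seed)
  n <- ped$n
  sire <- ped$ped$sire
  dam <- ped$ped$dam
  a1 <- matrix(0L, n, n_drops)
  a2 <- matrix(0L, n, n_drops)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (sire[i] == 0L) {
      a1[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[i, ] <- ifelse(pick, a1[sire[i], ], a2[sire[i], ])
    }
    if (dam[i] == 0L) {
      a2[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a2[i, ] <- ifelse(pick, a1[dam[i], ], a2[dam[i], ])
    }
  }
  # kinship(i,j) = P(random allele from i IBD to random allele from j)
  kin <- function(i, j) {
    mean((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
         (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 4
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * kin(i, j)
  }
  Fhat <- vapply(seq_len(n), function(i) mean(a1[i, ] == a2[i, ]), numeric(1))
  diag(A) <- 1 + Fhat
  list(A = A, F = Fhat, n_drops = n_drops)
}

# -- dense mixed-model / REML oracles ---------------------------------------

# dense GLS solution of the animal model: BLUE, BLUP and PEV straight from
# V = Za A Za' sa + Zpe Zpe' sp + I se (no mixed-model equations)
dense_gls_oracle <- function(X, Za, Zpe, y, A, vc) {
  sa <- vc[["sigma_a2"]]; sp <- vc[["sigma_pe2"]]; se <- vc[["sigma_e2"]]
  Za <- as.matrix(Za); n <- length(y)
  V <- sa * Za %*% A %*% t(Za) + se * diag(n)
  if (!is.null(Zpe) && sp > 0) {
    Zpe <- as.matrix(Zpe)
    V <- V + sp * Zpe %*% t(Zpe)
  }
  Vi <- solve(V)
  X <- as.matrix(X)
  if (ncol(X) > 0) {
    XtVi <- t(X) %*% Vi
    b <- solve(XtVi %*% X, XtVi %*% y)
    P <- Vi - Vi %*% X %*% solve(XtVi %*% X) %*% XtVi
  } else {
    b <- numeric(0)
    P <- Vi
  }
  G <- sa * A
  u <- G %*% t(Za) %*% P %*% y
  pev <- diag(G - G %*% t(Za) %*% P %*% Za %*% G)
  list(b = as.vector(b), u = as.vector(u), pev = as.vector(pev))
}

# dense REML log-likelihood (up to the usual constant) from V directly
dense_reml_ll <- function(X, Za, Zpe, y, A, sa, sp, se) {
  n <- length(y)
  Za <- as.matrix(Za)
  V <- sa * Za %*% A %*% t(Za) + se * diag(n)
  if (!is.null(Zpe) && sp > 0) V <- V + sp * as.matrix(Zpe) %*% t(as.matrix(Zpe))
  Vi <- solve(V)
  X <- as.matrix(X)
  XtViX <- t(X) %*% Vi %*% X
  Py <- Vi %*% y - Vi %*% X %*% solve(XtViX, t(X) %*% Vi %*% y)
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XtViX, logarithm = TRUE)$modulus +
            sum(y * Py))
}

# build a small repeated-records dataset and design for the BLUP/REML toys
toy_design <- function(seed = 3L, n_animals = 8L, vc = c(sigma_a2 = 4,
                                                         sigma_pe2 = 2,
                                                         sigma_e2 = 6)) {
  raw <- random_pedigree_raw(n_animals, n_founders = 4L, seed = seed)
  ped <- validate_pedigree(raw)
  does <- ped$ped$animal_id[ped$ped$sex == "doe"]
  set.seed(seed + 100L)
  reps <- sample(1:3, length(does), replace = TRUE)
  doe_id <- rep(does, reps)
  n <- length(doe_id)
  A <- additive_relationship(ped)
  tbv <- as.vector(t(chol(A + diag(1e-10, ped$n))) %*% rnorm(ped$n)) *
    sqrt(vc[["sigma_a2"]])
  names(tbv) <- ped$ped$animal_id
  pe <- stats::setNames(rnorm(length(does), 0, sqrt(vc[["sigma_pe2"]])), does)
  y <- 10 + tbv[doe_id] + pe[doe_id] + rnorm(n, 0, sqrt(vc[["sigma_e2"]]))
  idx <- match(doe_id, ped$ped$animal_id)
  pe_ids <- unique(doe_id)
  dm <- list(X = matrix(1, n, 1),
             Za = Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                                       dims = c(n, ped$n)),
             Zpe = Matrix::sparseMatrix(i = seq_len(n),
                                        j = match(doe_id, pe_ids), x = 1,
                                        dims = c(n, length(pe_ids))),
             Y = matrix(unname(y), ncol = 1),
             animal_ids = ped$ped$animal_id, pe_ids = pe_ids)
  list(ped = ped, A = A, dm = dm, vc = vc, doe_id = doe_id, tbv = tbv)
}

# moderate simulated dataset + design matrices for REML tests
sim_dataset <- function(seed, n_founder_bucks = 8L, n_founder_does = 40L,
                        n_generations = 3L, kids_per_doe = 3L,
                        lactation_range = c(1L, 3L), ...) {
  cfg <- sim_config(seed = seed, n_founder_bucks = n_founder_bucks,
                    n_founder_does = n_founder_does,
                    n_generations = n_generations,
                    kids_per_doe = kids_per_doe,
                    lactation_range = lactation_range, ...)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_lactation_dataset(ped, NULL, cfg)
  conn <- connect_to_pedigree(sim$records, ped)
  list(cfg = cfg, ped = ped, sim = sim, records = conn$records,
       Ainv = a_inverse_sparse(ped))
}
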