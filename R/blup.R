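#' Solve the mixed-model equations at fixed variance components
#'
#' Henderson's MME for one trait: returns BLUEs of the fixed effects and
#' BLUP predicted breeding values for every pedigree animal (record-less
#' animals are predicted through their relatives), together with per-animal
#' prediction error variances taken from the inverse coefficient matrix.
#'
#' @param dm Design list from [build_design_matrices()] (single trait), or a
#'   hand-built list with elements `X`, `Za`, `Zpe`, `Y`, `animal_ids`,
#'   `pe_ids`.
#' @param Ainv Sparse A-inverse for all pedigree animals.
#' @param vc Named variance components `c(sigma_a2, sigma_pe2, sigma_e2)`.
#' @param include_pe Fit the permanent-environment effect (default: TRUE
#'   when `sigma_pe2 > 0`).
#' @return Object of class `blup_solution`: `blue` (data frame `term`,
#'   `estimate`), `pbv`, `pe`, `pev`, `sep` (named per animal), `vc`,
#'   `sigma_a2`, `animal_ids`.
#' @details The prediction error variance of animal i is the i-th diagonal
#'   element of the additive block of the inverse MME coefficient matrix
#'   (the equations are scaled by the inverse residual variance, so that
#'   block is the PEV directly). The exact dense inverse is used; systems
#'   are expected to stay below a few thousand equations.
#' @export
solve_blup <- function(dm, Ainv, vc, include_pe = NULL) {
  if (is.null(include_pe)) include_pe <- vc[["sigma_pe2"]] > 0
  X <- dm$X; Za <- dm$Za; Zpe <- dm$Zpe
  Y <- dm$Y
  stopifnot(ncol(Y) == 1L)
  n <- nrow(Y)
  p <- if (is.null(X)) 0L else ncol(X)
  q <- ncol(Za)
  qp <- if (include_pe) ncol(Zpe) else 0L
  parts <- list()
  if (p > 0L) parts$X <- Matrix::Matrix(X, sparse = TRUE)
  parts$Za <- Za
  if (qp > 0L) parts$Zpe <- Zpe
  W <- do.call(cbind, parts)
  M <- as.matrix(Matrix::crossprod(W))
  WtY <- as.matrix(Matrix::crossprod(W, Y))
  G0 <- matrix(vc[["sigma_a2"]], 1, 1)
  P0 <- matrix(if (qp > 0L) vc[["sigma_pe2"]] else 0, 1, 1)
  R0 <- matrix(vc[["sigma_e2"]], 1, 1)
  mm <- mme_assemble(M, WtY, Ainv, G0, P0, R0, p, q, qp)
  ch <- tryCatch(chol(mm$C), error = function(e)
    stop("singular mixed-model equations beyond the declared constraints"))
  Cinv <- chol2inv(ch)
  theta <- as.vector(Cinv %*% mm$rhs)
  ia <- p + seq_len(q)
  ip <- if (qp > 0L) p + q + seq_len(qp) else integer(0)
  pbv <- stats::setNames(theta[ia], dm$animal_ids)
  pev <- stats::setNames(diag(Cinv)[ia], dm$animal_ids)
  out <- list(
    blue = if (p > 0L) data.frame(term = if (is.null(colnames(X)))
                                    paste0("beta", seq_len(p)) else colnames(X),
                                  estimate = theta[seq_len(p)],
                                  stringsAsFactors = FALSE)
           else data.frame(term = character(), estimate = numeric()),
    pbv = pbv,
    pe = if (qp > 0L) stats::setNames(theta[ip], dm$pe_ids) else NULL,
    pev = pev,
    sep = sqrt(pmax(pev, 0)),
    vc = vc, sigma_a2 = vc[["sigma_a2"]],
    animal_ids = dm$animal_ids, n_records = n)
  class(out) <- "blup_solution"
  out
}

#' @export
print.blup_solution <- function(x, ...) {
  cat("<blup_solution>", length(x$pbv), "animals,", x$n_records, "records\n",
      " PBV range:", paste(format(range(x$pbv), digits = 4), collapse = " to "),
      "\n  SEP range:", paste(format(range(x$sep), digits = 4), collapse = " to "),
      "\n")
  invisible(x)
}

#' Prediction error variance and SEP of a solved system
#'
#' @param solution A `blup_solution`.
#' @return Data frame: `animal_id`, `pev`, `sep`.
#' @export
prediction_error_variance <- function(solution) {
  stopifnot(inherits(solution, "blup_solution"))
  data.frame(animal_id = names(solution$pev),
             pev = unname(solution$pev), sep = unname(solution$sep),
             stringsAsFactors = FALSE)
}

#' Reliability and accuracy from SEP
#'
#' `R_AP = 1 - SEP^2 / sigma_a2` (clipped to `[0, 1]`) and `RTi =
#' sqrt(R_AP)`: the squared correlation between true and predicted breeding
#' value and its square root.
#'
#' @param sep Standard error(s) of prediction.
#' @param sigma_a2 Additive genetic variance.
#' @param F Inbreeding coefficient(s); `SEP^2` may legitimately reach
#'   `sigma_a2 (1 + F)` for animals with no information, which still maps to
#'   reliability 0 after clipping.
#' @param tol Tolerance beyond the `sigma_a2 (1 + F)` bound before warning.
#' @return List with `R_AP` and `RTi` vectors.
#' @export
reliability_accuracy <- function(sep, sigma_a2, F = 0, tol = 1e-6) {
  pev <- sep^2
  bound <- sigma_a2 * (1 + F)
  if (any(pev > bound * (1 + tol) + tol)) {
    warning("SEP^2 exceeds sigma_a2 (1 + F) for some animals; clipping")
  }
  rap <- 1 - pev / sigma_a2
  rap[rap < 0] <- 0
  rap[rap > 1] <- 1
  list(R_AP = rap, RTi = sqrt(rap))
}

#' Confidence range for a predicted breeding value
#'
#' `[PBV - k SEP, PBV + k SEP]`, with nominal normal coverage
#' `2 Phi(k) - 1` attached (about 68% at k = 1, 95% at k = 2).
#'
#' @param pbv,sep Predicted breeding value(s) and SEP(s).
#' @param k Half-width multiplier (> 0).
#' @return Data frame `lower`, `upper` with attribute `coverage`.
#' @export
confidence_range <- function(pbv, sep, k = 2) {
  stopifnot(k > 0)
  structure(data.frame(lower = pbv - k * sep, upper = pbv + k * sep),
            coverage = 2 * stats::pnorm(k) - 1)
}

#' Categorical interpretation of accuracy and reliability
#'
#' Accuracy (RTi) bands: below 0.50 "preliminary", 0.50-0.75 "medium",
#' 0.75-0.90 "medium/high", 0.90 and above "true-BV-grade". Reliability
#' (R_AP) bands: below 0.30 "unreliable", then "poor", "sufficient",
#' "more than sufficient", "good", and 0.90 and above "very reliable".
#' All band boundaries are lower-inclusive.
#'
#' @param rti Accuracy values in `[0, 1]`.
#' @param rap Reliability values in `[0, 1]`.
#' @return For the band helpers, a character vector; `interpret_scores()`
#'   returns the input data frame with `accuracy_band` and
#'   `reliability_band` columns appended.
#' @export
accuracy_band <- function(rti) {
  cut(rti, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf), right = FALSE,
      labels = c("preliminary", "medium", "medium/high", "true-BV-grade"))
}

#' @rdname accuracy_band
#' @export
reliability_band <- function(rap) {
  cut(rap, breaks = c(-Inf, 0.30, 0.55, 0.65, 0.75, 0.90, Inf), right = FALSE,
      labels = c("unreliable", "poor", "sufficient", "more than sufficient",
                 "good", "very reliable"))
}

#' @rdname accuracy_band
#' @param scores Data frame with `RTi` and `R_AP` columns.
#' @export
interpret_scores <- function(scores) {
  stopifnot(all(c("RTi", "R_AP") %in% names(scores)))
  scores$accuracy_band <- as.character(accuracy_band(scores$RTi))
  scores$reliability_band <- as.character(reliability_band(scores$R_AP))
  scores
}

#' Per-animal evaluation table
#'
#' Combines PBV, SEP, accuracy and reliability with sex, record and
#' offspring counts into the standard evaluation report for one trait.
#'
#' @param solution A `blup_solution`.
#' @param pedigree The `goat_pedigree` the system was built on.
#' @param records Optional records used in the evaluation (for `n_records`).
#' @return Data frame: `animal_id`, `sex`, `PBV`, `SEP`, `RTi`, `R_AP`,
#'   `accuracy_band`, `reliability_band`, `n_records`, `n_offspring`.
#' @export
evaluation_table <- function(solution, pedigree, records = NULL) {
  stopifnot(inherits(solution, "blup_solution"),
            inherits(pedigree, "goat_pedigree"))
  ped <- pedigree$ped
  ra <- reliability_accuracy(solution$sep, solution$sigma_a2,
                             F = pedigree$inbreeding)
  offs <- tabulate(c(ped$sire[ped$sire > 0L], ped$dam[ped$dam > 0L]),
                   nbins = pedigree$n)
  nrec <- if (is.null(records)) rep(NA_integer_, pedigree$n) else {
    cnt <- table(records$doe_id)
    as.integer(ifelse(ped$animal_id %in% names(cnt),
                      cnt[ped$animal_id], 0L))
  }
  out <- data.frame(animal_id = ped$animal_id, sex = ped$sex,
                    PBV = unname(solution$pbv[ped$animal_id]),
                    SEP = unname(solution$sep[ped$animal_id]),
                    RTi = unname(ra$RTi[ped$animal_id]),
                    R_AP = unname(ra$R_AP[ped$animal_id]),
                    n_records = nrec, n_offspring = offs,
                    stringsAsFactors = FALSE)
  interpret_scores(out)
}
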