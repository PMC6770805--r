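#' Declare an evaluation model
#'
#' Fixed effects are farm, parturition year, month, season and birth type,
#' optionally plus the CSN1S1 genotype class; age in months always enters as
#' a linear and quadratic covariate (centred at the sample mean). Random
#' effects are the additive animal effect (covariance A sigma_a2) and the
#' doe permanent-environment effect.
#'
#' @param traits Character subset of `c("milk", "fat", "protein", "dm")`.
#' @param include_genotype Include the genotype-class fixed effect?
#' @param fixed_factors Factor columns; default the five (or six) above.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(traits = "milk", include_genotype = TRUE,
                       fixed_factors = NULL) {
  stopifnot(all(traits %in% c("milk", "fat", "protein", "dm")))
  if (is.null(fixed_factors)) {
    fixed_factors <- c("farm", "year", "month", "season", "birth_type")
    if (include_genotype) fixed_factors <- c(fixed_factors, "genotype_class")
  }
  if (include_genotype && !"genotype_class" %in% fixed_factors) {
    stop("include_genotype requires genotype_class among the fixed factors")
  }
  out <- list(traits = traits, include_genotype = include_genotype,
              fixed_factors = fixed_factors)
  class(out) <- "model_spec"
  out
}

#' Build design matrices for the animal model
#'
#' Constructs the fixed-effect matrix X (intercept, reference-level-coded
#' factor dummies, centred age and age-squared), the sparse additive
#' incidence Za mapping records to all pedigree animals, and the sparse
#' permanent-environment incidence Zpe mapping records to does with records.
#' Columns of X aliased beyond the reference-level constraints (e.g. season
#' within month) are dropped and reported in the `aliased` attribute.
#'
#' @param records Lactation records carrying the factor columns named in
#'   `spec`,
#'   `age_months`, the trait columns `<trait>_kg`, and either `animal_idx`
#'   (from [connect_to_pedigree()]) or a `doe_id` present in the pedigree.
#' @param spec A [model_spec()].
#' @param pedigree A `goat_pedigree`.
#' @return List: `X`, `Za`, `Zpe`, `Y` (records x traits matrix), `animal_ids`,
#'   `pe_ids`, `spec`.
#' @export
build_design_matrices <- function(records, spec, pedigree) {
  stopifnot(inherits(spec, "model_spec"), inherits(pedigree, "goat_pedigree"))
  n <- nrow(records)
  if (n == 0L) stop("no records")
  idx <- records$animal_idx
  if (is.null(idx)) {
    idx <- match(records$doe_id, pedigree$ped$animal_id)
    if (anyNA(idx)) stop("records contain does absent from the pedigree")
  }
  df <- records
  for (f in spec$fixed_factors) {
    if (is.null(df[[f]])) stop("missing factor column: ", f)
    df[[f]] <- factor(df[[f]])
  }
  age_c <- df$age_months - mean(df$age_months)
  df$age_c <- age_c
  df$age_c2 <- age_c^2
  used <- spec$fixed_factors[vapply(spec$fixed_factors,
                                    function(f) nlevels(df[[f]]) > 1L,
                                    logical(1))]
  fml <- stats::as.formula(paste("~", paste(c(used, "age_c", "age_c2"),
                                            collapse = " + ")))
  X <- stats::model.matrix(fml, df)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    message("dropping ", length(aliased), " aliased column(s): ",
            paste(utils::head(aliased, 5L), collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = idx, x = 1,
                             dims = c(n, pedigree$n))
  pe_ids <- unique(records$doe_id)
  Zpe <- Matrix::sparseMatrix(i = seq_len(n),
                              j = match(records$doe_id, pe_ids), x = 1,
                              dims = c(n, length(pe_ids)))
  Y <- sapply(spec$traits, function(tr) {
    col <- paste0(tr, "_kg")
    if (is.null(records[[col]])) stop("missing trait column: ", col)
    records[[col]]
  })
  Y <- matrix(Y, nrow = n, dimnames = list(NULL, spec$traits))
  structure(list(X = X, Za = Za, Zpe = Zpe, Y = Y,
                 animal_ids = pedigree$ped$animal_id, pe_ids = pe_ids,
                 spec = spec),
            aliased = aliased)
}

# ---- internal REML machinery (T traits with equal design) -----------------

# assemble the mixed-model-equations coefficient matrix (dense) and rhs for
# T traits sharing the design W = [X Za Zpe]; ordering is trait-major with
# [fixed, additive, pe] within trait.
mme_assemble <- function(M, WtY, Ainv, G0, P0, R0, p, q, qp) {
  T_ <- nrow(R0)
  R0inv <- solve(R0)
  G0inv <- solve(G0)
  P0inv <- if (qp > 0L) solve(P0) else NULL
  b <- p + q + qp
  C <- matrix(0, T_ * b, T_ * b)
  rhs <- numeric(T_ * b)
  ia <- p + seq_len(q)
  ip <- if (qp > 0L) p + q + seq_len(qp) else integer(0)
  Ainv_d <- as.matrix(Ainv)
  for (t in seq_len(T_)) {
    rt <- (t - 1L) * b
    for (u in seq_len(T_)) {
      ru <- (u - 1L) * b
      C[rt + seq_len(b), ru + seq_len(b)] <- R0inv[t, u] * M
      C[rt + ia, ru + ia] <- C[rt + ia, ru + ia] + G0inv[t, u] * Ainv_d
      if (qp > 0L) {
        dd <- cbind(rt + ip, ru + ip)
        C[dd] <- C[dd] + P0inv[t, u]
      }
    }
    rhs[rt + seq_len(b)] <- as.vector(WtY %*% R0inv[t, ])
  }
  list(C = C, rhs = rhs, R0inv = R0inv)
}

# nearest symmetric PSD projection (eigenvalue clipping at a small floor)
nearest_psd <- function(S, floor_frac = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  fl <- floor_frac * max(abs(ev$values), 1e-12)
  if (min(ev$values) >= fl) return(S)
  V <- ev$vectors %*% diag(pmax(ev$values, fl), nrow(S)) %*% t(ev$vectors)
  (V + t(V)) / 2
}

#' EM/AI-REML for the repeated-records animal model
#'
#' Estimates the additive, permanent-environment and residual (co)variance
#' matrices for one or two traits sharing the same design, by monotone
#' EM-REML, optionally accelerated (univariate case) with safeguarded
#' average-information Newton steps after a short EM burn-in. Convergence is
#' declared when the squared relative change of the stacked parameter vector
#' falls below `tol`. The restricted log-likelihood is evaluated from the
#' mixed-model equations at every iterate and is non-decreasing across EM
#' steps; AI steps that would decrease it are replaced by EM steps.
#'
#' @param dm Design list from [build_design_matrices()] (1 or 2 traits).
#' @param Ainv Sparse inverse numerator relationship matrix (all pedigree
#'   animals, pedigree order).
#' @param start Optional list with `G0`, `P0`, `R0` start matrices (scalars
#'   for one trait). Default: var(y)/3 on every channel, near-zero
#'   covariances.
#' @param tol Convergence criterion on the squared relative parameter change.
#' @param max_iter Iteration cap; hitting it is flagged, not an error.
#' @param method `"ai"` (default; EM burn-in then safeguarded AI, univariate
#'   only) or `"em"` (pure EM).
#' @param include_pe Fit the permanent-environment effect? Default TRUE.
#' @param verbose Print the likelihood trace?
#' @return An object of class `reml_fit`: variance components (`G0`, `P0`,
#'   `R0` and, univariately, `vc = c(sigma_a2, sigma_pe2, sigma_e2,
#'   sigma_p2)`), `h2`, `h2_se`, `repeatability`, component standard errors
#'   (`se`, from the inverse average-information matrix), `loglik_trace`,
#'   `converged`, `criterion`, `iterations`, and the pieces needed to solve
#'   the MME at the estimates.
#' @export
reml_fit <- function(dm, Ainv, start = NULL, tol = 1e-12, max_iter = 200L,
                     method = c("ai", "em"), include_pe = TRUE,
                     verbose = FALSE) {
  method <- match.arg(method)
  X <- dm$X; Za <- dm$Za; Zpe <- dm$Zpe; Y <- dm$Y
  T_ <- ncol(Y)
  n <- nrow(Y)
  p <- ncol(X)
  q <- ncol(Za)
  qp <- if (include_pe) ncol(Zpe) else 0L
  W <- if (qp > 0L) cbind(Matrix::Matrix(X, sparse = TRUE), Za, Zpe)
       else cbind(Matrix::Matrix(X, sparse = TRUE), Za)
  M <- as.matrix(Matrix::crossprod(W))
  WtY <- as.matrix(Matrix::crossprod(W, Y))
  YtY <- crossprod(Y)
  # log|A| = -log|A^-1|, constant across iterations
  ldA <- -2 * sum(log(Matrix::diag(Matrix::chol(Ainv))))
  vary <- apply(Y, 2L, stats::var)
  floorv <- 1e-8 * max(vary)
  if (is.null(start)) {
    G0 <- diag(vary / 3, T_); R0 <- diag(vary / 3, T_)
    P0 <- if (qp > 0L) diag(vary / 3, T_) else diag(0, T_)
  } else {
    G0 <- as.matrix(start$G0); R0 <- as.matrix(start$R0)
    P0 <- if (qp > 0L) as.matrix(start$P0) else diag(0, T_)
  }
  ia <- p + seq_len(q)
  ip <- if (qp > 0L) p + q + seq_len(qp) else integer(0)
  b <- p + q + qp
  Ainv_d <- as.matrix(Ainv)

  pack <- function(G0, P0, R0) {
    v <- c(G0[upper.tri(G0, diag = TRUE)], R0[upper.tri(R0, diag = TRUE)])
    if (qp > 0L) v <- c(v, P0[upper.tri(P0, diag = TRUE)])
    v
  }

  loglik_trace <- numeric(0)
  crit <- Inf
  prev_ll <- -Inf
  last_step <- "em"
  state_prev <- NULL
  ai_prop <- NULL
  ai_halvings <- 0L
  ai_fails <- 0L     # after repeated full AI failures, stay with EM
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    mm <- mme_assemble(M, WtY, Ainv, G0, P0, R0, p, q, qp)
    ch <- tryCatch(chol(mm$C), error = function(e) NULL)
    if (is.null(ch)) stop("mixed-model equations not positive definite; ",
                          "check design rank and start values")
    Cinv <- chol2inv(ch)
    theta <- Cinv %*% mm$rhs
    ldC <- 2 * sum(log(diag(ch)))
    yPy <- sum(mm$R0inv * YtY) - sum(theta * mm$rhs)
    ll <- -0.5 * (n * determinant_log(R0) + q * determinant_log(G0) +
                  T_ * ldA +
                  (if (qp > 0L) qp * determinant_log(P0) else 0) +
                  ldC + yPy)
    if (!is.finite(ll)) stop("non-finite REML log-likelihood; aborting")
    # safeguard: an AI proposal that lowered the likelihood is first
    # step-halved towards its base point, then abandoned for an EM step
    if (last_step == "ai" && ll < prev_ll - 1e-8 && !is.null(state_prev)) {
      if (ai_halvings < 3L) {
        ai_halvings <- ai_halvings + 1L
        blend <- function(base, prop) base + (prop - base) / 2^ai_halvings
        G0 <- nearest_psd(pmax_diag(blend(state_prev$G0, ai_prop$G0), floorv))
        if (qp > 0L) P0 <- nearest_psd(pmax_diag(blend(state_prev$P0, ai_prop$P0),
                                                 floorv))
        R0 <- nearest_psd(pmax_diag(blend(state_prev$R0, ai_prop$R0), floorv))
        it <- it - 1L
        next
      }
      G0 <- state_prev$G0; P0 <- state_prev$P0; R0 <- state_prev$R0
      last_step <- "em-redo"
      ai_fails <- ai_fails + 1L
      it <- it - 1L
      next
    }
    ai_halvings <- 0L
    loglik_trace <- c(loglik_trace, ll)
    prev_ll <- ll

    TH <- matrix(theta, b, T_)           # columns are per-trait solutions
    Ahat <- TH[ia, , drop = FALSE]
    Phat <- if (qp > 0L) TH[ip, , drop = FALSE] else NULL
    Ehat <- Y - as.matrix(W %*% TH)

    # EM updates; the trace matrices are reused by the AI step
    G0_new <- matrix(0, T_, T_)
    P0_new <- matrix(0, T_, T_)
    R0_new <- matrix(0, T_, T_)
    trA <- matrix(0, T_, T_)   # tr(Ainv C^{a_t a_u})
    trPp <- matrix(0, T_, T_)  # tr(C^{p_t p_u})
    trMm <- matrix(0, T_, T_)  # tr(M C^{theta_t theta_u})
    for (t in seq_len(T_)) {
      rt <- (t - 1L) * b
      for (u in t:T_) {
        ru <- (u - 1L) * b
        Cau <- Cinv[rt + ia, ru + ia]
        trA[t, u] <- trA[u, t] <- sum(Ainv_d * Cau)
        G0_new[t, u] <- G0_new[u, t] <-
          (sum(Ahat[, t] * as.vector(Ainv %*% Ahat[, u])) + trA[t, u]) / q
        if (qp > 0L) {
          trPp[t, u] <- trPp[u, t] <- sum(diag_block(Cinv, rt + ip, ru + ip))
          P0_new[t, u] <- P0_new[u, t] <-
            (sum(Phat[, t] * Phat[, u]) + trPp[t, u]) / qp
        }
        trMm[t, u] <- trMm[u, t] <-
          sum(M * Cinv[rt + seq_len(b), ru + seq_len(b)])
        R0_new[t, u] <- R0_new[u, t] <-
          (sum(Ehat[, t] * Ehat[, u]) + trMm[t, u]) / n
      }
    }

    proposed <- NULL
    if (method == "ai" && it > 3L && last_step != "em-redo" && ai_fails < 4L) {
      proposed <- ai_step(G0, P0, R0, Ahat, Phat, Ehat, Cinv, Ainv, M, W,
                          dm$Za, dm$Zpe, mm$R0inv, trA, trPp, trMm,
                          n, q, qp, b, floorv)
    }
    state_prev <- list(G0 = G0, P0 = P0, R0 = R0)
    old <- pack(G0, P0, R0)
    if (!is.null(proposed)) {
      ai_prop <- proposed
      G0 <- proposed$G0
      if (qp > 0L) P0 <- proposed$P0
      R0 <- proposed$R0
      last_step <- "ai"
    } else {
      G0 <- nearest_psd(pmax_diag(G0_new, floorv))
      if (qp > 0L) P0 <- nearest_psd(pmax_diag(P0_new, floorv))
      R0 <- nearest_psd(pmax_diag(R0_new, floorv))
      last_step <- "em"
    }
    new <- pack(G0, P0, R0)
    crit <- sum((new - old)^2) / max(sum(old^2), floorv^2)
    if (verbose) message(sprintf("iter %3d  logL %.6f  crit %.3e (%s)",
                                 it, ll, crit, last_step))
    if (crit < tol) { converged <- TRUE; break }
  }

  fit <- list(G0 = G0, P0 = P0, R0 = R0, include_pe = qp > 0L,
              traits = colnames(Y),
              loglik_trace = loglik_trace, converged = converged,
              criterion = crit, iterations = it, n = n, p = p, q = q, qp = qp,
              dm = dm, Ainv = Ainv)
  class(fit) <- "reml_fit"
  # average-information matrix and SEs at the optimum
  fit <- add_reml_se(fit)
  if (T_ == 1L) {
    vc <- c(sigma_a2 = G0[1L], sigma_pe2 = if (qp > 0L) P0[1L] else 0,
            sigma_e2 = R0[1L])
    vc <- c(vc, sigma_p2 = sum(vc))
    fit$vc <- vc
    fit$h2 <- heritability(vc)
    fit$repeatability <- repeatability(vc)
  }
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", length(x$traits), "trait(s):",
      paste(x$traits, collapse = ", "), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)",
      " criterion:", format(x$criterion, digits = 3), "\n")
  if (!is.null(x$vc)) {
    cat("  sigma_a2:", format(x$vc[["sigma_a2"]], digits = 6),
        " sigma_pe2:", format(x$vc[["sigma_pe2"]], digits = 6),
        " sigma_e2:", format(x$vc[["sigma_e2"]], digits = 6), "\n")
    cat("  h2:", format(x$h2, digits = 4),
        if (!is.null(x$h2_se)) paste0("+/- ", format(x$h2_se, digits = 3)),
        " repeatability:", format(x$repeatability, digits = 4), "\n")
  }
  invisible(x)
}

determinant_log <- function(S) {
  d <- determinant(as.matrix(S), logarithm = TRUE)
  as.numeric(d$modulus)
}

pmax_diag <- function(S, floorv) {
  diag(S) <- pmax(diag(S), floorv)
  S
}

# diagonal (i,i) entries of a cross block as a vector product helper
diag_block <- function(Cinv, rows, cols) {
  Cinv[cbind(rows, cols)]
}

# One safeguarded AI-Newton proposal for the (co)variance matrices; works
# for any number of traits sharing the design. The score uses the trace
# identities tr(P V_a,tu) = m q (G0^-1)_tu - sum(B * trA) with
# B = G0^-1 E_tu^sym G0^-1 (and the analogous forms for the PE and residual
# blocks), where trA/trPp/trMm are the block traces already computed for
# the EM update; the average information is built from working vectors
# f_i = V_i P y. Returns NULL when the proposal leaves the admissible
# region, which falls back to the EM update.
ai_step <- function(G0, P0, R0, Ahat, Phat, Ehat, Cinv, Ainv, M, W, Za, Zpe,
                    R0inv, trA, trPp, trMm, n, q, qp, b, floorv) {
  T_ <- nrow(R0)
  G0inv <- tryCatch(solve(G0), error = function(e) NULL)
  P0inv <- if (qp > 0L) tryCatch(solve(P0), error = function(e) NULL) else NULL
  if (is.null(G0inv) || (qp > 0L && is.null(P0inv))) return(NULL)
  Py <- Ehat %*% R0inv
  ut <- which(upper.tri(diag(T_), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  npar_blk <- nrow(ut)
  sA <- matrix(0, q, T_)
  for (t in seq_len(T_)) {
    sA[, t] <- as.vector(Matrix::solve(Ainv, Matrix::crossprod(Za, Py[, t])))
  }
  gP <- if (qp > 0L) as.matrix(Matrix::crossprod(Zpe, Py)) else NULL

  esym <- function(t, u) {
    E <- matrix(0, T_, T_); E[t, u] <- E[t, u] + 1; E[u, t] <- E[u, t] + 1
    if (t == u) E[t, t] <- 1
    E
  }
  fvecs <- list(); grads <- numeric(0)
  # additive block
  for (r in seq_len(npar_blk)) {
    t <- ut[r, 1L]; u <- ut[r, 2L]
    E <- esym(t, u)
    f <- matrix(0, n, T_)
    f[, t] <- as.vector(Za %*% sA[, u])
    if (u != t) f[, u] <- f[, u] + as.vector(Za %*% sA[, t])
    B <- G0inv %*% E %*% G0inv
    trPV <- q * sum(G0inv * E) - sum(B * trA)
    grads <- c(grads, -0.5 * (trPV - sum(f * Py)))
    fvecs[[length(fvecs) + 1L]] <- f
  }
  if (qp > 0L) {
    for (r in seq_len(npar_blk)) {
      t <- ut[r, 1L]; u <- ut[r, 2L]
      E <- esym(t, u)
      f <- matrix(0, n, T_)
      f[, t] <- as.vector(Zpe %*% gP[, u])
      if (u != t) f[, u] <- f[, u] + as.vector(Zpe %*% gP[, t])
      B <- P0inv %*% E %*% P0inv
      trPV <- qp * sum(P0inv * E) - sum(B * trPp)
      grads <- c(grads, -0.5 * (trPV - sum(f * Py)))
      fvecs[[length(fvecs) + 1L]] <- f
    }
  }
  for (r in seq_len(npar_blk)) {
    t <- ut[r, 1L]; u <- ut[r, 2L]
    E <- esym(t, u)
    f <- matrix(0, n, T_)
    f[, t] <- Py[, u]
    if (u != t) f[, u] <- f[, u] + Py[, t]
    B <- R0inv %*% E %*% R0inv
    trPV <- n * sum(R0inv * E) - sum(B * trMm)
    grads <- c(grads, -0.5 * (trPV - sum(f * Py)))
    fvecs[[length(fvecs) + 1L]] <- f
  }
  P_apply <- function(V) {
    V1 <- V %*% R0inv
    U <- as.matrix(Matrix::crossprod(W, V1))
    S <- matrix(0, b, T_)
    for (t in seq_len(T_)) {
      rows <- (t - 1L) * b + seq_len(b)
      acc <- numeric(b)
      for (u in seq_len(T_)) {
        acc <- acc + Cinv[rows, (u - 1L) * b + seq_len(b)] %*% U[, u]
      }
      S[, t] <- acc
    }
    V1 - as.matrix(W %*% S) %*% R0inv
  }
  k <- length(fvecs)
  Pf <- lapply(fvecs, P_apply)
  AI <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fvecs[[i]] * Pf[[j]])
  }
  vech_get <- function(S) S[cbind(ut[, 1L], ut[, 2L])]
  vech_set <- function(v) {
    S <- matrix(0, T_, T_)
    S[cbind(ut[, 1L], ut[, 2L])] <- v
    S[cbind(ut[, 2L], ut[, 1L])] <- v
    S
  }
  cur <- c(vech_get(G0), if (qp > 0L) vech_get(P0), vech_get(R0))
  k_par <- length(cur)
  is_var <- rep(ut[, 1L] == ut[, 2L], times = k_par / npar_blk)
  # active-set Newton: variance components pushed below the floor are pinned
  # there and the step is re-solved for the free parameters, so the joint
  # move stays consistent with the constraint
  pinned <- rep(FALSE, k_par)
  step <- NULL
  for (pass in 1:3) {
    free <- !pinned
    delta <- numeric(k_par)
    delta[pinned] <- floorv - cur[pinned]
    rhs <- grads[free]
    if (any(pinned)) {
      rhs <- rhs - AI[free, pinned, drop = FALSE] %*% delta[pinned]
    }
    sol <- tryCatch(solve(AI[free, free, drop = FALSE], rhs),
                    error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    delta[free] <- sol
    step <- delta
    newly <- is_var & !pinned & (cur + step < floorv)
    if (!any(newly)) break
    pinned <- pinned | newly
  }
  if (any(!is.finite(step))) return(NULL)
  # damp extreme Newton steps (far from the optimum the AI matrix is a poor
  # curvature estimate); cap the largest relative change at 5x
  relmax <- max(abs(step) / (abs(cur) + 0.01 * max(abs(cur))))
  if (relmax > 5) step <- step * (5 / relmax)
  cand <- cur + step
  i0 <- 0L
  G0c <- vech_set(cand[i0 + seq_len(npar_blk)]); i0 <- i0 + npar_blk
  P0c <- if (qp > 0L) { v <- vech_set(cand[i0 + seq_len(npar_blk)])
                        i0 <- i0 + npar_blk; v } else P0
  R0c <- vech_set(cand[i0 + seq_len(npar_blk)])
  G0c <- nearest_psd(pmax_diag(G0c, floorv))
  if (qp > 0L) P0c <- nearest_psd(pmax_diag(P0c, floorv))
  R0c <- nearest_psd(pmax_diag(R0c, floorv))
  # the residual covariance must stay strictly positive definite
  if (min(eigen(R0c, symmetric = TRUE, only.values = TRUE)$values) <=
      0.5 * floorv) return(NULL)
  list(G0 = G0c, P0 = P0c, R0 = R0c)
}

# average-information matrix at the current estimates (any T); fills
# fit$ai_matrix, fit$se (component SEs) and, univariately, fit$h2_se
add_reml_se <- function(fit) {
  dm <- fit$dm
  X <- dm$X; Za <- dm$Za; Zpe <- dm$Zpe; Y <- dm$Y
  T_ <- ncol(Y); n <- nrow(Y)
  p <- fit$p; q <- fit$q; qp <- fit$qp
  W <- if (qp > 0L) cbind(Matrix::Matrix(X, sparse = TRUE), Za, Zpe)
       else cbind(Matrix::Matrix(X, sparse = TRUE), Za)
  b <- p + q + qp
  M <- as.matrix(Matrix::crossprod(W))
  WtY <- as.matrix(Matrix::crossprod(W, Y))
  mm <- mme_assemble(M, WtY, fit$Ainv, fit$G0, fit$P0, fit$R0, p, q, qp)
  ch <- chol(mm$C)
  Cinv <- chol2inv(ch)
  theta <- Cinv %*% mm$rhs
  TH <- matrix(theta, b, T_)
  Ehat <- Y - as.matrix(W %*% TH)
  R0inv <- mm$R0inv
  Py <- Ehat %*% R0inv
  ia <- p + seq_len(q)
  ipp <- if (qp > 0L) p + q + seq_len(qp) else integer(0)

  P_apply <- function(V) {                      # V is n x T
    V1 <- V %*% R0inv
    U <- as.matrix(Matrix::crossprod(W, V1))    # b x T
    S <- matrix(0, b, T_)
    for (t in seq_len(T_)) {
      rows <- (t - 1L) * b + seq_len(b)
      acc <- numeric(b)
      for (u in seq_len(T_)) {
        acc <- acc + Cinv[rows, (u - 1L) * b + seq_len(b)] %*% U[, u]
      }
      S[, t] <- acc
    }
    H <- as.matrix(W %*% S)
    V1 - H %*% R0inv
  }

  sA <- sapply(seq_len(T_), function(t)
    as.vector(Matrix::solve(fit$Ainv, Matrix::crossprod(Za, Py[, t]))))
  sA <- matrix(sA, ncol = T_)
  params <- list()
  fvecs <- list()
  ut <- which(upper.tri(diag(T_), diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(ut))) {
    t <- ut[r, 1L]; u <- ut[r, 2L]
    fa <- matrix(0, n, T_)
    fa[, t] <- as.vector(Za %*% sA[, u])
    if (u != t) fa[, u] <- fa[, u] + as.vector(Za %*% sA[, t])
    params[[length(params) + 1L]] <- c("a", t, u); fvecs[[length(fvecs) + 1L]] <- fa
  }
  if (qp > 0L) {
    gP <- sapply(seq_len(T_), function(t)
      as.vector(Matrix::crossprod(Zpe, Py[, t])))
    gP <- matrix(gP, ncol = T_)
    for (r in seq_len(nrow(ut))) {
      t <- ut[r, 1L]; u <- ut[r, 2L]
      fp <- matrix(0, n, T_)
      fp[, t] <- as.vector(Zpe %*% gP[, u])
      if (u != t) fp[, u] <- fp[, u] + as.vector(Zpe %*% gP[, t])
      params[[length(params) + 1L]] <- c("pe", t, u); fvecs[[length(fvecs) + 1L]] <- fp
    }
  }
  for (r in seq_len(nrow(ut))) {
    t <- ut[r, 1L]; u <- ut[r, 2L]
    fe <- matrix(0, n, T_)
    fe[, t] <- Py[, u]
    if (u != t) fe[, u] <- fe[, u] + Py[, t]
    params[[length(params) + 1L]] <- c("e", t, u); fvecs[[length(fvecs) + 1L]] <- fe
  }
  k <- length(fvecs)
  Pf <- lapply(fvecs, P_apply)
  AI <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fvecs[[i]] * Pf[[j]])
  }
  labs <- vapply(params, function(z) paste0(z[1L], z[2L], z[3L]), character(1))
  dimnames(AI) <- list(labs, labs)
  fit$ai_matrix <- AI
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  if (is.null(covm)) {
    warning("singular average-information matrix; standard errors missing")
    fit$se <- NULL
    return(fit)
  }
  fit$param_cov <- covm
  fit$se <- sqrt(pmax(diag(covm), 0))
  names(fit$se) <- labs
  if (T_ == 1L) {
    sa <- fit$G0[1L]; sp_ <- if (qp > 0L) fit$P0[1L] else 0; se_ <- fit$R0[1L]
    stot <- sa + sp_ + se_
    grad <- if (qp > 0L) c((stot - sa) / stot^2, -sa / stot^2, -sa / stot^2)
            else c((stot - sa) / stot^2, -sa / stot^2)
    fit$h2_se <- sqrt(max(0, t(grad) %*% covm %*% grad))
  }
  fit
}

#' Heritability from variance components
#'
#' `h2 = sigma_a2 / sigma_p2` with `sigma_p2 = sigma_a2 + sigma_pe2 +
#' sigma_e2`.
#'
#' @param vc Named vector with `sigma_a2`, `sigma_pe2`, `sigma_e2` (a
#'   `sigma_p2` element, if present, is ignored and recomputed).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  sp <- vc[["sigma_a2"]] + vc[["sigma_pe2"]] + vc[["sigma_e2"]]
  if (sp <= 0) stop("zero phenotypic variance")
  unname(vc[["sigma_a2"]] / sp)
}

#' Repeatability from variance components
#'
#' `(sigma_a2 + sigma_pe2) / sigma_p2`; always >= h2.
#'
#' @inheritParams heritability
#' @return Repeatability in `[0, 1]`.
#' @export
repeatability <- function(vc) {
  sp <- vc[["sigma_a2"]] + vc[["sigma_pe2"]] + vc[["sigma_e2"]]
  if (sp <= 0) stop("zero phenotypic variance")
  unname((vc[["sigma_a2"]] + vc[["sigma_pe2"]]) / sp)
}

#' Genetic and phenotypic correlations from a bivariate fit
#'
#' `r_G = sigma_a12 / sqrt(sigma_a1^2 sigma_a2^2)`; the phenotypic
#' covariance is the sum of the additive, permanent-environment and residual
#' covariances. Approximate standard errors come from the inverse
#' average-information matrix by the delta method.
#'
#' @param fit A bivariate `reml_fit` (or a list with `G0`, `P0`, `R0`).
#' @return List: `r_G`, `r_P`, and (when the fit carries a parameter
#'   covariance) `r_G_se`, `r_P_se`.
#' @export
correlations <- function(fit) {
  G0 <- fit$G0; P0 <- fit$P0; R0 <- fit$R0
  stopifnot(nrow(G0) == 2L)
  if (any(diag(G0) <= 0)) stop("zero additive variance")
  S <- G0 + P0 + R0
  r_G <- G0[1L, 2L] / sqrt(G0[1L, 1L] * G0[2L, 2L])
  r_P <- S[1L, 2L] / sqrt(S[1L, 1L] * S[2L, 2L])
  out <- list(r_G = r_G, r_P = r_P)
  if (!is.null(fit$param_cov)) {
    labs <- colnames(fit$param_cov)
    # d r / d (v1, c, v2) for r = c / sqrt(v1 v2)
    dr <- function(v1, c12, v2) {
      r <- c12 / sqrt(v1 * v2)
      c(-r / (2 * v1), 1 / sqrt(v1 * v2), -r / (2 * v2))
    }
    gG <- numeric(length(labs)); names(gG) <- labs
    gG[c("a11", "a12", "a22")] <- dr(G0[1, 1], G0[1, 2], G0[2, 2])
    out$r_G_se <- sqrt(max(0, t(gG) %*% fit$param_cov %*% gG))
    gP <- numeric(length(labs)); names(gP) <- labs
    d <- dr(S[1, 1], S[1, 2], S[2, 2])
    for (pref in intersect(c("a", "pe", "e"),
                           unique(sub("[0-9]+$", "", labs)))) {
      gP[paste0(pref, c("11", "12", "22"))] <- d
    }
    out$r_P_se <- sqrt(max(0, t(gP) %*% fit$param_cov %*% gP))
  }
  out
}
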