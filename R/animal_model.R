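#' Specify a multivariate animal model
#'
#' Describes the model `Y = Xb + Z_v v + Z_a a + e`: trait-specific
#' fixed effects (intercept plus the listed factors, reference-level
#' coded, full trait-by-factor interaction), an optional among-vial
#' random term, and a pedigree-based additive genetic term whose
#' covariance is the Kronecker product of the additive covariance
#' matrix G with the numerator relationship matrix A.
#'
#' @param traits Character vector of trait column names (>= 1).
#' @param fixed Character vector of fixed-effect factor columns
#'   (subset of `c("generation", "observer")` or other columns present
#'   in the data); factors with a single level are dropped.
#' @param vial Include the among-vial random term (default `TRUE`).
#' @param vial_diagonal Constrain the vial covariance to be diagonal
#'   (scalar per-trait variances, no covariances); default `FALSE`
#'   (unstructured).
#' @param arm Restrict the fit to one mating arm (`"outbred"` or
#'   `"inbred"`); `NULL` uses all records.
#' @param tol Relative log-likelihood convergence tolerance
#'   (default `1e-8`).
#' @param max_iter Maximum REML rounds (default 200).
#' @return A `model_spec` list.
#' @export
model_spec <- function(traits, fixed = c("generation", "observer"),
                       vial = TRUE, vial_diagonal = FALSE, arm = NULL,
                       tol = 1e-8, max_iter = 200L) {
  stopifnot(length(traits) >= 1L, is.character(traits))
  if (!is.null(arm)) arm <- match.arg(arm, c("outbred", "inbred"))
  structure(list(traits = traits, fixed = fixed, vial = vial,
                 vial_diagonal = vial_diagonal, arm = arm,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "model_spec")
}

# ---- parameter blocks ------------------------------------------------
# Each covariance component is either unstructured ("us", parameters =
# lower-triangle elements of a t x t covariance) or factor-analytic
# ("fa", covariance = Lambda Lambda', Lambda lower-triangular t x r).

us_block <- function(name, t, q_em, diagonal = FALSE) {
  ij <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  if (diagonal) ij <- ij[ij[, 1] == ij[, 2], , drop = FALSE]
  list(name = name, type = "us", t = t, q_em = q_em,
       diagonal = diagonal, ij = ij, npar = nrow(ij))
}

fa_block <- function(name, t, r, q_em) {
  ij <- which(lower.tri(matrix(0, t, r), diag = TRUE), arr.ind = TRUE)
  ij <- ij[ij[, 2] <= r, , drop = FALSE]
  list(name = name, type = "fa", t = t, r = r, q_em = q_em, ij = ij,
       npar = nrow(ij))
}

block_cov <- function(blk, theta) {
  t <- blk$t
  if (blk$type == "us") {
    S <- matrix(0, t, t)
    S[blk$ij] <- theta
    S[blk$ij[, c(2, 1), drop = FALSE]] <- theta
    S
  } else {
    tcrossprod(block_lambda(blk, theta))
  }
}

block_lambda <- function(blk, theta) {
  L <- matrix(0, blk$t, blk$r)
  L[blk$ij] <- theta
  L
}

# derivative of the covariance wrt parameter k (t x t symmetric)
block_dcov <- function(blk, theta, k) {
  t <- blk$t
  D <- matrix(0, t, t)
  i <- blk$ij[k, 1]; j <- blk$ij[k, 2]
  if (blk$type == "us") {
    D[i, j] <- D[j, i] <- 1
  } else {
    L <- block_lambda(blk, theta)
    D[i, ] <- D[i, ] + L[, j]
    D[, i] <- D[, i] + L[, j]
  }
  D
}

# initial values from the phenotypic covariance of OLS residuals
init_theta <- function(blk, S_p) {
  share <- c(additive = 0.4, vial = 0.2, residual = 0.4)[blk$name]
  if (is.na(share)) share <- 1 / 3
  S0 <- S_p * share + diag(1e-6 * mean(diag(S_p)), nrow(S_p))
  if (blk$type == "us") {
    if (blk$diagonal) diag(S0)[blk$ij[, 1]] else S0[blk$ij]
  } else {
    ee <- eigen(S0, symmetric = TRUE)
    r <- blk$r
    lam <- pmax(ee$values[seq_len(r)], 1e-8 * mean(diag(S0)))
    L0 <- ee$vectors[, seq_len(r), drop = FALSE] %*% diag(sqrt(lam), r)
    lower_triangularize(L0, r)[blk$ij]
  }
}

# LQ-rotate a t x r loading matrix to lower-triangular form without
# changing L L'; column signs fixed so the diagonal is non-negative
lower_triangularize <- function(L0, r) {
  L <- t(qr.R(qr(t(L0))))[, seq_len(r), drop = FALSE]
  sgn <- sign(diag(as.matrix(L[seq_len(r), seq_len(r), drop = FALSE])))
  sgn[sgn == 0] <- 1
  L %*% diag(sgn, r)
}

psd_clamp <- function(S, floor = 0) {
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(ee$values) >= floor) return((S + t(S)) / 2)
  ee$vectors %*% (pmax(ee$values, floor) * t(ee$vectors))
}

chol_lower <- function(S, t) {
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(ee$values, 1e-12 * max(abs(ee$values), 1e-300))
  lower_triangularize(ee$vectors %*% diag(sqrt(vals), t), t)
}

# ---- likelihood strata ----------------------------------------------
# The REML log-likelihood is a sum over independent strata:
#   dense:   y ~ N(X beta, sum_c Sigma_c (x) K_c)   (trait-major)
#   scatter: N iid t-vectors with covariance C = sum_c s_c Sigma_c,
#            summarized by their scatter matrix W (used for balanced
#            within-family contrasts, where the vial term drops out
#            and the additive kernel is a known scalar)

eval_problem <- function(blocks, thetas, prob, need_P = TRUE) {
  Sig <- Map(block_cov, blocks, thetas)
  names(Sig) <- names(blocks)
  t <- prob$t
  ll <- 0
  caches <- vector("list", length(prob$strata))
  for (si in seq_along(prob$strata)) {
    st <- prob$strata[[si]]
    if (st$type == "dense") {
      n <- nrow(st$Y)
      V <- 0
      for (cn in names(st$Ks))
        V <- V + kronecker(Sig[[cn]], st$Ks[[cn]])
      cholV <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(cholV)) return(NULL)
      yv <- as.numeric(st$Y)
      logdetV <- 2 * sum(log(diag(cholV)))
      if (need_P) {
        Vi <- chol2inv(cholV)
        ViX <- Vi %*% st$X
        Viy <- as.numeric(Vi %*% yv)
      } else {
        ViX <- backsolve(cholV, forwardsolve(t(cholV), st$X))
        Viy <- as.numeric(backsolve(cholV,
                                    forwardsolve(t(cholV), yv)))
      }
      if (ncol(st$X) > 0) {
        C <- crossprod(st$X, ViX)
        cholC <- tryCatch(chol(C), error = function(e) NULL)
        if (is.null(cholC)) return(NULL)
        logdetC <- 2 * sum(log(diag(cholC)))
        beta <- backsolve(cholC,
                          forwardsolve(t(cholC), crossprod(st$X, Viy)))
        w <- Viy - as.numeric(ViX %*% beta)
      } else {
        logdetC <- 0
        beta <- numeric(0)
        w <- Viy
        cholC <- NULL
      }
      ll <- ll - 0.5 * (logdetV + logdetC + sum(yv * w))
      cache <- list(w = w, beta = beta, n = n)
      if (need_P) {
        P <- Vi
        if (ncol(st$X) > 0)
          P <- P - ViX %*% backsolve(cholC,
                                     forwardsolve(t(cholC), t(ViX)))
        cache$P <- P
      }
      caches[[si]] <- cache
    } else {  # scatter
      C <- 0
      for (cn in names(st$s)) C <- C + st$s[[cn]] * Sig[[cn]]
      cholC <- tryCatch(chol(C), error = function(e) NULL)
      if (is.null(cholC)) return(NULL)
      B <- chol2inv(cholC)
      ll <- ll - 0.5 * (st$N * 2 * sum(log(diag(cholC))) +
                          sum(B * st$W))
      caches[[si]] <- list(B = B, BWB = B %*% st$W %*% B)
    }
  }
  list(ll = ll, caches = caches, thetas = thetas)
}

add_P <- function(ev, blocks, prob) {
  has_P <- all(vapply(seq_along(prob$strata), function(si)
    prob$strata[[si]]$type != "dense" || !is.null(ev$caches[[si]]$P),
    TRUE))
  if (has_P) ev else eval_problem(blocks, ev$thetas, prob,
                                  need_P = TRUE)
}

# Aggregated trace (Tc) and quadratic (Wc) matrices per component,
# plus the per-stratum pieces needed for the AI matrix.
iter_stats <- function(blocks, ev, prob) {
  t <- prob$t
  comp <- names(blocks)
  Tc <- Wc <- stats::setNames(rep(list(matrix(0, t, t)), length(comp)),
                              comp)
  Ms <- vector("list", length(prob$strata))
  for (si in seq_along(prob$strata)) {
    st <- prob$strata[[si]]
    ca <- ev$caches[[si]]
    if (st$type == "dense") {
      n <- ca$n
      Wm <- matrix(ca$w, n, t)
      Mlist <- list()
      for (cn in names(st$Ks)) {
        M <- st$Ks[[cn]] %*% Wm
        Mlist[[cn]] <- M
        Wc[[cn]] <- Wc[[cn]] + crossprod(Wm, M)
        Tadd <- matrix(0, t, t)
        for (r in seq_len(t)) for (s in seq_len(r)) {
          v <- sum(ca$P[(s - 1L) * n + seq_len(n),
                        (r - 1L) * n + seq_len(n)] * st$Ks[[cn]])
          Tadd[r, s] <- Tadd[s, r] <- v
        }
        Tc[[cn]] <- Tc[[cn]] + Tadd
      }
      Ms[[si]] <- Mlist
    } else {
      for (cn in names(st$s)) {
        Tc[[cn]] <- Tc[[cn]] + st$s[[cn]] * st$N * ca$B
        Wc[[cn]] <- Wc[[cn]] + st$s[[cn]] * ca$BWB
      }
    }
  }
  list(Tc = Tc, Wc = Wc, Ms = Ms)
}

# gradient and average-information matrix over the stacked parameters
grad_ai <- function(blocks, thetas, stats, ev, prob) {
  t <- prob$t
  npar <- vapply(blocks, `[[`, 0L, "npar")
  npar_all <- sum(npar)
  offset <- cumsum(c(0L, npar))[seq_along(blocks)]
  Dlist <- vector("list", npar_all)
  comp_of <- integer(npar_all)
  grad <- numeric(npar_all)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    dT <- stats$Tc[[blk$name]] - stats$Wc[[blk$name]]
    for (k in seq_len(blk$npar)) {
      D <- block_dcov(blk, thetas[[b]], k)
      i <- offset[b] + k
      Dlist[[i]] <- D
      comp_of[i] <- b
      grad[i] <- -0.5 * sum(D * dT)
    }
  }
  AI <- matrix(0, npar_all, npar_all)
  for (si in seq_along(prob$strata)) {
    st <- prob$strata[[si]]
    ca <- ev$caches[[si]]
    if (st$type == "dense") {
      n <- ca$n
      H <- matrix(0, n * t, npar_all)
      for (i in seq_len(npar_all)) {
        cn <- names(blocks)[comp_of[i]]
        if (!is.null(stats$Ms[[si]][[cn]]))
          H[, i] <- as.numeric(stats$Ms[[si]][[cn]] %*% Dlist[[i]])
      }
      AI <- AI + 0.5 * crossprod(H, ca$P %*% H)
    } else {
      sw <- vapply(names(blocks), function(cn)
        if (is.null(st$s[[cn]])) 0 else st$s[[cn]], 0)
      act <- which(sw[comp_of] != 0)
      for (ii in act) {
        TiB <- (sw[comp_of[ii]] * Dlist[[ii]]) %*% ca$B
        for (jj in act[act >= ii]) {
          v <- 0.5 * sw[comp_of[jj]] *
            sum(TiB * t(Dlist[[jj]] %*% ca$BWB))
          AI[ii, jj] <- AI[ii, jj] + v
          if (jj > ii) AI[jj, ii] <- AI[jj, ii] + v
        }
      }
    }
  }
  list(grad = grad, AI = (AI + t(AI)) / 2)
}

# One EM update of all unstructured components (guaranteed ascent,
# stays positive semi-definite).
em_update <- function(blocks, thetas, stats) {
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (blk$type != "us") next
    S <- block_cov(blk, thetas[[b]])
    S_new <- S + (S %*% (stats$Wc[[blk$name]] - stats$Tc[[blk$name]])
                  %*% S) / blk$q_em
    floor <- if (blk$name == "residual")
      1e-10 * (mean(diag(S_new)) + 1e-12) else 0
    S_new <- psd_clamp(S_new, floor)
    if (blk$diagonal) S_new <- diag(diag(S_new), blk$t)
    thetas[[b]] <- if (blk$diagonal) diag(S_new)[blk$ij[, 1]]
                   else S_new[blk$ij]
  }
  thetas
}

# Unstructured components are iterated on the Cholesky scale
# (covariance = L L', L lower-triangular), so positive
# semi-definiteness is automatic and boundary optima (singular
# components) are reached smoothly; fa blocks pass through unchanged.
opt_blocks_of <- function(blocks) {
  ob <- lapply(blocks, function(blk) {
    if (blk$type != "us") return(blk)
    fb <- fa_block(blk$name, blk$t, blk$t, blk$q_em)
    if (blk$diagonal) {
      fb$ij <- cbind(seq_len(blk$t), seq_len(blk$t))
      fb$npar <- blk$t
    }
    fb
  })
  names(ob) <- names(blocks)
  ob
}

opt_from_report <- function(blocks, opt_blocks, thetas) {
  out <- thetas
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (blk$type != "us") next
    L <- chol_lower(block_cov(blk, thetas[[b]]), blk$t)
    out[[b]] <- L[opt_blocks[[b]]$ij]
  }
  out
}

report_from_opt <- function(blocks, opt_blocks, thetas_opt) {
  out <- thetas_opt
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (blk$type != "us") next
    S <- block_cov(opt_blocks[[b]], thetas_opt[[b]])
    out[[b]] <- if (blk$diagonal) diag(S)[blk$ij[, 1]] else S[blk$ij]
  }
  out
}

update_thetas <- function(blocks, thetas, delta) {
  pos <- 0L
  out <- thetas
  for (b in seq_along(blocks)) {
    out[[b]] <- thetas[[b]] + delta[pos + seq_len(blocks[[b]]$npar)]
    pos <- pos + blocks[[b]]$npar
  }
  out
}

# Average-information REML.  Iterations run on the Cholesky scale:
# quasi-Newton AI steps with ridge damping and step-halving, and
# expectation-maximization fallback steps (taken on the covariance
# scale) when no damped AI step improves the likelihood.  The AI
# matrix is re-evaluated on the covariance ("G-") scale at the
# optimum.
reml_engine <- function(prob, blocks, tol = 1e-8, max_iter = 200L,
                        verbose = FALSE) {
  ob <- opt_blocks_of(blocks)
  thetas <- opt_from_report(blocks, ob, attr(blocks, "init"))
  ev <- eval_problem(ob, thetas, prob)
  if (is.null(ev)) stop("initial covariance values are not positive definite")
  # L-BFGS pre-optimization on the Cholesky scale with analytic
  # gradients; the AI loop below then polishes the optimum and
  # supplies the average-information matrix
  npar <- vapply(ob, `[[`, 0L, "npar")
  relist_th <- function(par) {
    out <- thetas
    pos <- 0L
    for (b in seq_along(ob)) {
      out[[b]] <- par[pos + seq_len(npar[b])]
      pos <- pos + npar[b]
    }
    out
  }
  fn <- function(par) {
    e <- eval_problem(ob, relist_th(par), prob, need_P = FALSE)
    if (is.null(e) || !is.finite(e$ll)) 1e10 else -e$ll
  }
  gr <- function(par) {
    th <- relist_th(par)
    e <- eval_problem(ob, th, prob, need_P = TRUE)
    if (is.null(e)) return(numeric(sum(npar)))
    st <- iter_stats(ob, e, prob)
    -grad_ai(ob, th, st, e, prob)$grad
  }
  opt <- tryCatch(
    stats::optim(unlist(thetas, use.names = FALSE), fn, gr,
                 method = "L-BFGS-B",
                 control = list(maxit = 500L, factr = 1e7)),
    error = function(e) NULL)
  if (!is.null(opt) && is.finite(opt$value) && -opt$value >= ev$ll) {
    thetas <- relist_th(opt$par)
    ev <- eval_problem(ob, thetas, prob)
    if (verbose)
      message(sprintf("L-BFGS stage: logL = %.8f (%d evals)",
                      ev$ll, opt$counts[1]))
  }
  trajectory <- ev$ll
  converged <- FALSE
  iter <- 0L
  consec_small <- 0L
  for (iter in seq_len(max_iter)) {
    stats <- iter_stats(ob, ev, prob)
    ga <- grad_ai(ob, thetas, stats, ev, prob)
    base_ll <- ev$ll
    best <- NULL
    n_trials <- 0L
    for (ridge in c(0, 10^(-4:2) * mean(diag(ga$AI)))) {
      delta <- tryCatch(solve(ga$AI + diag(ridge, length(ga$grad)),
                              ga$grad),
                        error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) next
      step <- 1
      while (step >= 1 / 32 && is.null(best) && n_trials < 24L) {
        cand <- update_thetas(ob, thetas, step * delta)
        ev2 <- eval_problem(ob, cand, prob, need_P = FALSE)
        n_trials <- n_trials + 1L
        if (!is.null(ev2) && is.finite(ev2$ll) &&
            ev2$ll > base_ll + 1e-12)
          best <- ev2
        step <- step / 2
      }
      if (!is.null(best) || n_trials >= 24L) break
    }
    em_used <- is.null(best)
    if (is.null(best)) {
      # EM fallback on the covariance scale (guaranteed ascent)
      rep_th <- report_from_opt(blocks, ob, thetas)
      cand <- opt_from_report(blocks, ob,
                              em_update(blocks, rep_th, stats))
      ev2 <- eval_problem(ob, cand, prob, need_P = FALSE)
      if (!is.null(ev2) && ev2$ll >= base_ll - 1e-10) best <- ev2
    }
    # expected gain (Newton decrement): guards against declaring
    # convergence after a tiny fallback step
    decr <- tryCatch({
      d0 <- solve(ga$AI + diag(1e-6 * mean(diag(ga$AI)),
                               length(ga$grad)), ga$grad)
      0.5 * sum(ga$grad * d0)
    }, error = function(e) Inf)
    if (is.null(best)) {       # stationary: nothing improves
      converged <- TRUE
      break
    }
    thetas <- best$thetas
    ev <- add_P(best, ob, prob)
    trajectory <- c(trajectory, ev$ll)
    if (verbose)
      message(sprintf("iter %3d  logL = %.8f  (dL = %.3g, decr = %.3g, %s)",
                      iter, ev$ll, ev$ll - base_ll, decr,
                      if (em_used) "EM" else "AI"))
    small <- abs(ev$ll - base_ll) < tol * (abs(ev$ll) + 1)
    consec_small <- if (small) consec_small + 1L else 0L
    if (small && (consec_small >= 2L || !is.finite(decr) ||
                  decr < sqrt(tol) * (abs(ev$ll) + 1))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " rounds (last |dlogL| = ",
            format(abs(diff(utils::tail(trajectory, 2)))), ")")
  # final AI on the reporting (covariance) scale at the optimum
  thetas_rep <- report_from_opt(blocks, ob, thetas)
  stats <- iter_stats(blocks, ev, prob)
  ga <- grad_ai(blocks, thetas_rep, stats, ev, prob)
  beta <- NULL
  for (si in seq_along(prob$strata))
    if (prob$strata[[si]]$type == "dense" &&
        length(ev$caches[[si]]$beta))
      beta <- ev$caches[[si]]$beta
  list(thetas = thetas_rep, loglik = ev$ll, AI = ga$AI, beta = beta,
       converged = converged, iterations = iter,
       trajectory = trajectory)
}

# ---- data preparation ------------------------------------------------

prep_model_data <- function(phenotypes, A, spec) {
  if (!is.null(spec$arm))
    phenotypes <- phenotypes[phenotypes$arm == spec$arm, , drop = FALSE]
  if (nrow(phenotypes) == 0L) stop("no phenotype records after arm subset")
  if (anyDuplicated(phenotypes$id))
    stop("one phenotype record per individual is required")
  missing <- setdiff(phenotypes$id, rownames(A))
  if (length(missing))
    stop("relationship matrix does not cover phenotyped individuals: ",
         paste(utils::head(missing, 5), collapse = ", "))
  t <- length(spec$traits)
  Y <- as.matrix(phenotypes[, spec$traits, drop = FALSE])
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  # per-trait fixed design: intercept + requested factors
  X0 <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (f in spec$fixed) {
    if (!f %in% names(phenotypes)) next
    fac <- droplevels(factor(phenotypes[[f]]))
    if (nlevels(fac) < 2L) next
    mm <- stats::model.matrix(~fac)[, -1, drop = FALSE]
    colnames(mm) <- paste0(f, levels(fac)[-1])
    X0 <- cbind(X0, mm)
  }
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    aliased <- colnames(X0)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular fixed-effects design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  K_add <- unclass(A)[phenotypes$id, phenotypes$id]
  vial <- if (isTRUE(spec$vial)) {
    if (!"vial" %in% names(phenotypes))
      stop("model includes a vial term but phenotypes lack a vial column")
    factor(phenotypes$vial)
  } else NULL
  # OLS residual covariance for starting values
  R0 <- qr.resid(qrX, Y)
  S_p <- crossprod(R0) / max(1, n - qrX$rank)
  prob <- build_problem(Y, X0, K_add, vial, t)
  list(prob = prob, S_p = S_p, ids = phenotypes$id, n = n, t = t,
       n_vials = if (is.null(vial)) NA_integer_ else nlevels(vial))
}

# Assemble the likelihood strata.  When the data are
# full-sib-family-grouped (one vial per family, fixed effects constant
# within vial, A compound-symmetric within and block-constant across
# vials - the MCN design guarantees all three), the likelihood is
# collapsed exactly into within-vial contrast scatter strata plus a
# dense stratum of scaled vial means; otherwise a single dense stratum
# over all records is used.
build_problem <- function(Y, X0, K_add, vial, t) {
  n <- nrow(Y)
  full_dense <- function() {
    Ks <- list(additive = K_add)
    if (!is.null(vial))
      Ks$vial <- tcrossprod(stats::model.matrix(~ 0 + vial))
    Ks$residual <- diag(n)
    list(t = t, n = n,
         strata = list(list(type = "dense", Y = Y,
                            X = kronecker(diag(t), X0), Ks = Ks)))
  }
  if (is.null(vial) || nlevels(vial) < 2L) return(full_dense())
  idx <- split(seq_len(n), vial)
  m <- lengths(idx)
  nv <- length(idx)
  # fixed effects constant within vials?
  for (cl in seq_len(ncol(X0)))
    for (v in seq_len(nv))
      if (length(unique(X0[idx[[v]], cl])) > 1L) return(full_dense())
  # A compound-symmetric within vials, block-constant across?
  d_diag <- diag(K_add)
  Z <- stats::model.matrix(~ 0 + vial)
  ZAZ <- crossprod(Z, K_add %*% Z)
  c_within <- (diag(ZAZ) - vapply(idx, function(i) sum(d_diag[i]), 0)) /
    pmax(m * (m - 1), 1)
  Abar <- ZAZ / tcrossprod(m)          # mean relationship per block
  diag(Abar) <- c_within
  d_v <- vapply(idx, function(i) d_diag[i][1], 0)
  Ahat <- Z %*% Abar %*% t(Z)
  add_diag <- numeric(n)
  for (v in seq_len(nv)) add_diag[idx[[v]]] <- d_diag[idx[[v]]] -
      c_within[v]
  Ahat <- Ahat + diag(add_diag)
  if (max(abs(K_add - Ahat)) > 1e-8) return(full_dense())
  if (max(vapply(idx, function(i) max(d_diag[i]) - min(d_diag[i]), 0)) >
      1e-10) return(full_dense())
  # contrast scatter strata, grouped by the within-family additive
  # kernel weight s = (1 + F) - a_sib
  s_v <- d_v - c_within
  key <- as.character(round(s_v, 10))
  strata <- list()
  for (kk in unique(key[m > 1])) {
    sel <- which(key == kk & m > 1)
    W <- matrix(0, t, t)
    N <- 0L
    for (v in sel) {
      Yv <- Y[idx[[v]], , drop = FALSE]
      W <- W + crossprod(sweep(Yv, 2L, colMeans(Yv)))
      N <- N + unname(m[v]) - 1L
    }
    strata[[length(strata) + 1L]] <-
      list(type = "scatter", W = W, N = N,
           s = list(additive = unname(s_v[sel[1]]), residual = 1))
  }
  # vial-mean stratum (scaled so the residual kernel stays identity)
  Ymean <- t(vapply(idx, function(i)
    colMeans(Y[i, , drop = FALSE]), numeric(t))) * sqrt(m)
  Xmean <- X0[vapply(idx, function(i) i[1], 0L), , drop = FALSE] *
    sqrt(m)
  Atil <- ZAZ / sqrt(tcrossprod(m))
  strata[[length(strata) + 1L]] <-
    list(type = "dense", Y = matrix(Ymean, ncol = t),
         X = kronecker(diag(t), Xmean),
         Ks = list(additive = Atil, vial = diag(m, nv),
                   residual = diag(nv)))
  list(t = t, n = n, strata = strata)
}

make_blocks <- function(dat, spec, G_rank = NULL) {
  t <- dat$t
  blocks <- list()
  blocks$additive <- if (is.null(G_rank))
    us_block("additive", t, q_em = dat$n)
  else fa_block("additive", t, G_rank, q_em = dat$n)
  if (isTRUE(spec$vial))
    blocks$vial <- us_block("vial", t, q_em = dat$n_vials,
                            diagonal = isTRUE(spec$vial_diagonal))
  blocks$residual <- us_block("residual", t, q_em = dat$n)
  attr(blocks, "init") <- lapply(blocks, init_theta, S_p = dat$S_p)
  blocks
}

# ---- user-facing fits ------------------------------------------------

#' Fit the multivariate animal model by average-information REML
#'
#' Restricted maximum likelihood for `Y = Xb + Z_v v + Z_a a + e` with
#' unstructured `t x t` covariance matrices for the additive genetic
#' term (Kronecker with the numerator relationship matrix, whose
#' `1 + F` diagonals absorb the purely additive inflation of variance
#' under inbreeding), the among-vial term and the residual.  Iterates
#' average-information (quasi-Newton) updates with ridge damping and
#' step-halving, falling back on expectation-maximization steps;
#' internally parameters move on the Cholesky scale so covariance
#' matrices stay positive semi-definite throughout.  For family-
#' grouped data (the MCN design) the likelihood is collapsed exactly
#' into within-vial contrasts plus vial means, which makes fits fast
#' at experimental scale.  The average-information matrix is evaluated
#' at the optimum directly on the covariance ("G-") scale, ready for
#' REML-MVN sampling.
#'
#' @param phenotypes Phenotype table: columns `id`, the trait columns
#'   named in `spec`, and any fixed-effect / `vial` / `arm` columns the
#'   spec uses.
#' @param A A `relationship_matrix` (from [build_A()]) covering all
#'   phenotyped individuals (ancestors enter through the relationship
#'   values, so A may be the full-pedigree matrix).
#' @param spec A [model_spec()].
#' @param verbose Print the log-likelihood trajectory.
#' @return A `g_estimate`: list with `G`, `vial`, `R` (t x t matrices),
#'   `loglik`, `converged`, `iterations`, `AI` (average-information
#'   matrix over the stacked distinct covariance parameters), `params`
#'   (the stacked parameter vector), `manifest` (data.frame mapping
#'   parameters to component/row/col), `beta`, `trajectory`,
#'   `n_records` and the model spec.
#' @export
fit_reml <- function(phenotypes, A, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- prep_model_data(phenotypes, A, spec)
  blocks <- make_blocks(dat, spec)
  fit <- reml_engine(dat$prob, blocks, tol = spec$tol,
                     max_iter = spec$max_iter, verbose = verbose)
  as_g_estimate(fit, blocks, dat, spec, G_rank = NULL)
}

#' Fit the animal model with a reduced-rank additive covariance
#'
#' Identical to [fit_reml()] except the additive covariance is
#' parameterized factor-analytically as `Lambda Lambda'` with `Lambda`
#' lower-triangular `t x r` (`t r - r(r-1)/2` parameters), for rank
#' likelihood-ratio testing via [rank_lrt()].
#'
#' @inheritParams fit_reml
#' @param rank Rank `r` of the additive covariance, `1 <= r <= t`.
#' @return A `g_estimate` (with `G = Lambda Lambda'` and an extra
#'   `Lambda` element); its AI matrix is on the `Lambda` scale.
#' @export
fit_reduced_rank <- function(phenotypes, A, spec, rank, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  t <- length(spec$traits)
  if (rank < 1 || rank > t)
    stop("rank must lie in [1, ", t, "]")
  dat <- prep_model_data(phenotypes, A, spec)
  blocks <- make_blocks(dat, spec, G_rank = as.integer(rank))
  fit <- reml_engine(dat$prob, blocks, tol = spec$tol,
                     max_iter = spec$max_iter, verbose = verbose)
  as_g_estimate(fit, blocks, dat, spec, G_rank = as.integer(rank))
}

as_g_estimate <- function(fit, blocks, dat, spec, G_rank) {
  covs <- Map(block_cov, blocks, fit$thetas)
  manifest <- do.call(rbind, lapply(names(blocks), function(nm) {
    blk <- blocks[[nm]]
    data.frame(component = nm,
               parameter = if (blk$type == "fa") "lambda" else "cov",
               row = blk$ij[, 1], col = blk$ij[, 2])
  }))
  out <- list(G = covs$additive, vial = covs$vial, R = covs$residual,
              loglik = fit$loglik, converged = fit$converged,
              iterations = fit$iterations, AI = fit$AI,
              params = unlist(fit$thetas, use.names = FALSE),
              manifest = manifest, beta = fit$beta,
              trajectory = fit$trajectory, spec = spec,
              traits = spec$traits, n_records = dat$n,
              ids = dat$ids, G_rank = G_rank)
  if (!is.null(G_rank))
    out$Lambda <- block_lambda(blocks$additive, fit$thetas$additive)
  dimnames(out$G) <- list(spec$traits, spec$traits)
  dimnames(out$R) <- list(spec$traits, spec$traits)
  if (!is.null(out$vial))
    dimnames(out$vial) <- list(spec$traits, spec$traits)
  class(out) <- "g_estimate"
  out
}

#' @export
print.g_estimate <- function(x, ...) {
  cat("<g_estimate> ", length(x$traits), " trait(s), ", x$n_records,
      " records; logL = ", format(x$loglik, digits = 8),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("G (additive", if (!is.null(x$G_rank))
    paste0(", rank ", x$G_rank), "):\n", sep = "")
  print(round(x$G, 5))
  invisible(x)
}

#' Number of additive-covariance parameters of a fit
#'
#' `t(t+1)/2` for an unstructured fit; `t r - r(r-1)/2` for a
#' factor-analytic fit of rank `r`.
#'
#' @param estimate A `g_estimate`.
#' @return Integer parameter count.
#' @export
n_G_params <- function(estimate) {
  t <- length(estimate$traits)
  r <- estimate$G_rank
  if (is.null(r)) t * (t + 1) / 2 else t * r - r * (r - 1) / 2
}

#' Likelihood-ratio test of G-matrix rank
#'
#' Compares two nested animal-model fits (full vs reduced additive
#' rank) on identical data: `chi2 = 2 (logL_full - logL_reduced)`
#' clipped at zero, degrees of freedom equal to the difference in
#' additive-covariance parameter counts, p-value from the upper
#' chi-square tail.
#'
#' @param full,reduced `g_estimate` objects from [fit_reml()] /
#'   [fit_reduced_rank()] on the same data and fixed effects.
#' @return A list `chi2`, `df`, `p`.
#' @export
rank_lrt <- function(full, reduced) {
  stopifnot(inherits(full, "g_estimate"), inherits(reduced, "g_estimate"))
  if (!identical(full$traits, reduced$traits) ||
      full$n_records != reduced$n_records ||
      !identical(full$ids, reduced$ids))
    stop("rank LRT requires nested fits on identical data")
  df <- n_G_params(full) - n_G_params(reduced)
  if (df < 0) stop("`full` must have more G parameters than `reduced`")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  # df = 0: same model space (e.g. full rank vs unstructured) - no test
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}
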