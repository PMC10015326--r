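#' REML-MVN sampling of estimated covariance parameters
#'
#' Draws parameter vectors from a multivariate normal centred at the
#' REML estimates with covariance equal to the inverse of the
#' average-information matrix ("G-scale" sampling: draws live on the
#' covariance scale and are deliberately unconstrained, so sampled
#' matrices may be non-positive-definite).  The G-block of each draw is
#' reshaped into a symmetric `t x t` matrix.
#'
#' @param estimate A `g_estimate` from [fit_reml()] (unstructured
#'   parameterization).
#' @param n Number of samples (default 10000).
#' @param seed Random seed (required, logged in the result).
#' @param sigma Optional override of the sampling covariance (e.g. a
#'   zero matrix as a degenerate test hook); default `solve(AI)`.
#' @return An `mvn_sample_set`: list with `G` (array `t x t x n`),
#'   `params` (n x p draws), `mu`, `n`, `seed`.
#' @export
sample_mvn <- function(estimate, n = 10000L, seed, sigma = NULL) {
  stopifnot(inherits(estimate, "g_estimate"))
  if (!is.null(estimate$G_rank))
    stop("REML-MVN G-scale sampling requires an unstructured fit")
  if (missing(seed)) stop("a random seed is required for sample_mvn")
  mu <- estimate$params
  if (is.null(sigma)) {
    sigma <- tryCatch(solve(estimate$AI), error = function(e)
      stop("average-information matrix is singular; the fit may sit on ",
           "a boundary - consider a ridge or re-examining convergence"))
    sigma <- (sigma + t(sigma)) / 2
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  draws <- matrix(draws, nrow = n)
  t <- length(estimate$traits)
  gi <- which(estimate$manifest$component == "additive")
  Gs <- array(0, c(t, t, n),
              dimnames = list(estimate$traits, estimate$traits, NULL))
  ij <- as.matrix(estimate$manifest[gi, c("row", "col")])
  for (k in seq_along(gi)) {
    Gs[ij[k, 1], ij[k, 2], ] <- draws[, gi[k]]
    Gs[ij[k, 2], ij[k, 1], ] <- draws[, gi[k]]
  }
  structure(list(G = Gs, params = draws, mu = mu, n = n, seed = seed),
            class = "mvn_sample_set")
}

#' @export
print.mvn_sample_set <- function(x, ...) {
  cat("<mvn_sample_set> ", x$n, " draws of ", ncol(x$params),
      " parameters (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Project a trait combination through a covariance matrix
#'
#' The variance of the multivariate trait combination `v` under
#' covariance `S` is the quadratic form `v' S v`; `v` is normalized to
#' unit length first.  Projecting an eigenvector of `S` returns its
#' eigenvalue.
#'
#' @param v A non-zero trait-combination vector.
#' @param S A symmetric matrix, or an array `t x t x n` of matrices.
#' @return A scalar (or length-`n` vector) of projected variances.
#' @export
project_variance <- function(v, S) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot project through a zero vector")
  v <- v / nv
  if (is.matrix(S)) return(as.numeric(crossprod(v, S %*% v)))
  stopifnot(length(dim(S)) == 3L)
  apply(S, 3L, function(M) sum(v * (M %*% v)))
}

ci_levels <- function(level) c((1 - level) / 2, 1 - (1 - level) / 2)

#' Paired variance-ratio confidence intervals
#'
#' For each requested quantity (per-trait variance, total variance /
#' trace, or the variance projected on a supplied vector) computes the
#' outbred-to-inbred ratio `V_AO / V_AI`: the ratio of REML point
#' estimates, the median of the ratios over index-paired REML-MVN
#' samples, and an equal-tail percentile CI of those paired ratios.
#' Values above 1 indicate deflation of additive variance under
#' inbreeding relative to the `(1 + F)` additive expectation (which the
#' relationship matrix has already absorbed).  Pairs whose denominator
#' sample is non-positive are dropped, with the count reported.
#'
#' @param G_O,G_I Point-estimate G matrices (outbred, inbred).
#' @param samples_O,samples_I [sample_mvn()] results (equal `n`; pairs
#'   are formed by sample index).
#' @param which `"per-trait"`, `"trace"`, or `"vector"`.
#' @param v Trait-combination vector (required for `which = "vector"`).
#' @param level CI level (default 0.95).
#' @return A `data.frame` with one row per quantity: `point_ratio`,
#'   `median_ratio`, `lower`, `upper`, `n_dropped`, `excludes_1`.
#' @export
variance_ratio_ci <- function(G_O, G_I, samples_O, samples_I,
                              which = c("trace", "per-trait", "vector"),
                              v = NULL, level = 0.95) {
  which <- match.arg(which)
  stopifnot(inherits(samples_O, "mvn_sample_set"),
            inherits(samples_I, "mvn_sample_set"))
  if (samples_O$n != samples_I$n)
    stop("sample sets must have equal n for index pairing")
  quant <- switch(which,
    trace = function(M) sum(diag(M)),
    `per-trait` = function(M) diag(M),
    vector = {
      if (is.null(v)) stop("which = 'vector' requires `v`")
      function(M) project_variance(v, M)
    })
  num_pt <- quant(G_O); den_pt <- quant(G_I)
  nq <- length(num_pt)
  num <- apply(samples_O$G, 3L, quant)
  den <- apply(samples_I$G, 3L, quant)
  num <- matrix(num, nrow = nq); den <- matrix(den, nrow = nq)
  out <- lapply(seq_len(nq), function(i) {
    keep <- den[i, ] > 0
    r <- num[i, keep] / den[i, keep]
    qs <- stats::quantile(r, ci_levels(level), names = FALSE)
    data.frame(point_ratio = num_pt[i] / den_pt[i],
               median_ratio = stats::median(r),
               lower = qs[1], upper = qs[2],
               n_dropped = sum(!keep),
               excludes_1 = qs[1] > 1 || qs[2] < 1)
  })
  out <- do.call(rbind, out)
  rownames(out) <- switch(which, trace = "trace",
                          `per-trait` = colnames(G_O) %||%
                            paste0("trait", seq_len(nq)),
                          vector = "vector")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eigenanalysis with projected confidence intervals
#'
#' Eigendecomposes the REML point estimate (descending eigenvalues) and
#' places an equal-tail percentile CI on each eigenvalue by projecting
#' the point-estimate eigenvector through every REML-MVN sample of the
#' matrix (`p_ij = e_i' S_j e_i`).  Eigenvector sign is irrelevant:
#' every reported quantity is a quadratic form.
#'
#' @param G Symmetric point-estimate matrix.
#' @param samples An [sample_mvn()] result for the same fit.
#' @param level CI level (0.95 default; 0.90 is conventional for
#'   eigenvalue displays).
#' @return A list with `values` (data.frame: eigenvalue, lower, upper,
#'   prop_variance) and `vectors` (columns are eigenvectors).
#' @export
eigen_with_ci <- function(G, samples, level = 0.95) {
  if (max(abs(G - t(G))) > 1e-8 * (1 + max(abs(G))))
    stop("matrix must be symmetric")
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  t <- nrow(G)
  tab <- lapply(seq_len(t), function(i) {
    proj <- project_variance(ee$vectors[, i], samples$G)
    qs <- stats::quantile(proj, ci_levels(level), names = FALSE)
    data.frame(eigenvalue = ee$values[i], lower = qs[1], upper = qs[2],
               prop_variance = ee$values[i] / sum(ee$values))
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- paste0("e", seq_len(t))
  list(values = tab, vectors = ee$vectors)
}

#' Absolute dot products of paired eigenvectors
#'
#' Eigendecomposes both matrices (descending eigenvalues) and returns
#' `|e_i(G_O) . e_i(G_I)|` for each rank `i`: 1 means the two matrices
#' share that trait combination, 0 means orthogonality.
#'
#' @param G_O,G_I Symmetric matrices over the same traits.
#' @return Numeric vector of `t` absolute dot products in `[0, 1]`.
#' @export
dot_products <- function(G_O, G_I) {
  if (!all(dim(G_O) == dim(G_I)))
    stop("matrices must have identical dimensions")
  eo <- eigen((G_O + t(G_O)) / 2, symmetric = TRUE)$vectors
  ei <- eigen((G_I + t(G_I)) / 2, symmetric = TRUE)$vectors
  abs(colSums(eo * ei))
}

#' Difference-matrix eigentensor comparison of two G matrices
#'
#' The difference matrix `C = G_O - G_I` describes the departure of the
#' inbred from the outbred additive covariance on the absolute scale
#' (after the relationship matrix has absorbed the additive `1 + F`
#' expectation).  Its eigenvectors are the trait combinations of
#' greatest divergence; eigenvalues are ordered by signed value, so the
#' leading one (most positive: deflation under inbreeding) and the last
#' one (most negative: inflation) bracket the departure.  CIs come from
#' projecting the point-estimate eigenvectors of `C` through the paired
#' sample differences `C_j = S_Oj - S_Ij`.
#'
#' @inheritParams variance_ratio_ci
#' @param level CI level (default 0.95).
#' @return A list: `C`, `values` (data.frame eigenvalue/lower/upper/
#'   excludes_0 with the most-positive labelled `c1` and most-negative
#'   `c<t>`), `vectors`.
#' @export
eigentensor <- function(G_O, G_I, samples_O, samples_I, level = 0.95) {
  if (!all(dim(G_O) == dim(G_I)))
    stop("matrices must share trait set and order")
  if (samples_O$n != samples_I$n)
    stop("sample sets must have equal n for index pairing")
  C <- (G_O - G_I)
  C <- (C + t(C)) / 2
  ee <- eigen(C, symmetric = TRUE)  # descending signed eigenvalues
  Cs <- samples_O$G - samples_I$G
  t <- nrow(C)
  tab <- lapply(seq_len(t), function(i) {
    proj <- project_variance(ee$vectors[, i], Cs)
    qs <- stats::quantile(proj, ci_levels(level), names = FALSE)
    data.frame(eigenvalue = ee$values[i], lower = qs[1], upper = qs[2],
               excludes_0 = qs[1] > 0 || qs[2] < 0)
  })
  tab <- do.call(rbind, tab)
  rownames(tab) <- paste0("c", seq_len(t))
  list(C = C, values = tab, vectors = ee$vectors)
}

#' Inbreeding depression per sire family
#'
#' For every sire with measured offspring in both arms, compares the
#' outbred sons' mean with the inbred sons' mean, linearly extrapolated
#' to full inbreeding (`F = 1`):
#' `zbar_I = zbar_O + (zbar_obs - zbar_O) / F_inbred`, and reports
#' `ID = 1 - zbar_I / zbar_O` as a percentage.  Nonzero mean ID across
#' sires indicates directional dominance, which would confound the
#' dominance-deflation test.
#'
#' @param phenotypes Phenotype table with `sire`, `arm` and trait
#'   columns.
#' @param traits Character vector of trait columns.
#' @param F_inbred Inbreeding coefficient of the inbred arm (0.25 for
#'   full-sib matings).
#' @param level Interval level for the summaries (default 0.95).
#' @return A list: `per_sire` (data.frame sire x trait ID estimates,
#'   percent), `summary` (per trait: `mean_id`, the percentile interval
#'   of the per-sire distribution `dist_lower`/`dist_upper`, and a
#'   normal-theory CI of the mean `mean_lower`/`mean_upper` — both are
#'   reported and labelled because they answer different questions).
#' @export
inbreeding_depression <- function(phenotypes, traits, F_inbred = 0.25,
                                  level = 0.95) {
  stopifnot(all(traits %in% names(phenotypes)))
  sp <- split(phenotypes, phenotypes$sire)
  rows <- lapply(sp, function(d) {
    o <- d[d$arm == "outbred", traits, drop = FALSE]
    i <- d[d$arm == "inbred", traits, drop = FALSE]
    if (nrow(o) == 0L || nrow(i) == 0L) return(NULL)
    zo <- colMeans(o); zobs <- colMeans(i)
    if (any(zo == 0))
      stop("undefined inbreeding-depression ratio: zero outbred mean ",
           "for sire ", d$sire[1], " (trait ",
           paste(traits[zo == 0], collapse = ", "), ")")
    zi <- zo + (zobs - zo) / F_inbred
    id <- 100 * (1 - zi / zo)
    c(n_out = nrow(o), n_in = nrow(i), id)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no sire has measured offspring in both arms")
  per_sire <- as.data.frame(do.call(rbind, rows))
  per_sire$sire <- names(rows)
  pr <- ci_levels(level)
  summary <- do.call(rbind, lapply(traits, function(tr) {
    x <- per_sire[[tr]]
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    z <- stats::qnorm(pr[2])
    data.frame(trait = tr, mean_id = m,
               dist_lower = stats::quantile(x, pr[1], names = FALSE),
               dist_upper = stats::quantile(x, pr[2], names = FALSE),
               mean_lower = m - z * se, mean_upper = m + z * se,
               n_sires = length(x))
  }))
  list(per_sire = per_sire, summary = summary)
}
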