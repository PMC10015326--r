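#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between each
#' landmark and the configuration centroid — the standard geometric-
#' morphometrics size measure.
#'
#' @param config A `k x 2` coordinate matrix.
#' @return Centroid size (same units as the coordinates).
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  stopifnot(ncol(config) == 2L, all(is.finite(config)))
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (cs == 0) stop("all landmarks coincide: zero centroid size")
  cs
}

#' Generalized Procrustes alignment
#'
#' Translates each configuration to the origin, scales it to unit
#' centroid size, and iteratively rotates all configurations onto the
#' running mean shape (itself renormalized to unit centroid size each
#' round) until the mean shape stabilizes.  Rotations are proper
#' (determinant +1): reflections are not allowed, as all wings are from
#' one body side.  Per-specimen centroid sizes are recorded before
#' scaling.
#'
#' @param configs A list of `k x 2` matrices, or a `k x 2 x n` array,
#'   with identical landmark count `k >= 3` and `n >= 2` specimens.
#' @param tol Convergence tolerance on the root-mean-square change of
#'   the mean shape (default `1e-10`).
#' @param max_iter Maximum iterations (default 100).
#' @return A list: `aligned` (`k x 2 x n` array, each specimen with
#'   centroid (0,0) and unit centroid size), `cs` (original centroid
#'   sizes), `mean_shape`, `iterations`.
#' @export
procrustes_align <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[3]),
                      function(i) configs[, , i])
  n <- length(configs)
  if (n < 2L) stop("need at least two configurations to align")
  k <- nrow(configs[[1]])
  cs <- vapply(configs, centroid_size, 0)
  A <- array(0, c(k, 2, n))
  for (i in seq_len(n)) {
    X <- as.matrix(configs[[i]])
    if (nrow(X) != k) stop("all configurations must share landmark count")
    X <- sweep(X, 2L, colMeans(X))
    A[, , i] <- X / cs[i]
  }
  rotate_onto <- function(X, M) {
    # proper orthogonal Procrustes rotation of X onto M
    sv <- svd(crossprod(X, M))
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    X %*% R
  }
  M <- A[, , 1]
  M <- M / sqrt(sum(M^2))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) A[, , i] <- rotate_onto(A[, , i], M)
    M_new <- apply(A, c(1, 2), mean)
    msize <- sqrt(sum(sweep(M_new, 2L, colMeans(M_new))^2))
    if (msize < 1e-12)
      stop("degenerate configuration set: mean shape collapsed")
    M_new <- sweep(M_new, 2L, colMeans(M_new)) / msize
    delta <- sqrt(mean((M_new - M)^2))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("Procrustes alignment did not converge in ", max_iter,
         " iterations (degenerate configurations?)")
  dimnames(A) <- list(rownames(configs[[1]]), c("x", "y"),
                      names(configs))
  list(aligned = A, cs = cs, mean_shape = M, iterations = it)
}

#' Default wing landmark-pair list
#'
#' The ten landmark pairs whose inter-landmark distances, together with
#' centroid size, make up the 11-trait wing set.  Pairs are labelled
#' `ILD<i>.<j>`.
#'
#' @return A 10 x 2 integer matrix of landmark indices.
#' @export
default_ild_pairs <- function() {
  m <- rbind(c(1, 5), c(1, 9), c(2, 6), c(2, 9), c(3, 7),
             c(3, 9), c(4, 8), c(4, 9), c(5, 8), c(6, 9))
  rownames(m) <- paste0("ILD", m[, 1], ".", m[, 2])
  m
}

#' Inter-landmark distances on aligned configurations
#'
#' Euclidean distances between named landmark pairs, computed on
#' unit-centroid-size aligned coordinates so the distances are "in
#' units of CS".
#'
#' @param aligned `k x 2 x n` array from [procrustes_align()].
#' @param pairs Two-column matrix of landmark index pairs (default
#'   [default_ild_pairs()]); row names become trait names.
#' @return An `n x nrow(pairs)` matrix of distances.
#' @export
interlandmark_distances <- function(aligned, pairs = default_ild_pairs()) {
  pairs <- as.matrix(pairs)
  k <- dim(aligned)[1]
  if (any(pairs < 1) || any(pairs > k))
    stop("landmark pair indices must lie in 1..", k)
  n <- dim(aligned)[3]
  out <- matrix(0, n, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- aligned[pairs[p, 1], , ] - aligned[pairs[p, 2], , ]
    d <- matrix(d, nrow = 2)
    out[, p] <- sqrt(colSums(d^2))
  }
  colnames(out) <- rownames(pairs) %||%
    paste0("ILD", pairs[, 1], ".", pairs[, 2])
  rownames(out) <- dimnames(aligned)[[3]]
  out
}

#' Assemble the 11-trait wing table from landmark configurations
#'
#' Runs [procrustes_align()], computes centroid size (`CS`) and the ten
#' inter-landmark distances, and binds any per-specimen metadata.
#'
#' @param configs List of `9 x 2` landmark matrices.
#' @param metadata Optional `data.frame` (one row per specimen) with
#'   e.g. `id`, `observer`, `generation`.
#' @param pairs Landmark pairs (default [default_ild_pairs()]).
#' @return A `data.frame` with metadata, `CS`, and ILD columns.
#' @export
wing_traits <- function(configs, metadata = NULL,
                        pairs = default_ild_pairs()) {
  al <- procrustes_align(configs)
  ild <- interlandmark_distances(al$aligned, pairs)
  out <- data.frame(CS = al$cs, ild, check.names = FALSE)
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(out))
    out <- cbind(metadata, out)
  }
  out
}

#' Scale wing traits to estimation units
#'
#' Multiplies ILD traits by 1000 and centroid size by 200 (constants
#' chosen to put all traits on similar numerical scales for REML
#' convergence); the constants are recorded as attributes so
#' [unscale_traits()] recovers the originals exactly.
#'
#' @param traits Trait table containing `CS` and `ILD*` columns.
#' @param ild_factor,cs_factor Scaling constants (defaults 1000, 200).
#' @return The scaled table, with attribute `trait_scaling`.
#' @export
scale_traits <- function(traits, ild_factor = 1000, cs_factor = 200) {
  ild_cols <- grep("^ILD", names(traits), value = TRUE)
  for (cl in ild_cols) traits[[cl]] <- traits[[cl]] * ild_factor
  if ("CS" %in% names(traits)) traits$CS <- traits$CS * cs_factor
  attr(traits, "trait_scaling") <- list(ild_factor = ild_factor,
                                        cs_factor = cs_factor)
  traits
}

#' @rdname scale_traits
#' @export
unscale_traits <- function(traits) {
  sc <- attr(traits, "trait_scaling")
  if (is.null(sc)) stop("table carries no trait_scaling attribute")
  ild_cols <- grep("^ILD", names(traits), value = TRUE)
  for (cl in ild_cols) traits[[cl]] <- traits[[cl]] / sc$ild_factor
  if ("CS" %in% names(traits)) traits$CS <- traits$CS / sc$cs_factor
  attr(traits, "trait_scaling") <- NULL
  traits
}

#' Mahalanobis-distance outlier filter
#'
#' Transforms each observation to a deviation from its
#' observer-by-generation stratum mean (per trait), computes squared
#' Mahalanobis distances against the pooled covariance of the centred
#' data, and removes records whose distance exceeds the chi-square
#' critical value (`alpha = 0.001`, `df` = number of traits, by
#' default).  Applied once, without re-iteration.
#'
#' @param table Trait table.
#' @param traits Character vector of trait columns.
#' @param alpha Tail probability for the chi-square cutoff.
#' @param df Degrees of freedom of the cutoff (default
#'   `length(traits)`).
#' @param strata Stratum columns for mean-centring (default
#'   `c("observer", "generation")`, intersected with available
#'   columns).
#' @return A list: `retained`, `removed` (data.frames), `d2` (distances
#'   in input order), `cutoff`.
#' @export
mahalanobis_filter <- function(table, traits, alpha = 0.001,
                               df = length(traits),
                               strata = c("observer", "generation")) {
  stopifnot(all(traits %in% names(table)))
  Y <- as.matrix(table[, traits, drop = FALSE])
  strata <- intersect(strata, names(table))
  g <- if (length(strata))
    interaction(table[strata], drop = TRUE) else factor(rep(1, nrow(Y)))
  ctr <- Y
  for (cl in seq_along(traits)) {
    mu <- tapply(Y[, cl], g, mean)
    ctr[, cl] <- Y[, cl] - mu[g]
  }
  S <- stats::cov(ctr)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    # name the trait(s) most aligned with the collapsed direction
    vecs <- eigen(S, symmetric = TRUE)$vectors
    worst <- order(abs(vecs[, length(ev)]), decreasing = TRUE)[1:2]
    stop("singular pooled covariance; collinear traits include: ",
         paste(traits[worst], collapse = ", "))
  }
  d2 <- stats::mahalanobis(ctr, center = rep(0, ncol(ctr)), cov = S)
  cutoff <- stats::qchisq(1 - alpha, df)
  keep <- d2 <= cutoff
  list(retained = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE],
       d2 = d2, cutoff = cutoff)
}

#' Paired-sire filter
#'
#' Retains a record only if its sire has at least one measured
#' offspring in each mating arm within the (already outlier-filtered)
#' table — i.e. every remaining male has an assayed half-brother from
#' the other arm, so both analyses draw on the same sire families.
#'
#' @param table Trait table with `sire` and `arm` columns (or supply
#'   `ped` to resolve sires from the pedigree by `id`).
#' @param ped Optional validated [pedigree_table()].
#' @return A list: `retained`, `removed`, `kept_sires`.
#' @export
paired_sire_filter <- function(table, ped = NULL) {
  if (!"sire" %in% names(table)) {
    if (is.null(ped)) stop("table lacks a sire column and no pedigree given")
    stopifnot_validated(ped)
    table$sire <- ped$sire[match(table$id, ped$id)]
  }
  tab <- table(table$sire, table$arm)
  ok <- rownames(tab)[tab[, "inbred", drop = TRUE] > 0 &
                      tab[, "outbred", drop = TRUE] > 0]
  keep <- table$sire %in% ok
  list(retained = table[keep, , drop = FALSE],
       removed = table[!keep, , drop = FALSE],
       kept_sires = ok)
}

#' Read and write TPS landmark files
#'
#' Minimal reader/writer for the TPS digitizing format: records start
#' with `LM=<k>`, followed by `k` lines of `x y` coordinates and
#' optional `ID=`/`IMAGE=`/`SCALE=` lines.
#'
#' @param path File path.
#' @return `read_tps()` returns a named list of `k x 2` matrices.
#' @export
read_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^LM=", ln, ignore.case = TRUE)) {
      k <- as.integer(sub("^LM=", "", ln, ignore.case = TRUE))
      coords <- matrix(0, k, 2)
      for (j in seq_len(k)) {
        xy <- as.numeric(strsplit(trimws(lines[i + j]), "\\s+")[[1]])
        coords[j, ] <- xy[1:2]
      }
      i <- i + k + 1L
      id <- paste0("spec", length(out) + 1L)
      while (i <= length(lines) &&
             !grepl("^LM=", trimws(lines[i]), ignore.case = TRUE)) {
        if (grepl("^ID=", trimws(lines[i]), ignore.case = TRUE))
          id <- sub("^ID=", "", trimws(lines[i]), ignore.case = TRUE)
        i <- i + 1L
      }
      out[[id]] <- coords
    } else i <- i + 1L
  }
  out
}

#' @param configs Named list of `k x 2` matrices to write.
#' @rdname read_tps
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(configs)) {
    X <- configs[[nm]]
    writeLines(sprintf("LM=%d", nrow(X)), con)
    writeLines(sprintf("%.8f %.8f", X[, 1], X[, 2]), con)
    writeLines(sprintf("ID=%s", nm), con)
  }
  invisible(path)
}
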