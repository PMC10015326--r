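# a tiny converged fit reused across the comparison tests
fit_cache <- new.env(parent = emptyenv())
mcn_fits <- function() {
  if (!is.null(fit_cache$x)) return(fit_cache$x)
  x <- small_mcn()
  fits <- list()
  for (arm in c("outbred", "inbred"))
    fits[[arm]] <- fit_reml(x$phen, x$A,
                            model_spec(c("trait1", "trait2"),
                                       arm = arm,
                                       vial_diagonal = TRUE))
  fit_cache$x <- c(x, list(fits = fits))
  fit_cache$x
}

test_that("REML-MVN sampling honours mean, covariance and the
           degenerate hook", {
  f <- mcn_fits()$fits$outbred
  # Sigma = 0 -> all samples equal the point estimate
  s0 <- sample_mvn(f, 50, seed = 1,
                   sigma = matrix(0, length(f$params),
                                  length(f$params)))
  expect_equal(s0$G[, , 1], f$G, tolerance = 1e-12)
  expect_equal(s0$G[, , 50], f$G, tolerance = 1e-12)
  # sample mean and covariance reproduce mu and inverse AI
  s <- sample_mvn(f, 20000, seed = 2)
  iAI <- solve(f$AI)
  expect_equal(colMeans(s$params), f$params,
               tolerance = 5 * max(sqrt(diag(iAI)) / sqrt(20000)) /
                 min(abs(f$params[abs(f$params) > 1])) + 0.02)
  emp <- stats::cov(s$params)
  sds <- sqrt(diag(iAI))
  expect_lt(max(abs(emp - iAI) / outer(sds, sds)), 0.06)
  # G block is reshaped symmetrically
  expect_equal(s$G[1, 2, 7], s$G[2, 1, 7])
  expect_error(sample_mvn(f, 10), "seed")
})

test_that("projection is the quadratic form with its stated examples", {
  S <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(project_variance(c(1, 1) / sqrt(2), S), 3)
  expect_equal(project_variance(c(5, 5), S), 3)  # normalized internally
  expect_equal(project_variance(c(1, 0), diag(2)), 1)
  ee <- eigen(S)
  expect_equal(project_variance(ee$vectors[, 1], S), ee$values[1])
  expect_error(project_variance(c(0, 0), S), "zero vector")
})

test_that("paired variance ratios behave on identical and degenerate
           streams", {
  f <- mcn_fits()$fits$outbred
  z <- matrix(0, length(f$params), length(f$params))
  sA <- sample_mvn(f, 200, seed = 3, sigma = z)
  sB <- sample_mvn(f, 200, seed = 4, sigma = z)
  vr <- variance_ratio_ci(f$G, f$G, sA, sB, which = "trace")
  expect_equal(vr$point_ratio, 1)
  expect_equal(vr$median_ratio, 1)
  expect_equal(c(vr$lower, vr$upper), c(1, 1))
  expect_false(vr$excludes_1)
  pt <- variance_ratio_ci(f$G, f$G, sA, sB, which = "per-trait")
  expect_equal(nrow(pt), 2)
  expect_equal(pt$median_ratio, c(1, 1))
  pv <- variance_ratio_ci(f$G, f$G, sA, sB, which = "vector",
                          v = c(1, 1))
  expect_equal(pv$median_ratio, 1)
  # pairing invariance: permuting both streams together changes nothing
  s1 <- sample_mvn(f, 500, seed = 5)
  s2 <- sample_mvn(f, 500, seed = 6)
  perm <- sample(500)
  s1p <- s1; s1p$G <- s1$G[, , perm]
  s2p <- s2; s2p$G <- s2$G[, , perm]
  expect_equal(variance_ratio_ci(f$G, f$G, s1, s2, which = "trace"),
               variance_ratio_ci(f$G, f$G, s1p, s2p, which = "trace"))
})

test_that("eigenanalysis CIs collapse and expand correctly", {
  f <- mcn_fits()$fits$outbred
  D <- diag(c(5, 2))
  z <- matrix(0, length(f$params), length(f$params))
  s0 <- sample_mvn(f, 100, seed = 7, sigma = z)
  # diagonal matrix: eigenvalues are the diagonal, axes are vectors
  e <- eigen_with_ci(D, s0, level = 0.9)
  expect_equal(e$values$eigenvalue, c(5, 2))
  expect_equal(abs(e$vectors), diag(2), tolerance = 1e-12)
  expect_equal(e$values$prop_variance, c(5 / 7, 2 / 7))
  # degenerate samples -> CIs collapse onto projected point values
  eG <- eigen_with_ci(f$G, s0)
  expect_equal(eG$values$lower, eG$values$eigenvalue,
               tolerance = 1e-10)
  expect_equal(eG$values$upper, eG$values$eigenvalue,
               tolerance = 1e-10)
  expect_error(eigen_with_ci(matrix(c(1, 2, 0, 1), 2), s0),
               "symmetric")
})

test_that("dot products read matrix orientation", {
  G <- matrix(c(3, 1, 1, 2), 2)
  expect_equal(dot_products(G, G), c(1, 1))
  # 90-degree rotation of an anisotropic matrix -> leading pair orthogonal
  A <- diag(c(4, 1))
  R <- matrix(c(0, 1, -1, 0), 2)
  expect_equal(dot_products(A, R %*% A %*% t(R)), c(0, 0))
  expect_error(dot_products(diag(2), diag(3)), "dimensions")
})

test_that("eigentensor difference matrix satisfies its identities", {
  x <- mcn_fits()
  fo <- x$fits$outbred; fi <- x$fits$inbred
  so <- sample_mvn(fo, 1000, seed = 8)
  si <- sample_mvn(fi, 1000, seed = 9)
  te <- eigentensor(fo$G, fi$G, so, si)
  expect_equal(sum(diag(te$C)),
               sum(diag(fo$G)) - sum(diag(fi$G)))
  expect_equal(sum(te$values$eigenvalue), sum(diag(te$C)),
               tolerance = 1e-10)
  # signed descending order; labels c1..ct
  expect_true(all(diff(te$values$eigenvalue) <= 1e-12))
  expect_equal(rownames(te$values), c("c1", "c2"))
  # trivial cases
  z <- matrix(0, length(fo$params), length(fo$params))
  s0a <- sample_mvn(fo, 50, seed = 10, sigma = z)
  s0b <- sample_mvn(fo, 50, seed = 11, sigma = z)
  t0 <- eigentensor(fo$G, fo$G, s0a, s0b)
  expect_equal(t0$values$eigenvalue, c(0, 0), tolerance = 1e-12)
  t2 <- eigentensor(diag(c(2, 1)), diag(c(1, 1)), s0a, s0b)
  expect_equal(t2$values$eigenvalue, c(1, 0))
  # eigenvector sign flips leave projected CIs unchanged
  proj1 <- project_variance(te$vectors[, 1], so$G - si$G)
  proj2 <- project_variance(-te$vectors[, 1], so$G - si$G)
  expect_equal(proj1, proj2)
})

test_that("inbreeding depression follows the linear extrapolation", {
  # hand example: outbred mean 100, inbred-sons mean 99 at F = 0.25
  ph <- data.frame(
    id = paste0("m", 1:4),
    sire = "s1", arm = c("outbred", "outbred", "inbred", "inbred"),
    tr = c(99, 101, 98.5, 99.5))
  id <- inbreeding_depression(ph, "tr", F_inbred = 0.25)
  expect_equal(id$per_sire$tr, 4)   # percent
  expect_equal(id$summary$mean_id, 4)
  # no depression when means are equal
  ph$tr <- c(100, 100, 100, 100)
  expect_equal(inbreeding_depression(ph, "tr")$summary$mean_id, 0)
  # zero outbred mean errors
  ph$tr <- c(-1, 1, 2, 2)
  expect_error(inbreeding_depression(ph, "tr"), "zero outbred mean")
})

test_that("symmetric dominance yields near-zero mean inbreeding
           depression", {
  params <- design_params(n_pairs = 150, n_generations = 1,
                          offspring_per_arm = 5, n_traits = 1,
                          seed = 81)
  ped <- simulate_mcn_pedigree(params)
  loci <- random_locus_set(100, 1, q = 0.2, a = 0.3, d = 1,
                           symmetric_d = TRUE, seed = 82)
  geno <- gene_drop(ped, loci, seed = 83)
  phen <- simulate_phenotypes(ped, geno, loci,
                              vial_cov = matrix(0.5),
                              residual_cov = matrix(2), seed = 84)
  phen$trait1 <- phen$trait1 + 100   # ratio needs a nonzero scale
  id <- inbreeding_depression(phen, "trait1")
  # mean ID within half the percentile spread of zero
  expect_lt(abs(id$summary$mean_id),
            (id$summary$dist_upper - id$summary$dist_lower) / 4)
  expect_equal(id$summary$n_sires, 150)
})
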