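test_that("balanced half-sib REML equals the ANOVA oracle", {
  hs <- make_half_sib(S = 80, k = 8, VA = 1, VE = 2, seed = 12)
  A <- build_A(hs$ped)
  fit <- fit_reml(hs$phen, A,
                  model_spec("y", fixed = character(0), vial = FALSE))
  va_oracle <- anova_half_sib_va(hs$phen$y, hs$fam, hs$k)
  expect_true(fit$converged)
  expect_equal(fit$G[1, 1], va_oracle, tolerance = 1e-4)
})

test_that("zero additive variance is recovered at the PSD boundary", {
  set.seed(2)
  hs <- make_half_sib(S = 60, k = 6, VA = 0, VE = 2, seed = 3)
  A <- build_A(hs$ped)
  fit <- fit_reml(hs$phen, A,
                  model_spec("y", fixed = character(0), vial = FALSE))
  expect_gte(fit$G[1, 1], 0)
  expect_lt(fit$G[1, 1], 0.25)
})

test_that("collapsed and dense likelihood paths agree", {
  x <- small_mcn()
  spec <- model_spec(c("trait1", "trait2"), arm = "inbred")
  dat <- pairedG:::prep_model_data(x$phen, x$A, spec)
  types <- vapply(dat$prob$strata, `[[`, "", "type")
  expect_true("scatter" %in% types)   # collapse detected
  # force the dense path by perturbing one within-vial fixed effect
  ph2 <- x$phen[x$phen$arm == "inbred", ]
  Y <- as.matrix(ph2[, c("trait1", "trait2")])
  X0 <- cbind(1, stats::model.matrix(~factor(ph2$generation))[, -1,
                                                              drop = FALSE],
              stats::model.matrix(~factor(ph2$observer))[, -1,
                                                         drop = FALSE])
  K <- unclass(x$A)[ph2$id, ph2$id]
  Z <- stats::model.matrix(~ 0 + factor(ph2$vial))
  dense <- list(t = 2L, n = nrow(Y), strata = list(list(
    type = "dense", Y = Y, X = kronecker(diag(2), X0),
    Ks = list(additive = K, vial = tcrossprod(Z),
              residual = diag(nrow(Y))))))
  blocks <- pairedG:::make_blocks(dat, spec)
  ob <- pairedG:::opt_blocks_of(blocks)
  th <- pairedG:::opt_from_report(blocks, ob, attr(blocks, "init"))
  e1 <- pairedG:::eval_problem(ob, th, dat$prob, need_P = FALSE)
  e2 <- pairedG:::eval_problem(ob, th, dense, need_P = FALSE)
  expect_equal(e1$ll, e2$ll, tolerance = 1e-10)
})

test_that("analytic gradient matches finite differences", {
  x <- small_mcn()
  spec <- model_spec(c("trait1", "trait2"), arm = "outbred")
  dat <- pairedG:::prep_model_data(x$phen, x$A, spec)
  blocks <- pairedG:::make_blocks(dat, spec)
  ob <- pairedG:::opt_blocks_of(blocks)
  th <- pairedG:::opt_from_report(blocks, ob, attr(blocks, "init"))
  ev <- pairedG:::eval_problem(ob, th, dat$prob)
  st <- pairedG:::iter_stats(ob, ev, dat$prob)
  ga <- pairedG:::grad_ai(ob, th, st, ev, dat$prob)
  h <- 1e-6
  pos <- 0L
  for (b in seq_along(ob)) for (k in seq_len(ob[[b]]$npar)) {
    up <- th; up[[b]][k] <- up[[b]][k] + h
    dn <- th; dn[[b]][k] <- dn[[b]][k] - h
    fd <- (pairedG:::eval_problem(ob, up, dat$prob, need_P = FALSE)$ll -
           pairedG:::eval_problem(ob, dn, dat$prob,
                                  need_P = FALSE)$ll) / (2 * h)
    pos <- pos + 1L
    expect_equal(ga$grad[pos], fd, tolerance = 1e-4)
  }
})

test_that("MCN parameter recovery is unbiased within sampling error", {
  x <- small_mcn()
  Gexp <- expected_G(x$loci)
  for (arm in c("outbred", "inbred")) {
    fit <- fit_reml(x$phen, x$A,
                    model_spec(c("trait1", "trait2"), arm = arm,
                               vial_diagonal = TRUE))
    expect_true(fit$converged)
    se <- sqrt(diag(solve(fit$AI)))[1:3]
    z <- (fit$G[c(1, 2, 4)] - Gexp[c(1, 2, 4)]) / se
    expect_true(all(abs(z) < 4))
    # log-likelihood non-decreasing across iterations
    expect_true(all(diff(fit$trajectory) > -1e-6))
    # AI symmetric, PD at the optimum
    expect_equal(fit$AI, t(fit$AI))
    expect_gt(min(eigen(fit$AI, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("fitting with F = 0 data gives identical results whether A
           comes from the full pedigree or its outbred block", {
  hs <- make_half_sib(S = 40, k = 5, VA = 1.5, VE = 1, seed = 9)
  A_full <- build_A(hs$ped)
  ids <- hs$phen$id
  A_sub <- structure(unclass(A_full)[ids, ids],
                     class = class(A_full))
  spec <- model_spec("y", fixed = character(0), vial = FALSE)
  f1 <- fit_reml(hs$phen, A_full, spec)
  f2 <- fit_reml(hs$phen, A_sub, spec)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f1$G, f2$G, tolerance = 1e-6)
})

test_that("reduced-rank fits satisfy their contracts", {
  x <- small_mcn()
  spec <- model_spec(c("trait1", "trait2"), arm = "outbred",
                     vial_diagonal = TRUE)
  full <- fit_reml(x$phen, x$A, spec)
  fa2 <- fit_reduced_rank(x$phen, x$A, spec, rank = 2)
  fa1 <- fit_reduced_rank(x$phen, x$A, spec, rank = 1)
  # r = t spans the same model space
  expect_equal(fa2$loglik, full$loglik, tolerance = 1e-4)
  expect_lte(fa1$loglik, full$loglik + 1e-6)
  # parameter counts: t r - r(r-1)/2
  expect_equal(n_G_params(full), 3)
  expect_equal(n_G_params(fa2), 3)
  expect_equal(n_G_params(fa1), 2)
  expect_equal(ncol(fa1$Lambda), 1)
  expect_error(fit_reduced_rank(x$phen, x$A, spec, rank = 3), "rank")
  # rank LRT mechanics
  lrt <- rank_lrt(full, fa1)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$p, pchisq(lrt$chi2, 1, lower.tail = FALSE))
  expect_error(rank_lrt(fa1, full), "G parameters")
  # identical fits -> chi2 0, p 1
  same <- rank_lrt(full, fa2)
  expect_lt(same$chi2, 0.01)
  expect_equal(same$p, 1)
  # 11-trait parameter count difference between rank 11 and 10 is 1
  t11 <- 11
  expect_equal((t11 * 11 - 11 * 10 / 2) - (t11 * 10 - 10 * 9 / 2), 1)
})

test_that("rank-deficient simulated G keeps the likelihood flat above
           the true rank", {
  # 3 traits, rank-1 genetic architecture by construction
  params <- design_params(n_pairs = 60, n_generations = 2,
                          offspring_per_arm = 5, n_traits = 3,
                          seed = 71)
  ped <- simulate_mcn_pedigree(params)
  lam <- c(1, 0.8, -0.5)
  loci <- locus_set(rep(0.5, 80), rep(1, 80), rep(0, 80),
                    matrix(rep(lam, each = 80), 80))
  geno <- gene_drop(ped, loci, seed = 72)
  phen <- simulate_phenotypes(ped, geno, loci,
                              vial_cov = diag(2, 3),
                              residual_cov = diag(20, 3), seed = 73)
  A <- build_A(ped)
  spec <- model_spec(paste0("trait", 1:3), arm = "outbred",
                     vial_diagonal = TRUE)
  f1 <- fit_reduced_rank(phen, A, spec, rank = 1)
  f3 <- fit_reduced_rank(phen, A, spec, rank = 3)
  expect_lt(2 * (f3$loglik - f1$loglik), 6)
})

test_that("model preparation rejects bad input", {
  x <- small_mcn()
  spec <- model_spec(c("trait1", "trait2"), arm = "outbred")
  i_out <- which(x$phen$arm == "outbred")[1]
  dup <- rbind(x$phen, x$phen[i_out, ])
  expect_error(fit_reml(dup, x$A, spec), "one phenotype record")
  ph <- x$phen
  ph$id[i_out] <- "not_in_pedigree"
  expect_error(fit_reml(ph, x$A, spec), "does not cover")
  ph2 <- x$phen[setdiff(names(x$phen), "vial")]
  expect_error(fit_reml(ph2, x$A, spec), "vial")
  # aliased fixed-effect columns are named
  ph3 <- x$phen
  ph3$dupfac <- ph3$observer
  spec3 <- model_spec(c("trait1", "trait2"),
                      fixed = c("observer", "dupfac"), arm = "outbred")
  expect_error(fit_reml(ph3, x$A, spec3), "aliased")
})
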