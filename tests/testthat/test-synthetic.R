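test_that("MCN pedigree has the stated paired structure", {
  params <- design_params(n_pairs = 2, n_generations = 1,
                          offspring_per_arm = 5, seed = 1)
  ped <- simulate_mcn_pedigree(params)
  F <- inbreeding_coefficients(ped)
  expect_equal(unname(F[ped$id[ped$arm == "inbred"]]),
               rep(0.25, sum(ped$arm == "inbred")))
  expect_equal(unname(F[ped$id[ped$arm == "outbred"]]),
               rep(0, sum(ped$arm == "outbred")))
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 4)  # founders
  expect_error(design_params(n_pairs = 1), "n_pairs")
  expect_error(design_params(offspring_per_arm = 6), "offspring")
})

test_that("every measured inbred male has a measured outbred
           half-brother, and vice versa", {
  params <- design_params(n_pairs = 30, n_generations = 3,
                          offspring_per_arm = 5, seed = 5)
  ped <- simulate_mcn_pedigree(params)
  meas <- ped[ped$arm %in% c("outbred", "inbred"), ]
  tab <- table(meas$sire, meas$arm)
  expect_true(all(tab[, "inbred"] > 0 & tab[, "outbred"] > 0))
})

test_that("outbred pairings avoid full sibs across seeds", {
  for (seed in 1:10) {
    params <- design_params(n_pairs = 5, n_generations = 2,
                            offspring_per_arm = 0, seed = seed)
    ped <- simulate_mcn_pedigree(suppressWarnings(params))
    # a full-sib outbred mating would give a parental couple that are
    # themselves siblings: check every sire/dam couple of measured or
    # focal offspring
    couples <- unique(stats::na.omit(ped[, c("sire", "dam")]))
    sibs <- function(a, b) {
      pa <- ped[match(a, ped$id), c("sire", "dam")]
      pb <- ped[match(b, ped$id), c("sire", "dam")]
      !is.na(pa$sire) && !is.na(pb$sire) &&
        pa$sire == pb$sire && pa$dam == pb$dam
    }
    arm_of <- function(s, d) {
      kids <- ped$arm[!is.na(ped$sire) & ped$sire == s &
                      !is.na(ped$dam) & ped$dam == d]
      unique(kids)
    }
    for (r in seq_len(nrow(couples))) {
      arms <- arm_of(couples$sire[r], couples$dam[r])
      if (any(arms %in% c("outbred", "parent")))
        expect_false(sibs(couples$sire[r], couples$dam[r]))
    }
  }
})

test_that("gene dropping is Mendelian and Hardy-Weinberg at founders", {
  x <- small_mcn()
  geno <- x$geno
  founders <- x$ped$id[is.na(x$ped$sire)]
  expect_true(all(geno %in% 0:2))
  # founder mean allele count ~ 2q
  expect_equal(mean(geno[founders, ]), 1,
               tolerance = 4 / sqrt(length(founders) * ncol(geno)))
  # Mendelian bounds: offspring count within reach of parent counts
  kids <- x$ped[!is.na(x$ped$sire) & !is.na(x$ped$dam), ]
  gs <- geno[kids$sire, , drop = FALSE]
  gd <- geno[kids$dam, , drop = FALSE]
  gk <- geno[kids$id, , drop = FALSE]
  lo <- (gs == 2) + (gd == 2)
  hi <- 2 - ((gs == 0) + (gd == 0))
  expect_true(all(gk >= lo & gk <= hi))
  expect_error(gene_drop(x$ped, locus_set(1, 1, 0, matrix(1)), 1),
               "strictly")
})

test_that("rare-allele homozygosity is enriched ~25x in the inbred arm", {
  params <- design_params(n_pairs = 150, n_generations = 2,
                          offspring_per_arm = 5, seed = 11)
  ped <- simulate_mcn_pedigree(params)
  loci <- locus_set(rep(0.01, 400), rep(1, 400), rep(0, 400),
                    matrix(1, 400, 1))
  geno <- gene_drop(ped, loci, seed = 12)
  hom_i <- mean(geno[ped$id[ped$arm == "inbred"], ] == 2)
  hom_o <- mean(geno[ped$id[ped$arm == "outbred"], ] == 2)
  # theory: (q^2 + F q(1-q)) / q^2 = 25.75 at q = 0.01, F = 0.25
  expect_gt(hom_i / hom_o, 10)
  expect_equal(hom_i / hom_o, 25.75, tolerance = 0.5)
})

test_that("phenotype simulation obeys its degenerate and variance
           contracts", {
  x <- small_mcn()
  # all effects zero -> phenotypes equal fixed-effect means exactly
  loci0 <- locus_set(x$loci$q, rep(0, x$loci$n_loci),
                     rep(0, x$loci$n_loci), x$loci$loadings)
  sh <- list(generation = matrix(c(3, -1), 2, 2))
  ph0 <- simulate_phenotypes(x$ped, x$geno, loci0,
                             vial_cov = matrix(0, 2, 2),
                             residual_cov = matrix(0, 2, 2),
                             fixed_effects = sh, seed = 1)
  gens <- sort(unique(ph0$generation))
  expect_equal(ph0$trait1, sh$generation[match(ph0$generation, gens), 1])
  # single additive locus: outbred phenotypic variance ~ 2 p q a^2
  set.seed(2)
  big <- design_params(n_pairs = 400, n_generations = 1,
                       offspring_per_arm = 5, n_traits = 1, seed = 21)
  bped <- simulate_mcn_pedigree(big)
  l1 <- locus_set(0.3, 2, 0, matrix(1))
  g1 <- gene_drop(bped, l1, seed = 22)
  p1 <- simulate_phenotypes(bped, g1, l1, vial_cov = matrix(0),
                            residual_cov = matrix(0), seed = 23)
  v_emp <- stats::var(p1$trait1[p1$arm == "outbred"])
  expect_equal(v_emp, va_outbred_textbook(0.3, 2, 0), tolerance = 0.12)
  expect_error(simulate_phenotypes(x$ped, x$geno, x$loci,
                                   vial_cov = matrix(c(1, 2, 2, 1), 2),
                                   residual_cov = diag(2)),
               "positive semi-definite")
})

test_that("paired +/-d loci leave arm means equal up to sampling error", {
  params <- design_params(n_pairs = 200, n_generations = 1,
                          offspring_per_arm = 5, n_traits = 1,
                          seed = 31)
  ped <- simulate_mcn_pedigree(params)
  loci <- random_locus_set(100, 1, q = 0.2, a = 0, d = 1,
                           symmetric_d = TRUE, seed = 32)
  expect_equal(mean(loci$d), 0)
  geno <- gene_drop(ped, loci, seed = 33)
  ph <- simulate_phenotypes(ped, geno, loci, vial_cov = matrix(0),
                            residual_cov = matrix(0), seed = 34)
  # paired comparison: per-sire arm-mean differences (records within a
  # family are correlated, so the family is the sampling unit)
  ds <- tapply(seq_len(nrow(ph)), ph$sire, function(i) {
    mean(ph$trait1[i][ph$arm[i] == "outbred"]) -
      mean(ph$trait1[i][ph$arm[i] == "inbred"])
  })
  expect_lt(abs(mean(ds)), 5 * stats::sd(ds) / sqrt(length(ds)))
})

test_that("additive-only inbred-arm genetic variance is inflated by
           about 1 + F", {
  # gene-dropping realization of the purely additive expectation
  params <- design_params(n_pairs = 500, n_generations = 1,
                          offspring_per_arm = 5, n_traits = 1,
                          seed = 41)
  ped <- simulate_mcn_pedigree(params)
  loci <- random_locus_set(60, 1, q = 0.5, a = 1, d = 0, seed = 42)
  geno <- gene_drop(ped, loci, seed = 43)
  ph <- simulate_phenotypes(ped, geno, loci, vial_cov = matrix(0),
                            residual_cov = matrix(0), seed = 44)
  vi <- stats::var(ph$trait1[ph$arm == "inbred"])
  vo <- stats::var(ph$trait1[ph$arm == "outbred"])
  expect_equal(vi / vo, 1.25, tolerance = 0.08)
})

test_that("identical seeds reproduce identical tables", {
  params <- design_params(n_pairs = 10, n_generations = 2, seed = 7)
  p1 <- simulate_mcn_pedigree(params)
  p2 <- simulate_mcn_pedigree(params)
  expect_identical(p1, p2)
  loci <- random_locus_set(20, 2, seed = 8)
  expect_identical(gene_drop(p1, loci, seed = 9),
                   gene_drop(p2, loci, seed = 9))
})

test_that("outlier injection flags the requested fraction", {
  x <- small_mcn()
  tr <- c("trait1", "trait2")
  expect_identical(inject_outliers(x$phen, tr, fraction = 0)$`.outlier`,
                   rep(FALSE, nrow(x$phen)))
  out <- inject_outliers(x$phen, tr, fraction = 0.01, magnitude = 10,
                         seed = 5)
  expect_equal(sum(out$.outlier), round(0.01 * nrow(x$phen)))
  expect_error(inject_outliers(x$phen, tr, fraction = 0.2), "fraction")
})

test_that("expected_G matches a brute-force locus sum", {
  loci <- random_locus_set(30, 2, q = 0.3, a = 1.5, d = 0.4, seed = 3)
  G <- matrix(0, 2, 2)
  for (l in seq_len(loci$n_loci)) {
    alpha <- loci$a[l] + loci$d[l] * (loci$q[l] - (1 - loci$q[l]))
    w <- 2 * loci$q[l] * (1 - loci$q[l]) * alpha^2
    G <- G + w * tcrossprod(loci$loadings[l, ])
  }
  expect_equal(unname(expected_G(loci)), G, tolerance = 1e-12)
})
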