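# Independent oracles used across test files.  These deliberately do
# not share code with the implementation paths they check.

# classic outbred additive-variance identity: 2pq (a + d(q - p))^2
va_outbred_textbook <- function(q, a, d) {
  p <- 1 - q
  2 * p * q * (a + d * (q - p))^2
}

# labelled-allele gene dropping: Monte-Carlo estimate of the additive
# relationship 2 * kinship(i, j) (independent of the tabular method)
ibd_drop_A <- function(ped, n_drops = 1e4, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  # drop all replicates at once; founder allele labels 2i-1 / 2i are
  # unique within a replicate, which is all IBD comparison needs
  al1 <- matrix(0L, n, n_drops)
  al2 <- matrix(0L, n, n_drops)
  for (i in idx) {
    al1[i, ] <- if (si[i] == 0L) rep(2L * i - 1L, n_drops) else {
      pick <- stats::runif(n_drops) < 0.5
      ifelse(pick, al1[si[i], ], al2[si[i], ])
    }
    al2[i, ] <- if (di[i] == 0L) rep(2L * i, n_drops) else {
      pick <- stats::runif(n_drops) < 0.5
      ifelse(pick, al1[di[i], ], al2[di[i], ])
    }
  }
  acc <- matrix(0, n, n)
  for (i in idx) for (j in idx[idx <= i]) {
    # A_ij ~ 2 * mean IBD over the four allele pairings
    v <- mean((al1[i, ] == al1[j, ]) + (al1[i, ] == al2[j, ]) +
              (al2[i, ] == al1[j, ]) + (al2[i, ] == al2[j, ])) / 2
    acc[i, j] <- acc[j, i] <- v
  }
  acc
}

# balanced one-way (paternal half-sib) ANOVA estimator of V_A
anova_half_sib_va <- function(y, fam, k) {
  gm <- tapply(y, fam, mean)
  S <- length(gm)
  MSB <- k * sum((gm - mean(y))^2) / (S - 1)
  MSW <- sum((y - gm[fam])^2) / (S * (k - 1))
  4 * (MSB - MSW) / k
}

# small half-sib dataset simulated from the infinitesimal model
make_half_sib <- function(S = 80, k = 8, VA = 1, VE = 2, seed = 1) {
  set.seed(seed)
  sires <- paste0("s", seq_len(S))
  off <- paste0("o", seq_len(S * k))
  ped <- pedigree_table(data.frame(
    id = c(sires, off),
    sire = c(rep(NA, S), rep(sires, each = k)),
    dam = NA, stringsAsFactors = FALSE))
  bv_s <- stats::rnorm(S, 0, sqrt(VA))
  y <- 0.5 * rep(bv_s, each = k) +
    stats::rnorm(S * k, 0, sqrt(0.75 * VA)) +
    stats::rnorm(S * k, 0, sqrt(VE))
  list(ped = ped,
       phen = data.frame(id = off, arm = "outbred",
                         sire = rep(sires, each = k), y = y,
                         stringsAsFactors = FALSE),
       fam = rep(sires, each = k), k = k)
}

# one small MCN dataset shared by several test files (memoized)
mcn_cache <- new.env(parent = emptyenv())
small_mcn <- function() {
  if (!is.null(mcn_cache$x)) return(mcn_cache$x)
  params <- design_params(n_pairs = 40, n_generations = 2,
                          offspring_per_arm = 5, n_traits = 2,
                          seed = 4242)
  ped <- simulate_mcn_pedigree(params)
  loci <- random_locus_set(120, 2, q = 0.5, a = 1, d = 0, seed = 4243)
  geno <- gene_drop(ped, loci, seed = 4244)
  phen <- simulate_phenotypes(ped, geno, loci,
                              vial_cov = diag(10, 2),
                              residual_cov = diag(60, 2), seed = 4245)
  mcn_cache$x <- list(params = params, ped = ped, loci = loci,
                      geno = geno, phen = phen, A = build_A(ped))
  mcn_cache$x
}
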