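#' Design parameters for a middle-class-neighbourhood simulation
#'
#' The MCN design keeps `n_pairs` breeding pairs per generation, every
#' pair contributing exactly one continuing son and daughter (equalizing
#' family sizes, maximizing effective population size and minimizing
#' drift).  Each round, focal sires are mated both to an unrelated focal
#' female (outbred arm) and to their own full sister (inbred arm,
#' offspring `F = 0.25`); up to five sons per cross arm are measured.
#'
#' @param n_pairs Number of breeding pairs per generation (>= 2, so that
#'   brother-sister outbred pairings can be avoided).
#' @param n_generations Number of focal-cross rounds (>= 1).
#' @param offspring_per_arm Measured sons per cross arm, in `[0, 5]`.
#' @param n_traits Number of phenotyped traits.
#' @param seed Master random seed (integer, recorded in all outputs).
#' @return A `design_params` list.
#' @export
design_params <- function(n_pairs = 200, n_generations = 1,
                          offspring_per_arm = 5, n_traits = 2,
                          seed = 1L) {
  if (!is.numeric(n_pairs) || n_pairs < 2)
    stop("n_pairs must be >= 2 to avoid brother-sister outbred pairings")
  if (offspring_per_arm < 0 || offspring_per_arm > 5)
    stop("offspring_per_arm must lie in [0, 5]")
  if (n_generations < 1) stop("n_generations must be >= 1")
  structure(list(n_pairs = as.integer(n_pairs),
                 n_generations = as.integer(n_generations),
                 offspring_per_arm = as.integer(offspring_per_arm),
                 n_traits = as.integer(n_traits),
                 seed = as.integer(seed)),
            class = "design_params")
}

#' A set of biallelic loci with additive and dominance effects
#'
#' Each locus has a focal-allele frequency `q` in (0, 1), an additive
#' effect `a`, a dominance effect `d` (genotypic values `-a`, `d`, `+a`
#' for 0/1/2 copies of the focal allele), and a loading vector mapping
#' its genotypic value onto the traits (pleiotropy).  Loci are
#' unlinked (linkage equilibrium).
#'
#' @param q,a,d Numeric vectors of length `n_loci`.
#' @param loadings `n_loci x n_traits` matrix of trait loadings.
#' @return A `locus_set` object.
#' @seealso [random_locus_set()] for a convenience generator.
#' @export
locus_set <- function(q, a, d, loadings) {
  loadings <- as.matrix(loadings)
  L <- length(q)
  stopifnot(length(a) == L, length(d) == L, nrow(loadings) == L)
  if (any(q <= 0) || any(q >= 1))
    stop("locus allele frequencies must lie strictly in (0, 1)")
  if (any(!is.finite(loadings))) stop("loadings must be finite")
  if (is.null(colnames(loadings)))
    colnames(loadings) <- paste0("trait", seq_len(ncol(loadings)))
  structure(list(q = as.numeric(q), a = as.numeric(a), d = as.numeric(d),
                 loadings = loadings, n_loci = L,
                 n_traits = ncol(loadings)),
            class = "locus_set")
}

#' @export
print.locus_set <- function(x, ...) {
  cat("<locus_set> ", x$n_loci, " loci, ", x$n_traits, " traits; ",
      "mean q = ", format(mean(x$q), digits = 3),
      ", E[d] = ", format(mean(x$d), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Random polygenic architecture
#'
#' Draws a `locus_set` with common allele frequency `q`, additive effect
#' `a`, dominance effect `d` and standard-normal trait loadings.  With
#' `symmetric_d = TRUE` (the default) loci come in pairs with dominance
#' effects `+d` and `-d`, so `E[d] = 0` by construction (no directional
#' dominance) while `d^2 > 0` at every locus.
#'
#' @param n_loci Number of loci (rounded up to even when `symmetric_d`).
#' @param n_traits Number of traits.
#' @param q Allele frequency, recycled across loci.
#' @param a Additive effect, recycled.
#' @param d Dominance-effect magnitude, recycled.
#' @param symmetric_d Pair loci with `+d` / `-d` signs.
#' @param seed Random seed for the loadings.
#' @return A [locus_set()].
#' @export
random_locus_set <- function(n_loci, n_traits, q = 0.5, a = 1, d = 0,
                             symmetric_d = TRUE, seed = 1L) {
  if (symmetric_d && n_loci %% 2L == 1L) n_loci <- n_loci + 1L
  set.seed(seed)
  qv <- rep_len(q, n_loci)
  av <- rep_len(a, n_loci)
  dv <- rep_len(d, n_loci)
  if (symmetric_d) dv <- dv * rep_len(c(1, -1), n_loci)
  loadings <- matrix(stats::rnorm(n_loci * n_traits), n_loci, n_traits)
  locus_set(qv, av, dv, loadings)
}

#' Expected outbred additive genetic covariance of a locus set
#'
#' Under linkage equilibrium and Hardy-Weinberg founders, the expected
#' outbred (`F = 0`) additive genetic covariance matrix is
#' `sum_l 2 p_l q_l alpha_l^2 lambda_l lambda_l'`, where
#' `alpha = a + d(q - p)` is the average effect of an allele
#' substitution and `lambda_l` the locus loading vector.
#'
#' @param loci A [locus_set()].
#' @return `n_traits x n_traits` expected G matrix.
#' @export
expected_G <- function(loci) {
  stopifnot(inherits(loci, "locus_set"))
  p <- 1 - loci$q
  alpha <- loci$a + loci$d * (loci$q - p)
  w <- 2 * p * loci$q * alpha^2
  crossprod(loci$loadings * sqrt(w))
}

#' Simulate a middle-class-neighbourhood paired pedigree
#'
#' Generation 0 consists of `n_pairs` unrelated founder couples.  Each
#' focal-cross round `r` (1 to `n_generations`): every couple of the
#' previous round contributes one focal son, one focal (continuing)
#' daughter, and one additional daughter who will be mated to her
#' brother.  Focal sons are paired with non-sib focal daughters via a
#' random cyclic derangement (no brother-sister outbred pairings by
#' construction).  Each focal sire's outbred cross produces
#' `offspring_per_arm` measured outbred sons plus the next round's focal
#' offspring; his inbred cross (with his full sister) produces
#' `offspring_per_arm` measured inbred sons (`F = 0.25`).  Measured
#' brothers of a cross arm share one rearing vial.
#'
#' @param params A [design_params()] object.
#' @return A validated [pedigree_table()] with extra columns `vial`
#'   (rearing unit of measured sons, `NA` otherwise) and `cross`.
#' @export
simulate_mcn_pedigree <- function(params) {
  stopifnot(inherits(params, "design_params"))
  np <- params$n_pairs
  k <- params$offspring_per_arm
  set.seed(params$seed)
  rows <- list()
  add <- function(id, sire, dam, sex, gen, arm, vial = NA_character_,
                  cross = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, generation = gen,
      arm = arm, vial = vial, cross = cross, stringsAsFactors = FALSE)
  }
  cid <- function(prefix, r, c) sprintf("%s%d.%03d", prefix, r, c)
  # founder couples
  sires <- vapply(seq_len(np), function(c) cid("M", 0L, c), "")
  dams <- vapply(seq_len(np), function(c) cid("F", 0L, c), "")
  add(sires, NA_character_, NA_character_, "M", 0L, "parent")
  add(dams, NA_character_, NA_character_, "F", 0L, "parent")
  for (r in seq_len(params$n_generations)) {
    sons <- vapply(seq_len(np), function(c) cid("M", r, c), "")
    daughters <- vapply(seq_len(np), function(c) cid("F", r, c), "")
    sisters <- vapply(seq_len(np), function(c) cid("X", r, c), "")
    add(sons, sires, dams, "M", r, "parent")
    add(daughters, sires, dams, "F", r, "parent")
    add(sisters, sires, dams, "F", r, "parent")
    # random cyclic derangement: son_c mates daughter of the next cross
    # along a random cycle, so no son is ever paired with a full sister
    ord <- sample.int(np)
    mate <- integer(np)
    mate[ord] <- ord[c(2:np, 1L)]
    if (k > 0L) {
      for (c in seq_len(np)) {
        cross_o <- cid("CO", r, c)
        cross_i <- cid("CI", r, c)
        vial_o <- cid("VO", r, c)
        vial_i <- cid("VI", r, c)
        oid <- sprintf("%s.s%d", cross_o, seq_len(k))
        iid <- sprintf("%s.s%d", cross_i, seq_len(k))
        add(oid, sons[c], daughters[mate[c]], "M", r + 1L, "outbred",
            vial_o, cross_o)
        add(iid, sons[c], sisters[c], "M", r + 1L, "inbred",
            vial_i, cross_i)
      }
    }
    # next round's parental couples come from the outbred crosses
    new_sires <- vapply(seq_len(np), function(c) cid("M", r, c), "")
    new_dams <- vapply(seq_len(np), function(c) daughters[mate[c]], "")
    sires <- new_sires
    dams <- new_dams
  }
  ped <- do.call(rbind, rows)
  out <- pedigree_table(ped)
  attr(out, "seed") <- params$seed
  out
}

#' Drop genes down a pedigree
#'
#' Founders receive two alleles per locus drawn Bernoulli(`q`)
#' (Hardy-Weinberg); every meiosis transmits one of the parent's two
#' alleles with a fair coin.  An unknown parent contributes a fresh
#' founder allele.  Transmission is independent across loci (no
#' linkage).
#'
#' @param ped A validated [pedigree_table()] (topological order).
#' @param loci A [locus_set()].
#' @param seed Random seed.
#' @return Integer matrix (`n_individuals x n_loci`) of focal-allele
#'   counts (0/1/2), rownames = ids.
#' @export
gene_drop <- function(ped, loci, seed = 1L) {
  stopifnot_validated(ped)
  stopifnot(inherits(loci, "locus_set"))
  set.seed(seed)
  n <- nrow(ped)
  L <- loci$n_loci
  q <- loci$q
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  pat <- matrix(0L, n, L)  # allele inherited via the sire
  mat <- matrix(0L, n, L)
  founder_allele <- function() as.integer(stats::runif(L) < q)
  for (i in idx) {
    pat[i, ] <- if (si[i] == 0L) founder_allele() else {
      pick <- stats::runif(L) < 0.5
      ifelse(pick, pat[si[i], ], mat[si[i], ])
    }
    mat[i, ] <- if (di[i] == 0L) founder_allele() else {
      pick <- stats::runif(L) < 0.5
      ifelse(pick, pat[di[i], ], mat[di[i], ])
    }
  }
  geno <- pat + mat
  rownames(geno) <- ped$id
  colnames(geno) <- paste0("L", seq_len(L))
  geno
}

#' Simulate phenotypes for the measured individuals of an MCN pedigree
#'
#' Genotypic value at a locus is `-a`, `d`, `+a` for 0/1/2 copies of the
#' focal allele, mapped to traits through the locus loading vector and
#' summed over loci.  Each rearing vial receives one multivariate-normal
#' effect draw (covariance `vial_cov`); each record receives a residual
#' draw (covariance `residual_cov`); observers are assigned cyclically
#' to vials and contribute additive per-trait shifts, as do generations
#' (`fixed_effects`).
#'
#' @param ped Pedigree from [simulate_mcn_pedigree()] (must carry the
#'   `vial` column).
#' @param genotypes Genotype matrix from [gene_drop()].
#' @param loci The [locus_set()] used for the gene drop.
#' @param vial_cov,residual_cov `t x t` symmetric PSD covariance
#'   matrices.
#' @param fixed_effects Optional list with matrices `observer`
#'   (`n_observers x t`) and/or `generation` (rows indexed by measured
#'   generation, in increasing order) of additive per-trait shifts;
#'   defaults to zero shifts.
#' @param n_observers Number of observers cycled over vials (default 6).
#' @param trait_means Baseline trait mean(s), recycled across traits
#'   (default 0; use a large positive value to emulate size-like traits
#'   so proportional statistics such as inbreeding depression are
#'   well scaled).
#' @param seed Random seed.
#' @return A `data.frame` phenotype table: one row per measured
#'   individual with columns `id, sire, dam, arm, vial, observer,
#'   generation` and one column per trait.
#' @export
simulate_phenotypes <- function(ped, genotypes, loci, vial_cov,
                                residual_cov, fixed_effects = NULL,
                                n_observers = 6L, trait_means = 0,
                                seed = 1L) {
  stopifnot_validated(ped)
  stopifnot(inherits(loci, "locus_set"))
  t <- loci$n_traits
  vial_cov <- check_psd(vial_cov, t, "vial_cov")
  residual_cov <- check_psd(residual_cov, t, "residual_cov")
  meas <- ped[ped$arm %in% c("outbred", "inbred"), , drop = FALSE]
  if (nrow(meas) == 0L) stop("pedigree has no measured individuals")
  if (!"vial" %in% names(meas) || anyNA(meas$vial))
    stop("pedigree must carry vial assignments for measured individuals")
  set.seed(seed)
  G <- genotypes[meas$id, , drop = FALSE]
  # per-locus genotypic values
  vals <- matrix(0, nrow(G), ncol(G))
  vals[G == 0L] <- -1
  vals[G == 2L] <- 1
  vals <- sweep(vals, 2L, loci$a, "*")
  vals[G == 1L] <- rep(loci$d, each = nrow(G))[G == 1L]
  Y <- vals %*% loci$loadings
  # vial effects (one draw per vial) and observer assignment
  vials <- sort(unique(meas$vial))
  veff <- MASS::mvrnorm(length(vials), mu = rep(0, t), Sigma = vial_cov)
  veff <- matrix(veff, ncol = t)
  rownames(veff) <- vials
  observer <- paste0("obs", (match(meas$vial, vials) - 1L) %% n_observers + 1L)
  Y <- Y + veff[meas$vial, , drop = FALSE]
  # fixed-effect shifts
  gens <- sort(unique(meas$generation))
  if (!is.null(fixed_effects$observer)) {
    sh <- as.matrix(fixed_effects$observer)
    stopifnot(nrow(sh) >= n_observers, ncol(sh) == t)
    Y <- Y + sh[as.integer(sub("obs", "", observer)), , drop = FALSE]
  }
  if (!is.null(fixed_effects$generation)) {
    sh <- as.matrix(fixed_effects$generation)
    stopifnot(nrow(sh) >= length(gens), ncol(sh) == t)
    Y <- Y + sh[match(meas$generation, gens), , drop = FALSE]
  }
  # baseline means and residuals
  Y <- sweep(Y, 2L, rep_len(trait_means, t), "+")
  Y <- Y + matrix(MASS::mvrnorm(nrow(meas), rep(0, t), residual_cov),
                  ncol = t)
  colnames(Y) <- colnames(loci$loadings)
  out <- data.frame(id = meas$id, sire = meas$sire, dam = meas$dam,
                    arm = meas$arm, vial = meas$vial, observer = observer,
                    generation = meas$generation,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(Y))
}

check_psd <- function(S, t, what) {
  S <- as.matrix(S)
  if (nrow(S) != t || ncol(S) != t)
    stop(what, " must be ", t, " x ", t)
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
    stop(what, " must be symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(what, " must be positive semi-definite")
  (S + t(S)) / 2
}

#' Inject labelled outliers into a phenotype table
#'
#' Perturbs a random subset of records by `magnitude` trait standard
#' deviations along a random direction in trait space, retaining truth
#' flags (column `.outlier`) so outlier-filter recovery can be scored.
#'
#' @param phen Phenotype table (as from [simulate_phenotypes()]).
#' @param traits Character vector of trait column names.
#' @param fraction Fraction of records to contaminate, in `[0, 0.1)`.
#' @param magnitude Perturbation size in per-trait SD units.
#' @param seed Random seed.
#' @return The table with perturbed records and a logical `.outlier`
#'   column.
#' @export
inject_outliers <- function(phen, traits, fraction = 0.01, magnitude = 10,
                            seed = 1L) {
  if (fraction < 0 || fraction >= 0.1)
    stop("outlier fraction must lie in [0, 0.1)")
  phen$.outlier <- FALSE
  n_out <- round(nrow(phen) * fraction)
  if (n_out == 0L) return(phen)
  set.seed(seed)
  sel <- sample.int(nrow(phen), n_out)
  sds <- vapply(phen[traits], stats::sd, 0)
  for (i in sel) {
    u <- stats::rnorm(length(traits))
    u <- u / sqrt(sum(u^2))
    phen[i, traits] <- phen[i, traits] + magnitude * u * sds
  }
  phen$.outlier[sel] <- TRUE
  phen
}

#' Simulate landmark configurations for morphometrics testing
#'
#' Jitters a base 9-landmark wing-like shape, then applies random
#' rotation, translation and scale per specimen, emulating digitized
#' landmark data upstream of Procrustes alignment.
#'
#' @param n Number of specimens.
#' @param base 9 x 2 base shape (default: a stylized wing outline).
#' @param noise_sd Isotropic landmark jitter SD (shape units).
#' @param seed Random seed.
#' @return A list of `n` matrices (9 x 2), named `spec1..specn`.
#' @export
simulate_landmark_configs <- function(n, base = wing_base_shape(),
                                      noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    X <- base + matrix(stats::rnorm(length(base), sd = noise_sd),
                       nrow(base))
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    s <- exp(stats::rnorm(1, sd = 0.2))
    sweep(s * X %*% R, 2L, stats::rnorm(2, sd = 2), "+")
  })
  names(out) <- paste0("spec", seq_len(n))
  out
}

#' Stylized 9-landmark wing shape
#' @return A 9 x 2 coordinate matrix.
#' @export
wing_base_shape <- function() {
  matrix(c(0.00, 0.00,
           0.35, 0.12,
           0.70, 0.18,
           1.00, 0.10,
           0.95, -0.05,
           0.70, -0.12,
           0.40, -0.15,
           0.15, -0.10,
           0.50, 0.02),
         ncol = 2, byrow = TRUE,
         dimnames = list(paste0("lm", 1:9), c("x", "y")))
}
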