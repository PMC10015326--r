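#' Single-locus parameters for additive variance under inbreeding
#'
#' Bundles the parameters of a biallelic locus: the frequency `q` of the
#' focal allele (the other allele has frequency `p = 1 - q`, never stored
#' separately), the additive effect `a` (homozygote genotypic values are
#' `-a` and `+a`), the dominance effect `d` (heterozygote value), and the
#' inbreeding coefficient `F` of the individuals being considered.
#'
#' @param q Frequency of the focal allele, in `[0, 1]`.
#' @param a Additive effect, in trait units.
#' @param d Dominance effect, in trait units.
#' @param F Inbreeding coefficient, in `[0, 1]`.
#' @return An object of class `locus_params`.
#' @examples
#' locus_params(q = 0.1, a = 0.5, d = 0.5, F = 0.25)
#' @export
locus_params <- function(q, a = 0, d = 0, F = 0) {
  stopifnot(is.numeric(q), is.numeric(a), is.numeric(d), is.numeric(F))
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("allele frequency `q` must lie in [0, 1]")
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("inbreeding coefficient `F` must lie in [0, 1]")
  structure(list(q = q, a = a, d = d, F = F), class = "locus_params")
}

#' @export
print.locus_params <- function(x, ...) {
  cat("<locus_params> q =", x$q, " a =", x$a, " d =", x$d, " F =", x$F, "\n")
  invisible(x)
}

#' Additive genetic variance at one locus under one generation of inbreeding
#'
#' Computes the single-locus additive genetic variance for a population
#' with inbreeding coefficient `F`, decomposed into its three terms:
#'
#' \deqn{V_A = 2pq(1+F)a^2
#'   + [4pq\,ad(q-p) - 4F\,pq\,ad(q-p)]
#'   + 2pq\,d^2(q-p)^2\frac{(1-F)^2}{1+F}}
#'
#' Term 1 is the purely additive part, inflated by `1 + F`.  Term 2 is the
#' additive-by-dominance interaction, the only term that can be negative;
#' it sums to zero across loci when there is no directional dominance
#' (`E[d] = 0`).  Term 3 is the contribution of dominant gene action at
#' unequal allele frequencies; inbreeding scales it by
#' `(1-F)^2/(1+F)` (see [deflation_factor()]), which is what can pull
#' `V_A` below the `(1+F)` additive expectation.
#'
#' @param locus A [locus_params()] object (vectorized over its fields).
#' @return A list with components `term1`, `term2`, `term3` and `total`
#'   (their sum), all in squared trait units.
#' @examples
#' va_under_inbreeding(locus_params(q = 0.5, a = 0.5))$total  # 2pq a^2 = 0.125
#' @export
va_under_inbreeding <- function(locus) {
  stopifnot(inherits(locus, "locus_params"))
  q <- locus$q; p <- 1 - q; a <- locus$a; d <- locus$d; F <- locus$F
  term1 <- 2 * p * q * (1 + F) * a^2
  term2 <- 4 * p * q * a * d * (q - p) - 4 * F * p * q * a * d * (q - p)
  term3 <- 2 * p * q * d^2 * (q - p)^2 * (1 - F)^2 / (1 + F)
  list(term1 = term1, term2 = term2, term3 = term3,
       total = term1 + term2 + term3)
}

#' Inbreeding deflation factor for the dominance term
#'
#' The factor `(1-F)^2/(1+F)` by which inbreeding rescales the
#' contribution of dominant gene action (term 3 of the single-locus
#' variance) relative to its outbred value.  It equals 1 at `F = 0`,
#' 0.45 at `F = 0.25` (full-sib mating) and tends to 0 as `F` tends to 1;
#' because it is always below `1 + F`, dominance at unequal allele
#' frequencies deflates `V_A` below the purely additive expectation.
#'
#' @param F Inbreeding coefficient(s) in `[0, 1]`.
#' @return Dimensionless scalar (or vector) deflation factor.
#' @examples
#' deflation_factor(0.25)  # 0.45
#' @export
deflation_factor <- function(F) {
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("inbreeding coefficient `F` must lie in [0, 1]")
  (1 - F)^2 / (1 + F)
}

#' Homozygote-frequency enrichment under inbreeding
#'
#' Frequency of individuals homozygous for an allele at frequency `q`
#' with (`q^2 + F q(1-q)`) and without (`q^2`) inbreeding, and their
#' ratio.  For rare alleles (`q < 0.01`) at `F = 0.25` the ratio exceeds
#' 25: close inbreeding makes rare recessives visible to selection and
#' to variance-component estimation.
#'
#' @param q Allele frequency in `(0, 1]` (the ratio is undefined at 0).
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @param ratio Whether to compute the enrichment ratio (default `TRUE`).
#' @return A list with `freq_inbred`, `freq_outbred`, and (if requested)
#'   `ratio`.
#' @examples
#' homozygote_enrichment(0.01, 0.25)$ratio  # 25.75
#' @export
homozygote_enrichment <- function(q, F, ratio = TRUE) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("allele frequency `q` must lie in [0, 1]")
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1))
    stop("inbreeding coefficient `F` must lie in [0, 1]")
  out <- list(freq_inbred = q^2 + F * q * (1 - q), freq_outbred = q^2)
  if (ratio) {
    if (any(q == 0))
      stop("enrichment ratio is undefined at q = 0")
    out$ratio <- out$freq_inbred / out$freq_outbred
  }
  out
}

#' Relative-variance surface over allele frequency and dominance effect
#'
#' Evaluates the ratio of single-locus additive variance with inbreeding
#' (`V_AI`, at inbreeding coefficient `F`) to without (`V_AO`, at `F = 0`)
#' over a grid of allele frequencies `q` and dominance effects `d`.
#' Following the convention of the heat-map presentation of this
#' quantity, only terms 1 and 3 of the variance are used (the
#' additive-by-dominance term is omitted, as it sums to zero across loci
#' without directional dominance); the full three-term variance is
#' available from [va_under_inbreeding()].
#'
#' Cells with `d = 0`, or with `q = p = 0.5`, equal `1 + F` exactly.  At
#' the boundary columns `q = 0` and `q = 1` both variances vanish and the
#' ratio is reported as `NaN` with `boundary = TRUE` (a deliberate
#' continuity choice rather than a silent 0/0).
#'
#' @param q_grid Numeric vector of allele frequencies in `[0, 1]`.
#' @param d_grid Numeric vector of dominance effects.
#' @param a Additive effect (> 0); default 0.5.
#' @param F Inbreeding coefficient for the numerator; default 0.25.
#' @return A long-format `data.frame` with columns `q`, `d`, `ratio`,
#'   `boundary`.
#' @examples
#' va_ratio_surface(c(0.1, 0.5), c(0, 1))
#' @export
va_ratio_surface <- function(q_grid, d_grid, a = 0.5, F = 0.25) {
  if (length(q_grid) == 0L || length(d_grid) == 0L)
    stop("q_grid and d_grid must be non-empty")
  if (any(q_grid < 0) || any(q_grid > 1))
    stop("q_grid values must lie in [0, 1]")
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("`a` must be a single positive number")
  if (F < 0 || F > 1) stop("`F` must lie in [0, 1]")
  grid <- expand.grid(q = q_grid, d = d_grid, KEEP.OUT.ATTRS = FALSE)
  va13 <- function(q, d, F) {
    p <- 1 - q
    2 * p * q * (1 + F) * a^2 +
      2 * p * q * d^2 * (q - p)^2 * (1 - F)^2 / (1 + F)
  }
  num <- va13(grid$q, grid$d, F)
  den <- va13(grid$q, grid$d, 0)
  boundary <- grid$q == 0 | grid$q == 1
  ratio <- num / den
  ratio[boundary] <- NaN
  data.frame(q = grid$q, d = grid$d, ratio = ratio, boundary = boundary)
}

#' Write a relative-variance surface as long-format CSV
#'
#' Convenience exporter for plotting: columns `q`, `d`, `ratio`
#' (boundary cells are written as empty fields).
#'
#' @param path Output CSV path.
#' @inheritParams va_ratio_surface
#' @return The path, invisibly.
#' @export
write_ratio_surface_csv <- function(path, q_grid = seq(0, 1, by = 0.01),
                                    d_grid = seq(-1, 1, by = 0.02),
                                    a = 0.5, F = 0.25) {
  surf <- va_ratio_surface(q_grid, d_grid, a = a, F = F)
  utils::write.csv(surf[, c("q", "d", "ratio")], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
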