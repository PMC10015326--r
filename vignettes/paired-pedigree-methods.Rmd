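---
title: "Testing dominance deflation of additive genetic (co)variance with paired pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing dominance deflation of additive genetic (co)variance with paired pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Additive genetic variance ($V_A$) predicts both adaptive and neutral
phenotypic evolution, but its response to inbreeding depends on gene
action.  Under purely additive allelic effects, one generation of
inbreeding at coefficient $F$ inflates the genetic variance by a factor
$1 + F$.  With dominance, the single-locus additive variance is

$$V_A = 2pq(1+F)a^2
  + \left[4pq\,ad(q-p) - 4F\,pq\,ad(q-p)\right]
  + 2pq\,d^2(q-p)^2\,\frac{(1-F)^2}{1+F},$$

where $q = 1 - p$ is the focal-allele frequency, $a$ the additive and
$d$ the dominance effect.  The middle (additive-by-dominance) term sums
to zero across loci when there is no directional dominance
($E[d] = 0$), which is checkable from the data via inbreeding
depression.  The third term — dominant gene action at unequal allele
frequencies — is rescaled by $(1-F)^2/(1+F)$, which equals 0.45 at
$F = 0.25$ and is always below $1 + F$: if rare (partially) recessive
alleles contribute to a trait, inbreeding deflates $V_A$ below the
additive expectation.  `deflation_factor()`, `va_under_inbreeding()`
and `homozygote_enrichment()` implement these closed forms;
`va_ratio_surface()` evaluates the two-term (terms 1 and 3) relative
magnitude $V_{AI}/V_{AO}$ over a $(q, d)$ grid, the convention used for
heat-map displays of the prediction; the full three-term evaluation
stays available in `va_under_inbreeding()`.

The experimental design that makes the prediction testable is a paired
pedigree in a middle-class-neighbourhood (MCN) population: every focal
sire is mated both to an unrelated female (outbred arm, $F \approx 0$)
and to his full sister (inbred arm, $F \approx 0.25$).  Because the
same sires and dams feed both arms, the two arms share allele
frequencies and differ only in genotype frequencies.  An inbreeding-
aware animal model fit separately to each arm then estimates two
additive covariance matrices $G_O$ and $G_I$ whose equality is the
purely-additive null: the numerator relationship matrix **A** (with
diagonals $1 + F$) already absorbs the $1+F$ inflation, so any
departure of $G_I$ from $G_O$ indicates non-additive gene action.

## The model

Each arm is analysed with the multivariate animal model

$$\mathbf{Y} = \mathbf{X}_b\mathbf{b} + \mathbf{Z}_v\mathbf{v} +
  \mathbf{Z}_a\mathbf{a} + \mathbf{e},$$

with trait-specific fixed effects for trait mean, generation and
observer (reference-level coding, full trait-by-factor interaction), a
random among-vial effect (one rearing vial per cross arm; brothers
photographed together share it, so any inflated resemblance among
brothers is absorbed here), and additive genetic effects with
covariance $G \otimes \mathbf{A}$.  `fit_reml()` estimates unstructured
$t \times t$ covariance matrices for the additive, vial and residual
terms by restricted maximum likelihood.

The model notation for the vial term ($V = I\sigma_v^2$) can be read
two ways; we implement both.  `model_spec(vial_diagonal = FALSE)` (the
default) fits an unstructured vial covariance — the conservative
multivariate reading; `vial_diagonal = TRUE` fits per-trait vial
variances without covariances — the literal reading.  Our own
simulation studies use the diagonal option: it matches the generating
model and removes a family of boundary solutions (vial correlations of
$\pm 1$) that degrade the curvature estimates used for confidence
intervals.

### Numerics

* **Average-information REML.**  The engine iterates quasi-Newton steps
  preconditioned by the average-information (AI) matrix, with ridge
  damping and step-halving, and falls back on expectation-maximization
  (EM) updates — which can never decrease the restricted likelihood and
  never leave the positive-semi-definite cone — when no damped AI step
  improves it.  Convergence requires a relative log-likelihood change
  below `tol` (default $10^{-8}$) backed by a small Newton decrement
  (or two consecutive sub-tolerance steps), which prevents a tiny EM
  step from masquerading as convergence; `max_iter` defaults to 200.
* **Cholesky-scale iterations.**  Internally, parameters move on the
  Cholesky scale ($\Sigma = LL'$, $L$ lower-triangular), so every
  iterate is automatically positive semi-definite and boundary optima
  (singular component matrices, common when a variance is truly small)
  are approached smoothly instead of by constrained projection.  An
  L-BFGS stage with analytic gradients runs first; the AI loop then
  polishes the optimum.  The AI matrix reported with the fit is
  re-evaluated at the optimum on the covariance ("G-") scale — the
  scale on which REML-MVN sampling operates.
* **Exact likelihood collapse.**  For family-grouped data — every vial
  a full-sib group, fixed effects constant within vials, which the MCN
  design guarantees — **A** is compound-symmetric within vials and
  block-constant across them, so the likelihood factorizes exactly into
  (i) within-vial contrasts, iid $t$-vectors with covariance
  $s\,G + R$ ($s$ = within-family Mendelian coefficient, e.g. $0.5$
  for outbred and $1.25 - 0.75 = 0.5$ for sib-mated full sibs),
  summarized by their scatter matrices, and (ii) a dense system over
  scaled vial means.  The collapse is verified against the dense
  likelihood in the test suite (agreement to $10^{-14}$) and reduces a
  3000-record fit from minutes to seconds.  Data that do not satisfy
  the structure silently fall back to the dense path.
* **Reduced-rank fits.**  `fit_reduced_rank()` parameterizes
  $G = \Lambda\Lambda'$ with $\Lambda$ lower-triangular $t \times r$
  ($tr - r(r-1)/2$ parameters) for factor-analytic rank testing;
  `rank_lrt()` compares nested ranks with
  $\chi^2 = 2\,\Delta\log L$ (clipped at zero) on the difference in
  parameter counts — 1 degree of freedom for rank $t$ versus $t - 1$.

## Comparing the two G matrices

`sample_mvn()` draws parameter vectors from
$\mathcal{N}(\hat\theta, \mathrm{AI}^{-1})$ — REML-MVN sampling on the
G-scale, deliberately unconstrained, so sampled matrices may be
non-positive-definite.  All downstream uncertainty statements are
equal-tail percentile intervals over these draws (default 95%; 90% is
conventional for eigenvalue displays):

* `variance_ratio_ci()` pairs the two sample streams by index and
  computes $V_{AO}/V_{AI}$ per trait, for the trace, or along any unit
  trait combination.  Values above 1 mean deflation under inbreeding
  beyond the additive expectation.  Pairs with non-positive denominator
  samples are dropped with a reported count (the sampling distribution
  is unconstrained; the source publications are silent on this, so the
  count is surfaced rather than hidden).  Both the ratio of point
  estimates and the median of paired ratios are reported, because the
  two conventions differ and published summaries have used the median.
* `eigen_with_ci()` projects point-estimate eigenvectors through the
  matrix samples ($p_{ij} = e_i' S_j e_i$); eigenvector sign never
  matters since every reported quantity is a quadratic form or an
  absolute dot product.
* `dot_products()` measures orientation agreement of paired
  eigenvectors.
* `eigentensor()` analyses the difference matrix $C = G_O - G_I$:
  eigenvalues ordered by signed value, the most positive ($c_1$,
  deflation) and most negative ($c_t$, inflation) bracketing the
  departure; CIs come from projecting the eigenvectors of the point
  estimate of $C$ through the paired sample differences.
* `inbreeding_depression()` estimates directional dominance per sire
  family as $ID = 1 - \bar z_I/\bar z_O$ (in percent), with the inbred
  mean linearly extrapolated to full inbreeding:
  $\bar z_I = \bar z_O + (\bar z_{obs} - \bar z_O)/F$.  Because "the
  95% CI of the per-sire estimates" can mean either the percentile
  spread of the family distribution or a CI of the mean, both are
  computed and labelled (`dist_lower/dist_upper` vs
  `mean_lower/mean_upper`).

## What the synthetic data emulate

`simulate_mcn_pedigree()` builds founder couples, then per focal-cross
round gives every couple one focal son, one continuing daughter and one
sister; sons are paired to non-sib daughters by a random cyclic
derangement (no brother–sister outbred matings by construction — a
cyclic derangement is drawn instead of rejection-sampling a general
one, a negligible restriction that guarantees termination), and each
sire's outbred and inbred crosses contribute up to five measured sons
sharing one vial per arm.  `gene_drop()` realizes genotypes by fair
Mendelian transmission from Hardy–Weinberg founders;
`simulate_phenotypes()` maps genotypes $(-a, d, +a)$ through per-locus
pleiotropic loading vectors and adds vial, observer/generation and
residual effects.  `random_locus_set(symmetric_d = TRUE)` pairs loci
with $+d$ and $-d$ so $E[d] = 0$ holds by construction while
$d^2 > 0$ at every locus.

Default parameter choices, used by the acceptance simulations and
chosen once:

* **100 pairs × 3 focal-cross rounds** (300 sire families, 5 + 5 sons
  each, 3000 measured wings).  One round is *not* enough: with a single
  measured generation each sire family is exactly one vial per arm, and
  $G$ is then confounded with the vial variance; identification flows
  through cross-generation pedigree links (uncle–nephew 0.25,
  grandparental chains), exactly as in the real multigeneration
  experiment.  This is a deliberately scaled-down analogue of the
  original ~3500-sire, 10-generation data set, not a reproduction.
* **200 additive loci, $q = 0.5$, $a = 1$, standard-normal loadings**,
  giving $V_A \approx 100$ per trait; **vial variance 15** and
  **residual 120**, i.e. heritability $\approx 0.4$ and a vial share of
  ~6% — realistic for insect wing traits, and far enough from the
  parameter-space boundary that curvature-based intervals behave.
* The rare-recessive power scenario uses **600 loci at $q = 0.05$,
  $|d| = a$**, matching the additive world's $V_A$ scale; the single-locus
  variance decomposition above predicts an outbred/inbred
  total-variance ratio of about 1.40 there, and the simulated fits recover ≈1.38.

What a green test does *not* establish: the generator has no linkage,
mutation, selection, maternal effects, or environmental trends beyond
the stated observer/generation shifts; vials are perfectly balanced;
measurement error beyond the residual term is absent; and the inbred
arm's sib covariances contain dominance-variance components that the
animal model (by design, following the source analysis) does not model
separately — the comparison detects their net effect on estimated
additive (co)variance, which is the point of the design, but simulated
ratios under strong dominance need not match the single-locus formula
exactly.

## Wing morphometrics

`procrustes_align()` implements generalized Procrustes alignment
(translation to a common centroid, scaling to unit centroid size,
proper rotations only — wings come from one body side, so reflections
are disallowed) iterated until the mean shape stabilizes
(RMS change $< 10^{-10}$, max 100 rounds; degenerate sets raise a
non-convergence error).  Centroid size is recorded before scaling;
inter-landmark distances are computed on the unit-CS aligned
coordinates, which realizes "distances in units of CS" — the
alternative reading (raw distance divided by specimen CS) differs only
by the rotation step and is not separately implemented.
`scale_traits()` applies the ×1000 (ILD) and ×200 (CS) constants used
to aid REML convergence, recording them for exact inversion.

Outlier filtering follows the published recipe literally: observations
are centred within observer × generation strata per trait, squared
Mahalanobis distances are computed against the pooled covariance of the
centred data (pooled globally — whether the original covariance was
pooled or stratified is not stated; global pooling is the stable choice
at modest stratum sizes), and records beyond the $\chi^2$ critical
value ($\alpha = 0.001$, d.f. = number of traits) are removed, once,
with no re-iteration.  The paired-sire filter then keeps a record only
if its sire has measured sons in both arms, and runs *after* the
outlier filter, matching the narrative order of the original
processing (the order changes retained counts).

## Boundary and degenerate inputs

* Allele frequencies for simulated loci must lie strictly inside
  $(0, 1)$; the theory functions accept the closed interval but the
  homozygote-enrichment *ratio* is refused at $q = 0$.
* The ratio surface reports `NaN` with a `boundary` flag at
  $q \in \{0, 1\}$ (both variances vanish; the limit is direction-
  dependent, and a silent 0/0 would be worse than an explicit flag).
* Unknown parents are legal only as founders; parents referenced but
  absent from the records are promoted to founders with a warning
  naming them; cycles and duplicate ids are hard errors naming the
  individuals.
* In `variance_ratio_ci()` a zero or negative sampled denominator
  cannot produce a meaningful ratio draw and is dropped with a count.
* `sample_mvn()` refuses a singular AI matrix (typically a fit stuck on
  a boundary) rather than silently regularizing it.

## Reproducibility

Every stochastic function takes an explicit seed; `run_pipeline()`
derives all stage seeds from the single master seed in its config and
serializes the config (YAML) plus a manifest (seed, config hash,
record counts, convergence flags) into each output directory.  Re-
running a config byte-identically reproduces all reports; this is
enforced in the test suite.  Test-suite REML-MVN intervals use 2000
draws per fit (the acceptance script uses the conventional 10000);
the draw count affects only the Monte-Carlo error of interval
endpoints.

## Known limitations

* The dense fallback path scales as $O((nt)^3)$ per iteration and is
  practical to a few thousand records; the exact collapse handles the
  MCN design at experimental scale, but unbalanced real-world data
  with fragmented vial structure would need a sparse mixed-model-
  equations backend, which is out of scope.
* Dominance variance is deliberately not modelled as a random term —
  the design estimates the *effect of dominance on additive*
  (co)variance, not $V_D$ itself.
* Missing trait values within a record are not supported; the wing
  pipeline produces complete vectors.
* Multi-generation recursion of $F$ is out of scope: the closed forms
  hold for one generation of inbreeding, which is what the paired
  design produces.
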