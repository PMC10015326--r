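#' Build a run configuration
#'
#' Collects every knob of an end-to-end run (simulate -> traits ->
#' filter -> paired fits -> comparison) with the design defaults: an
#' MCN population with paired outbred / full-sib cross arms, five
#' measured sons per arm, additive-only loci unless dominance is
#' requested, the Mahalanobis and paired-sire filters, unstructured
#' vial and residual covariances, and 10000 REML-MVN samples.
#'
#' @param n_pairs,n_generations,offspring_per_arm,n_traits MCN design
#'   (see [design_params()]).
#' @param n_loci,q,a,d,symmetric_d Genetic architecture (see
#'   [random_locus_set()]).
#' @param vial_var,residual_var Scalar variances used to build
#'   diagonal vial / residual covariance matrices.
#' @param trait_means Baseline trait means (default 500, a size-like
#'   scale so proportional statistics are well behaved).
#' @param vial_diagonal Fit per-trait vial variances without
#'   covariances (the literal reading of the vial term; default
#'   `TRUE`).
#' @param outlier_fraction,outlier_magnitude Contamination injected
#'   before filtering (0 disables).
#' @param alpha Mahalanobis filter tail probability.
#' @param n_samples REML-MVN sample count.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_pairs = 100, n_generations = 3,
                       offspring_per_arm = 5, n_traits = 2,
                       n_loci = 200, q = 0.5, a = 1, d = 0,
                       symmetric_d = TRUE, vial_var = 15,
                       residual_var = 120, trait_means = 500,
                       vial_diagonal = TRUE,
                       outlier_fraction = 0,
                       outlier_magnitude = 10, alpha = 0.001,
                       n_samples = 10000, seed = 1L) {
  if (seed >= 2^31 - 10) stop("seed must be below 2^31 - 10")
  cfg <- list(n_pairs = n_pairs, n_generations = n_generations,
              offspring_per_arm = offspring_per_arm,
              n_traits = n_traits, n_loci = n_loci, q = q, a = a,
              d = d, symmetric_d = symmetric_d, vial_var = vial_var,
              residual_var = residual_var, trait_means = trait_means,
              vial_diagonal = isTRUE(vial_diagonal),
              outlier_fraction = outlier_fraction,
              outlier_magnitude = outlier_magnitude, alpha = alpha,
              n_samples = n_samples, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage_seed <- function(cfg, offset) cfg$seed + offset

#' Run the full paired-pedigree pipeline
#'
#' Stages, in order: simulate the MCN pedigree, drop genes, simulate
#' phenotypes (optionally contaminated), filter (Mahalanobis then
#' paired-sire), build the full-pedigree relationship matrix once, fit
#' the multivariate animal model separately to the outbred and inbred
#' arms (disjoint record subsets, shared A), and compare the two G
#' estimates (variance ratios, eigenanalysis, dot products,
#' eigentensor, inbreeding depression).  When `outdir` is given, all
#' reports are serialized (JSON/CSV) together with the verbatim config
#' and a manifest naming the seed and config hash; a rerun with the
#' same config is byte-identical.
#'
#' @param cfg A [run_config()].
#' @param outdir Optional output directory (created if needed).
#' @return Invisibly, a list with all intermediate and final objects:
#'   `pedigree`, `phenotypes`, `filtered`, `A`, `fit_O`, `fit_I`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  params <- design_params(cfg$n_pairs, cfg$n_generations,
                          cfg$offspring_per_arm, cfg$n_traits,
                          seed = stage_seed(cfg, 1L))
  ped <- stage("simulate", simulate_mcn_pedigree(params))
  loci <- random_locus_set(cfg$n_loci, cfg$n_traits, q = cfg$q,
                           a = cfg$a, d = cfg$d,
                           symmetric_d = cfg$symmetric_d,
                           seed = stage_seed(cfg, 2L))
  geno <- stage("gene_drop", gene_drop(ped, loci,
                                       seed = stage_seed(cfg, 3L)))
  traits <- colnames(loci$loadings)
  phen <- stage("phenotypes", simulate_phenotypes(
    ped, geno, loci,
    vial_cov = diag(cfg$vial_var, cfg$n_traits),
    residual_cov = diag(cfg$residual_var, cfg$n_traits),
    trait_means = cfg$trait_means,
    seed = stage_seed(cfg, 4L)))
  if (cfg$outlier_fraction > 0)
    phen <- stage("outliers", inject_outliers(
      phen, traits, cfg$outlier_fraction, cfg$outlier_magnitude,
      seed = stage_seed(cfg, 5L)))
  mh <- stage("mahalanobis", mahalanobis_filter(phen, traits,
                                                alpha = cfg$alpha))
  ps <- stage("paired_sire", paired_sire_filter(mh$retained))
  filtered <- ps$retained
  A <- stage("relationship", build_A(ped))
  spec_O <- model_spec(traits, arm = "outbred",
                       vial_diagonal = cfg$vial_diagonal)
  spec_I <- model_spec(traits, arm = "inbred",
                       vial_diagonal = cfg$vial_diagonal)
  fit_O <- stage("fit_outbred", fit_reml(filtered, A, spec_O))
  fit_I <- stage("fit_inbred", fit_reml(filtered, A, spec_I))
  smp_O <- stage("mvn_O", sample_mvn(fit_O, cfg$n_samples,
                                     seed = stage_seed(cfg, 6L)))
  smp_I <- stage("mvn_I", sample_mvn(fit_I, cfg$n_samples,
                                     seed = stage_seed(cfg, 7L)))
  comparison <- stage("compare", list(
    trace_ratio = variance_ratio_ci(fit_O$G, fit_I$G, smp_O, smp_I,
                                    which = "trace"),
    trait_ratios = variance_ratio_ci(fit_O$G, fit_I$G, smp_O, smp_I,
                                     which = "per-trait"),
    eigen_O = eigen_with_ci(fit_O$G, smp_O),
    eigen_I = eigen_with_ci(fit_I$G, smp_I),
    dot_products = dot_products(fit_O$G, fit_I$G),
    tensor = eigentensor(fit_O$G, fit_I$G, smp_O, smp_I),
    depression = inbreeding_depression(filtered, traits)))
  manifest <- list(seed = cfg$seed, package = "pairedG",
                   version = as.character(utils::packageVersion("pairedG")),
                   n_records = nrow(filtered),
                   n_removed_outliers = nrow(mh$removed),
                   n_removed_unpaired = nrow(ps$removed),
                   converged = c(outbred = fit_O$converged,
                                 inbred = fit_I$converged))
  result <- list(pedigree = ped, phenotypes = phen,
                 filtered = filtered, A = A, fit_O = fit_O,
                 fit_I = fit_I, samples_O = smp_O, samples_I = smp_I,
                 comparison = comparison, manifest = manifest)
  if (!is.null(outdir)) write_run_outputs(result, cfg, outdir)
  if (!fit_O$converged || !fit_I$converged)
    warning("one or both REML fits did not converge")
  invisible(result)
}

write_run_outputs <- function(result, cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  result$manifest$config_hash <-
    unname(tools::md5sum(cfg_path))
  write_pedigree_csv(result$pedigree, file.path(outdir, "pedigree.csv"))
  utils::write.csv(result$phenotypes,
                   file.path(outdir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$filtered, file.path(outdir, "filtered.csv"),
                   row.names = FALSE)
  for (arm in c("O", "I")) {
    fit <- result[[paste0("fit_", arm)]]
    jsonlite::write_json(fit_report(fit),
                         file.path(outdir, paste0("fit_", arm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(fit$G),
                     file.path(outdir, paste0("G_", arm, ".csv")))
  }
  cmp <- result$comparison
  jsonlite::write_json(list(
    trace_ratio = cmp$trace_ratio, trait_ratios = cmp$trait_ratios,
    eigen_O = cmp$eigen_O$values, eigen_I = cmp$eigen_I$values,
    dot_products = cmp$dot_products, tensor_values = cmp$tensor$values,
    depression_summary = cmp$depression$summary),
    file.path(outdir, "comparison.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

fit_report <- function(fit) {
  list(traits = fit$traits, loglik = fit$loglik,
       converged = fit$converged, iterations = fit$iterations,
       G = fit$G, vial = fit$vial, R = fit$R, AI = fit$AI,
       params = fit$params, manifest = fit$manifest,
       n_records = fit$n_records)
}
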