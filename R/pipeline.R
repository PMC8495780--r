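#' Fit the phylogenetic hierarchical model end to end
#'
#' Convenience wrapper chaining the whole pipeline: trait assembly and log
#' transforms, between/within-species size decomposition, standardization,
#' relatedness matrix from the tree (or averaged over a set of trees),
#' design construction, and posterior sampling.
#'
#' @param specimens Specimen table ([as_specimens()]).
#' @param metadata Species metadata ([as_species_metadata()]).
#' @param tree A `phylo` tree, or a list of trees to average.
#' @param response `"length"`, `"diameter"`, or `"surface"`.
#' @param fixed_terms,random,dev_slope Model structure, see [build_design()].
#' @param priors [gut_priors()] object.
#' @param chains,iter,warmup,seed,gaussian,fix Passed to
#'   [sample_posterior()].
#' @param compute_diagnostics Passed to [sample_posterior()].
#' @return `gut_draws` object.
#' @export
fit_gut_model <- function(specimens, metadata, tree,
                          response = c("length", "diameter", "surface"),
                          fixed_terms = FIXED_TERMS,
                          random = c("phylo", "species", "slope"),
                          dev_slope = TRUE,
                          priors = gut_priors(),
                          chains = 4L, iter = 8000L, warmup = 2000L,
                          seed = 1L, gaussian = FALSE, fix = list(),
                          compute_diagnostics = TRUE) {
  response <- match.arg(response)
  tab <- assemble_model_table(specimens, metadata, response)
  tab <- decompose_size(tab)
  std <- standardize(tab)
  species <- sort(unique(tab$species))
  A <- if (inherits(tree, "phylo")) {
    to_correlation(shared_path_matrix(tree, species))
  } else {
    average_correlation(tree, species)
  }
  data <- build_design(std, A, fixed_terms = fixed_terms, random = random,
                       dev_slope = dev_slope)
  sample_posterior(data, priors = priors, chains = chains, iter = iter,
                   warmup = warmup, seed = seed, gaussian = gaussian,
                   fix = fix, compute_diagnostics = compute_diagnostics)
}

#' Summarize a fit into the standard output tables
#'
#' @param fit `gut_draws` object.
#' @param specimens,metadata Inputs used for the fit (needed for the
#'   scaling report).
#' @param sl_pred Standard length (cm) for species predictions.
#' @param h2_denominator Passed to [heritability()].
#' @param predict_mode Passed to [predict_species()].
#' @param force Proceed even if the convergence flag failed.
#' @return List of data frames / summaries: `fixed_effects`, `h2`, `r2`,
#'   `predictions`, `scaling`, `diagnostics`.
#' @export
summarize_fit <- function(fit, specimens, metadata, sl_pred = 15,
                          h2_denominator = "total", predict_mode = "inter",
                          force = FALSE) {
  h2 <- heritability(fit, denominator = h2_denominator, force = force)
  r2 <- bayes_r2(fit, force = force)
  list(
    fixed_effects = fixed_effect_table(fit, force = force),
    h2 = data.frame(mean = h2$mean, q2.5 = h2$ci95[1], q97.5 = h2$ci95[2]),
    r2 = data.frame(mean = r2$mean, q2.5 = r2$ci95[1], q97.5 = r2$ci95[2]),
    predictions = predict_species(fit, SL = sl_pred, mode = predict_mode,
                                  force = force),
    scaling = if ("slope" %in% fit$data$random) {
      scaling_report(fit, specimens, metadata, force = force)
    },
    diagnostics = fit$diagnostics
  )
}
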