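#' Ground-truth parameters for synthetic datasets
#'
#' Defaults mirror the magnitudes of the length model reported for real
#' reef-fish data (interspecific size slope near 1, a clearly negative
#' trophic-level slope, strong phylogenetic signal with heritability around
#' 0.9, and mildly heavy-tailed residuals), so that recovery experiments
#' exercise the realistic regime.
#'
#' @param gamma00 Intercept (log-trait at average covariates).
#' @param beta_sl Interspecific (species-mean) log-size slope.
#' @param beta_tl Trophic-level slope (standardized scale).
#' @param gamma30 Mean within-species size slope (log-log exponent).
#' @param beta_el Log-elongation slope (standardized scale).
#' @param beta_st Stomach-presence effect.
#' @param beta_du Durophagy effect.
#' @param beta_stdu Stomach-by-durophagy interaction.
#' @param sigma_phy,sigma_spp,sigma_slope Random-effect sds (phylogenetic
#'   intercept, non-phylogenetic intercept, within-species slope).
#' @param sigma_resid Student-t residual scale.
#' @param nu Student-t degrees of freedom (> 2 so the residual variance is
#'   finite).
#' @return List of class `truth_params`.
#' @export
truth_params <- function(gamma00 = 3.4, beta_sl = 0.97, beta_tl = -0.38,
                         gamma30 = 1.0, beta_el = -0.4, beta_st = -0.15,
                         beta_du = -0.1, beta_stdu = 0.05,
                         sigma_phy = sqrt(0.30), sigma_spp = sqrt(0.02),
                         sigma_slope = 0.15, sigma_resid = 0.1, nu = 10) {
  stopifnot(sigma_phy >= 0, sigma_spp >= 0, sigma_slope >= 0,
            sigma_resid >= 0, nu > 2)
  structure(as.list(environment()), class = "truth_params")
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Pure-birth topology with exponential waiting times, rescaled so every
#' tip is at depth 1. Stands in for a dated species tree.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed (optional; omit to use the current RNG stream).
#' @return `phylo` tree with tip labels `sp_001`, `sp_002`, ...
#' @export
simulate_yule_tree <- function(n_species, seed = NULL) {
  stopifnot(n_species >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp_%03d", seq_len(n_species))
  tree
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Draws tip values from the multivariate normal with covariance
#' `sigma2 * shared_path_matrix(tree)`, via the Cholesky factor of the
#' shared-path matrix. Equivalent in distribution to simulating the random
#' walk edge by edge.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit depth), >= 0.
#' @param seed Integer seed (optional).
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2 = 1, seed = NULL) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  M <- shared_path_matrix(tree)
  if (sigma2 == 0) {
    return(stats::setNames(rep(0, nrow(M)), rownames(M)))
  }
  R <- chol_relatedness(M)
  z <- stats::rnorm(nrow(M))
  stats::setNames(sqrt(sigma2) * drop(crossprod(R, z)), rownames(M))
}

#' Simulate a full dataset under the generative model
#'
#' Generates a Yule tree, species covariates (trophic level uniform on
#' [2, 4.5], log-elongation normal, stomach/durophagy Bernoulli), specimen
#' body sizes (lognormal around a species-specific mean), and the response
#' built exactly per the hierarchical model: phylogenetic intercept
#' deviations from Brownian motion on the tree, iid species intercept and
#' slope deviations, and Student-t residuals. Covariates are standardized
#' internally the same way the fitting path standardizes them, so the truth
#' coefficients live on the same scale the fit reports.
#'
#' The simulated log trait is taken as log intestinal length; a mean
#' diameter is generated from a simple size-scaling rule so that the
#' specimen table carries a full set of measurements (10 diameter readings
#' whose mean is the species value exactly), and surface area follows
#' deterministically.
#'
#' @param params `truth_params` object.
#' @param n_species Number of species (default 142, the scale of the real
#'   study).
#' @param n_per_species Either a single count or a length-2 range from
#'   which per-species sample sizes are drawn uniformly (default `c(3, 30)`).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param gaussian If `TRUE`, residuals are normal instead of Student-t.
#' @param tl_range,ln_el_sd,p_stomach,p_durophagy Covariate generators.
#' @param sl_meanlog,sl_sdlog_between,sl_sdlog_within Specimen size
#'   generator: species mean sizes are lognormal(meanlog, sdlog_between);
#'   individuals are lognormal around their species mean with
#'   `sl_sdlog_within`.
#' @return List of class `gut_synthetic`: `tree`, `specimens`, `metadata`,
#'   `params`, `effects` (realized `u_phy`, `u_spp`, `u_slope` per
#'   species), `seed`.
#' @export
simulate_dataset <- function(params = truth_params(),
                             n_species = 142L,
                             n_per_species = c(3L, 30L),
                             seed = 1L,
                             gaussian = FALSE,
                             tl_range = c(2.0, 4.5),
                             ln_el_sd = 0.35,
                             p_stomach = 0.8,
                             p_durophagy = 0.25,
                             sl_meanlog = log(15),
                             sl_sdlog_between = 0.5,
                             sl_sdlog_within = 0.15) {
  stopifnot(inherits(params, "truth_params"), n_species >= 2)
  set.seed(as.integer(seed))

  tree <- simulate_yule_tree(n_species)
  species <- tree$tip.label

  # species-level covariates
  tl <- stats::runif(n_species, tl_range[1], tl_range[2])
  ln_el <- stats::rnorm(n_species, log(2.5), ln_el_sd)
  stomach <- stats::rbinom(n_species, 1, p_stomach)
  durophagy <- stats::rbinom(n_species, 1, p_durophagy)

  # realized species effects
  u_phy <- if (params$sigma_phy > 0) {
    simulate_bm(tree, params$sigma_phy^2)[species]
  } else stats::setNames(rep(0, n_species), species)
  u_spp <- stats::setNames(stats::rnorm(n_species, 0, params$sigma_spp), species)
  u_slope <- stats::setNames(stats::rnorm(n_species, 0, params$sigma_slope), species)

  # specimens: sizes per species
  if (length(n_per_species) == 1L) n_per_species <- rep(n_per_species, 2L)
  n_range <- seq.int(n_per_species[1], n_per_species[2])
  n_j <- if (length(n_range) == 1L) {
    rep(n_range, n_species)
  } else {
    sample(n_range, n_species, replace = TRUE)
  }
  sl_bar_log <- stats::rnorm(n_species, sl_meanlog, sl_sdlog_between)
  sp_col <- rep(species, n_j)
  jdx <- rep(seq_len(n_species), n_j)
  n_obs <- length(sp_col)
  sl <- exp(stats::rnorm(n_obs, sl_bar_log[jdx], sl_sdlog_within))

  # standardized covariates, constructed the same way the fitting path does
  ln_sl <- log(sl)
  ln_sl_bar_obs <- as.numeric(tapply(ln_sl, sp_col, mean)[sp_col])
  c_dev <- ln_sl - ln_sl_bar_obs
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  z_lnslbar <- zs(ln_sl_bar_obs)
  z_tl <- zs(tl[jdx])
  z_lnel <- zs(ln_el[jdx])

  lin <- params$gamma00 +
    params$beta_sl * z_lnslbar +
    params$beta_tl * z_tl +
    (params$gamma30 + u_slope[jdx]) * c_dev +
    params$beta_el * z_lnel +
    params$beta_st * stomach[jdx] +
    params$beta_du * durophagy[jdx] +
    params$beta_stdu * stomach[jdx] * durophagy[jdx] +
    u_phy[jdx] + u_spp[jdx]

  resid <- if (params$sigma_resid == 0) {
    rep(0, n_obs)
  } else if (gaussian) {
    stats::rnorm(n_obs, 0, params$sigma_resid)
  } else {
    params$sigma_resid * stats::rt(n_obs, df = params$nu)
  }
  ln_il <- lin + resid
  il <- exp(ln_il)

  # mean diameter from a simple allometric rule (isometric in size with a
  # mild trophic signal), with lognormal scatter
  ln_id <- -3.0 + 1.0 * ln_sl - 0.1 * z_tl + stats::rnorm(n_obs, 0, 0.15)
  id <- exp(ln_id)
  # ten diameter readings rescaled so their arithmetic mean is exactly id
  D <- matrix(id, n_obs, 10) * matrix(exp(stats::rnorm(10L * n_obs, 0, 0.05)),
                                      n_obs, 10)
  D <- D * (id / rowMeans(D))
  colnames(D) <- paste0("d", 1:10, "_cm")

  specimens <- as_specimens(data.frame(
    species = sp_col, sl_cm = sl, il_cm = il, D,
    stringsAsFactors = FALSE, check.names = FALSE
  ))

  # reported maximum body size: above the largest simulated individual so
  # size-range coverage varies realistically across species
  max_obs_sl <- as.numeric(tapply(sl, sp_col, max)[species])
  max_size <- max_obs_sl * stats::runif(n_species, 1.2, 3.0)

  metadata <- as_species_metadata(data.frame(
    species = species, tl = tl, el = exp(ln_el),
    stomach = stomach, durophagy = durophagy,
    max_size_cm = max_size, stringsAsFactors = FALSE
  ))

  structure(list(
    tree = tree,
    specimens = specimens,
    metadata = metadata,
    params = params,
    effects = list(u_phy = u_phy, u_spp = u_spp, u_slope = u_slope),
    seed = as.integer(seed),
    gaussian = gaussian
  ), class = "gut_synthetic")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the pipeline reads (Newick tree, specimen and
#' metadata CSVs) plus a JSON sidecar with the ground-truth parameters,
#' realized species effects, and seed.
#'
#' @param dataset `gut_synthetic` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gut_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tree <- file.path(dir, "tree.nwk")
  f_spec <- file.path(dir, "specimens.csv")
  f_meta <- file.path(dir, "metadata.csv")
  f_truth <- file.path(dir, "truth.json")
  ape::write.tree(dataset$tree, file = f_tree)
  utils::write.csv(dataset$specimens, f_spec, row.names = FALSE)
  utils::write.csv(dataset$metadata, f_meta, row.names = FALSE)
  jsonlite::write_json(list(
    params = unclass(dataset$params),
    effects = lapply(dataset$effects, as.list),
    seed = dataset$seed,
    gaussian = dataset$gaussian
  ), f_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(f_tree, f_spec, f_meta, f_truth))
}
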