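#' Posterior of phylogenetic heritability
#'
#' Per draw, the ratio of the phylogenetic variance component to the total
#' variance. With the default `denominator = "total"` the total is
#' `sigma_phy^2 + sigma_spp^2 + v_resid`, where the Student-t residual
#' variance is `sigma_resid^2 * nu / (nu - 2)`; draws with `nu <= 2`
#' (infinite residual variance) fall back to `sigma_resid^2` with a logged
#' warning. `denominator = "species"` restricts the total to the two
#' species-level components, the strict Pagel's-lambda reading.
#'
#' @param fit `gut_draws` from [sample_posterior()].
#' @param denominator `"total"` (default) or `"species"`.
#' @param force Proceed even if the convergence flag failed.
#' @return List with `draws` (per-draw heritability in [0, 1]), `mean`, and
#'   `ci95`.
#' @export
heritability <- function(fit, denominator = c("total", "species"),
                         force = FALSE) {
  denominator <- match.arg(denominator)
  assert_converged(fit, force)
  m <- as_draws_matrix(fit)
  if (!"sigma_phy" %in% colnames(m)) {
    stop("fit has no phylogenetic component (random term 'phylo' was disabled)")
  }
  v_phy <- m[, "sigma_phy"]^2
  v_spp <- if ("sigma_spp" %in% colnames(m)) m[, "sigma_spp"]^2 else 0
  h2 <- if (denominator == "species") {
    v_phy / (v_phy + v_spp)
  } else {
    v_res <- resid_variance_draws(m, fit$settings$gaussian)
    v_phy / (v_phy + v_spp + v_res)
  }
  list(draws = h2, mean = mean(h2), ci95 = ci_quantile(h2, 0.95),
       denominator = denominator)
}

# Per-draw residual variance: t variance where finite, else sigma^2.
resid_variance_draws <- function(m, gaussian) {
  s2 <- m[, "sigma_resid"]^2
  if (gaussian || !"nu" %in% colnames(m)) return(s2)
  nu <- m[, "nu"]
  inf_var <- nu <= 2
  if (any(inf_var)) {
    gs_log("inference",
           "%d draw(s) with nu <= 2: residual variance taken as sigma_resid^2",
           sum(inf_var))
  }
  ifelse(inf_var, s2, s2 * nu / (nu - 2))
}

#' Posterior of Bayesian R-squared
#'
#' Per draw, `Var(mu) / (Var(mu) + v_resid)` where `mu` is the full linear
#' predictor (fixed plus all random effects) evaluated over the fitted
#' observations and `Var` is the sample variance across observations.
#'
#' @inheritParams heritability
#' @return List with `draws`, `mean`, `ci95`.
#' @export
bayes_r2 <- function(fit, force = FALSE) {
  assert_converged(fit, force)
  m <- as_draws_matrix(fit)
  mu <- posterior_linpred(fit, m)        # observations x draws
  var_mu <- apply(mu, 2, stats::var)     # per-draw variance over observations
  v_res <- resid_variance_draws(m, fit$settings$gaussian)
  r2 <- var_mu / (var_mu + v_res)
  list(draws = r2, mean = mean(r2), ci95 = ci_quantile(r2, 0.95))
}

# Linear predictor for every draw (rows = draws) over the fitted data.
# Returns draws x observations... transposed to observations in columns.
posterior_linpred <- function(fit, m = as_draws_matrix(fit)) {
  data <- fit$data
  j <- data$species_index
  fixed <- colnames(data$X)
  mu <- m[, fixed, drop = FALSE] %*% t(data$X)
  if (isTRUE(data$dev_slope)) {
    g3 <- m[, "dev_slope"]
    if ("slope" %in% data$random) {
      u3 <- m[, paste0("u_slope[", data$species, "]"), drop = FALSE]
      slope_draws <- g3 + u3[, j, drop = FALSE]
      mu <- mu + slope_draws * matrix(data$c, nrow(m), length(j), byrow = TRUE)
    } else {
      mu <- mu + outer(g3, data$c)
    }
  }
  if ("phylo" %in% data$random) {
    u <- m[, paste0("u_phy[", data$species, "]"), drop = FALSE]
    mu <- mu + u[, j, drop = FALSE]
  }
  if ("species" %in% data$random) {
    u <- m[, paste0("u_spp[", data$species, "]"), drop = FALSE]
    mu <- mu + u[, j, drop = FALSE]
  }
  t(mu)
}

#' Posterior summary table for the fixed effects
#'
#' Mean, median, and equal-tailed 50% and 95% credible intervals for each
#' fixed-effect coefficient (including the mean within-species size slope).
#'
#' @inheritParams heritability
#' @return Data frame, one row per fixed effect.
#' @export
fixed_effect_table <- function(fit, force = FALSE) {
  assert_converged(fit, force)
  pars <- c(colnames(fit$data$X), if (isTRUE(fit$data$dev_slope)) "dev_slope")
  m <- as_draws_matrix(fit)[, pars, drop = FALSE]
  out <- data.frame(
    param = pars,
    mean = colMeans(m),
    median = apply(m, 2, stats::median),
    q25 = apply(m, 2, function(x) ci_quantile(x, 0.5)[1]),
    q75 = apply(m, 2, function(x) ci_quantile(x, 0.5)[2]),
    q2.5 = apply(m, 2, function(x) ci_quantile(x, 0.95)[1]),
    q97.5 = apply(m, 2, function(x) ci_quantile(x, 0.95)[2]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Predict a species' trait at a standardized body size
#'
#' Evaluates the posterior of the trait (on the original cm / cm^2 scale)
#' for a fitted species as if its mean size were `SL` cm. In the default
#' `mode = "inter"` the species moves along the interspecific size axis:
#' the standardized species-mean size covariate is set to `ln(SL)` mapped
#' through the stored standardization, and the within-species deviation is
#' zero. `mode = "intra"` instead keeps the species' own mean size on the
#' interspecific axis and moves the fish along its own random slope
#' (`c = ln(SL) - mean ln SL`).
#'
#' @param fit `gut_draws` object.
#' @param species Species label(s) present in the fit.
#' @param SL Standard length in cm (default 15).
#' @param mode `"inter"` (default) or `"intra"`.
#' @param force Proceed even if the convergence flag failed.
#' @return Data frame with posterior mean and 95% CI of the predicted
#'   trait per species.
#' @export
predict_species <- function(fit, species = fit$data$species, SL = 15,
                            mode = c("inter", "intra"), force = FALSE) {
  mode <- match.arg(mode)
  assert_converged(fit, force)
  data <- fit$data
  unknown <- setdiff(species, data$species)
  if (length(unknown) > 0L) {
    stop("species not in fit: ", paste(unknown, collapse = ", "))
  }
  m <- as_draws_matrix(fit)
  tab <- data$table
  record <- data$record
  out <- data.frame(species = species, sl_cm = SL, mean = NA_real_,
                    q2.5 = NA_real_, q97.5 = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(species)) {
    sp <- species[i]
    row <- tab[match(sp, tab$species), ]
    x <- stats::setNames(numeric(ncol(data$X)), colnames(data$X))
    x["intercept"] <- 1
    if ("z_tl" %in% names(x)) x["z_tl"] <- row$z_tl
    if ("z_ln_el" %in% names(x)) x["z_ln_el"] <- row$z_ln_el
    if ("stomach" %in% names(x)) x["stomach"] <- row$stomach
    if ("durophagy" %in% names(x)) x["durophagy"] <- row$durophagy
    if ("stomach_durophagy" %in% names(x)) {
      x["stomach_durophagy"] <- row$stomach * row$durophagy
    }
    cdev <- 0
    if (mode == "inter") {
      if ("z_ln_sl_bar" %in% names(x)) {
        x["z_ln_sl_bar"] <- apply_standardization(record, "ln_sl_bar", log(SL))
      }
    } else {
      if ("z_ln_sl_bar" %in% names(x)) x["z_ln_sl_bar"] <- row$z_ln_sl_bar
      cdev <- log(SL) - row$ln_sl_bar
    }
    mu <- drop(m[, colnames(data$X), drop = FALSE] %*% x)
    if (isTRUE(data$dev_slope) && cdev != 0) {
      slope <- m[, "dev_slope"]
      if ("slope" %in% data$random) {
        slope <- slope + m[, paste0("u_slope[", sp, "]")]
      }
      mu <- mu + slope * cdev
    }
    if ("phylo" %in% data$random) mu <- mu + m[, paste0("u_phy[", sp, "]")]
    if ("species" %in% data$random) mu <- mu + m[, paste0("u_spp[", sp, "]")]
    pred <- exp(mu)
    out$mean[i] <- mean(pred)
    out[i, c("q2.5", "q97.5")] <- ci_quantile(pred, 0.95)
  }
  out
}

#' Percent change of a trait over a raw covariate range
#'
#' Converts a standardized log-scale slope back to the raw covariate scale
#' via the stored standardization sd, then expresses the multiplicative
#' change over `delta_raw` units as a percentage. Positive return values
#' are decreases (the usual reporting direction for negative slopes);
#' increases come back negative.
#'
#' @param beta_std Slope on the standardized-covariate, log-response scale.
#' @param sd_covariate Sample sd used in the standardization.
#' @param delta_raw Covariate change on the raw scale.
#' @return Percent decrease of the trait over `delta_raw`.
#' @export
percent_change <- function(beta_std, sd_covariate, delta_raw) {
  stopifnot(sd_covariate > 0)
  100 * (1 - exp((beta_std / sd_covariate) * delta_raw))
}

#' Per-species intraspecific scaling report
#'
#' Extracts each species' posterior of the within-species size slope
#' (`mean slope + species deviation`), summarises it (median, 80% and 95%
#' equal-tailed CIs), applies the reliability filter — at least `min_n`
#' specimens, a size range covering at least `min_coverage` of the species'
#' reported maximum body size, and a 95% CI entirely above zero — and
#' classifies each species' scaling against the isometry slope (1 for
#' length and diameter, 2 for surface area): `negative` if the CI lies
#' entirely below it, `positive` if entirely above, else `isometric`.
#'
#' @param fit `gut_draws` from a model with random slopes.
#' @param specimens Specimen table used in the fit.
#' @param metadata Species metadata (for `max_size_cm`).
#' @param isometry Isometry slope; defaults from the response that was fit
#'   (1 for length/diameter, 2 for surface).
#' @param min_n,min_coverage Reliability thresholds.
#' @param force Proceed even if the convergence flag failed.
#' @return Data frame, one row per fitted species with specimens: slope
#'   summaries, `n_specimens`, `size_coverage`, `reliable`, and allometry
#'   class at the 80% and 95% CI levels.
#' @export
scaling_report <- function(fit, specimens, metadata, isometry = NULL,
                           min_n = 10L, min_coverage = 0.25, force = FALSE) {
  assert_converged(fit, force)
  data <- fit$data
  if (!"slope" %in% data$random) stop("fit has no species-level random slopes")
  isometry <- isometry %||% switch(data$response, surface = 2, 1)
  m <- as_draws_matrix(fit)
  species <- data$species
  no_spec <- setdiff(species, unique(specimens$species))
  if (length(no_spec) > 0L) {
    gs_log("inference", "excluding %d species without specimens", length(no_spec))
    species <- setdiff(species, no_spec)
  }
  g3 <- m[, "dev_slope"]
  rows <- lapply(species, function(sp) {
    b3 <- g3 + m[, paste0("u_slope[", sp, "]")]
    sl <- specimens$sl_cm[specimens$species == sp]
    max_size <- metadata$max_size_cm[match(sp, metadata$species)]
    ci80 <- ci_quantile(b3, 0.80)
    ci95 <- ci_quantile(b3, 0.95)
    cover <- (max(sl) - min(sl)) / max_size
    classify <- function(ci) {
      if (ci[2] < isometry) "negative"
      else if (ci[1] > isometry) "positive"
      else "isometric"
    }
    data.frame(
      species = sp,
      median = stats::median(b3),
      q10 = ci80[1], q90 = ci80[2],
      q2.5 = ci95[1], q97.5 = ci95[2],
      n_specimens = length(sl),
      size_coverage = cover,
      reliable = (length(sl) >= min_n) && (cover >= min_coverage) && (ci95[1] > 0),
      class80 = classify(ci80),
      class95 = classify(ci95),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "isometry") <- isometry
  out
}

#' Refit on a minimum-sample-size subset (sensitivity analysis)
#'
#' Drops species with fewer than `min_n` specimens and re-runs the whole
#' pipeline (trait assembly, standardization, design, sampling) on the
#' subset, mirroring the robustness check of restricting to better-sampled
#' species.
#'
#' @param specimens,metadata,tree Full inputs.
#' @param min_n Minimum specimens per retained species.
#' @param response Trait to fit.
#' @param ... Passed to [fit_gut_model()] (sampler settings etc.).
#' @return `gut_draws` for the subset fit; the retained species are in
#'   `fit$data$species`.
#' @export
sensitivity_refit <- function(specimens, metadata, tree, min_n,
                              response = "length", ...) {
  counts <- table(specimens$species)
  keep <- names(counts)[counts >= min_n]
  if (length(keep) < 3L) {
    stop("subset with min_n = ", min_n, " leaves fewer than 3 species")
  }
  sub <- specimens[specimens$species %in% keep, , drop = FALSE]
  fit_gut_model(sub, metadata[metadata$species %in% keep, , drop = FALSE],
                tree, response = response, ...)
}
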