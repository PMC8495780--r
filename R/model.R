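# Fixed-effect column order used throughout the package. The within-species
# centered size term is kept separate (it carries the random slope).
FIXED_TERMS <- c("intercept", "z_ln_sl_bar", "z_tl", "z_ln_el",
                 "stomach", "durophagy", "stomach_durophagy")

#' Prior specification for the hierarchical model
#'
#' Weakly informative defaults: Normal(0, 10) on the intercept, Normal(0, 5)
#' on fixed-effect slopes (including the mean within-species size slope),
#' half-Student-t(3, 0, 2.5) on all standard deviations, and a Gamma(2, 0.1)
#' prior truncated to nu > 1 on the Student-t degrees of freedom. Normal
#' scales are standard deviations.
#'
#' @param intercept_sd,slope_sd Normal prior sd for intercept / slopes.
#' @param sd_df,sd_scale Half-Student-t parameters for all sd parameters.
#' @param nu_shape,nu_rate Gamma parameters for the degrees of freedom.
#' @return List of class `gut_priors`.
#' @export
gut_priors <- function(intercept_sd = 10, slope_sd = 5,
                       sd_df = 3, sd_scale = 2.5,
                       nu_shape = 2, nu_rate = 0.1) {
  stopifnot(intercept_sd > 0, slope_sd > 0, sd_df > 0, sd_scale > 0,
            nu_shape > 0, nu_rate > 0)
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 sd_df = sd_df, sd_scale = sd_scale,
                 nu_shape = nu_shape, nu_rate = nu_rate),
            class = "gut_priors")
}

# log density of the half-Student-t prior on a scale parameter (x > 0).
log_half_t <- function(x, df, scale) {
  ifelse(x < 0, -Inf,
         log(2) + stats::dt(x / scale, df = df, log = TRUE) - log(scale))
}

# log density of the truncated Gamma prior on nu (nu > 1), unnormalized by
# the truncation constant (constant w.r.t. nu, irrelevant for MCMC).
log_nu_prior <- function(nu, shape, rate) {
  ifelse(nu <= 1, -Inf, stats::dgamma(nu, shape = shape, rate = rate, log = TRUE))
}

#' Assemble model data for fitting
#'
#' Combines the standardized modeling table with the relatedness matrix
#' into the fixed-effect design, the within-species centered size column,
#' and the species index. Fixed-effect column order is `intercept`,
#' `z_ln_sl_bar`, `z_tl`, `z_ln_el`, `stomach`, `durophagy`,
#' `stomach_durophagy`; the centered-size slope column is stored separately
#' as `c`.
#'
#' @param std List from [standardize()] (table + record), where the table
#'   has passed through [decompose_size()].
#' @param A Relatedness matrix covering all species in the table.
#' @param fixed_terms Subset of fixed-effect terms to include (the
#'   intercept is always kept). Useful for reduced models in tests.
#' @param random Character vector among `"phylo"`, `"species"`, `"slope"`
#'   selecting which random terms the model carries. May be empty
#'   (`character(0)`) for a fixed-effects-only model.
#' @param dev_slope Include the mean within-species size slope (the
#'   centered-size fixed term). Forced `TRUE` when `"slope"` is among the
#'   random terms, since the random slope is a deviation from it.
#' @param jitter Diagonal jitter used if the relatedness matrix fails to
#'   factorize.
#' @return List of class `gut_modeldata` with elements `y`, `X`, `c`,
#'   `species`, `species_index`, `A`, `A_chol`, `record`, `table`.
#' @export
build_design <- function(std, A,
                         fixed_terms = FIXED_TERMS,
                         random = c("phylo", "species", "slope"),
                         dev_slope = TRUE,
                         jitter = 1e-8) {
  table <- std$table
  record <- std$record
  stopifnot(all(c("ln_y", "z_ln_sl_bar", "z_tl", "z_ln_el", "stomach",
                  "durophagy", "ln_sl_dev") %in% names(table)))
  if (length(random) > 0L) {
    random <- match.arg(random, several.ok = TRUE)
  }
  if ("slope" %in% random) dev_slope <- TRUE
  species <- sort(unique(table$species))
  missing <- setdiff(species, rownames(A))
  if (length(missing) > 0L) {
    stop("species absent from relatedness matrix: ",
         paste(missing, collapse = ", "))
  }
  A <- unclass(A)[species, species, drop = FALSE]

  Xfull <- cbind(
    intercept          = 1,
    z_ln_sl_bar        = table$z_ln_sl_bar,
    z_tl               = table$z_tl,
    z_ln_el            = table$z_ln_el,
    stomach            = as.numeric(table$stomach),
    durophagy          = as.numeric(table$durophagy),
    stomach_durophagy  = as.numeric(table$stomach) * as.numeric(table$durophagy)
  )
  fixed_terms <- union("intercept", intersect(FIXED_TERMS, fixed_terms))
  X <- Xfull[, FIXED_TERMS[FIXED_TERMS %in% fixed_terms], drop = FALSE]

  structure(list(
    y = table$ln_y,
    X = X,
    c = table$ln_sl_dev,
    species = species,
    species_index = match(table$species, species),
    A = A,
    A_chol = chol_relatedness(A, jitter = jitter),
    random = random,
    dev_slope = dev_slope,
    record = record,
    table = table,
    response = attr(table, "response") %||% "length"
  ), class = "gut_modeldata")
}

# Linear predictor for a full parameter list on given model data.
linear_predictor <- function(params, data) {
  j <- data$species_index
  mu <- drop(data$X %*% params$beta)
  if (isTRUE(data$dev_slope)) {
    g3 <- params$gamma30 %||% 0
    if ("slope" %in% data$random) {
      mu <- mu + (g3 + params$u_slope[j]) * data$c
    } else {
      mu <- mu + g3 * data$c
    }
  }
  if ("phylo" %in% data$random) mu <- mu + params$u_phy[j]
  if ("species" %in% data$random) mu <- mu + params$u_spp[j]
  mu
}

#' Observation-level log likelihood
#'
#' Student-t log likelihood of the data given a full set of parameters
#' (fixed effects, realized species effects, residual scale, and degrees of
#' freedom). With `gaussian = TRUE` the t is replaced by a normal, which is
#' the closed-form reference mode used by oracle tests.
#'
#' @param params List with `beta` (named fixed effects in design column
#'   order), `gamma30`, `u_phy`, `u_spp`, `u_slope` (length-S vectors),
#'   `sigma_resid`, `nu`.
#' @param data `gut_modeldata` from [build_design()].
#' @param gaussian Use a normal residual density instead of Student-t.
#' @return Scalar log likelihood (`-Inf` outside the support).
#' @export
log_likelihood <- function(params, data, gaussian = FALSE) {
  if (!is.finite(params$sigma_resid) || params$sigma_resid <= 0) return(-Inf)
  e <- data$y - linear_predictor(params, data)
  if (gaussian) {
    sum(stats::dnorm(e, sd = params$sigma_resid, log = TRUE))
  } else {
    if (is.null(params$nu) || !is.finite(params$nu) || params$nu <= 1) return(-Inf)
    sum(stats::dt(e / params$sigma_resid, df = params$nu, log = TRUE) -
          log(params$sigma_resid))
  }
}

#' Log prior, including the hierarchical terms for species effects
#'
#' The phylogenetic intercept deviations are jointly multivariate normal
#' with covariance `sigma_phy^2 * A` (evaluated through the Cholesky factor
#' of `A` computed once in [build_design()]); the non-phylogenetic
#' intercept and slope deviations are iid normal. Fixed effects, standard
#' deviations, and the degrees of freedom get the priors in [gut_priors()].
#'
#' @inheritParams log_likelihood
#' @param priors A `gut_priors` object.
#' @param gaussian If `TRUE`, the degrees-of-freedom prior term is omitted
#'   (no t residuals in the model).
#' @return Scalar log prior density (`-Inf` outside the support).
#' @export
log_prior <- function(params, data, priors = gut_priors(), gaussian = FALSE) {
  lp <- 0
  beta <- params$beta
  sds <- ifelse(names(beta) == "intercept", priors$intercept_sd, priors$slope_sd)
  lp <- lp + sum(stats::dnorm(beta, 0, sds, log = TRUE))
  if (!is.null(params$gamma30)) {
    lp <- lp + stats::dnorm(params$gamma30, 0, priors$slope_sd, log = TRUE)
  }
  for (s in c("sigma_phy", "sigma_spp", "sigma_slope", "sigma_resid")) {
    if (!is.null(params[[s]])) {
      lp <- lp + log_half_t(params[[s]], priors$sd_df, priors$sd_scale)
    }
  }
  if (!gaussian && !is.null(params$nu)) {
    lp <- lp + log_nu_prior(params$nu, priors$nu_shape, priors$nu_rate)
  }
  if (!is.finite(lp)) return(-Inf)

  S <- length(data$species)
  if ("phylo" %in% data$random) {
    if (params$sigma_phy < 0) return(-Inf)
    if (params$sigma_phy == 0) {
      if (any(params$u_phy != 0)) return(-Inf)
    } else {
      # MVN(0, sigma^2 A) via A = R'R: solve R' v = u, then u' A^-1 u = v'v
      R <- data$A_chol
      v <- backsolve(R, params$u_phy, transpose = TRUE)
      logdetA <- 2 * sum(log(diag(R)))
      lp <- lp - 0.5 * (S * log(2 * pi) + S * 2 * log(params$sigma_phy) +
                          logdetA + sum(v^2) / params$sigma_phy^2)
    }
  }
  if ("species" %in% data$random) {
    if (params$sigma_spp < 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(params$u_spp, 0, params$sigma_spp, log = TRUE))
  }
  if ("slope" %in% data$random) {
    if (params$sigma_slope < 0) return(-Inf)
    lp <- lp + sum(stats::dnorm(params$u_slope, 0, params$sigma_slope, log = TRUE))
  }
  lp
}

#' Joint log posterior (unnormalized)
#'
#' @inheritParams log_prior
#' @return `log_likelihood + log_prior`.
#' @export
log_posterior <- function(params, data, priors = gut_priors(), gaussian = FALSE) {
  lp <- log_prior(params, data, priors, gaussian = gaussian)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(params, data, gaussian = gaussian)
}
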