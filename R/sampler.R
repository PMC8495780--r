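#' Sample the posterior of the phylogenetic hierarchical model
#'
#' Blocked MCMC tailored to this model family. Given the variance
#' parameters and the latent Student-t weights, the fixed effects and all
#' species effects form one joint Gaussian block and are drawn exactly by a
#' single Cholesky solve (the species effects are parameterized
#' non-centered, `u = sigma * L'z`, so small variance components do not
#' stall the chain). Standard deviations and the degrees of freedom are
#' updated by random-walk Metropolis on the log scale with proposal scales
#' adapted during warm-up only. Student-t residuals use the
#' scale-mixture-of-normals augmentation: per-observation precision weights
#' `w_i ~ Gamma(nu/2, nu/2)` restore conjugacy of the Gaussian block, and
#' are themselves conjugate given the residuals.
#'
#' @param data `gut_modeldata` from [build_design()].
#' @param priors A [gut_priors()] object.
#' @param chains Number of chains (default 4).
#' @param iter Total iterations per chain, including warm-up (default 8000).
#' @param warmup Warm-up iterations discarded per chain (default 2000).
#' @param seed Integer seed; a fixed seed reproduces draws bitwise.
#' @param gaussian If `TRUE`, residuals are normal (weights fixed at 1 and
#'   the degrees of freedom dropped) — the reference mode used by
#'   closed-form oracle tests.
#' @param fix Named list pinning any of `sigma_phy`, `sigma_spp`,
#'   `sigma_slope`, `sigma_resid`, `nu` at known values (their updates are
#'   skipped). Used for conjugate-oracle checks.
#' @param init_retries Attempts to find a finite starting point.
#' @param compute_diagnostics Compute split-R-hat / bulk-ESS per parameter
#'   after sampling (default `TRUE`).
#' @return Object of class `gut_draws`: list with `draws` (one
#'   iterations-by-parameter matrix per chain, post-warm-up), `data`,
#'   `settings`, Metropolis `accept` rates, `diagnostics`, and `converged`
#'   (`TRUE`/`FALSE`/`NA` if not computed).
#' @export
sample_posterior <- function(data, priors = gut_priors(),
                             chains = 4L, iter = 8000L, warmup = 2000L,
                             seed = 1L, gaussian = FALSE, fix = list(),
                             init_retries = 100L,
                             compute_diagnostics = TRUE) {
  stopifnot(inherits(data, "gut_modeldata"), chains >= 1L, iter > warmup,
            warmup >= 0L)
  bad_fix <- setdiff(names(fix),
                     c("sigma_phy", "sigma_spp", "sigma_slope", "sigma_resid", "nu"))
  if (length(bad_fix) > 0L) stop("unknown fix parameter(s): ",
                                 paste(bad_fix, collapse = ", "))

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)

  draws <- vector("list", chains)
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- run_chain(data, priors, iter = iter, warmup = warmup,
                     seed = chain_seeds[ch], gaussian = gaussian, fix = fix,
                     init_retries = init_retries)
    draws[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }

  fit <- structure(list(
    draws = draws,
    params = colnames(draws[[1L]]),
    data = data,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    seed = as.integer(seed), gaussian = gaussian, fix = fix,
                    priors = priors),
    accept = accept,
    diagnostics = NULL,
    converged = NA
  ), class = "gut_draws")

  if (compute_diagnostics) {
    fit$diagnostics <- convergence_report(fit)
    ok <- with(fit$diagnostics,
               all(rhat <= 1.01, na.rm = TRUE) & all(ess_bulk >= 400, na.rm = TRUE))
    fit$converged <- isTRUE(ok)
    if (!fit$converged) {
      gs_log("sampler",
             "convergence flag not met (max rhat %.3f, min bulk ESS %.0f)",
             max(fit$diagnostics$rhat, na.rm = TRUE),
             min(fit$diagnostics$ess_bulk, na.rm = TRUE))
    }
  }
  fit
}

# One MCMC chain. Returns the post-warm-up draws matrix and MH acceptance
# rates. All state that the Gaussian block needs is kept as plain vectors.
run_chain <- function(data, priors, iter, warmup, seed, gaussian, fix,
                      init_retries) {
  set.seed(seed)
  y <- data$y; n <- length(y)
  X <- data$X; k <- ncol(X)
  cdev <- data$c
  j <- data$species_index
  S <- length(data$species)
  random <- data$random
  dev_slope <- isTRUE(data$dev_slope)
  R_A <- data$A_chol                      # A = R'R, upper triangular

  W <- if (dev_slope) cbind(X, dev_slope = cdev) else X
  kw <- ncol(W)
  use_phy <- "phylo" %in% random
  use_spp <- "species" %in% random
  use_slp <- "slope" %in% random

  # obs-level loading matrices for the non-centered species effects
  Zmat <- matrix(0, n, S)
  Zmat[cbind(seq_len(n), j)] <- 1
  ZLt <- if (use_phy) Zmat %*% t(R_A) else NULL   # u_phy = sigma * t(R) z
  Zc  <- if (use_slp) Zmat * cdev else NULL

  p <- kw + S * (use_phy + use_spp + use_slp)
  prior_prec <- c(
    1 / ifelse(colnames(W) == "intercept", priors$intercept_sd, priors$slope_sd)^2,
    rep(1, p - kw)
  )
  idx_beta <- seq_len(kw)
  off <- kw
  idx_phy <- if (use_phy) off + seq_len(S) else integer(0); off <- off + length(idx_phy)
  idx_spp <- if (use_spp) off + seq_len(S) else integer(0); off <- off + length(idx_spp)
  idx_slp <- if (use_slp) off + seq_len(S) else integer(0)

  is_fixed <- function(nm) !is.null(fix[[nm]])
  val_fixed <- function(nm, default) if (is_fixed(nm)) fix[[nm]] else default

  # --- initialization (least squares + per-chain jitter) ------------------
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    beta <- tryCatch(qr.solve(crossprod(W) + diag(1e-8, kw), crossprod(W, y)),
                     error = function(e) rep(0, kw))
    beta <- drop(beta) + stats::rnorm(kw, 0, 0.1)
    r0 <- drop(y - W %*% beta)
    s0 <- max(stats::sd(r0), 1e-3)
    sphy <- val_fixed("sigma_phy", 0.5 * s0 * exp(stats::rnorm(1, 0, 0.2)))
    sspp <- val_fixed("sigma_spp", 0.5 * s0 * exp(stats::rnorm(1, 0, 0.2)))
    sslp <- val_fixed("sigma_slope", 0.5 * s0 * exp(stats::rnorm(1, 0, 0.2)))
    sres <- val_fixed("sigma_resid", 0.5 * s0 * exp(stats::rnorm(1, 0, 0.2)))
    nu <- val_fixed("nu", 30)
    z1 <- rep(0, S); z2 <- rep(0, S); z3 <- rep(0, S)
    w <- rep(1, n)
    ok <- is.finite(sum(beta)) && sres > 0 && (gaussian || nu > 1)
    if (ok) break
    if (attempt >= init_retries) stop("non-finite posterior at initialization")
  }

  # effect vectors at observation level (unscaled by sigma)
  v_phy <- if (use_phy) drop(ZLt %*% z1) else NULL
  v_spp <- if (use_spp) z2[j] else NULL
  v_slp <- if (use_slp) z3[j] * cdev else NULL

  mu <- drop(W %*% beta)
  if (use_phy) mu <- mu + sphy * v_phy
  if (use_spp) mu <- mu + sspp * v_spp
  if (use_slp) mu <- mu + sslp * v_slp

  # --- adaptive MH bookkeeping -------------------------------------------
  mh_names <- c(if (use_phy && !is_fixed("sigma_phy")) "sigma_phy",
                if (use_spp && !is_fixed("sigma_spp")) "sigma_spp",
                if (use_slp && !is_fixed("sigma_slope")) "sigma_slope",
                if (!is_fixed("sigma_resid")) "sigma_resid",
                if (!gaussian && !is_fixed("nu")) "nu")
  ls <- stats::setNames(rep(log(0.3), length(mh_names)), mh_names)
  ls_ridge <- log(0.3)
  acc_n <- stats::setNames(rep(0, length(mh_names)), mh_names)
  prop_n <- stats::setNames(rep(0, length(mh_names)), mh_names)

  n_keep <- iter - warmup
  pn <- c(colnames(W),
          if (use_phy) "sigma_phy", if (use_spp) "sigma_spp",
          if (use_slp) "sigma_slope", "sigma_resid",
          if (!gaussian) "nu",
          if (use_phy) paste0("u_phy[", data$species, "]"),
          if (use_spp) paste0("u_spp[", data$species, "]"),
          if (use_slp) paste0("u_slope[", data$species, "]"))
  out <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))

  half_t_lp <- function(x) log_half_t(x, priors$sd_df, priors$sd_scale)
  # Robbins-Monro step toward the 0.44 target rate, frozen after warm-up
  adapt_step <- function(lsv, log_acc, it) {
    acc <- if (is.finite(log_acc)) min(1, exp(log_acc)) else 0
    lsv + (acc - 0.44) * min(0.5, 3 / sqrt(it))
  }

  for (it in seq_len(iter)) {
    # (1) joint Gaussian block: beta and all z's given sigmas, w
    Cmat <- W
    if (use_phy) Cmat <- cbind(Cmat, sphy * ZLt)
    if (use_spp) Cmat <- cbind(Cmat, sspp * Zmat)
    if (use_slp) Cmat <- cbind(Cmat, sslp * Zc)
    sw <- sqrt(w) / sres
    Cw <- Cmat * sw
    Q <- crossprod(Cw)
    diag(Q) <- diag(Q) + prior_prec
    rhs <- crossprod(Cw, y * sw)
    Rq <- chol(Q)
    mean_theta <- backsolve(Rq, backsolve(Rq, rhs, transpose = TRUE))
    theta <- drop(mean_theta + backsolve(Rq, stats::rnorm(p)))
    beta <- theta[idx_beta]
    if (use_phy) { z1 <- theta[idx_phy]; v_phy <- drop(ZLt %*% z1) }
    if (use_spp) { z2 <- theta[idx_spp]; v_spp <- z2[j] }
    if (use_slp) { z3 <- theta[idx_slp]; v_slp <- z3[j] * cdev }
    mu <- drop(W %*% beta)
    if (use_phy) mu <- mu + sphy * v_phy
    if (use_spp) mu <- mu + sspp * v_spp
    if (use_slp) mu <- mu + sslp * v_slp

    gauss_ll <- function(mu_) -0.5 * sum(w * (y - mu_)^2) / sres^2

    # (2) sd of each active random term: likelihood-informed MH in the
    # non-centered parameterization, then an interweaving move in the
    # centered one (independence MH from the conditional of sigma given the
    # realized effects, which only needs z'z because the effects are
    # whitened; the effects u = sigma * L'z are held fixed and z rescaled).
    # The two moves together mix well whether the component is large or
    # nearly zero.
    for (nm in intersect(mh_names, c("sigma_phy", "sigma_spp", "sigma_slope"))) {
      cur <- switch(nm, sigma_phy = sphy, sigma_spp = sspp, sigma_slope = sslp)
      v <- switch(nm, sigma_phy = v_phy, sigma_spp = v_spp, sigma_slope = v_slp)
      prop <- cur * exp(stats::rnorm(1, 0, exp(ls[nm])))
      mu_prop <- mu + (prop - cur) * v
      log_acc <- (gauss_ll(mu_prop) + half_t_lp(prop) + log(prop)) -
                 (gauss_ll(mu) + half_t_lp(cur) + log(cur))
      prop_n[nm] <- prop_n[nm] + 1
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        acc_n[nm] <- acc_n[nm] + 1
        mu <- mu_prop
        cur <- prop
      }
      if (it <= warmup) ls[nm] <- adapt_step(ls[nm], log_acc, it)

      # interweaving: sigma | u is prop. to sigma^-S exp(-q / 2 sigma^2)
      # times the half-t prior, with q = u'K^-1 u = cur^2 * z'z; propose
      # from the inverse-gamma part, accept on the prior ratio.
      zz <- switch(nm, sigma_phy = sum(z1^2), sigma_spp = sum(z2^2),
                   sigma_slope = sum(z3^2))
      if (zz > 0 && S >= 3L) {
        q <- cur^2 * zz
        v2 <- 1 / stats::rgamma(1, shape = (S - 1) / 2, rate = q / 2)
        cand <- sqrt(v2)
        if (is.finite(cand) && cand > 0 &&
            log(stats::runif(1)) < half_t_lp(cand) - half_t_lp(cur)) {
          scale_z <- cur / cand
          if (nm == "sigma_phy") { z1 <- z1 * scale_z }
          if (nm == "sigma_spp") { z2 <- z2 * scale_z }
          if (nm == "sigma_slope") { z3 <- z3 * scale_z }
          cur <- cand
        }
      }
      if (nm == "sigma_phy") sphy <- cur
      if (nm == "sigma_spp") sspp <- cur
      if (nm == "sigma_slope") sslp <- cur
    }
    # mu is unchanged by interweaving (u held fixed), but the unscaled
    # effect vectors must track the rescaled z's
    if (use_phy) v_phy <- drop(ZLt %*% z1)
    if (use_spp) v_spp <- z2[j]
    if (use_slp) v_slp <- z3[j] * cdev
    mu <- drop(W %*% beta)
    if (use_phy) mu <- mu + sphy * v_phy
    if (use_spp) mu <- mu + sspp * v_spp
    if (use_slp) mu <- mu + sslp * v_slp

    # (2b) joint antithetic move along the sigma_phy / sigma_spp ridge:
    # the two intercept variance components are near-exchangeable when the
    # tree signal is weak, so single-parameter moves crawl; an opposed
    # update of the two log-scales traverses the ridge directly.
    if (all(c("sigma_phy", "sigma_spp") %in% mh_names)) {
      dlt <- stats::rnorm(1, 0, exp(ls_ridge))
      sp_p <- sphy * exp(dlt)
      ss_p <- sspp * exp(-dlt)
      mu_prop <- mu + (sp_p - sphy) * v_phy + (ss_p - sspp) * v_spp
      log_acc <- (gauss_ll(mu_prop) + half_t_lp(sp_p) + half_t_lp(ss_p) +
                    log(sp_p) + log(ss_p)) -
                 (gauss_ll(mu) + half_t_lp(sphy) + half_t_lp(sspp) +
                    log(sphy) + log(sspp))
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        sphy <- sp_p; sspp <- ss_p
        mu <- mu_prop
      }
      if (it <= warmup) ls_ridge <- adapt_step(ls_ridge, log_acc, it)
    }

    # (3) residual scale and (4) degrees of freedom: random-walk MH on the
    # marginal (weights integrated out) residual density, which mixes much
    # faster than conditioning on the latent weights; the weights are then
    # redrawn from their exact conditional (partially collapsed Gibbs).
    e <- y - mu
    marg_ll <- function(s_, v_) {
      if (gaussian) {
        -n * log(s_) - 0.5 * sum(e^2) / s_^2
      } else {
        sum(stats::dt(e / s_, df = v_, log = TRUE)) - n * log(s_)
      }
    }
    if ("sigma_resid" %in% mh_names) {
      prop <- sres * exp(stats::rnorm(1, 0, exp(ls["sigma_resid"])))
      log_acc <- (marg_ll(prop, nu) + half_t_lp(prop) + log(prop)) -
                 (marg_ll(sres, nu) + half_t_lp(sres) + log(sres))
      prop_n["sigma_resid"] <- prop_n["sigma_resid"] + 1
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        acc_n["sigma_resid"] <- acc_n["sigma_resid"] + 1
        sres <- prop
      }
      if (it <= warmup) {
        ls["sigma_resid"] <- adapt_step(ls["sigma_resid"], log_acc, it)
      }
    }

    if (!gaussian) {
      if ("nu" %in% mh_names) {
        prop <- 1 + (nu - 1) * exp(stats::rnorm(1, 0, exp(ls["nu"])))
        log_acc <- (marg_ll(sres, prop) +
                      log_nu_prior(prop, priors$nu_shape, priors$nu_rate) +
                      log(prop - 1)) -
                   (marg_ll(sres, nu) +
                      log_nu_prior(nu, priors$nu_shape, priors$nu_rate) +
                      log(nu - 1))
        prop_n["nu"] <- prop_n["nu"] + 1
        if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
          acc_n["nu"] <- acc_n["nu"] + 1
          nu <- prop
        }
        if (it <= warmup) ls["nu"] <- adapt_step(ls["nu"], log_acc, it)
      }
      # (5) latent precision weights (conjugate)
      w <- stats::rgamma(n, shape = (nu + 1) / 2, rate = (nu + e^2 / sres^2) / 2)
      w <- pmax(w, 1e-12)
    }

    if (it > warmup) {
      row <- it - warmup
      vals <- c(beta,
                if (use_phy) sphy, if (use_spp) sspp, if (use_slp) sslp,
                sres,
                if (!gaussian) nu,
                if (use_phy) sphy * drop(crossprod(R_A, z1)),
                if (use_spp) sspp * z2,
                if (use_slp) sslp * z3)
      out[row, ] <- vals
    }
  }

  list(draws = out, accept = ifelse(prop_n > 0, acc_n / prop_n, NA_real_))
}

#' Stack posterior draws across chains
#'
#' @param fit A `gut_draws` object.
#' @param pars Optional character vector of parameter names (or unnamed
#'   prefixes like `"u_slope"` which select all indexed elements).
#' @return Matrix with one column per selected parameter, chains stacked.
#' @export
as_draws_matrix <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "gut_draws"))
  m <- do.call(rbind, fit$draws)
  if (is.null(pars)) return(m)
  cols <- unlist(lapply(pars, function(p) {
    if (p %in% colnames(m)) return(p)
    hits <- grep(paste0("^", p, "\\["), colnames(m), value = TRUE)
    if (length(hits) == 0L) stop("no such parameter: ", p)
    hits
  }))
  m[, cols, drop = FALSE]
}

#' @export
print.gut_draws <- function(x, ...) {
  s <- x$settings
  cat(sprintf("gut_draws: %d chains x %d kept iterations, %d parameters\n",
              s$chains, s$iter - s$warmup, length(x$params)))
  cat(sprintf("  gaussian mode: %s | converged flag: %s\n",
              s$gaussian, x$converged))
  invisible(x)
}
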