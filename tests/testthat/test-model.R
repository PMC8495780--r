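make_modeldata <- function(random = c("phylo", "species", "slope"), ...) {
  std <- standardize(decompose_size(
    assemble_model_table(tiny_specimens(), tiny_metadata(), "length")))
  A <- to_correlation(shared_path_matrix(toy_tree()))
  build_design(std, A, random = random, ...)
}

test_that("build_design produces the documented design", {
  md <- make_modeldata()
  expect_equal(ncol(md$X), 7L)
  expect_equal(nrow(md$X), 9L)
  expect_equal(colnames(md$X),
               c("intercept", "z_ln_sl_bar", "z_tl", "z_ln_el", "stomach",
                 "durophagy", "stomach_durophagy"))
  expect_equal(md$X[, "stomach_durophagy"],
               md$X[, "stomach"] * md$X[, "durophagy"])
  expect_equal(md$species, c("A", "B", "C"))
  expect_equal(rownames(md$A), md$species)
  # interaction is 1 only when both are 1
  b_rows <- md$species_index == 2L  # species B: stomach 1, durophagy 1
  expect_true(all(md$X[b_rows, "stomach_durophagy"] == 1))
  expect_true(all(md$X[!b_rows, "stomach_durophagy"] == 0))
})

test_that("build_design keeps row order and catches missing species", {
  sp <- tiny_specimens(); mdta <- tiny_metadata()
  perm <- sample(9)
  std1 <- standardize(decompose_size(assemble_model_table(sp, mdta)))
  std2 <- standardize(decompose_size(assemble_model_table(sp[perm, ], mdta)))
  A <- to_correlation(shared_path_matrix(toy_tree()))
  d1 <- build_design(std1, A); d2 <- build_design(std2, A)
  expect_equal(d2$X, d1$X[perm, ])
  expect_equal(d2$species_index, d1$species_index[perm])

  A2 <- A[c("A", "B"), c("A", "B")]
  expect_error(build_design(std1, A2), "C")
})

ref_params <- function(md, ...) {
  dots <- list(...)
  p <- list(
    beta = stats::setNames(rep(0, ncol(md$X)), colnames(md$X)),
    gamma30 = 0,
    u_phy = rep(0, 3), u_spp = rep(0, 3), u_slope = rep(0, 3),
    sigma_resid = 1, nu = 10
  )
  p[names(dots)] <- dots
  p
}

test_that("log_likelihood matches closed forms", {
  md <- make_modeldata()
  # single observation with mu = y, gaussian, sigma = 1
  md1 <- md
  md1$y <- md$y[1]; md1$X <- md$X[1, , drop = FALSE]
  md1$c <- md$c[1]; md1$species_index <- md$species_index[1]
  p <- ref_params(md1)
  p$beta["intercept"] <- md1$y
  expect_equal(log_likelihood(p, md1, gaussian = TRUE), -0.5 * log(2 * pi))

  # gaussian, all random effects zero: equals textbook OLS log-likelihood
  p2 <- ref_params(md, beta = stats::setNames(c(3, 0.5, -0.3, -0.2, 0.1, 0, 0),
                                              colnames(md$X)),
                   gamma30 = 0.8, sigma_resid = 0.4)
  e <- md$y - (md$X %*% p2$beta + p2$gamma30 * md$c)
  ols <- -length(e) / 2 * log(2 * pi * 0.4^2) - sum(e^2) / (2 * 0.4^2)
  expect_equal(log_likelihood(p2, md, gaussian = TRUE), drop(ols))

  # symmetry in the residuals: t density is even
  p3 <- ref_params(md, sigma_resid = 0.7, nu = 5)
  ll1 <- log_likelihood(p3, md)
  md_flip <- md
  md_flip$y <- 2 * drop(md$X %*% p3$beta) - md$y   # flips residual signs
  expect_equal(log_likelihood(p3, md_flip), ll1)

  # support guards
  expect_equal(log_likelihood(ref_params(md, sigma_resid = -1), md), -Inf)
  expect_equal(log_likelihood(ref_params(md, nu = 0.5), md), -Inf)
})

test_that("log_prior hierarchical terms match an independent MVN density", {
  md <- make_modeldata()
  base <- ref_params(md, sigma_resid = 0.5)
  base$sigma_phy <- 1; base$sigma_spp <- 0.5; base$sigma_slope <- 0.3

  # A = identity: phylogenetic term reduces to iid standard normals
  md_id <- md
  md_id$A <- diag(3); dimnames(md_id$A) <- dimnames(md$A)
  md_id$A_chol <- chol(md_id$A)
  p <- base; p$u_phy <- c(0.3, -0.2, 0.5)
  expect_equal(log_prior(p, md_id) - log_prior(base, md_id),
               sum(stats::dnorm(p$u_phy, 0, 1, log = TRUE)) -
                 sum(stats::dnorm(c(0, 0, 0), 0, 1, log = TRUE)))

  # doubling sigma_phy with u_phy = 0 lowers the MVN term by S * log 2
  # (after removing the half-t prior's own contribution)
  p_dbl <- base; p_dbl$sigma_phy <- 2
  hp <- function(s) log(2) + stats::dt(s / 2.5, df = 3, log = TRUE) - log(2.5)
  delta <- (log_prior(p_dbl, md) - hp(2)) - (log_prior(base, md) - hp(1))
  expect_equal(delta, -3 * log(2))

  # generic MVN oracle on the real 3-species correlation matrix
  p_mvn <- base; p_mvn$u_phy <- c(0.4, -0.1, 0.2); p_mvn$sigma_phy <- 0.8
  ref_mvn <- function(u, S) {
    -0.5 * (length(u) * log(2 * pi) + as.numeric(determinant(S)$modulus) +
              drop(u %*% solve(S) %*% u))
  }
  base_ref <- base; base_ref$sigma_phy <- 0.8
  expect_equal(log_prior(p_mvn, md) - log_prior(base_ref, md),
               ref_mvn(p_mvn$u_phy, 0.8^2 * unclass(md$A)) -
                 ref_mvn(c(0, 0, 0), 0.8^2 * unclass(md$A)),
               tolerance = 1e-8)
})

test_that("log_posterior is finite for prior-predictive parameter draws", {
  md <- make_modeldata()
  set.seed(4)
  for (i in 1:200) {
    p <- list(
      beta = stats::setNames(stats::rnorm(7, 0, 2), colnames(md$X)),
      gamma30 = stats::rnorm(1, 0, 2),
      u_phy = stats::rnorm(3), u_spp = stats::rnorm(3), u_slope = stats::rnorm(3),
      sigma_phy = abs(stats::rnorm(1, 0, 1)) + 0.01,
      sigma_spp = abs(stats::rnorm(1, 0, 1)) + 0.01,
      sigma_slope = abs(stats::rnorm(1, 0, 1)) + 0.01,
      sigma_resid = abs(stats::rnorm(1, 0, 1)) + 0.01,
      nu = 1 + stats::rgamma(1, 2, 0.1)
    )
    expect_true(is.finite(log_posterior(p, md)))
  }
})

test_that("posterior is invariant to species relabeling", {
  md <- make_modeldata()
  p <- list(
    beta = stats::setNames(c(3, 0.5, -0.3, -0.2, 0.1, 0.05, 0.02), colnames(md$X)),
    gamma30 = 0.9, u_phy = c(0.2, -0.1, 0.3), u_spp = c(0.1, 0, -0.1),
    u_slope = c(0.05, -0.02, 0.01),
    sigma_phy = 0.5, sigma_spp = 0.3, sigma_slope = 0.2,
    sigma_resid = 0.3, nu = 8
  )
  lp1 <- log_posterior(p, md)

  perm <- c(3, 1, 2)  # relabel species consistently everywhere
  md2 <- md
  md2$A <- md$A[perm, perm]
  md2$A_chol <- chol(md2$A)
  md2$species <- md$species[perm]
  md2$species_index <- match(md$species_index, perm)
  p2 <- p
  p2$u_phy <- p$u_phy[perm]; p2$u_spp <- p$u_spp[perm]
  p2$u_slope <- p$u_slope[perm]
  expect_equal(log_posterior(p2, md2), lp1, tolerance = 1e-10)
})
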