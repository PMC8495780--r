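# mock draws object with hand-set parameter columns, for summary functions
# that only touch the draw matrices
mock_fit <- function(cols, n = 500, data = NULL, gaussian = FALSE, chains = 2) {
  m <- do.call(cbind, lapply(cols, function(x) rep_len(x, n)))
  colnames(m) <- names(cols)
  structure(list(
    draws = replicate(chains, m, simplify = FALSE),
    params = colnames(m),
    data = data,
    settings = list(chains = chains, iter = n, warmup = 0, gaussian = gaussian),
    converged = NA
  ), class = "gut_draws")
}

test_that("heritability reproduces closed-form ratios", {
  f <- mock_fit(list(sigma_phy = 1, sigma_spp = 0, sigma_resid = 0, nu = 10))
  expect_equal(heritability(f)$mean, 1.0)

  f0 <- mock_fit(list(sigma_phy = 0, sigma_spp = 0.5, sigma_resid = 0.3, nu = 10))
  expect_equal(heritability(f0)$mean, 0.0)

  # sigma_phy^2 = 0.9, sigma_spp^2 = 0.06, v_resid = 0.04 -> 0.90
  # (v_resid = sigma^2 * nu/(nu-2); choose sigma so that equals 0.04)
  nu <- 10
  f9 <- mock_fit(list(sigma_phy = sqrt(0.9), sigma_spp = sqrt(0.06),
                      sigma_resid = sqrt(0.04 * (nu - 2) / nu), nu = nu))
  expect_equal(heritability(f9)$mean, 0.90, tolerance = 1e-12)

  # species denominator ignores the residual part
  expect_equal(heritability(f9, denominator = "species")$mean,
               0.9 / 0.96, tolerance = 1e-12)

  # nu <= 2 guard: falls back to sigma^2 with a message, stays in [0,1]
  fguard <- mock_fit(list(sigma_phy = 1, sigma_spp = 1, sigma_resid = 1, nu = 1.5))
  h <- suppressMessages(heritability(fguard))
  expect_equal(h$mean, 1 / 3)
  expect_true(all(h$draws >= 0 & h$draws <= 1))
})

test_that("heritability draws stay in [0,1] on a real fit", {
  h <- heritability(quick_fit()$fit, force = TRUE)
  expect_true(all(h$draws >= 0 & h$draws <= 1))
  expect_true(h$ci95[1] <= h$mean && h$mean <= h$ci95[2])
})

test_that("bayes_r2 matches an independent implementation of the ratio", {
  qf <- quick_fit()
  fit <- qf$fit
  r2 <- bayes_r2(fit, force = TRUE)
  expect_true(all(r2$draws >= 0 & r2$draws <= 1))

  # independent recomputation from raw draws, first 50 draws
  m <- as_draws_matrix(fit)[1:50, ]
  data <- fit$data
  j <- data$species_index
  v <- sapply(1:50, function(d) {
    mu <- drop(data$X %*% m[d, colnames(data$X)]) +
      (m[d, "dev_slope"] + m[d, paste0("u_slope[", data$species, "]")][j]) * data$c +
      m[d, paste0("u_phy[", data$species, "]")][j] +
      m[d, paste0("u_spp[", data$species, "]")][j]
    vres <- m[d, "sigma_resid"]^2 *
      if (m[d, "nu"] > 2) m[d, "nu"] / (m[d, "nu"] - 2) else 1
    stats::var(mu) / (stats::var(mu) + vres)
  })
  expect_equal(unname(r2$draws[1:50]), unname(v), tolerance = 1e-10)
})

test_that("bayes_r2 hits its limits in degenerate cases", {
  # zero residual scale -> R2 = 1 exactly
  qf <- quick_fit()
  fit <- qf$fit
  m0 <- as_draws_matrix(fit)[1:10, ]
  m0[, "sigma_resid"] <- 0
  fz <- fit
  fz$draws <- list(m0, m0)
  expect_equal(unname(bayes_r2(fz, force = TRUE)$draws), rep(1, 20))

  # null model (all effects zero) -> Var(mu) = 0 -> R2 = 0
  mnull <- m0
  mnull[, ] <- 0
  mnull[, "sigma_resid"] <- 0.5
  mnull[, "nu"] <- 10
  fn <- fit
  fn$draws <- list(mnull, mnull)
  expect_equal(unname(bayes_r2(fn, force = TRUE)$draws), rep(0, 20))
})

test_that("fixed_effect_table summarises draws with nested CIs", {
  fit <- quick_fit()$fit
  tab <- fixed_effect_table(fit, force = TRUE)
  expect_setequal(tab$param,
                  c("intercept", "z_ln_sl_bar", "z_tl", "z_ln_el", "stomach",
                    "durophagy", "stomach_durophagy", "dev_slope"))
  expect_true(all(tab$q2.5 <= tab$q25 & tab$q25 <= tab$q75 & tab$q75 <= tab$q97.5))
  expect_true(all(tab$q25 <= tab$median & tab$median <= tab$q75))
  # symmetric-ish posterior: mean close to median
  expect_equal(tab$mean, tab$median, tolerance = 0.05)
})

test_that("percent_change inverts the log-scale slope correctly", {
  expect_equal(percent_change(0, 1, 2.38), 0)
  # a raw-scale slope*delta of log(0.405) is a 59.5% decrease
  expect_equal(percent_change(log(0.405) / 2.38, 1, 2.38), 59.5, tolerance = 0.01)
  # monotone in |beta| for decreases
  p1 <- percent_change(-0.2, 1, 2); p2 <- percent_change(-0.4, 1, 2)
  expect_gt(p2, p1)
  # standardized slope with sd 2 is half the raw slope
  expect_equal(percent_change(-0.4, 2, 1), percent_change(-0.2, 1, 1))
  # increases come back negative
  expect_lt(percent_change(0.3, 1, 1), 0)
})

test_that("predict_species obeys its closed-form identities", {
  qf <- quick_fit()
  fit <- qf$fit
  sp <- fit$data$species[1]
  tab <- fit$data$table
  row <- tab[match(sp, tab$species), ]

  # prediction at the species' own mean SL (intra mode, c = 0) equals the
  # posterior mean of exp(fitted species mean)
  own_sl <- exp(row$ln_sl_bar)
  pr <- predict_species(fit, sp, SL = own_sl, mode = "intra", force = TRUE)
  m <- as_draws_matrix(fit)
  x <- c(1, row$z_ln_sl_bar, row$z_tl, row$z_ln_el, row$stomach, row$durophagy,
         row$stomach * row$durophagy)
  mu <- drop(m[, colnames(fit$data$X)] %*% x) +
    m[, paste0("u_phy[", sp, "]")] + m[, paste0("u_spp[", sp, "]")]
  expect_equal(pr$mean, mean(exp(mu)), tolerance = 1e-10)

  # log-linearity: shifting u_spp draws by delta scales prediction by e^delta
  delta <- 0.3
  fit2 <- fit
  fit2$draws <- lapply(fit$draws, function(d) {
    d[, paste0("u_spp[", sp, "]")] <- d[, paste0("u_spp[", sp, "]")] + delta
    d
  })
  pr2 <- predict_species(fit2, sp, SL = 15, force = TRUE)
  pr1 <- predict_species(fit, sp, SL = 15, force = TRUE)
  expect_equal(pr2$mean, pr1$mean * exp(delta), tolerance = 1e-10)

  expect_error(predict_species(fit, "nope", force = TRUE), "nope")
})

test_that("predictions are monotone in SL when the slope posterior is positive", {
  qf <- quick_fit()
  fit <- qf$fit
  # inter mode: the interspecific slope posterior is decisively positive here
  p10 <- predict_species(fit, SL = 10, force = TRUE)
  p20 <- predict_species(fit, SL = 20, force = TRUE)
  expect_true(all(p20$mean > p10$mean))
})

test_that("scaling_report flags and classes agree with a brute-force rebuild", {
  qf <- quick_fit()
  fit <- qf$fit
  ds <- qf$ds
  rep <- scaling_report(fit, ds$specimens, ds$metadata, force = TRUE)
  expect_equal(nrow(rep), length(fit$data$species))

  m <- as_draws_matrix(fit)
  for (i in seq_len(nrow(rep))) {
    sp <- rep$species[i]
    b3 <- m[, "dev_slope"] + m[, paste0("u_slope[", sp, "]")]
    sl <- ds$specimens$sl_cm[ds$specimens$species == sp]
    mx <- ds$metadata$max_size_cm[match(sp, ds$metadata$species)]
    ci95 <- stats::quantile(b3, c(0.025, 0.975), names = FALSE)
    ci80 <- stats::quantile(b3, c(0.10, 0.90), names = FALSE)
    cover <- (max(sl) - min(sl)) / mx
    expect_identical(rep$reliable[i],
                     (length(sl) >= 10) && (cover >= 0.25) && (ci95[1] > 0))
    expect_equal(rep$n_specimens[i], length(sl))
    expect_equal(rep$size_coverage[i], cover)
    cls <- function(ci, iso) if (ci[2] < iso) "negative" else
      if (ci[1] > iso) "positive" else "isometric"
    expect_identical(rep$class80[i], cls(ci80, 1))
    expect_identical(rep$class95[i], cls(ci95, 1))
  }
})

test_that("scaling_report applies the n >= 10 rule regardless of the CI", {
  # species with a tight, clearly allometric slope but too few specimens
  data <- quick_fit()$fit$data
  sp <- data$species
  cols <- stats::setNames(as.list(rep(0.1, length(sp))),
                          paste0("u_slope[", sp, "]"))
  cols$dev_slope <- 0.4   # slope posterior 0.5: negative allometry for length
  cols$sigma_resid <- 0.1
  f <- mock_fit(cols, data = data)
  spec9 <- data.frame(species = rep(sp[1], 9),
                      sl_cm = seq(10, 30, length.out = 9))
  md <- data.frame(species = sp[1], max_size_cm = 40)
  r <- suppressMessages(scaling_report(f, spec9, md))
  r1 <- r[r$species == sp[1], ]
  expect_false(r1$reliable)              # n = 9 < 10 although coverage = 0.5
  expect_identical(r1$class80, "negative")
})

test_that("sensitivity_refit keeps exactly the qualifying species", {
  ds <- simulate_dataset(n_species = 15, n_per_species = c(3, 12), seed = 13)
  counts <- table(ds$specimens$species)
  for (mn in c(1, 5, 8)) {
    expected <- sum(counts >= mn)
    if (expected < 3) next
    fit <- sensitivity_refit(ds$specimens, ds$metadata, ds$tree, min_n = mn,
                             chains = 2, iter = 60, warmup = 20, seed = 1,
                             compute_diagnostics = FALSE)
    expect_equal(length(fit$data$species), expected)
  }
  # all species at n = 8: min_n 5 and 8 give identical species sets
  ds8 <- simulate_dataset(n_species = 8, n_per_species = 8, seed = 14)
  f5 <- sensitivity_refit(ds8$specimens, ds8$metadata, ds8$tree, min_n = 5,
                          chains = 2, iter = 60, warmup = 20, seed = 1,
                          compute_diagnostics = FALSE)
  f8 <- sensitivity_refit(ds8$specimens, ds8$metadata, ds8$tree, min_n = 8,
                          chains = 2, iter = 60, warmup = 20, seed = 1,
                          compute_diagnostics = FALSE)
  expect_identical(f5$data$species, f8$data$species)
  expect_error(sensitivity_refit(ds8$specimens, ds8$metadata, ds8$tree,
                                 min_n = 50), "fewer than 3")
})
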