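# Rank-normalized split-R-hat and bulk effective sample size, computed per
# scalar parameter across chains (Vehtari-style formulas, implemented
# directly on the draw matrices).

# rank-normalize a vector of pooled draws (blended ranks -> normal scores)
rank_normal <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

# split each chain's column in half, giving a matrix n/2 x (2*chains)
split_chains <- function(mat_list, par) {
  cols <- lapply(mat_list, function(m) m[, par])
  n <- length(cols[[1L]])
  half <- floor(n / 2)
  do.call(cbind, unlist(lapply(cols, function(x) {
    list(x[seq_len(half)], x[seq.int(n - half + 1L, n)])
  }), recursive = FALSE))
}

rhat_from_splits <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  if (stats::var(as.vector(sm)) == 0) return(NA_real_)
  cm <- colMeans(sm)
  B <- n * stats::var(cm)
  Wv <- mean(apply(sm, 2, stats::var))
  if (Wv == 0) return(NA_real_)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

# autocovariance by FFT, biased (divided by n), as the ESS formula expects
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n
}

ess_from_splits <- function(sm) {
  n <- nrow(sm); m <- ncol(sm)
  if (n < 4L) return(NA_real_)
  if (stats::var(as.vector(sm)) == 0) return(NA_real_)
  acov <- sapply(seq_len(m), function(jj) autocov_fft(sm[, jj]))
  mean_acov <- rowMeans(acov)
  cm <- colMeans(sm)
  var_plus <- mean_acov[1L] * n / (n - 1) + stats::var(cm)
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (mean_acov[1L] - mean_acov) / var_plus
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 0
  prev <- Inf
  t <- 1L
  while (t + 1L < n) {
    pair <- rho[t + 1L] + if (t + 2L <= n) rho[t + 2L] else 0
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n * log10(m * n))
}

#' Per-parameter convergence diagnostics
#'
#' Computes rank-normalized split-R-hat and bulk effective sample size for
#' every stored scalar parameter. Chains with zero variance (degenerate,
#' e.g. a parameter pinned by `fix`) are reported as `NA` rather than
#' crashing.
#'
#' @param fit A `gut_draws` object with at least 2 chains.
#' @return Data frame with columns `param`, `rhat`, `ess_bulk`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "gut_draws"))
  if (length(fit$draws) < 2L) stop("convergence diagnostics require >= 2 chains")
  pars <- fit$params
  rhat <- ess <- rep(NA_real_, length(pars))
  for (i in seq_along(pars)) {
    sm <- split_chains(fit$draws, pars[i])
    z <- matrix(rank_normal(as.vector(sm)), nrow(sm), ncol(sm))
    rhat[i] <- rhat_from_splits(z)
    ess[i] <- ess_from_splits(z)
  }
  data.frame(param = pars, rhat = rhat, ess_bulk = ess,
             stringsAsFactors = FALSE)
}

# Guard used by downstream summaries: posterior summaries refuse to run on
# a fit whose convergence flag failed, unless force = TRUE.
assert_converged <- function(fit, force = FALSE) {
  if (identical(fit$converged, FALSE) && !force) {
    stop("fit did not meet the convergence flag (rhat <= 1.01, bulk ESS >= 400); ",
         "rerun with more iterations or pass force = TRUE")
  }
  invisible(TRUE)
}
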