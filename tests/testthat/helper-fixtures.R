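# shared fixtures and independent oracles, all built in code

# deterministic two-group dataset with two covariates and some censoring
toy_grouped <- function(n = 25, seed = 401, censor_frac = 0.3) {
  set.seed(seed)
  av <- matrix(TRUE, 2, 2, dimnames = list(c("ga", "gb"), c("x1", "x2")))
  params <- list(beta = matrix(c(1, 0.6, 0, 0), 2, 2, dimnames = dimnames(av)),
                 beta0 = c(0.3, -0.2), sigma2 = 1)
  sim_dataset(params, av, n_per_group = n, censor_frac = censor_frac)
}

# numerical-integration oracle: one-sample KS p-value of draws against an
# unnormalized log-density integrated on a grid
ks_against_logdens <- function(draws, logdens, lower, upper,
                               n_grid = 20001) {
  grid <- seq(lower, upper, length.out = n_grid)
  ld <- logdens(grid)
  w <- exp(ld - max(ld))
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  Fhat <- approxfun(grid, cdf, yleft = 0, yright = 1)
  suppressWarnings(stats::ks.test(draws, Fhat)$p.value)
}

# truth indicators and coefficients drawn exactly from the model's prior
# hierarchy (sigma^2 and intercepts held at tame values)
draw_prior_truth <- function(I, L) {
  truth <- beta <- matrix(NA_real_, I, L)
  for (l in seq_len(L)) {
    pi_l <- rbeta(1, 1, 1)
    g <- rbinom(I, 1, pi_l)
    sm <- rnorm(1)
    sv <- 1 / rgamma(1, 5, rate = 1)
    truth[, l] <- g
    beta[, l] <- ifelse(g == 1, rnorm(I, sm, sqrt(sv)),
                        rnorm(I, 0, sqrt(1e-4)))
  }
  list(truth = truth, beta = beta)
}
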