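# Full-conditional update kernels of the Gibbs sampler, in R.
#
# These are the single source of truth for the conjugate algebra; the C++
# chain in src/gibbs.cpp implements the identical arithmetic and RNG call
# sequence, which the test suite verifies draw-for-draw.  All updates assume
# the log-normal AFT likelihood log y_ij ~ N(beta_0i + x' beta_i, sigma^2).

#' Draw from a normal distribution truncated below
#'
#' Inverse-CDF sampling in the well-conditioned regime; when the lower bound
#' sits more than 5 sd above the mean the inverse CDF underflows, so a
#' shifted-exponential rejection sampler (Robert's method) is used instead.
#'
#' @param n number of draws.
#' @param mu,sigma mean and sd of the untruncated normal (recycled).
#' @param lower lower truncation bound(s).
#' @return Numeric vector of draws, each `>= lower`.
#' @keywords internal
rtnorm_lower <- function(n, mu, sigma, lower) {
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lower <- rep_len(lower, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    a <- (lower[k] - mu[k]) / sigma[k]
    if (!is.finite(a)) stop("non-finite truncation bound")
    if (a < 5) {
      u <- runif(1, pnorm(a), 1)
      x <- qnorm(u)
    } else {
      lam <- (a + sqrt(a * a + 4)) / 2
      repeat {
        x <- a + rexp(1) / lam
        if (runif(1) < exp(-(x - lam)^2 / 2)) break
      }
    }
    out[k] <- mu[k] + sigma[k] * x
  }
  out
}

# conjugate normal posterior for one coefficient given its prior and the
# group's partial residuals: sxx = sum(x^2), sxe = sum(x * e) where e is the
# residual with this coefficient's own contribution added back
coef_posterior <- function(sxx, sxe, sigma2, prior_mean, prior_var) {
  v <- 1 / (sxx / sigma2 + 1 / prior_var)
  c(mean = v * (sxe / sigma2 + prior_mean / prior_var), var = v)
}

update_coefficient <- function(sxx, sxe, sigma2, prior_mean, prior_var) {
  p <- coef_posterior(sxx, sxe, sigma2, prior_mean, prior_var)
  rnorm(1, p[["mean"]], sqrt(p[["var"]]))
}

# P(gamma = 1 | beta, pi, slab, spike), evaluated via log densities so that
# spike densities of order exp(-1000) do not underflow the ratio
indicator_prob <- function(beta, pi, slab_mean, slab_var, spike_var) {
  logit <- log(pi) - log1p(-pi) +
    dnorm(beta, slab_mean, sqrt(slab_var), log = TRUE) -
    dnorm(beta, 0, sqrt(spike_var), log = TRUE)
  1 / (1 + exp(-logit))
}

update_indicator <- function(beta, pi, slab_mean, slab_var, spike_var) {
  if (pi >= 1) return(1L)
  if (pi <= 0) return(0L)
  p <- indicator_prob(beta, pi, slab_mean, slab_var, spike_var)
  as.integer(runif(1) < p)
}

# P(gamma = 1 | data, pi, slab, spike) with the coefficient integrated out
# of its conjugate normal posterior.  The sweep uses this partially
# collapsed update (gamma first, then beta | gamma): conditioning gamma on
# the current beta instead creates a near-absorbing spike state whenever
# the inferred slab sits far from zero, because a coefficient pinned at
# ~N(0, z^2) then has vanishing slab density.  Integrating beta out removes
# that pathology while leaving the stationary distribution unchanged.
indicator_prob_integrated <- function(sxx, sxe, sigma2, pi, slab_mean,
                                      slab_var, spike_var) {
  v1 <- 1 / (sxx / sigma2 + 1 / slab_var)
  m1 <- v1 * (sxe / sigma2 + slab_mean / slab_var)
  v0 <- 1 / (sxx / sigma2 + 1 / spike_var)
  m0 <- v0 * (sxe / sigma2)
  logbf <- 0.5 * (log(v1 / slab_var) - log(v0 / spike_var)) +
    0.5 * (m1^2 / v1 - slab_mean^2 / slab_var) - 0.5 * (m0^2 / v0)
  logit <- log(pi) - log1p(-pi) + logbf
  1 / (1 + exp(-logit))
}

update_indicator_integrated <- function(sxx, sxe, sigma2, pi, slab_mean,
                                        slab_var, spike_var) {
  if (pi >= 1) return(1L)
  if (pi <= 0) return(0L)
  p <- indicator_prob_integrated(sxx, sxe, sigma2, pi, slab_mean, slab_var,
                                 spike_var)
  as.integer(runif(1) < p)
}

# Beta(a + s, b + n - s) update for an inclusion probability, s slab
# indicators out of n groups carrying the covariate
update_inclusion_prob <- function(s, n, a = 1, b = 1) {
  rbeta(1, a + s, b + n - s)
}

# slab mean then slab variance given the coefficients currently in the slab;
# with no slab members both collapse to their priors (same code path)
update_slab_mean <- function(beta_slab, slab_var, tau2) {
  nA <- length(beta_slab)
  v <- 1 / (nA / slab_var + 1 / tau2)
  m <- v * (sum(beta_slab) / slab_var)
  rnorm(1, m, sqrt(v))
}

update_slab_var <- function(beta_slab, slab_mean, a1, a2) {
  ss <- sum((beta_slab - slab_mean)^2)
  1 / rgamma(1, a1 + length(beta_slab) / 2, rate = a2 + ss / 2)
}

update_slab <- function(beta_slab, slab_var, tau2, a1, a2) {
  new_mean <- update_slab_mean(beta_slab, slab_var, tau2)
  new_var <- update_slab_var(beta_slab, new_mean, a1, a2)
  c(mean = new_mean, var = new_var)
}

update_sigma2 <- function(rss, n, shape, rate) {
  1 / rgamma(1, shape + n / 2, rate = rate + rss / 2)
}

# ---------------------------------------------------------------------------
# Reference implementation of one full Gibbs sweep and a chain driver, used
# by the tests to pin down the C++ engine bit-for-bit.  `prep` and `state`
# have the layout produced by prepare_gibbs() / init_state() in fit.R.

gibbs_sweep_r <- function(state, prep, hyper, mode, fixed_pi = 0.5) {
  I <- prep$I; L <- prep$L; M <- prep$M
  sigma <- sqrt(state$sigma2)

  # 1. impute censored outcomes from their truncated-normal full conditional
  for (i in seq_len(I)) {
    cidx <- which(prep$cens[[i]])
    for (j in cidx) {
      mu <- state$y[[i]][j] - state$resid[[i]][j]
      draw <- rtnorm_lower(1, mu, sigma, prep$bound[[i]][j])
      state$y[[i]][j] <- draw
      state$resid[[i]][j] <- draw - mu
    }
  }

  # 2. indicators (coefficient integrated out) then coefficients
  for (m in seq_len(M)) {
    i <- prep$slot_group[m]; cc <- prep$slot_col[m]; l <- prep$slot_cov[m]
    x <- prep$X[[i]][, cc]
    b_old <- state$beta[m]
    sxe <- sum(x * state$resid[[i]]) + prep$sxx[m] * b_old
    if (mode != 3L) {
      p_l <- switch(as.character(mode),
                    "0" = state$pi[l], "1" = fixed_pi, "2" = state$pi[1])
      state$gamma[m] <- update_indicator_integrated(
        prep$sxx[m], sxe, state$sigma2, p_l, state$slab_mean[l],
        state$slab_var[l], hyper$spike_var)
    }
    g <- state$gamma[m]
    m0 <- if (g == 1L) state$slab_mean[l] else 0
    v0 <- if (g == 1L) state$slab_var[l] else hyper$spike_var
    b_new <- update_coefficient(prep$sxx[m], sxe, state$sigma2, m0, v0)
    state$resid[[i]] <- state$resid[[i]] + x * (b_old - b_new)
    state$beta[m] <- b_new
  }

  # 3. inclusion probabilities
  if (mode == 0L) {
    for (l in seq_len(L)) {
      sl <- prep$cov_slots[[l]]
      s <- sum(state$gamma[sl])
      state$pi[l] <- update_inclusion_prob(s, length(sl),
                                           hyper$pi_shape1, hyper$pi_shape2)
    }
  } else if (mode == 2L) {
    s <- sum(state$gamma)
    state$pi[1] <- update_inclusion_prob(s, M, hyper$pi_shape1, hyper$pi_shape2)
  }

  # 4. slab mean and variance per covariate
  for (l in seq_len(L)) {
    sl <- prep$cov_slots[[l]]
    A <- sl[state$gamma[sl] == 1L]
    upd <- update_slab(state$beta[A], state$slab_var[l],
                       hyper$slab_mean_var, hyper$slab_var_shape,
                       hyper$slab_var_rate)
    state$slab_mean[l] <- upd[["mean"]]
    state$slab_var[l] <- upd[["var"]]
  }

  # 5. group intercepts, then their hypermean and hypervariance
  for (i in seq_len(I)) {
    ni <- prep$n_i[i]
    esum <- sum(state$resid[[i]]) + ni * state$beta0[i]
    v <- 1 / (ni / state$sigma2 + 1 / state$b0_var)
    mn <- v * (esum / state$sigma2 + state$b0_mean / state$b0_var)
    b_new <- rnorm(1, mn, sqrt(v))
    state$resid[[i]] <- state$resid[[i]] + (state$beta0[i] - b_new)
    state$beta0[i] <- b_new
  }
  v <- 1 / (I / state$b0_var + 1 / hyper$intercept_mean_var)
  mn <- v * sum(state$beta0) / state$b0_var
  state$b0_mean <- rnorm(1, mn, sqrt(v))
  ss <- sum((state$beta0 - state$b0_mean)^2)
  state$b0_var <- 1 / rgamma(1, hyper$intercept_var_shape + I / 2,
                             rate = hyper$intercept_var_rate + ss / 2)

  # 6. shared error variance
  rss <- sum(vapply(state$resid, function(r) sum(r * r), numeric(1)))
  state$sigma2 <- update_sigma2(rss, prep$N, hyper$sigma_shape,
                                hyper$sigma_rate)
  state
}

gibbs_chain_r <- function(prep, hyper, init, iterations, burnin, thin,
                          mode, fixed_pi = 0.5) {
  state <- init
  keep <- integer(0)
  draws <- list(beta0 = NULL, beta = NULL, gamma = NULL, pi = NULL,
                slab_mean = NULL, slab_var = NULL, b0_mean = NULL,
                b0_var = NULL, sigma2 = NULL)
  Tn <- (iterations - burnin) %/% thin
  npi <- if (mode == 0L) prep$L else if (mode == 2L) 1L else 0L
  draws$beta0 <- matrix(0, Tn, prep$I)
  draws$beta <- matrix(0, Tn, prep$M)
  draws$gamma <- matrix(0L, Tn, prep$M)
  draws$pi <- matrix(0, Tn, npi)
  draws$slab_mean <- matrix(0, Tn, prep$L)
  draws$slab_var <- matrix(0, Tn, prep$L)
  draws$b0_mean <- numeric(Tn)
  draws$b0_var <- numeric(Tn)
  draws$sigma2 <- numeric(Tn)
  t <- 0L
  for (it in seq_len(iterations)) {
    state <- gibbs_sweep_r(state, prep, hyper, mode, fixed_pi)
    if (it > burnin && (it - burnin) %% thin == 0L) {
      t <- t + 1L
      draws$beta0[t, ] <- state$beta0
      if (prep$M) {
        draws$beta[t, ] <- state$beta
        draws$gamma[t, ] <- state$gamma
      }
      if (npi) draws$pi[t, ] <- state$pi[seq_len(npi)]
      if (prep$L) {
        draws$slab_mean[t, ] <- state$slab_mean
        draws$slab_var[t, ] <- state$slab_var
      }
      draws$b0_mean[t] <- state$b0_mean
      draws$b0_var[t] <- state$b0_var
      draws$sigma2[t] <- state$sigma2
    }
  }
  draws$final <- state
  draws
}
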