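# kernels accessed via ::: — they are sampler internals with a documented
# contract, pinned here against closed forms and numerical-integration oracles

test_that("the coefficient posterior matches the conjugate closed form", {
  # one observation, x = 1, partial residual 1, sigma^2 = 1, slab N(0, 1)
  p <- ssaft:::coef_posterior(sxx = 1, sxe = 1, sigma2 = 1,
                              prior_mean = 0, prior_var = 1)
  expect_equal(unname(p), c(0.5, 0.5))
  # same data under the spike: precision 10^4 dominates
  p2 <- ssaft:::coef_posterior(1, 1, 1, 0, 1e-4)
  expect_equal(unname(p2), c(1 / 10001, 1 / 10001))
  # no information (all x zero): posterior equals the prior
  p3 <- ssaft:::coef_posterior(0, 0, 1, 0.7, 2.5)
  expect_equal(unname(p3), c(0.7, 2.5))
  # the draw is the posterior normal under the same RNG state
  set.seed(1); d1 <- ssaft:::update_coefficient(1, 1, 1, 0, 1)
  set.seed(1); d2 <- rnorm(1, 0.5, sqrt(0.5))
  expect_identical(d1, d2)
})

test_that("indicator probabilities given beta follow the two-density ratio", {
  # beta = 0: spike density is 100x the slab density, so p = 1/101
  expect_equal(ssaft:::indicator_prob(0, 0.5, 0, 1, 1e-4), 1 / 101)
  # away from zero the spike vanishes
  expect_gt(ssaft:::indicator_prob(0.5, 0.5, 0, 1, 1e-4), 1 - 1e-10)
  # degenerate prior probabilities are deterministic
  expect_identical(ssaft:::update_indicator(0, 1, 0, 1, 1e-4), 1L)
  expect_identical(ssaft:::update_indicator(5, 0, 0, 1, 1e-4), 0L)
})

test_that("the integrated indicator probability matches numerical integration", {
  set.seed(7)
  x <- rnorm(6); e <- rnorm(6, 0.4 * x, 1)
  sxx <- sum(x^2); sxe <- sum(x * e)
  sigma2 <- 0.8; pi <- 0.4; sm <- 0.6; sv <- 0.5; z2 <- 1e-4
  marg <- function(m0, v0) {
    # integrate the likelihood of e against the coefficient prior on a grid
    b <- seq(-6, 6, length.out = 40001)
    lik <- vapply(b, function(bb)
      exp(-0.5 * sum((e - x * bb)^2) / sigma2), numeric(1))
    sum(lik * dnorm(b, m0, sqrt(v0))) * diff(b[1:2])
  }
  p_num <- pi * marg(sm, sv) / (pi * marg(sm, sv) + (1 - pi) * marg(0, z2))
  p_ana <- ssaft:::indicator_prob_integrated(sxx, sxe, sigma2, pi, sm, sv, z2)
  expect_equal(p_ana, p_num, tolerance = 1e-6)
  # no information: the prior inclusion probability comes back
  expect_equal(ssaft:::indicator_prob_integrated(0, 0, 1, 0.3, 1, 0.5, 1e-4),
               0.3, tolerance = 1e-12)
})

test_that("inclusion probabilities update by conjugate Beta counting", {
  set.seed(2); d1 <- ssaft:::update_inclusion_prob(s = 2, n = 4)
  set.seed(2); expect_identical(d1, rbeta(1, 3, 3))
  set.seed(3); d2 <- ssaft:::update_inclusion_prob(s = 5, n = 5)
  set.seed(3); expect_identical(d2, rbeta(1, 6, 1))   # mean 6/7
  set.seed(4); d3 <- ssaft:::update_inclusion_prob(s = 0, n = 1)
  set.seed(4); expect_identical(d3, rbeta(1, 1, 2))   # mean 1/3
})

test_that("slab mean and variance updates follow their conjugate forms", {
  # one slab member beta = 2, slab var 1, tau^2 = 1 -> posterior N(1, 0.5)
  set.seed(5); m <- ssaft:::update_slab_mean(2, 1, 1)
  set.seed(5); expect_identical(m, rnorm(1, 1, sqrt(0.5)))
  # two members equal to the slab mean -> IG(5 + 1, 1 + 0)
  set.seed(6); v <- ssaft:::update_slab_var(c(0.4, 0.4), 0.4, 5, 1)
  set.seed(6); expect_identical(v, 1 / rgamma(1, 6, rate = 1))
  # empty slab: draws come from the priors; IG(5,1) has mean 1/4
  set.seed(8)
  draws <- replicate(10000, ssaft:::update_slab(numeric(0), 0.25, 1, 5, 1))
  expect_lt(abs(mean(draws["var", ]) - 0.25), 0.01)
  expect_lt(abs(mean(draws["mean", ])), 0.04)
  expect_lt(abs(var(draws["mean", ]) - 1), 0.05)
})

test_that("the error-variance update is the pooled inverse-gamma", {
  set.seed(9); s2 <- ssaft:::update_sigma2(rss = 2, n = 2,
                                           shape = 0.01, rate = 0.01)
  set.seed(9); expect_identical(s2, 1 / rgamma(1, 1.01, rate = 1.01))
  # precision draws have mean shape/rate = 1 here
  set.seed(10)
  prec <- replicate(20000, 1 / ssaft:::update_sigma2(2, 2, 0.01, 0.01))
  expect_lt(abs(mean(prec) - 1), 0.03)
})

test_that("truncated-normal imputation draws respect the bound everywhere", {
  set.seed(11)
  for (a in c(-10, -1, 0, 3, 4.9, 5.5, 8, 20)) {
    d <- ssaft:::rtnorm_lower(2000, mu = 0, sigma = 1, lower = a)
    expect_true(all(d >= a))
  }
  expect_error(ssaft:::rtnorm_lower(1, 0, 1, NaN), "bound")
})

test_that("truncated-normal moments match the closed form", {
  set.seed(12)
  # bound at the mean: E[X] = mu + sigma * phi(0)/(1 - Phi(0)) = mu + 0.7979
  d <- ssaft:::rtnorm_lower(40000, mu = 2, sigma = 1, lower = 2)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (2 + sqrt(2 / pi))), 4 * se)
  # bound 10 sd below the mean: truncation negligible
  d2 <- ssaft:::rtnorm_lower(10000, mu = 5, sigma = 0.5, lower = 0)
  expect_lt(abs(mean(d2) - 5), 4 * 0.5 / sqrt(10000))
})

test_that("the C++ truncated-normal sampler is the R sampler, draw for draw", {
  for (a in c(-2, 0, 4.99, 5.01, 12)) {
    set.seed(13); rd <- ssaft:::rtnorm_lower(500, 1, 2, a)
    set.seed(13); cd <- ssaft:::.rtnorm_lower_cpp(500, 1, 2, a)
    expect_identical(rd, cd)
  }
})

test_that("conjugate full-conditional draws match numerical-integration
           oracles (KS at alpha = 0.001)", {
  set.seed(14)
  x <- rnorm(8); e <- rnorm(8, 0.5 * x, 0.9)
  sxx <- sum(x^2); sxe <- sum(x * e)

  # coefficient under the slab prior
  d_coef <- replicate(8000, ssaft:::update_coefficient(sxx, sxe, 0.81,
                                                       0.3, 0.6))
  p <- ks_against_logdens(d_coef, function(b)
    dnorm(b, 0.3, sqrt(0.6), log = TRUE) -
      0.5 * (sxx * b^2 - 2 * sxe * b) / 0.81, -4, 4)
  expect_gt(p, 0.001)

  # error variance given residuals
  d_s2 <- replicate(8000, ssaft:::update_sigma2(rss = 3.7, n = 12,
                                                shape = 0.01, rate = 0.01))
  p <- ks_against_logdens(d_s2, function(v)
    -(0.01 + 6 + 1) * log(v) - (0.01 + 3.7 / 2) / v, 0.02, 6)
  expect_gt(p, 0.001)

  # slab mean given three slab members
  bA <- c(0.4, -0.1, 0.7)
  d_sm <- replicate(8000, ssaft:::update_slab_mean(bA, 0.3, 1))
  p <- ks_against_logdens(d_sm, function(m)
    dnorm(m, 0, 1, log = TRUE) +
      vapply(m, function(mm) -0.5 * sum((bA - mm)^2) / 0.3, numeric(1)),
    -4, 4)
  expect_gt(p, 0.001)

  # slab variance given members and mean
  d_sv <- replicate(8000, ssaft:::update_slab_var(bA, 0.2, 5, 1))
  ssq <- sum((bA - 0.2)^2)
  p <- ks_against_logdens(d_sv, function(v)
    -(5 + 1.5 + 1) * log(v) - (1 + ssq / 2) / v, 0.01, 3)
  expect_gt(p, 0.001)

  # inclusion probability with s = 3 of n = 7
  d_pi <- replicate(8000, ssaft:::update_inclusion_prob(3, 7))
  p <- ks_against_logdens(d_pi, function(q) 3 * log(q) + 4 * log1p(-q),
                          1e-6, 1 - 1e-6)
  expect_gt(p, 0.001)

  # truncated normal against its explicit density
  d_tn <- ssaft:::rtnorm_lower(8000, 0.5, 1.2, 1)
  p <- ks_against_logdens(d_tn, function(z)
    ifelse(z >= 1, dnorm(z, 0.5, 1.2, log = TRUE), -Inf), 1, 8)
  expect_gt(p, 0.001)
})
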