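test_that("the compiled chain reproduces the R reference sweep bit for bit", {
  d <- toy_grouped(n = 20, seed = 55, censor_frac = 0.4)
  hyper <- ssaft_hyper()
  prep <- ssaft:::prepare_gibbs(d)
  for (mode in 0:3) {
    set.seed(77)
    init <- ssaft:::init_state(prep, hyper, mode)
    out_cpp <- ssaft:::.gibbs_chain_cpp(
      prep$y, prep$cens, prep$bound, prep$X, prep$n_i, prep$slot_group,
      prep$slot_col, prep$slot_cov, prep$sxx, prep$cov_slots, prep$L,
      unclass(hyper), init, 150L, 50L, 2L, mode, 0.5)
    set.seed(77)
    init2 <- ssaft:::init_state(prep, hyper, mode)
    out_r <- ssaft:::gibbs_chain_r(prep, hyper, init2, 150L, 50L, 2L,
                                   mode, 0.5)
    for (nm in c("beta0", "beta", "pi", "slab_mean", "slab_var",
                 "sigma2", "b0_mean", "b0_var"))
      expect_identical(as.vector(out_cpp[[nm]]), as.vector(out_r[[nm]]),
                       label = paste0(nm, " (mode ", mode, ")"))
    expect_identical(as.vector(out_cpp$gamma), as.vector(out_r$gamma))
  }
})

test_that("identical seeds give bit-identical fits; different seeds differ", {
  d <- toy_grouped(n = 15, seed = 60)
  ch <- ssaft_chain(300, 100, 2)
  f1 <- ssaft(d, "hierarchical", chain = ch, seed = 5)
  f2 <- ssaft(d, "hierarchical", chain = ch, seed = 5)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$gamma_hat, f2$gamma_hat)
  f3 <- ssaft(d, "hierarchical", chain = ch, seed = 6)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("imputed censored outcomes always sit above their bounds", {
  d <- toy_grouped(n = 30, seed = 61, censor_frac = 0.6)
  fit <- ssaft(d, "hierarchical", chain = ssaft_chain(200, 100, 2), seed = 9)
  prep <- ssaft:::prepare_gibbs(d)
  for (i in seq_along(prep$y)) {
    ci <- prep$cens[[i]]
    expect_true(all(fit$draws$final_y[[i]][ci] >= prep$bound[[i]][ci]))
  }
})

test_that("the null variant reports intercepts and error variance only", {
  d <- toy_grouped(n = 15, seed = 62)
  fit <- ssaft(d, "null", chain = ssaft_chain(300, 100, 2), seed = 1)
  expect_true(all(fit$gamma_hat[fit$availability] == 0))
  s <- summary(fit)
  expect_true(all(is.na(s$mean_effect)))
  expect_length(fit$intercept_mean, 2)
  expect_true(is.finite(fit$sigma2_mean))
})

test_that("with no covariates and no censoring the posterior tracks the
           closed-form normal-inverse-gamma limit", {
  set.seed(63)
  logy <- rnorm(600, 1.7, 0.8)
  d <- grouped_survival(data.frame(group = "g", time = exp(logy), event = 1))
  fit <- ssaft(d, "null", chain = ssaft_chain(2000, 500, 3), seed = 2)
  # intercept posterior concentrates on the sample mean of the log times
  expect_lt(abs(fit$intercept_mean - mean(logy)), 4 * 0.8 / sqrt(600))
  # sigma^2 posterior mean near (0.01 + RSS/2) / (0.01 + N/2 - 1)
  rss <- sum((logy - mean(logy))^2)
  expect_lt(abs(fit$sigma2_mean - (0.01 + rss / 2) / (0.01 + 300 - 1)),
            0.02)
})

test_that("per-covariate and pooled inclusion updates satisfy the
           Rao-Blackwell Beta identity", {
  d <- toy_grouped(n = 40, seed = 64)
  ch <- ssaft_chain(2000, 500, 3)
  fit <- ssaft(d, "hierarchical", chain = ch, seed = 3)
  sl <- fit$slots
  for (l in seq_along(fit$covariates)) {
    cols <- which(sl$covariate == fit$covariates[l])
    s_t <- rowSums(fit$draws$gamma[, cols, drop = FALSE])
    # E[pi | gamma] = (1 + s) / (2 + n_l); chain averages must agree
    expect_lt(abs(mean(fit$draws$pi[, l]) -
                    mean((1 + s_t) / (2 + length(cols)))), 0.02)
  }
  fsh <- ssaft(d, "shared", chain = ch, seed = 4)
  expect_equal(ncol(fsh$draws$pi), 1L)
  s_t <- rowSums(fsh$draws$gamma)
  expect_lt(abs(mean(fsh$draws$pi) - mean((1 + s_t) / (2 + d$M))), 0.02)
})

test_that("a strong signal is recovered: active slots selected, null not", {
  set.seed(65)
  av <- matrix(TRUE, 3, 2, dimnames = list(c("a", "b", "c"), c("x1", "x2")))
  params <- list(beta = matrix(c(2, 2, 2, 0, 0, 0), 3, 2,
                               dimnames = dimnames(av)),
                 beta0 = c(0, 0, 0), sigma2 = 1)
  d <- sim_dataset(params, av, n_per_group = 200, censor_frac = 0)
  fit <- ssaft(d, "hierarchical", chain = ssaft_chain(2000, 1000, 10),
               seed = 2)
  expect_true(all(fit$gamma_hat[, "x1"] > 0.9))
  expect_true(all(fit$gamma_hat[, "x2"] < 0.5))
})

test_that("successive-conditional simulation returns the prior marginals
           (joint-correctness check)", {
  set.seed(66)
  I <- 2; n <- 5; L <- 2
  av <- matrix(TRUE, I, L, dimnames = list(paste0("g", 1:I),
                                           paste0("x", 1:L)))
  hy <- ssaft_hyper(sigma_shape = 3, sigma_rate = 3, intercept_mean_var = 1,
                    intercept_var_shape = 3, intercept_var_rate = 3)
  X <- matrix(rnorm(I * n * L), I * n, L)
  cens_bound <- rep(0.5, I * n)
  df0 <- data.frame(group = rep(paste0("g", 1:I), each = n), time = 1,
                    event = 1, x1 = X[, 1], x2 = X[, 2])
  prep <- ssaft:::prepare_gibbs(grouped_survival(df0, availability = av))

  th <- list(pi = rbeta(L, 1, 1), slab_mean = rnorm(L),
             slab_var = 1 / rgamma(L, 5, rate = 1),
             b0_mean = rnorm(1), b0_var = 1 / rgamma(1, 3, rate = 3),
             sigma2 = 1 / rgamma(1, 3, rate = 3))
  th$gamma <- matrix(rbinom(I * L, 1, rep(th$pi, each = I)), I, L)
  th$beta <- matrix(0, I, L)
  for (l in 1:L) th$beta[, l] <- ifelse(th$gamma[, l] == 1,
    rnorm(I, th$slab_mean[l], sqrt(th$slab_var[l])), rnorm(I, 0, 1e-2))
  th$beta0 <- rnorm(I, th$b0_mean, sqrt(th$b0_var))

  ncycle <- 2500
  rec <- matrix(NA_real_, ncycle, 6)
  for (cy in seq_len(ncycle)) {
    ylat <- numeric(I * n)
    for (i in 1:I) {
      rows <- (i - 1) * n + 1:n
      mfit <- th$beta0[i] + X[rows, , drop = FALSE] %*% th$beta[i, ]
      ylat[rows] <- rnorm(n, mfit, sqrt(th$sigma2))
    }
    cens <- ylat > cens_bound
    yobs <- ifelse(cens, cens_bound, ylat)
    state <- list(y = list(), resid = list(), beta0 = th$beta0,
                  beta = numeric(prep$M), gamma = integer(prep$M),
                  pi = th$pi, slab_mean = th$slab_mean,
                  slab_var = th$slab_var, b0_mean = th$b0_mean,
                  b0_var = th$b0_var, sigma2 = th$sigma2)
    for (m in seq_len(prep$M)) {
      state$beta[m] <- th$beta[prep$slot_group[m], prep$slot_cov[m]]
      state$gamma[m] <- th$gamma[prep$slot_group[m], prep$slot_cov[m]]
    }
    for (i in 1:I) {
      rows <- (i - 1) * n + 1:n
      mfit <- th$beta0[i] + X[rows, , drop = FALSE] %*% th$beta[i, ]
      state$y[[i]] <- ylat[rows]
      state$resid[[i]] <- ylat[rows] - drop(mfit)
      prep$y[[i]] <- yobs[rows]
      prep$cens[[i]] <- cens[rows]
      prep$bound[[i]] <- yobs[rows]
    }
    for (s in 1:3) state <- ssaft:::gibbs_sweep_r(state, prep, hy, 0L, 0.5)
    th$pi <- state$pi; th$slab_mean <- state$slab_mean
    th$slab_var <- state$slab_var; th$beta0 <- state$beta0
    th$b0_mean <- state$b0_mean; th$b0_var <- state$b0_var
    th$sigma2 <- state$sigma2
    for (m in seq_len(prep$M)) {
      th$beta[prep$slot_group[m], prep$slot_cov[m]] <- state$beta[m]
      th$gamma[prep$slot_group[m], prep$slot_cov[m]] <- state$gamma[m]
    }
    rec[cy, ] <- c(state$pi[1], state$slab_mean[1], mean(state$gamma),
                   state$sigma2, state$b0_var, state$slab_var[1])
  }
  expect_lt(abs(mean(rec[, 1]) - 0.5), 0.04)          # pi ~ Beta(1,1)
  expect_lt(abs(var(rec[, 1]) - 1 / 12), 0.012)
  expect_lt(abs(mean(rec[, 2])), 0.12)                # slab mean ~ N(0,1)
  expect_lt(abs(var(rec[, 2]) - 1), 0.2)
  expect_lt(abs(mean(rec[, 3]) - 0.5), 0.04)          # gamma ~ Bern(pi)
  expect_lt(abs(mean(rec[, 4]) - 1.5), 0.2)           # sigma^2 ~ IG(3,3)
  expect_lt(abs(mean(rec[, 5]) - 1.5), 0.2)           # lambda0^2 ~ IG(3,3)
  expect_lt(abs(mean(rec[, 6]) - 0.25), 0.03)         # slab var ~ IG(5,1)
})
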