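#' Fit a hierarchical spike-and-slab log-normal AFT model
#'
#' Fits a Bayesian accelerated failure time model to grouped survival data:
#' log survival time is normal with a group-specific intercept and
#' group-specific covariate effects, a shared error variance, and a
#' spike-and-slab prior on every coefficient.  Slab means and variances are
#' inferred hierarchically from the groups in which a covariate is included,
#' and covariate-level inclusion probabilities borrow strength across groups.
#' Right-censored outcomes are imputed from their truncated-normal full
#' conditional inside the Gibbs sweep.  Comparison variants of the model
#' (see [make_variant()]) reuse the same engine.
#'
#' One Gibbs sweep updates, in order: imputed censored outcomes;
#' coefficients and inclusion indicators (covariate-major order); inclusion
#' probabilities; slab means and variances; group intercepts with their
#' hypermean and hypervariance; the error variance.
#'
#' @param data a [grouped_survival()] object (predictors are expected on a
#'   standardized scale; see [standardize_predictors()]).
#' @param variant one of [ssaft_variants()].
#' @param hyper prior settings, see [ssaft_hyper()].
#' @param chain MCMC settings, see [ssaft_chain()].
#' @param seed RNG seed; the same seed yields a bit-identical fit.  Falls
#'   back to `chain$seed`; when both are `NULL` the current RNG state is
#'   used.
#' @param fixed_pi inclusion probability for the `fixed_0.5` variant.
#' @return An object of class `ssaft`; see Details.  Key components:
#'   `gamma_hat` (posterior inclusion probabilities, groups x covariates,
#'   `NA` where a covariate is unavailable), `coef_mean` / `ci_lower` /
#'   `ci_upper` (posterior means and central 95% credible intervals),
#'   `draws` (retained chain draws) and `summary(fit)` (a selection table
#'   ordered by inclusion probability).
#' @export
ssaft <- function(data, variant = "hierarchical", hyper = ssaft_hyper(),
                  chain = ssaft_chain(), seed = NULL, fixed_pi = 0.5) {
  stopifnot(inherits(data, "grouped_survival"))
  cl <- match.call()
  v <- make_variant(variant, fixed_pi)
  if (is.null(seed)) seed <- chain$seed
  if (!is.null(seed)) set.seed(seed)

  if (v$structure == "separate") {
    subfits <- lapply(data$groups, function(g) {
      sub <- subset_groups(data, g)
      fit_engine(sub, hyper, chain, make_variant("hierarchical"))
    })
    names(subfits) <- data$groups
    gamma_hat <- coef_mean <- ci_lower <- ci_upper <-
      empty_report_matrix(data)
    for (g in data$groups) {
      f <- subfits[[g]]
      covs <- colnames(f$gamma_hat)
      gamma_hat[g, covs] <- f$gamma_hat[1, ]
      coef_mean[g, covs] <- f$coef_mean[1, ]
      ci_lower[g, covs] <- f$ci_lower[1, ]
      ci_upper[g, covs] <- f$ci_upper[1, ]
    }
    fit <- list(subfits = subfits, gamma_hat = gamma_hat,
                coef_mean = coef_mean, ci_lower = ci_lower,
                ci_upper = ci_upper,
                intercept_mean = vapply(subfits, function(f)
                  unname(f$intercept_mean), numeric(1)),
                sigma2_mean = vapply(subfits, function(f) f$sigma2_mean,
                                     numeric(1)),
                draws = NULL)
  } else if (v$structure == "merged") {
    merged <- merge_groups(data)
    f <- fit_engine(merged, hyper, chain, v)
    gamma_hat <- coef_mean <- ci_lower <- ci_upper <-
      empty_report_matrix(data)
    for (l in data$covariates) {
      rows <- data$availability[, l]
      gamma_hat[rows, l] <- f$gamma_hat[1, l]
      coef_mean[rows, l] <- f$coef_mean[1, l]
      ci_lower[rows, l] <- f$ci_lower[1, l]
      ci_upper[rows, l] <- f$ci_upper[1, l]
    }
    fit <- f
    fit$gamma_hat <- gamma_hat; fit$coef_mean <- coef_mean
    fit$ci_lower <- ci_lower; fit$ci_upper <- ci_upper
    fit$merged <- merged
  } else {
    workdata <- data
    if (v$strip_covariates) {
      df <- data$data[, c("group", "time", "event"), drop = FALSE]
      workdata <- grouped_survival(df)
    }
    fit <- fit_engine(workdata, hyper, chain, v)
    if (v$strip_covariates) {
      # intercept-only model: nothing is ever included
      fit$gamma_hat <- variant_gamma_hat("null", data$availability)
      fit$coef_mean <- fit$ci_lower <- fit$ci_upper <-
        empty_report_matrix(data)
    }
  }

  fit$call <- cl
  fit$variant <- v$name
  fit$data <- data
  fit$groups <- data$groups
  fit$covariates <- data$covariates
  fit$availability <- data$availability
  fit$hyper <- hyper
  fit$chain <- chain
  fit$seed <- seed
  class(fit) <- "ssaft"
  fit
}

empty_report_matrix <- function(data) {
  m <- matrix(NA_real_, length(data$groups), length(data$covariates),
              dimnames = list(data$groups, data$covariates))
  m
}

# layout of one dataset for the sampler: per-group outcome vectors, design
# matrices, and the covariate-major slot table shared with the C++ engine
prepare_gibbs <- function(data) {
  I <- length(data$groups)
  covs <- data$covariates
  L <- length(covs)
  avail <- data$availability
  y <- cens <- bound <- X <- avail_idx <- vector("list", I)
  for (i in seq_len(I)) {
    rows <- which(data$data$group == data$groups[i])
    ylog <- log(data$data$time[rows])
    y[[i]] <- ylog
    cens[[i]] <- data$data$event[rows] == 0
    bound[[i]] <- ylog
    idx <- which(avail[i, ])
    avail_idx[[i]] <- idx
    X[[i]] <- if (length(idx))
      as.matrix(data$data[rows, covs[idx], drop = FALSE])
    else matrix(0, length(rows), 0)
  }
  M <- sum(avail)
  slot_group <- slot_cov <- slot_col <- integer(M)
  m <- 0L
  for (l in seq_len(L)) for (i in seq_len(I)) {
    if (avail[i, l]) {
      m <- m + 1L
      slot_group[m] <- i
      slot_cov[m] <- l
      slot_col[m] <- match(l, avail_idx[[i]])
    }
  }
  sxx <- numeric(M)
  for (m in seq_len(M))
    sxx[m] <- sum(X[[slot_group[m]]][, slot_col[m]]^2)
  cov_slots <- lapply(seq_len(L), function(l) which(slot_cov == l))
  list(I = I, L = L, M = M, N = nrow(data$data),
       n_i = as.integer(unname(data$n_i)),
       y = y, cens = cens, bound = bound, X = X,
       slot_group = slot_group, slot_cov = slot_cov, slot_col = slot_col,
       sxx = sxx, cov_slots = cov_slots, groups = data$groups,
       covariates = covs, availability = avail)
}

# deterministic initial state, except gamma ~ Bernoulli(0.5) (seed-governed)
init_state <- function(prep, hyper, mode) {
  beta0 <- vapply(prep$y, mean, numeric(1))
  sigma2 <- if (prep$N > 1) var(unlist(prep$y)) else 1
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  slab_var0 <- if (hyper$slab_var_shape > 1)
    hyper$slab_var_rate / (hyper$slab_var_shape - 1) else 1
  gamma <- if (prep$M == 0L) integer(0)
  else if (mode == 3L) rep(1L, prep$M)
  else as.integer(runif(prep$M) < 0.5)
  yinit <- prep$y
  resid <- vector("list", prep$I)
  for (i in seq_len(prep$I)) {
    ci <- prep$cens[[i]]
    yinit[[i]][ci] <- prep$bound[[i]][ci] + 0.01
    resid[[i]] <- yinit[[i]] - beta0[i]
  }
  list(y = yinit, resid = resid, beta0 = beta0,
       beta = rep(0, prep$M), gamma = gamma,
       pi = rep(0.5, max(prep$L, 1L))[seq_len(prep$L)],
       slab_mean = rep(0, prep$L), slab_var = rep(slab_var0, prep$L),
       b0_mean = mean(beta0), b0_var = 1, sigma2 = sigma2)
}

fit_engine <- function(workdata, hyper, chain, v) {
  prep <- prepare_gibbs(workdata)
  init <- init_state(prep, hyper, v$mode)
  out <- .gibbs_chain_cpp(prep$y, prep$cens, prep$bound, prep$X,
                          prep$n_i, prep$slot_group, prep$slot_col,
                          prep$slot_cov, prep$sxx, prep$cov_slots,
                          prep$L, unclass(hyper), init,
                          chain$iterations, chain$burnin, chain$thin,
                          v$mode, v$fixed_pi)
  build_fit(out, prep, workdata, chain)
}

build_fit <- function(out, prep, workdata, chain) {
  Tn <- chain$T
  gamma_hat <- coef_mean <- ci_lower <- ci_upper <-
    empty_report_matrix(workdata)
  if (prep$M) {
    g_mean <- colMeans(out$gamma)
    b_mean <- colMeans(out$beta)
    qs <- apply(out$beta, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    for (m in seq_len(prep$M)) {
      i <- prep$slot_group[m]; l <- prep$slot_cov[m]
      gamma_hat[i, l] <- g_mean[m]
      coef_mean[i, l] <- b_mean[m]
      ci_lower[i, l] <- qs[1, m]
      ci_upper[i, l] <- qs[2, m]
    }
  }
  colnames(out$beta0) <- prep$groups
  slots <- data.frame(slot = seq_len(prep$M),
                      covariate = prep$covariates[prep$slot_cov],
                      group = prep$groups[prep$slot_group],
                      stringsAsFactors = FALSE)
  list(draws = out, slots = slots, gamma_hat = gamma_hat,
       coef_mean = coef_mean, ci_lower = ci_lower, ci_upper = ci_upper,
       intercept_mean = colMeans(out$beta0),
       sigma2_mean = mean(out$sigma2),
       fit_groups = prep$groups, fit_availability = prep$availability)
}

#' @export
print.ssaft <- function(x, ...) {
  cat("Hierarchical spike-and-slab AFT fit (variant: ", x$variant, ")\n",
      sep = "")
  cat("  ", nrow(x$data$data), " subjects, ", length(x$groups),
      " group(s), ", length(x$covariates), " covariate(s), M = ",
      x$data$M, " coefficient slots\n", sep = "")
  cat("  chain: ", x$chain$iterations, " iterations, burn-in ",
      x$chain$burnin, ", thin ", x$chain$thin, " (", x$chain$T,
      " retained draws)\n", sep = "")
  if (!is.null(x$sigma2_mean))
    cat("  posterior mean error variance: ",
        signif(mean(x$sigma2_mean), 4), "\n", sep = "")
  sel <- summary(x)
  sel <- sel[sel$incl_prob > 0.5 & !is.na(sel$incl_prob), , drop = FALSE]
  cat("  covariate-group pairs with inclusion probability > 0.5: ",
      nrow(sel), "\n", sep = "")
  invisible(x)
}

#' Selection summary of a fitted model
#'
#' One row per available (covariate, group) pair: posterior mean effect,
#' central 95% credible interval and posterior inclusion probability
#' (the average of the pair's inclusion indicators over retained draws),
#' ordered by decreasing inclusion probability.
#'
#' @param object an `ssaft` fit.
#' @param ... unused.
#' @export
summary.ssaft <- function(object, ...) {
  av <- object$availability
  idx <- which(av, arr.ind = TRUE)
  out <- data.frame(
    covariate = colnames(av)[idx[, 2]],
    group = rownames(av)[idx[, 1]],
    mean_effect = object$coef_mean[idx],
    ci_lower = object$ci_lower[idx],
    ci_upper = object$ci_upper[idx],
    incl_prob = object$gamma_hat[idx],
    stringsAsFactors = FALSE)
  out <- out[order(-out$incl_prob, out$covariate, out$group), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary.ssaft", "data.frame")
  out
}

#' @export
coef.ssaft <- function(object, ...) {
  list(intercepts = object$intercept_mean,
       coefficients = object$coef_mean)
}

#' @export
residuals.ssaft <- function(object, ...) {
  lp <- predict(object, type = "lp")
  r <- log(object$data$data$time) - lp
  attr(r, "censored") <- object$data$data$event == 0
  r
}

#' Posterior-mean predictions from a fitted model
#'
#' @param object an `ssaft` fit.
#' @param newdata a `grouped_survival` on the same covariate scale as the
#'   training data; defaults to the training data.
#' @param type `"lp"` for the expected log survival time (the linear
#'   predictor at the posterior means) or `"time"` for the corresponding
#'   median survival time `exp(lp)`.
#' @param ... unused.
#' @export
predict.ssaft <- function(object, newdata = NULL, type = c("lp", "time"),
                          ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  stopifnot(inherits(newdata, "grouped_survival"))
  df <- newdata$data
  unknown <- setdiff(unique(df$group), object$groups)
  if (length(unknown))
    stop("test subjects from group(s) absent in training: ",
         paste(unknown, collapse = ", "))
  lp <- numeric(nrow(df))
  intercepts <- object$intercept_mean
  if (object$variant == "joint") intercepts <- rep(
    unname(intercepts[1]), length(object$groups)) |> setNames(object$groups)
  for (g in unique(df$group)) {
    rows <- which(df$group == g)
    covs <- object$covariates[!is.na(object$coef_mean[g, ])]
    lp[rows] <- intercepts[[g]]
    if (length(covs)) {
      Xg <- as.matrix(df[rows, covs, drop = FALSE])
      Xg[is.na(Xg)] <- 0
      lp[rows] <- lp[rows] + drop(Xg %*% object$coef_mean[g, covs])
    }
  }
  if (type == "lp") lp else exp(lp)
}

#' Simulate survival times from the posterior predictive distribution
#'
#' For each simulation a retained posterior draw is selected at random and
#' log survival times are generated from the log-normal AFT likelihood at
#' that draw's parameters.
#'
#' @param object an `ssaft` fit.
#' @param nsim number of simulated datasets.
#' @param seed optional RNG seed.
#' @param newdata covariates to simulate for; defaults to the training data.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated survival times.
#' @export
simulate.ssaft <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                           ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$data
  lpd <- linpred_draws(object, newdata)
  n <- nrow(newdata$data)
  Tn <- length(lpd$sigma2)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    t <- sample.int(Tn, 1)
    for (k in seq_along(lpd$rows)) {
      rows <- lpd$rows[[k]]
      mu <- lpd$lp[[k]][, t]
      out[rows, s] <- exp(rnorm(length(rows), mu,
                                sqrt(lpd$sigma2_by[[k]][t])))
    }
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.ssaft <- function(x, which = c("trace", "inclusion"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    s2 <- if (is.null(x$draws)) x$subfits[[1]]$draws$sigma2 else
      x$draws$sigma2
    plot(s2, type = "l", xlab = "retained draw",
         ylab = expression(sigma^2),
         main = paste0("Error-variance trace (", x$variant, ")"), ...)
  } else {
    g <- x$gamma_hat
    if (!length(g) || all(is.na(g))) stop("no inclusion probabilities to plot")
    image(seq_len(ncol(g)), seq_len(nrow(g)), t(g), zlim = c(0, 1),
          xlab = "covariate", ylab = "group", axes = FALSE,
          main = "Posterior inclusion probability", ...)
    axis(1, seq_len(ncol(g)), colnames(g), las = 2, cex.axis = 0.6)
    axis(2, seq_len(nrow(g)), rownames(g), las = 2, cex.axis = 0.6)
  }
  invisible(x)
}

# per-draw linear predictors for newdata, organised so that both the
# posterior predictive likelihood and simulate() can reuse them.  Returns
# one block per fitted chain (a single chain, or one per group for the
# `separate` variant).
linpred_draws <- function(fit, newdata) {
  stopifnot(inherits(newdata, "grouped_survival"))
  df <- newdata$data
  unknown <- setdiff(unique(df$group), fit$groups)
  if (length(unknown))
    stop("test subjects from group(s) absent in training: ",
         paste(unknown, collapse = ", "))

  if (!is.null(fit$subfits)) {
    blocks <- list(lp = list(), rows = list(), sigma2_by = list())
    Tn <- fit$chain$T
    sigma2 <- rep(0, Tn)  # placeholder; per-block sigmas carried separately
    k <- 0L
    for (g in unique(df$group)) {
      k <- k + 1L
      sub <- fit$subfits[[g]]
      rows <- which(df$group == g)
      blocks$rows[[k]] <- rows
      blocks$lp[[k]] <- block_lp(sub$draws, sub$slots, g, df[rows, ,
                                                             drop = FALSE])
      blocks$sigma2_by[[k]] <- sub$draws$sigma2
    }
    return(list(lp = blocks$lp, rows = blocks$rows,
                sigma2_by = blocks$sigma2_by, sigma2 = sigma2))
  }

  if (fit$variant == "joint") {
    rows <- seq_len(nrow(df))
    dfz <- df
    for (v in fit$covariates) dfz[[v]][is.na(dfz[[v]])] <- 0
    dfz$group <- fit$fit_groups[1]
    lp <- block_lp(fit$draws, fit$slots, fit$fit_groups[1], dfz)
    return(list(lp = list(lp), rows = list(rows),
                sigma2_by = list(fit$draws$sigma2),
                sigma2 = fit$draws$sigma2))
  }

  blocks <- list(lp = list(), rows = list(), sigma2_by = list())
  k <- 0L
  for (g in unique(df$group)) {
    k <- k + 1L
    rows <- which(df$group == g)
    blocks$rows[[k]] <- rows
    blocks$lp[[k]] <- block_lp(fit$draws, fit$slots, g,
                               df[rows, , drop = FALSE])
    blocks$sigma2_by[[k]] <- fit$draws$sigma2
  }
  list(lp = blocks$lp, rows = blocks$rows, sigma2_by = blocks$sigma2_by,
       sigma2 = fit$draws$sigma2)
}

# n x T matrix of linear predictors for the subjects of one group
block_lp <- function(draws, slots, group, df_group) {
  sl <- slots[slots$group == group, , drop = FALSE]
  Tn <- nrow(draws$beta0)
  n <- nrow(df_group)
  lp <- matrix(rep(draws$beta0[, group], each = n), n, Tn)
  if (nrow(sl)) {
    X <- as.matrix(df_group[, sl$covariate, drop = FALSE])
    X[is.na(X)] <- 0
    B <- draws$beta[, sl$slot, drop = FALSE]
    lp <- lp + X %*% t(B)
  }
  lp
}
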