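#' Synthetic group-by-covariate availability pattern
#'
#' A fixed, deterministically constructed availability map with 29 groups
#' and 66 covariates that mimics the sharing profile of a pan-cancer
#' application: one covariate (`age`) and ten further covariates span all
#' groups, twenty-five covariates span contiguous subsets of 2 to 15 groups
#' (sizes and offsets cycle deterministically), and thirty covariates are
#' specific to a single group.  The construction uses no random numbers, so
#' the pattern is identical in every session.
#'
#' @param I number of groups (default 29).
#' @return logical `I` x 66 matrix; `sum()` of it is the total number of
#'   coefficient slots M.
#' @export
default_availability <- function(I = 29) {
  covs <- c("age", sprintf("m%02d", 1:65))
  av <- matrix(FALSE, I, length(covs),
               dimnames = list(sprintf("g%02d", seq_len(I)), covs))
  av[, 1:11] <- TRUE  # age + m01..m10 span all groups
  sizes <- c(2, 3, 4, 5, 6, 8, 10, 12, 15)
  for (t in 1:25) {
    size <- sizes[(t - 1) %% length(sizes) + 1]
    start <- ((t - 1) * 7) %% I
    members <- (start + seq_len(size) - 1) %% I + 1
    av[members, 11 + t] <- TRUE
  }
  for (t in 1:30)
    av[(t - 1) %% I + 1, 36 + t] <- TRUE
  av
}

#' Draw true inclusion indicators for one data-generating condition
#'
#' The six conditions: (1) each covariate is included for *all* groups that
#' carry it with probability 0.5, (2) same with probability 0.1, (3) each
#' (group, covariate) slot is included independently with probability 0.5
#' (no true hierarchical structure), (4) same with probability 0.1, (5) all
#' covariates included, (6) all excluded.
#'
#' @param condition integer 1..6.
#' @param availability logical groups x covariates matrix.
#' @return numeric matrix of 0/1 truth indicators, `NA` where unavailable.
#' @export
sim_truth <- function(condition, availability = default_availability()) {
  stopifnot(condition %in% 1:6)
  g <- matrix(NA_real_, nrow(availability), ncol(availability),
              dimnames = dimnames(availability))
  p <- switch(condition, 0.5, 0.1, 0.5, 0.1, 1, 0)
  for (l in seq_len(ncol(availability))) {
    rows <- availability[, l]
    g[rows, l] <- switch(as.character(condition),
                         "1" = , "2" = rbinom(1, 1, p),
                         "3" = , "4" = rbinom(sum(rows), 1, p),
                         "5" = 1, "6" = 0)
  }
  g
}

#' Draw generative parameters given truth indicators
#'
#' Included coefficients are drawn from the model's own slab hierarchy:
#' per covariate a slab mean `N(0, 1)` and slab variance `Inverse-Gamma(5,
#' 1)`, then per included group a coefficient `N(slab mean, slab variance)`.
#' Excluded coefficients are exactly zero.  Group intercepts are `N(0, 1)`
#' and the error variance defaults to 1.
#'
#' @param truth matrix from [sim_truth()].
#' @param sigma2 true error variance.
#' @return list with `beta` (coefficients, `NA` where unavailable), `beta0`
#'   (group intercepts), `sigma2`, `slab_mean`, `slab_var`.
#' @export
sim_params <- function(truth, sigma2 = 1) {
  I <- nrow(truth); L <- ncol(truth)
  beta <- truth
  slab_mean <- slab_var <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    inc <- which(!is.na(truth[, l]) & truth[, l] == 1)
    avail <- which(!is.na(truth[, l]))
    beta[avail, l] <- 0
    if (length(inc)) {
      slab_mean[l] <- rnorm(1)
      slab_var[l] <- 1 / rgamma(1, 5, rate = 1)
      beta[inc, l] <- rnorm(length(inc), slab_mean[l], sqrt(slab_var[l]))
    }
  }
  list(beta = beta, beta0 = rnorm(I), sigma2 = sigma2,
       slab_mean = slab_mean, slab_var = slab_var)
}

#' Generate a grouped survival dataset from the model
#'
#' Covariates are standard normal; log survival times are normal with the
#' linear predictor implied by `params`; independent log-normal censoring
#' times are drawn with their location calibrated by bisection on the
#' generated event times so the expected censoring fraction equals
#' `censor_frac`.
#'
#' @param params list from [sim_params()].
#' @param availability availability matrix matching `params`.
#' @param n_per_group subjects per group (scalar or per-group vector).
#' @param censor_frac target fraction of censored subjects (0 disables
#'   censoring).
#' @return a `grouped_survival`.
#' @export
sim_dataset <- function(params, availability = default_availability(),
                        n_per_group = 50, censor_frac = 0.5) {
  I <- nrow(availability); L <- ncol(availability)
  groups <- rownames(availability)
  covs <- colnames(availability)
  n_per_group <- rep_len(n_per_group, I)
  dfs <- vector("list", I)
  for (i in seq_len(I)) {
    n <- n_per_group[i]
    idx <- which(availability[i, ])
    X <- matrix(rnorm(n * length(idx)), n, length(idx))
    lp <- params$beta0[i] + drop(X %*% params$beta[i, idx])
    logy <- rnorm(n, lp, sqrt(params$sigma2))
    d <- data.frame(group = groups[i], time = exp(logy), event = 1L)
    full <- matrix(NA_real_, n, L, dimnames = list(NULL, covs))
    full[, idx] <- X
    d <- cbind(d, as.data.frame(full))
    dfs[[i]] <- d
  }
  df <- do.call(rbind, dfs)
  if (censor_frac > 0) {
    logy <- log(df$time)
    s_c <- sd(logy)
    if (!is.finite(s_c) || s_c == 0) s_c <- 1
    # expected censored fraction, decreasing in the censoring location c
    frac <- function(cc) mean(pnorm((logy - cc) / s_c))
    lo <- min(logy) - 10 * s_c; hi <- max(logy) + 10 * s_c
    if (frac(lo) < censor_frac || frac(hi) > censor_frac)
      stop("infeasible censoring target")
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (frac(mid) > censor_frac) lo <- mid else hi <- mid
    }
    cc <- (lo + hi) / 2
    logc <- rnorm(nrow(df), cc, s_c)
    censored <- logc < logy
    df$event <- as.integer(!censored)
    df$time <- exp(pmin(logy, logc))
  }
  grouped_survival(df, availability = availability)
}

#' Mean squared deviation between truth and estimated inclusion
#'
#' `SSD = (1/M) * sum over available (group, covariate) slots of
#' (truth - estimate)^2`, where `M` is the total number of coefficient
#' slots.  Zero means perfect selection; one means maximally wrong.
#'
#' @param truth 0/1 truth matrix ([sim_truth()]).
#' @param gamma_hat posterior inclusion probabilities on the same slots.
#' @param availability logical availability matrix.
#' @export
ssd <- function(truth, gamma_hat, availability) {
  if (!all(dim(truth) == dim(gamma_hat)) ||
      !all(dim(truth) == dim(availability)))
    stop("truth, gamma_hat and availability must have identical shape")
  slots <- which(availability)
  if (any(is.na(truth[slots])) || any(is.na(gamma_hat[slots])))
    stop("truth/gamma_hat must be defined on every available slot")
  mean((truth[slots] - gamma_hat[slots])^2)
}

#' Run the simulation study
#'
#' For each replication and condition: draw truth indicators and generative
#' parameters, generate a training dataset, fit every requested variant,
#' compute its selection SSD, then generate a matched test set (same truth
#' and parameters) and compute each variant's log posterior predictive
#' likelihood.  Results are averaged over replications.  All randomness
#' flows from a single master seed, so reruns are bit-identical.
#'
#' @param conditions integer vector of condition ids (1..6).
#' @param variants character vector of variant names.
#' @param replications number of replications (>= 1).
#' @param n_per_group subjects per group.
#' @param availability availability matrix.
#' @param hyper,chain sampler settings.
#' @param censor_frac target censoring fraction.
#' @param seed master seed.
#' @return object of class `ssaft_study` with arrays
#'   `ssd[rep, condition, variant]` and `logpred[rep, condition, variant]`
#'   plus their means.
#' @export
run_study <- function(conditions = 1:6, variants = ssaft_variants(),
                      replications = 10, n_per_group = 50,
                      availability = default_availability(),
                      hyper = ssaft_hyper(),
                      chain = ssaft_chain(2000, 1000, 10),
                      censor_frac = 0.5, seed = NULL) {
  if (replications < 1) stop("`replications` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  dn <- list(rep = seq_len(replications),
             condition = paste0("cond", conditions),
             variant = variants)
  a_ssd <- array(NA_real_, dim = c(replications, length(conditions),
                                   length(variants)), dimnames = dn)
  a_lp <- a_ssd
  for (r in seq_len(replications)) {
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      truth <- sim_truth(cond, availability)
      params <- sim_params(truth)
      train <- sim_dataset(params, availability, n_per_group, censor_frac)
      test <- sim_dataset(params, availability, n_per_group, censor_frac)
      for (vi in seq_along(variants)) {
        v <- variants[vi]
        fit <- ssaft(train, variant = v, hyper = hyper, chain = chain)
        a_ssd[r, ci, vi] <- ssd(truth, fit$gamma_hat, availability)
        a_lp[r, ci, vi] <- logpred(fit, test)$estimate
      }
    }
  }
  structure(list(ssd = a_ssd, logpred = a_lp,
                 mean_ssd = apply(a_ssd, c(2, 3), mean),
                 mean_logpred = apply(a_lp, c(2, 3), mean),
                 conditions = conditions, variants = variants,
                 replications = replications, n_per_group = n_per_group,
                 chain = chain, seed = seed),
            class = "ssaft_study")
}

#' @export
print.ssaft_study <- function(x, ...) {
  cat("Simulation study: ", x$replications, " replication(s), conditions ",
      paste(x$conditions, collapse = ", "), "\n", sep = "")
  cat("\nMean SSD (selection accuracy; lower is better):\n")
  print(round(x$mean_ssd, 4))
  cat("\nMean log posterior predictive likelihood (higher is better):\n")
  print(round(x$mean_logpred, 2))
  invisible(x)
}

#' Pairwise-t comparison of models on a per-replication metric
#'
#' Identifies the best model (lowest mean when `higher_better = FALSE`) and
#' marks as co-best every model whose paired t-test against the best has
#' p > `alpha`.  Two identical metric vectors are co-best by convention;
#' a constant non-zero difference is treated as significant (the degenerate
#' zero-variance paired t).
#'
#' @param metric replications x models numeric matrix.
#' @param higher_better direction of the metric.
#' @param alpha significance level (default 0.01).
#' @return list with `best` (column name or index), `cobest` (logical per
#'   model), `means`, `pvalues`.
#' @export
compare_models <- function(metric, higher_better = FALSE, alpha = 0.01) {
  metric <- as.matrix(metric)
  if (nrow(metric) < 2) stop("need at least 2 replications to compare")
  means <- colMeans(metric)
  bi <- if (higher_better) which.max(means) else which.min(means)
  pv <- rep(NA_real_, ncol(metric))
  cobest <- rep(FALSE, ncol(metric))
  cobest[bi] <- TRUE
  for (j in seq_len(ncol(metric))) {
    if (j == bi) next
    d <- metric[, j] - metric[, bi]
    if (sd(d) == 0) {
      cobest[j] <- all(d == 0)
      pv[j] <- if (all(d == 0)) 1 else 0
    } else {
      pv[j] <- t.test(metric[, j], metric[, bi], paired = TRUE)$p.value
      cobest[j] <- pv[j] > alpha
    }
  }
  names(cobest) <- names(pv) <- colnames(metric)
  list(best = if (!is.null(colnames(metric))) colnames(metric)[bi] else bi,
       cobest = cobest, means = means, pvalues = pv)
}
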