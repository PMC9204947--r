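#' Stable log of a mean of exponentials
#'
#' `log_mean_exp(x)` computes `log(mean(exp(x)))` without overflow or
#' underflow; it is bounded by `min(x)` and `max(x)`.
#'
#' @param x numeric vector of log values (may contain `-Inf`).
#' @export
log_mean_exp <- function(x) {
  if (!length(x)) return(0)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Per-draw test-set log-likelihood
#'
#' For each retained posterior draw, the log of the product over uncensored
#' test subjects of the log-normal density at the observed time and over
#' censored subjects of the survival probability beyond the censoring time,
#' at that draw's parameters.  An empty test set gives log-likelihood 0 for
#' every draw.
#'
#' @param fit an `ssaft` fit.
#' @param newdata a `grouped_survival` test set; every test group must have
#'   been present in training.
#' @return numeric vector of length `T` (retained draws).
#' @export
draw_logliks <- function(fit, newdata) {
  stopifnot(inherits(fit, "ssaft"))
  if (nrow(newdata$data) == 0L) return(rep(0, fit$chain$T))
  lpd <- linpred_draws(fit, newdata)
  df <- newdata$data
  total <- rep(0, fit$chain$T)
  for (k in seq_along(lpd$rows)) {
    rows <- lpd$rows[[k]]
    lp <- lpd$lp[[k]]
    sig <- sqrt(lpd$sigma2_by[[k]])
    logy <- log(df$time[rows])
    cens <- df$event[rows] == 0
    z <- sweep(lp - logy, 2, sig, "/") * -1  # (logy - mu)/sigma, n x T
    if (any(!cens)) {
      zu <- z[!cens, , drop = FALSE]
      dens <- -0.5 * zu^2 - 0.5 * log(2 * pi)
      dens <- sweep(dens, 2, log(sig), "-")
      dens <- dens - logy[!cens]  # Jacobian of the log transform
      total <- total + colSums(dens)
    }
    if (any(cens)) {
      zc <- z[cens, , drop = FALSE]
      surv <- pnorm(zc, lower.tail = FALSE, log.p = TRUE)
      total <- total + colSums(surv)
    }
  }
  total
}

#' Log posterior predictive likelihood of a test set
#'
#' The posterior predictive likelihood is the test-set likelihood averaged
#' over retained posterior draws; it is estimated by a log-mean-exp of the
#' per-draw log-likelihoods and reported on the log scale (higher is a
#' better fit).
#'
#' @inheritParams draw_logliks
#' @return list with `estimate` (the log posterior predictive likelihood)
#'   and `per_draw` (the per-draw log-likelihoods).
#' @export
logpred <- function(fit, newdata) {
  ll <- draw_logliks(fit, newdata)
  list(estimate = log_mean_exp(ll), per_draw = ll)
}

#' Group-stratified cross-validation folds
#'
#' Subjects are partitioned into `k` folds by a seeded shuffle stratified
#' within each group (proportional allocation), so that every training fold
#' contains every group and group intercepts remain estimable.
#'
#' @param data a `grouped_survival`.
#' @param k number of folds (>= 2); every group must have at least `k`
#'   subjects.
#' @param seed optional RNG seed for the shuffle.
#' @return integer vector of fold labels (1..k), one per subject row.
#' @export
make_folds <- function(data, k = 5, seed = NULL) {
  stopifnot(inherits(data, "grouped_survival"))
  if (k < 2) stop("`k` must be at least 2 (no test set otherwise)")
  if (any(data$n_i < k))
    stop("every group needs at least k = ", k, " subjects to stratify; ",
         "too small: ",
         paste(data$groups[data$n_i < k], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(nrow(data$data))
  for (g in data$groups) {
    rows <- which(data$data$group == g)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' k-fold cross-validated log posterior predictive likelihood
#'
#' Fits the chosen model variant on each training fold, scores the held-out
#' fold with [logpred()], and averages the per-fold log posterior predictive
#' likelihoods.
#'
#' @inheritParams ssaft
#' @param k number of folds (default 5).
#' @param folds optional precomputed fold labels (so several variants can
#'   share identical splits).
#' @param standardize `"global"` (default) uses the data as supplied;
#'   `"fold"` restandardizes predictors on each training fold and maps the
#'   test fold through the training transform.
#' @return list of class `ssaft_cv` with `fold_scores`, `mean_score`,
#'   `variant` and `folds`.
#' @export
cv_logpred <- function(data, variant = "hierarchical", k = 5,
                       hyper = ssaft_hyper(), chain = ssaft_chain(),
                       seed = NULL, folds = NULL,
                       standardize = c("global", "fold")) {
  standardize <- match.arg(standardize)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(folds)) folds <- make_folds(data, k)
  k <- max(folds)
  scores <- numeric(k)
  for (f in seq_len(k)) {
    train <- grouped_survival(data$data[folds != f, , drop = FALSE],
                              availability = data$availability)
    test <- grouped_survival(data$data[folds == f, , drop = FALSE],
                             availability =
                               data$availability[unique(
                                 data$data$group[folds == f]), ,
                                 drop = FALSE])
    if (standardize == "fold") {
      train <- standardize_predictors(train, scope = "refit")
      test <- apply_standardization(train, test)
    }
    fit <- ssaft(train, variant = variant, hyper = hyper, chain = chain)
    scores[f] <- logpred(fit, test)$estimate
  }
  structure(list(variant = variant, fold_scores = scores,
                 mean_score = mean(scores), folds = folds, k = k),
            class = "ssaft_cv")
}

#' @export
print.ssaft_cv <- function(x, ...) {
  cat("Cross-validated log posterior predictive likelihood (",
      x$variant, ", ", x$k, " folds)\n", sep = "")
  cat("  per fold:", paste(signif(x$fold_scores, 6), collapse = ", "), "\n")
  cat("  mean:    ", signif(x$mean_score, 6), "\n")
  invisible(x)
}

#' Compare model variants by cross-validated predictive likelihood
#'
#' Runs [cv_logpred()] for each requested variant on identical folds and
#' returns one row per variant with its mean log posterior predictive
#' likelihood, ordered best first.
#'
#' @inheritParams cv_logpred
#' @param variants character vector of variant names.
#' @export
ssaft_suite <- function(data, variants = ssaft_variants(), k = 5,
                        hyper = ssaft_hyper(), chain = ssaft_chain(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- make_folds(data, k)
  res <- lapply(variants, function(v)
    cv_logpred(data, v, hyper = hyper, chain = chain, folds = folds))
  out <- data.frame(
    variant = variants,
    mean_logpred = vapply(res, function(r) r$mean_score, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_logpred), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "folds") <- folds
  attr(out, "fold_scores") <- lapply(res, function(r) r$fold_scores)
  out
}
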