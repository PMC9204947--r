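#' Prior hyperparameters of the hierarchical spike-and-slab AFT model
#'
#' Defaults follow the model as used in practice on standardized predictors:
#' a spike variance of 1/10000 (a near point mass at zero), a N(0, 1) prior
#' on each slab mean, an Inverse-Gamma(5, 1) prior on each slab variance, a
#' N(0, 10^2) prior on the intercept hypermean with Inverse-Gamma(1, 1) on
#' the intercept hypervariance, an Inverse-Gamma(0.01, 0.01) prior on the
#' shared error variance, and a Beta(1, 1) prior on each covariate's
#' inclusion probability.
#'
#' @param spike_var variance z^2 of the spike component (must be much smaller
#'   than `slab_mean_var`).
#' @param slab_mean_var prior variance tau^2 of each slab mean.
#' @param slab_var_shape,slab_var_rate Inverse-Gamma shape/rate for the slab
#'   variances.
#' @param intercept_mean_var prior variance of the intercept hypermean.
#' @param intercept_var_shape,intercept_var_rate Inverse-Gamma prior for the
#'   intercept hypervariance.
#' @param sigma_shape,sigma_rate Inverse-Gamma prior for the error variance.
#' @param pi_shape1,pi_shape2 Beta prior for the inclusion probabilities.
#' @return A list of class `ssaft_hyper`.
#' @export
ssaft_hyper <- function(spike_var = 1 / 10000, slab_mean_var = 1,
                        slab_var_shape = 5, slab_var_rate = 1,
                        intercept_mean_var = 100,
                        intercept_var_shape = 1, intercept_var_rate = 1,
                        sigma_shape = 0.01, sigma_rate = 0.01,
                        pi_shape1 = 1, pi_shape2 = 1) {
  h <- list(spike_var = spike_var, slab_mean_var = slab_mean_var,
            slab_var_shape = slab_var_shape, slab_var_rate = slab_var_rate,
            intercept_mean_var = intercept_mean_var,
            intercept_var_shape = intercept_var_shape,
            intercept_var_rate = intercept_var_rate,
            sigma_shape = sigma_shape, sigma_rate = sigma_rate,
            pi_shape1 = pi_shape1, pi_shape2 = pi_shape2)
  bad <- vapply(h, function(v) !is.numeric(v) || length(v) != 1 || v <= 0,
                logical(1))
  if (any(bad))
    stop("hyperparameters must be positive scalars: ",
         paste(names(h)[bad], collapse = ", "))
  if (h$spike_var >= h$slab_mean_var)
    stop("the spike variance must be much smaller than the slab-mean variance")
  class(h) <- "ssaft_hyper"
  h
}

#' MCMC chain settings
#'
#' @param iterations total Gibbs sweeps.
#' @param burnin sweeps discarded before retention (must be < `iterations`).
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed optional RNG seed; the same seed gives a bit-identical chain.
#' @return A list of class `ssaft_chain` with the derived number of retained
#'   draws `T = floor((iterations - burnin) / thin)`.
#' @export
ssaft_chain <- function(iterations = 10000, burnin = 5000, thin = 10,
                        seed = NULL) {
  stopifnot(iterations >= 1, burnin >= 0, thin >= 1)
  if (burnin >= iterations) stop("`burnin` must be smaller than `iterations`")
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = seed,
                 T = as.integer((iterations - burnin) %/% thin)),
            class = "ssaft_chain")
}
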