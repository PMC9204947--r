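#' Model variants of the grouped spike-and-slab AFT framework
#'
#' Seven configurations of the same Gibbs engine are supported:
#' \describe{
#'   \item{`hierarchical`}{the proposed model: per-covariate inclusion
#'     probabilities with Beta priors, hierarchical slab, grouped data.}
#'   \item{`null`}{random intercept per group only; no covariates.}
#'   \item{`full`}{no spike-and-slab component: every coefficient is
#'     permanently included (indicator pinned at 1).}
#'   \item{`fixed_0.5`}{spike-and-slab with all prior inclusion
#'     probabilities fixed at 0.5 (no Beta update).}
#'   \item{`shared`}{a single inclusion probability shared by all
#'     covariates and groups, Beta(1,1) prior updated with pooled counts.}
#'   \item{`joint`}{all groups appended row-wise and treated as one group;
#'     a covariate missing from a subject's source group is zero-filled.}
#'   \item{`separate`}{the hierarchical machinery fit to each group
#'     independently (no borrowing across groups).}
#' }
#'
#' @param name variant name.
#' @param fixed_pi the fixed inclusion probability for `fixed_0.5`.
#' @return list describing the sampler configuration.
#' @export
make_variant <- function(name, fixed_pi = 0.5) {
  name <- match.arg(name, ssaft_variants())
  mode <- switch(name,
                 hierarchical = 0L, joint = 0L, separate = 0L,
                 fixed_0.5 = 1L, shared = 2L, full = 3L, null = 3L)
  list(name = name, mode = mode,
       strip_covariates = name == "null",
       structure = switch(name, joint = "merged", separate = "separate",
                          "grouped"),
       fixed_pi = fixed_pi)
}

#' @rdname make_variant
#' @export
ssaft_variants <- function() {
  c("hierarchical", "null", "full", "fixed_0.5", "shared", "joint",
    "separate")
}

#' Posterior inclusion probabilities implied by a deterministic variant
#'
#' The `full` variant includes every coefficient with probability exactly 1
#' and the `null` variant excludes every coefficient with probability exactly
#' 0, with no sampling noise; their inclusion-probability matrices can be
#' written down without running a chain.
#'
#' @param variant `"full"` or `"null"`.
#' @param availability logical groups x covariates matrix.
#' @return numeric matrix of the same shape, `NA` where unavailable.
#' @export
variant_gamma_hat <- function(variant, availability) {
  variant <- match.arg(variant, c("full", "null"))
  g <- matrix(if (variant == "full") 1 else 0,
              nrow(availability), ncol(availability),
              dimnames = dimnames(availability))
  g[!availability] <- NA_real_
  g
}

# restrict a grouped_survival to a subset of groups, dropping covariates
# that are structurally absent from every retained group
subset_groups <- function(data, groups) {
  df <- data$data[data$data$group %in% groups, , drop = FALSE]
  avail <- data$availability[groups, , drop = FALSE]
  keep <- colnames(avail)[colSums(avail) > 0]
  df <- df[, c("group", "time", "event", keep), drop = FALSE]
  out <- grouped_survival(df, availability = avail[, keep, drop = FALSE])
  out$center <- data$center[keep]
  out$scale <- data$scale[keep]
  out
}

# append all groups row-wise into a single pseudo-group; covariates missing
# from a subject's source group are zero-filled (zero is the mean of each
# standardized predictor, so this is a neutral fill)
merge_groups <- function(data, label = ".joint") {
  df <- data$data
  for (v in data$covariates)
    df[[v]][is.na(df[[v]])] <- 0
  df$group <- label
  avail <- matrix(TRUE, 1, length(data$covariates),
                  dimnames = list(label, data$covariates))
  out <- grouped_survival(df, availability = avail)
  out$center <- data$center
  out$scale <- data$scale
  out
}
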