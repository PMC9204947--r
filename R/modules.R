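#' Low-rank multi-source module
#'
#' A module is one low-rank matrix from an integrative factorization of
#' bidimensionally-linked data (multiple omics sources x multiple sample
#' groups), restricted to the block of sources and groups on which it is
#' non-zero.  Columns are samples; each column belongs to one of the spanned
#' groups.  The SVD of the module yields per-sample component scores used as
#' survival-model predictors.
#'
#' @param mat numeric matrix (features x samples) holding the module values
#'   on its spanned block.  All entries must be finite.
#' @param module integer module index (used to label components `"k.r"`).
#' @param groups character vector of group identifiers the module spans.
#' @param sources optional identifiers of the sources (rows) it spans.
#' @param sample_groups character vector, one entry per column of `mat`,
#'   assigning each sample to a group in `groups`.  Defaults to the single
#'   group when `length(groups) == 1`.
#' @return An object of class `lowrank_module`.
#' @export
lowrank_module <- function(mat, module = 1L, groups, sources = NULL,
                           sample_groups = NULL) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) stop("module matrix must be finite")
  groups <- as.character(groups)
  if (is.null(sample_groups)) {
    if (length(groups) != 1L)
      stop("`sample_groups` is required when the module spans several groups")
    sample_groups <- rep(groups, ncol(mat))
  }
  sample_groups <- as.character(sample_groups)
  if (length(sample_groups) != ncol(mat))
    stop("`sample_groups` must have one entry per sample column")
  if (!all(sample_groups %in% groups))
    stop("`sample_groups` contains groups outside the declared span")
  structure(list(mat = mat, module = as.integer(module), groups = groups,
                 sources = sources, sample_groups = sample_groups),
            class = "lowrank_module")
}

#' @export
print.lowrank_module <- function(x, ...) {
  cat("Low-rank module ", x$module, ": ", nrow(x$mat), " features x ",
      ncol(x$mat), " samples, spanning ", length(x$groups), " group(s)\n",
      sep = "")
  invisible(x)
}

#' Singular value decomposition of a module, with a fixed sign convention
#'
#' Computes the SVD `U diag(d) V'` of the module matrix.  Singular vectors
#' are only defined up to a joint sign flip of each (u_r, v_r) pair, so each
#' pair is canonicalized: the entry of largest magnitude in `v_r` is made
#' positive.  Singular values are nonnegative and nonincreasing.
#'
#' @param module a `lowrank_module`.
#' @return list with `d` (singular values), `u` (loadings), `v` (per-sample
#'   right singular vectors).
#' @export
module_svd <- function(module) {
  stopifnot(inherits(module, "lowrank_module"))
  s <- svd(module$mat)
  for (r in seq_along(s$d)) {
    i <- which.max(abs(s$v[, r]))
    if (s$v[i, r] < 0) {
      s$v[, r] <- -s$v[, r]
      s$u[, r] <- -s$u[, r]
    }
  }
  list(d = s$d, u = s$u, v = s$v)
}

module_rank <- function(d, tol = 1e-10) {
  if (!length(d) || d[1] <= tol) return(0L)
  sum(d > tol * d[1])
}

#' Component scores of a module
#'
#' The r-th component score vector is the product of the r-th singular value
#' with the r-th right singular vector: one score per sample in the module's
#' group span.  Components are labelled `"k.r"` after the module index k and
#' component rank r.
#'
#' @param module a `lowrank_module`.
#' @param r component rank (must not exceed the numerical rank).
#' @param total_ss optional total sum of squares of the full multi-source
#'   data, used to record the component's eigenvalue ratio d_r^2 / total_ss.
#' @return An object of class `component_predictor` with fields `label`,
#'   `module`, `r`, `scores`, `sample_groups`, `groups`, `eigenvalue`
#'   and (if `total_ss` given) `ratio`.
#' @export
component_scores <- function(module, r, total_ss = NULL) {
  s <- module_svd(module)
  rk <- module_rank(s$d)
  if (r > rk)
    stop("component rank ", r, " exceeds module rank ", rk)
  structure(list(
    label = paste0(module$module, ".", r),
    module = module$module, r = as.integer(r),
    scores = s$d[r] * s$v[, r],
    sample_groups = module$sample_groups, groups = module$groups,
    eigenvalue = s$d[r]^2,
    ratio = if (is.null(total_ss)) NA_real_ else s$d[r]^2 / total_ss
  ), class = "component_predictor")
}

#' @export
print.component_predictor <- function(x, ...) {
  cat("Component ", x$label, ": ", length(x$scores), " samples, eigenvalue ",
      signif(x$eigenvalue, 4),
      if (!is.na(x$ratio)) paste0(" (ratio ", signif(x$ratio, 4), ")"), "\n",
      sep = "")
  invisible(x)
}

#' Select predictor components from a set of modules
#'
#' Inclusion rules: the first component of every module is always selected
#' (it explains the most variation within the module); any further component
#' is selected when its eigenvalue ratio — squared singular value divided by
#' the total sum of squares of the full multi-source data — exceeds
#' `threshold`.  A module of rank zero contributes nothing.
#'
#' @param modules list of `lowrank_module` objects.
#' @param total_ss total sum of squares of the concatenated multi-source data
#'   (strictly positive).  Supplied as a scalar so selection can run from the
#'   modules alone.
#' @param threshold eigenvalue-ratio cutoff for components beyond the first
#'   (default 0.01, i.e. at least 1% of total variation).
#' @return list of `component_predictor` objects.
#' @export
select_components <- function(modules, total_ss, threshold = 0.01) {
  stopifnot(is.numeric(total_ss), total_ss > 0)
  out <- list()
  for (mod in modules) {
    s <- module_svd(mod)
    rk <- module_rank(s$d)
    if (rk == 0L) next
    take <- c(1L, which(s$d^2 / total_ss > threshold))
    take <- sort(unique(take[take <= rk]))
    for (r in take)
      out[[length(out) + 1L]] <- component_scores(mod, r, total_ss = total_ss)
  }
  out
}

#' Assemble a grouped survival design from component predictors
#'
#' Each selected component becomes one covariate, available exactly for the
#' groups its module spans; clinical covariates already present in `data`
#' (e.g. age) stay available for every group.  Component score columns are
#' aligned to subjects by group: the scores of a component must be ordered as
#' the subjects of its spanned groups appear in `data`.  All covariates are
#' standardized to mean 0, sd 1.
#'
#' @param components list of `component_predictor` objects.
#' @param data a `grouped_survival` holding subjects, outcomes and any
#'   clinical covariates.
#' @param standardize standardize the assembled design (default TRUE).
#' @return a `grouped_survival` with one covariate per component plus the
#'   clinical covariates.
#' @export
assemble_design <- function(components, data, standardize = TRUE) {
  stopifnot(inherits(data, "grouped_survival"))
  df <- data$data
  avail <- data$availability
  for (comp in components) {
    if (!all(comp$groups %in% data$groups))
      stop("component ", comp$label, " spans groups absent from the data")
    rows <- which(df$group %in% comp$groups)
    if (length(rows) != length(comp$scores))
      stop("sample alignment mismatch for component ", comp$label, ": ",
           length(comp$scores), " scores vs ", length(rows), " subjects")
    if (!identical(as.character(df$group[rows]),
                   as.character(comp$sample_groups)))
      stop("sample alignment mismatch for component ", comp$label,
           ": group order differs between scores and subjects")
    col <- rep(NA_real_, nrow(df))
    col[rows] <- comp$scores
    df[[comp$label]] <- col
    avail <- cbind(avail, data$groups %in% comp$groups)
    colnames(avail)[ncol(avail)] <- comp$label
  }
  out <- grouped_survival(df, availability = avail)
  if (standardize) standardize_predictors(out) else out
}
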