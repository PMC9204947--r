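#' Grouped censored survival data
#'
#' Container for survival data organised in groups (e.g. cancer types) where
#' each group may carry a different subset of the covariates.  A subject has a
#' positive observed time `time` (an event time if `event == 1`, a right
#' censoring time if `event == 0`), a group label, and numeric covariates.
#' Covariates absent from a whole group are *structurally* missing and are
#' recorded in the group-by-covariate availability map; a covariate that a
#' group does carry must be observed for every subject of that group.
#'
#' @param data data.frame with columns `group`, `time`, `event` (1 = event
#'   observed, 0 = censored) followed by numeric covariate columns.  `NA`
#'   covariate cells are only allowed where a covariate is structurally
#'   missing for the whole group.
#' @param availability optional logical matrix (groups x covariates).  When
#'   `NULL` it is inferred: a covariate is available for a group unless all of
#'   its values in that group are `NA`.
#'
#' @return An object of class `grouped_survival`: a list with elements
#'   `data` (the subject table), `groups`, `covariates`, `availability`
#'   (logical groups x covariates matrix), `n_i` (subjects per group), `M`
#'   (total number of coefficient slots, `sum(availability)`), and `center`/
#'   `scale` (standardization transform, `NULL` until
#'   [standardize_predictors()] is applied).
#' @seealso [filter_subjects()], [standardize_predictors()],
#'   [read_grouped_survival()]
#' @export
grouped_survival <- function(data, availability = NULL) {
  data <- as.data.frame(data)
  required <- c("group", "time", "event")
  if (!all(required %in% names(data)))
    stop("`data` must contain columns 'group', 'time' and 'event'")
  data$group <- as.character(data$group)
  covs <- setdiff(names(data), required)
  data <- data[, c(required, covs), drop = FALSE]
  groups <- unique(data$group)

  if (nrow(data) == 0L) stop("no subjects in `data`")
  if (anyNA(data$time) || any(!is.finite(data$time)) || any(data$time <= 0))
    stop("all observed times must be finite and > 0")
  if (!all(data$event %in% c(0, 1)))
    stop("`event` must be 0 (censored) or 1 (event observed)")

  if (is.null(availability)) {
    availability <- matrix(TRUE, length(groups), length(covs),
                           dimnames = list(groups, covs))
    for (g in groups) {
      rows <- data$group == g
      for (v in covs)
        availability[g, v] <- !all(is.na(data[rows, v]))
    }
  } else {
    availability <- as.matrix(availability)
    if (!setequal(rownames(availability), groups) ||
        !setequal(colnames(availability), covs))
      stop("availability dimnames must match the groups and covariates")
    availability <- availability[groups, covs, drop = FALSE]
    storage.mode(availability) <- "logical"
  }
  if (length(covs) && any(colSums(availability) == 0))
    stop("every covariate must be available in at least one group: ",
         paste(covs[colSums(availability) == 0], collapse = ", "))

  # within-group missingness is not modelled: an available covariate must be
  # observed for every subject of the group
  for (g in groups) {
    rows <- data$group == g
    for (v in covs[availability[g, ]]) {
      if (anyNA(data[rows, v]))
        stop("covariate '", v, "' is available for group '", g,
             "' but has missing values; drop those records first ",
             "(see filter_subjects())")
      if (!is.numeric(data[rows, v]))
        stop("covariate '", v, "' must be numeric")
    }
  }

  n_i <- vapply(groups, function(g) sum(data$group == g), integer(1))
  structure(list(
    data = data, groups = groups, covariates = covs,
    availability = availability, n_i = n_i, M = sum(availability),
    center = NULL, scale = NULL
  ), class = "grouped_survival")
}

#' @export
print.grouped_survival <- function(x, ...) {
  cat("Grouped survival data: ", nrow(x$data), " subjects in ",
      length(x$groups), " group(s)\n", sep = "")
  cat("  covariates: ", length(x$covariates),
      " (", x$M, " group-level coefficient slots)\n", sep = "")
  cat("  censored:   ", sum(x$data$event == 0), " (",
      round(100 * mean(x$data$event == 0), 1), "%)\n", sep = "")
  if (!is.null(x$center)) cat("  predictors standardized\n")
  invisible(x)
}

#' @export
as.data.frame.grouped_survival <- function(x, ...) x$data

#' @export
summary.grouped_survival <- function(object, ...) {
  d <- object$data
  out <- data.frame(
    group = object$groups,
    n = as.integer(object$n_i),
    events = vapply(object$groups,
                    function(g) sum(d$event[d$group == g] == 1), numeric(1)),
    censored = vapply(object$groups,
                      function(g) sum(d$event[d$group == g] == 0), numeric(1)),
    covariates = as.integer(rowSums(object$availability)),
    row.names = NULL)
  class(out) <- c("summary.grouped_survival", "data.frame")
  out
}

normalize_raw_table <- function(raw) {
  raw <- as.data.frame(raw)
  if (all(c("event_time", "censor_time") %in% names(raw))) {
    time <- ifelse(!is.na(raw$event_time), raw$event_time, raw$censor_time)
    event <- ifelse(!is.na(raw$event_time), 1, ifelse(!is.na(raw$censor_time), 0, NA))
    covs <- setdiff(names(raw), c("group", "event_time", "censor_time"))
    out <- data.frame(group = raw$group, time = time, event = event)
    out[covs] <- raw[covs]
    out
  } else if (all(c("time", "event") %in% names(raw))) {
    raw
  } else {
    stop("raw table needs columns ('time','event') or ('event_time','censor_time')")
  }
}

#' Filter subjects to those usable by the survival model
#'
#' Applies, in order, the subject-level exclusion rules used before model
#' fitting: (1) remove subjects missing both an event time and a censoring
#' time; (2) remove subjects whose observed time is negative or zero;
#' (3) remove subjects missing a value for a required covariate (by default
#' `age`, when such a column is present); (4) remove subjects missing a value
#' for any other covariate their group carries (the model has no within-group
#' missingness mechanism).  Covariates missing for an entire group are treated
#' as structurally absent, not as violations.
#'
#' @param raw a data.frame with a `group` column and either `time`/`event`
#'   columns or a pair `event_time`/`censor_time` (at most one of which is
#'   observed per subject), plus covariate columns; or a `grouped_survival`
#'   object (in which case filtering is a validated no-op, making the
#'   operation idempotent).
#' @param required character vector of covariates for which individual
#'   missingness removes the subject under rule (3); defaults to `"age"`
#'   when present.
#' @return A `grouped_survival` object.  The removal counts are attached as
#'   attribute `"filter_report"` (see [filter_report()]).
#' @export
filter_subjects <- function(raw, required = "age") {
  if (inherits(raw, "grouped_survival")) raw <- raw$data
  raw <- normalize_raw_table(raw)
  covs <- setdiff(names(raw), c("group", "time", "event"))
  required <- intersect(required, covs)
  raw$group <- as.character(raw$group)

  # structural availability decided on the raw table, before any removal
  groups <- unique(raw$group)
  avail <- matrix(TRUE, length(groups), length(covs),
                  dimnames = list(groups, covs))
  for (g in groups) for (v in covs)
    avail[g, v] <- !all(is.na(raw[raw$group == g, v]))

  report <- c(missing_time = 0L, nonpositive_time = 0L,
              missing_required = 0L, incomplete_covariates = 0L)

  drop <- is.na(raw$event)  # neither time observed
  report["missing_time"] <- sum(drop)
  keep <- raw[!drop, , drop = FALSE]

  bad <- is.na(keep$time) | keep$time <= 0
  report["nonpositive_time"] <- sum(bad)
  keep <- keep[!bad, , drop = FALSE]

  if (length(required)) {
    bad <- rep(FALSE, nrow(keep))
    for (v in required)
      bad <- bad | (avail[keep$group, v] & is.na(keep[[v]]))
    report["missing_required"] <- sum(bad)
    keep <- keep[!bad, , drop = FALSE]
  }

  other <- setdiff(covs, required)
  if (length(other)) {
    bad <- rep(FALSE, nrow(keep))
    for (v in other)
      bad <- bad | (avail[keep$group, v] & is.na(keep[[v]]))
    report["incomplete_covariates"] <- sum(bad)
    keep <- keep[!bad, , drop = FALSE]
  }

  if (nrow(keep) == 0L)
    stop("no subjects remain after filtering; input is unusable")
  kept_groups <- unique(keep$group)
  out <- grouped_survival(keep, availability = avail[kept_groups, , drop = FALSE])
  attr(out, "filter_report") <- c(report,
                                  n_removed = sum(report),
                                  n_retained = nrow(keep))
  out
}

#' Removal counts recorded by [filter_subjects()]
#' @param x a `grouped_survival` returned by [filter_subjects()].
#' @return Named integer vector of per-rule removal counts, or `NULL`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Standardize predictors to mean zero and unit standard deviation
#'
#' Each covariate is centred and scaled over the union of subjects belonging
#' to groups that carry it, using the sample standard deviation (divisor
#' n - 1).  The transform is stored on the object so that new data can be
#' mapped to the same scale.  By default standardization is computed once on
#' the full dataset ("global"); under `scope = "refit"` a previously stored
#' transform is discarded and recomputed.
#'
#' @param x a `grouped_survival` object.
#' @param scope `"global"` (default) computes/updates the transform on `x`.
#' @return `x` with standardized covariate columns and `center`/`scale`
#'   recording the mapping from the *original* scale.
#' @export
standardize_predictors <- function(x, scope = c("global", "refit")) {
  stopifnot(inherits(x, "grouped_survival"))
  scope <- match.arg(scope)
  covs <- x$covariates
  if (!length(covs)) return(x)
  old_center <- if (is.null(x$center)) setNames(rep(0, length(covs)), covs) else x$center
  old_scale <- if (is.null(x$scale)) setNames(rep(1, length(covs)), covs) else x$scale
  if (scope == "refit") {
    old_center[] <- 0; old_scale[] <- 1
  }
  m <- s <- setNames(numeric(length(covs)), covs)
  for (v in covs) {
    vals <- x$data[[v]][x$availability[x$data$group, v]]
    m[v] <- mean(vals)
    s[v] <- sd(vals)
    if (!is.finite(s[v]) || s[v] == 0)
      stop("covariate '", v, "' has zero variance; cannot standardize")
    x$data[[v]] <- (x$data[[v]] - m[v]) / s[v]
  }
  # compose with any earlier transform so center/scale always map raw -> current
  x$center <- setNames(old_center + old_scale * m, covs)
  x$scale <- setNames(old_scale * s, covs)
  x
}

#' Apply a stored standardization transform to new data
#' @param x a standardized `grouped_survival` carrying `center`/`scale`.
#' @param newdata a `grouped_survival` on the original covariate scale.
#' @return `newdata` with covariates mapped to `x`'s scale.
#' @export
apply_standardization <- function(x, newdata) {
  stopifnot(inherits(x, "grouped_survival"), inherits(newdata, "grouped_survival"))
  if (is.null(x$center)) return(newdata)
  for (v in intersect(names(x$center), newdata$covariates))
    newdata$data[[v]] <- (newdata$data[[v]] - x$center[v]) / x$scale[v]
  newdata
}

#' Read / write grouped survival tables
#'
#' The on-disk format is a delimited text table (comma or tab separated,
#' header row) with columns `group`, `time`, `event` and one column per
#' covariate; empty cells denote missing values.  Structural availability is
#' inferred from all-empty columns within a group unless supplied.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @param availability optional availability matrix, see [grouped_survival()].
#' @return `read_grouped_survival()` returns a `grouped_survival`;
#'   `write_grouped_survival()` invisibly returns `path`.
#' @export
read_grouped_survival <- function(path, sep = NULL, availability = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  grouped_survival(raw, availability = availability)
}

#' @rdname read_grouped_survival
#' @param x a `grouped_survival` object.
#' @export
write_grouped_survival <- function(x, path, sep = NULL) {
  stopifnot(inherits(x, "grouped_survival"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- x$data
  for (v in names(df)) {
    if (is.double(df[[v]])) {
      # 17 significant digits so doubles survive the text round trip exactly
      out <- sprintf("%.17g", df[[v]])
      out[is.na(df[[v]])] <- ""
      df[[v]] <- out
    }
  }
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}
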