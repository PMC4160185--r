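# Two-step aggregation to per-participant/condition summaries (the deposited
# feature-table row shape), stability metrics, estimator comparison, and
# tidy export for external inferential statistics.

.default_features <- c("delta_phi_hilbert_deg", "delta_phi_time_deg",
                       "r_amp", "r_time", "theta_offset_deg")

#' Two-step condition summary
#'
#' Means and standard deviations of each feature, aggregated exactly as in
#' the study's feature statistics: first per transition (two transitions for
#' the circular patterns, four for the figure-of-eight), then averaged across
#' transitions *unweighted*. This is deliberately not a pooled statistic:
#' transitions with unequal event counts contribute equally. Transitions
#' with zero valid events for a feature are excluded and counted in
#' `n_transitions`.
#'
#' @param features feature table from [extract_features()], carrying a
#'   `transition_id` column
#' @param feature_cols feature columns to summarize
#' @param metadata optional named list of condition descriptors attached as
#'   columns (participant id, pattern, tempo, ...)
#' @return data.frame, one row per feature: `feature`, `mean`, `sd`,
#'   `n_transitions`, `n_events` plus metadata columns
#' @export
summarize_condition <- function(features, feature_cols = .default_features,
                                metadata = list()) {
  if (!"transition_id" %in% names(features))
    stop("features must carry a transition_id column")
  feature_cols <- intersect(feature_cols, names(features))
  ids <- sort(unique(features$transition_id))
  rows <- lapply(feature_cols, function(fc) {
    per <- lapply(ids, function(id) {
      v <- features[[fc]][features$transition_id == id]
      v <- v[is.finite(v)]
      if (!length(v)) return(NULL)
      c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        n = length(v))
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (!length(per))
      return(data.frame(feature = fc, mean = NA_real_, sd = NA_real_,
                        n_transitions = 0L, n_events = 0L))
    m <- do.call(rbind, per)
    data.frame(feature = fc,
               mean = mean(m[, "mean"]),
               sd = mean(m[, "sd"]),
               n_transitions = nrow(m),
               n_events = as.integer(sum(m[, "n"])))
  })
  out <- do.call(rbind, rows)
  for (nm in names(metadata)) out[[nm]] <- metadata[[nm]]
  rownames(out) <- NULL
  out
}

#' Coefficient of variation
#'
#' `sd / |mean|`; an error for zero mean, where the CV is undefined.
#'
#' @param values numeric vector
#' @return dimensionless
#' @export
coefficient_of_variation <- function(values) {
  v <- values[is.finite(values)]
  m <- mean(v)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(v) / abs(m)
}

#' Compare two estimators across conditions
#'
#' Pearson correlation and ordinary-least-squares slope of `y` on `x`
#' ("alternative vs. regular" ordering: `x` = regular estimate, `y` =
#' alternative estimate). Pairs with a missing value in either estimate are
#' excluded pairwise.
#'
#' @param x per-condition means of the regular estimator
#' @param y per-condition means of the alternative estimator
#' @return list: `pearson_r`, `slope`, `n`
#' @export
compare_estimators <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x")
  list(pearson_r = stats::cor(x, y),
       slope = stats::cov(x, y) / stats::var(x),
       n = length(x))
}

#' Tidy long-format export of condition summaries
#'
#' One row per participant x condition x feature x statistic, suitable for
#' any mixed-design ANOVA tool. The `mean` and `sd` columns of the summary
#' are melted into a `statistic`/`value` pair; all other columns are carried
#' along as identifiers.
#'
#' @param summaries data.frame as returned by (rbind-ed) calls to
#'   [summarize_condition()]
#' @return long data.frame with columns `feature`, id columns, `statistic`,
#'   `value`
#' @export
export_tidy <- function(summaries) {
  if (!nrow(summaries)) stop("need at least one summary row")
  idcols <- setdiff(names(summaries), c("mean", "sd"))
  long <- rbind(
    cbind(summaries[idcols], statistic = "mean", value = summaries$mean),
    cbind(summaries[idcols], statistic = "sd", value = summaries$sd)
  )
  ord <- do.call(order, c(unname(long[intersect(c("feature", idcols), names(long))]),
                          list(long$statistic)))
  long <- long[ord, ]
  rownames(long) <- NULL
  long
}
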