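#' Configuration for uninformative-feature removal
#'
#' Three criteria, applied sequentially, mark descriptors as uninformative:
#' (1) *extreme values*: the largest absolute value exceeds `extreme_fold`
#' times the average absolute value; (2) *scarcity*: at least `zero_fraction`
#' of the entries are exactly zero; (3) *low variation*: fewer than
#' `min_unique` distinct values. Defaults are 100-fold, 30% and 12.
#'
#' With small-n tables the maximum can never exceed 100 times a mean that
#' includes it, so the reference average for criterion (1) excludes the
#' candidate maximum by default (`extreme_mean = "loo"`); the all-inclusive
#' mean is available as `extreme_mean = "all"`.
#'
#' @param extreme_fold fold-change threshold for criterion (1); > 1.
#' @param zero_fraction inclusive zero-share threshold for criterion (2).
#' @param min_unique minimum distinct-value count for criterion (3);
#'   a feature with exactly `min_unique` distinct values is retained.
#' @param extreme_mean how to compute the reference mean of absolute values:
#'   `"loo"` (exclude the candidate maximum) or `"all"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(extreme_fold = 100, zero_fraction = 0.30,
                          min_unique = 12, extreme_mean = c("loo", "all")) {
  stopifnot(extreme_fold > 1, zero_fraction >= 0, zero_fraction <= 1,
            min_unique >= 2)
  structure(list(extreme_fold = extreme_fold, zero_fraction = zero_fraction,
                 min_unique = as.integer(min_unique),
                 extreme_mean = match.arg(extreme_mean)),
            class = "filter_config")
}

#' Remove uninformative descriptors
#'
#' Applies the three filters of [filter_config()] sequentially, each on the
#' survivors of the previous one, so each removed feature is attributed to the
#' first criterion that fired. Boundary semantics: the zero-share comparison
#' is inclusive (a feature with exactly 30% zeros is scarce) while the
#' distinct-value comparison is strict (exactly 12 distinct values is
#' retained). Zeros are compared by exact equality: descriptor values are
#' computed quantities and their zeros are structural.
#'
#' @param table a [descriptor_table()] with at least 2 chemicals.
#' @param config a [filter_config()].
#' @return A list with `table` (the filtered [descriptor_table()]) and
#'   `report` (a `filter_report` with the removal lists and survivor count).
#' @export
remove_useless_features <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(config, "filter_config"))
  if (nrow(table$values) < 2) stop("need at least 2 chemicals to filter")
  vals <- table$values

  is_extreme <- function(x) {
    a <- abs(x)
    i <- which.max(a)
    m <- if (config$extreme_mean == "loo") mean(a[-i]) else mean(a)
    if (m == 0) return(a[i] > 0)
    a[i] > config$extreme_fold * m
  }
  extreme <- colnames(vals)[apply(vals, 2, is_extreme)]
  keep <- setdiff(colnames(vals), extreme)

  zero_frac <- colMeans(vals[, keep, drop = FALSE] == 0)
  scarce <- keep[zero_frac >= config$zero_fraction]
  keep <- setdiff(keep, scarce)

  n_unique <- apply(vals[, keep, drop = FALSE], 2,
                    function(x) length(unique(x)))
  lowvar <- keep[n_unique < config$min_unique]
  keep <- setdiff(keep, lowvar)

  if (!length(keep)) stop("no features survive filtering")
  report <- structure(list(removed_extreme = extreme,
                           removed_scarce = scarce,
                           removed_low_variation = lowvar,
                           n_surviving = length(keep)),
                      class = "filter_report")
  list(table = subset_table(table, features = keep), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n",
      "  extreme values : ", length(x$removed_extreme), " removed\n",
      "  scarcity       : ", length(x$removed_scarce), " removed\n",
      "  low variation  : ", length(x$removed_low_variation), " removed\n",
      "  surviving      : ", x$n_surviving, "\n", sep = "")
  invisible(x)
}

#' Learn z-score normalization parameters from a training table
#'
#' Computes per-feature center (arithmetic mean) and scale on the given table
#' only; the same parameters are later applied unchanged to test or external
#' tables so that no test information leaks into the preprocessing. The scale
#' is the population standard deviation (divisor n); `scale = "variance"`
#' divides by the population variance instead, for parity experiments with
#' tables normalized that way.
#'
#' @param table a [descriptor_table()] (the training set).
#' @param scale `"sd"` (default) or `"variance"`.
#' @return A `normalization_params` object with `center`, `scale` and `mode`.
#' @export
fit_normalizer <- function(table, scale = c("sd", "variance")) {
  stopifnot(inherits(table, "descriptor_table"))
  scale <- match.arg(scale)
  mu <- colMeans(table$values)
  v <- colMeans(sweep(table$values, 2, mu)^2)  # population variance
  if (any(v == 0))
    stop("zero-scale (constant) feature: ",
         paste(names(v)[v == 0], collapse = ", "))
  s <- if (scale == "sd") sqrt(v) else v
  structure(list(center = mu, scale = s, mode = scale),
            class = "normalization_params")
}

#' Apply z-score normalization
#'
#' Replaces each value x by (x - mu) / sigma using parameters learned with
#' [fit_normalizer()]. Target columns (`ci`, `ci_min`, `ci_variation`) are
#' left untouched.
#'
#' @param table a [descriptor_table()].
#' @param params a `normalization_params` covering every feature of `table`.
#' @return The normalized [descriptor_table()] (flagged `normalized`).
#' @export
apply_normalizer <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(params, "normalization_params"))
  miss <- setdiff(table$feature_names, names(params$center))
  if (length(miss))
    stop("features missing from normalization params: ",
         paste(miss, collapse = ", "))
  mu <- params$center[table$feature_names]
  s <- params$scale[table$feature_names]
  z <- sweep(sweep(table$values, 2, mu), 2, s, "/")
  out <- table
  out$values <- z
  out$normalized <- TRUE
  out
}

#' Invert z-score normalization
#'
#' @param table a normalized [descriptor_table()].
#' @param params the `normalization_params` used to normalize it.
#' @return The table on the original scale.
#' @export
invert_normalizer <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(params, "normalization_params"))
  mu <- params$center[table$feature_names]
  s <- params$scale[table$feature_names]
  out <- table
  out$values <- sweep(sweep(table$values, 2, s, "*"), 2, mu, "+")
  out$normalized <- FALSE
  out
}
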