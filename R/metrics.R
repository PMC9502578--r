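#' Sample Pearson correlation coefficient
#'
#' The workflow's single performance criterion: model fitting, LOOCV and test
#' performance are all summarized as the Pearson correlation between observed
#' and predicted clearance indices.
#'
#' @param a,b numeric vectors of equal length >= 3, neither constant.
#' @return The sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for constant input")
  stats::cor(a, b)
}

#' Mean absolute error
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return mean(|observed - predicted|).
#' @export
mae <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("vectors must have equal length")
  mean(abs(observed - predicted))
}

#' Relative absolute error
#'
#' Absolute error divided by the observed value, the scale-free error used
#' when judging single external predictions.
#'
#' @param observed positive observed value(s).
#' @param predicted predicted value(s).
#' @return |observed - predicted| / observed.
#' @export
relative_absolute_error <- function(observed, predicted) {
  if (any(observed == 0))
    stop("relative absolute error undefined for observed value 0")
  abs(observed - predicted) / observed
}

#' Evaluate a model against observed CI or minimum CI
#'
#' Predicts the table with the model and reports the Pearson correlation,
#' mean absolute error and per-chemical errors against the chosen target:
#' `"ci"` (the reported average clearance index) or `"ci_min"` (the minimum
#' CI within experimental variation, a variation-aware target for external
#' sets). Per-chemical relative errors are `NA` where the observed value is
#' zero.
#'
#' @param model a fitted `ci_model`.
#' @param table a [descriptor_table()] carrying the chosen target column.
#' @param against `"ci"` or `"ci_min"`.
#' @param predictions optional precomputed predictions aligned with the
#'   table (e.g. LOOCV predictions); default is `predict(model, table)`.
#' @return An `evaluation` list: `pearson_r`, `mae`, `n`, `against` and a
#'   `per_chemical` data.frame.
#' @export
evaluate_model <- function(model, table, against = c("ci", "ci_min"),
                           predictions = NULL) {
  against <- match.arg(against)
  obs <- table[[against]]
  if (is.null(obs)) stop("table has no `", against, "` column")
  pred <- if (is.null(predictions)) predict(model, table)
          else as.numeric(predictions)
  if (length(pred) != length(obs))
    stop("predictions not aligned with table")
  abs_err <- abs(obs - pred)
  rel_err <- ifelse(obs == 0, NA_real_, abs_err / obs)
  structure(list(
    pearson_r = pearson_r(obs, pred),
    mae = mean(abs_err),
    n = length(obs),
    against = against,
    per_chemical = data.frame(chemical_id = table$chemical_ids,
                              observed = obs, predicted = as.numeric(pred),
                              absolute_error = abs_err,
                              relative_absolute_error = rel_err,
                              stringsAsFactors = FALSE)
  ), class = "evaluation")
}

#' @export
print.evaluation <- function(x, ...) {
  cat("<evaluation> against =", x$against, "| n =", x$n, "\n")
  cat(sprintf("  pearson_r = %.4f   mae = %.4f\n", x$pearson_r, x$mae))
  invisible(x)
}
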