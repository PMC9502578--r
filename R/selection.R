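#' Sequential forward feature selection driven by LOOCV correlation
#'
#' Greedy wrapper selection: at each step every unselected feature is
#' appended in turn to the current set, the candidate set is scored by the
#' Pearson correlation between observed CI and leave-one-out
#' cross-validation predictions, and the best candidate (ties broken by
#' lowest column index) is taken. The first feature is accepted
#' unconditionally; afterwards a step is accepted only if it improves the
#' LOOCV correlation by at least `threshold` (an absolute increment of 0.01
#' in r by default; `relative = TRUE` interprets the threshold as a fraction
#' of the current r). Selection stops at the first step whose best candidate
#' falls short of the threshold, or when `max_features` is reached; the
#' triggering step is retained in the trace as rejected.
#'
#' Every candidate evaluation reuses the spec's seed, so forest-based scores
#' are comparable across candidates. A candidate whose LOOCV fails (e.g.
#' singular design) is scored `-Inf` and logged, not fatal.
#'
#' @param table a normalized [descriptor_table()] with `ci` and >= 2
#'   candidate features.
#' @param spec a [model_spec()].
#' @param threshold minimum LOOCV-r improvement to accept a step; default
#'   0.01.
#' @param max_features cap on accepted features; default `min(n - 2, 30)`.
#' @param relative interpret `threshold` as a fraction of the current r.
#' @return An `sfs_trace`: a data.frame with one row per step (`feature`,
#'   `loocv_r`, `improvement`, `accepted`) carrying the selected feature set
#'   and settings as attributes.
#' @export
sequential_forward_select <- function(table, spec = model_spec(seed = 1),
                                      threshold = 0.01, max_features = NULL,
                                      relative = FALSE) {
  stopifnot(inherits(table, "descriptor_table"), inherits(spec, "model_spec"),
            threshold > 0)
  if (is.null(table$ci)) stop("selection requires target column `ci`")
  n <- nrow(table$values)
  p <- ncol(table$values)
  if (p < 2) stop("need at least 2 candidate features")
  if (is.null(max_features)) max_features <- min(n - 2L, 30L)
  X <- table$values
  y <- table$ci

  selected <- integer(0)
  best_r <- -Inf
  steps <- list()
  failures <- character(0)

  repeat {
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining) || length(selected) >= max_features) break
    cand_best_r <- -Inf
    cand_best_j <- NA_integer_
    for (j in remaining) {  # ascending column order => deterministic ties
      r_j <- tryCatch({
        preds <- loocv_core(X[, c(selected, j), drop = FALSE], y, spec)
        pearson_r(y, preds)
      }, error = function(e) {
        failures <<- c(failures, paste0(colnames(X)[j], ": ",
                                        conditionMessage(e)))
        -Inf
      })
      if (is.na(r_j)) r_j <- -Inf
      if (r_j > cand_best_r) {
        cand_best_r <- r_j
        cand_best_j <- j
      }
    }
    if (!is.finite(cand_best_r)) break
    need <- if (!length(selected)) -Inf
            else if (relative) threshold * abs(best_r) else threshold
    improvement <- cand_best_r - best_r
    accepted <- improvement >= need
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L,
      feature = colnames(X)[cand_best_j],
      loocv_r = cand_best_r,
      improvement = if (length(selected)) improvement else NA_real_,
      accepted = accepted,
      stringsAsFactors = FALSE)
    if (!accepted) break
    selected <- c(selected, cand_best_j)
    best_r <- cand_best_r
  }

  if (!length(steps))
    stop("no candidate feature could be scored (all LOOCV evaluations ",
         "failed); first failure: ",
         if (length(failures)) failures[1] else "none recorded")
  trace <- do.call(rbind, steps)
  structure(trace,
            features = colnames(X)[selected],
            accepted_count = length(selected),
            threshold = threshold,
            relative = relative,
            final_loocv_r = best_r,
            candidate_failures = failures,
            class = c("sfs_trace", "data.frame"))
}

#' Selected features of a selection trace
#'
#' @param trace an `sfs_trace` from [sequential_forward_select()].
#' @return Character vector of accepted features, in selection order.
#' @export
selected_features <- function(trace) {
  stopifnot(inherits(trace, "sfs_trace"))
  attr(trace, "features")
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat("<sfs_trace>", attr(x, "accepted_count"), "features accepted",
      sprintf("(final LOOCV r = %.4f, threshold = %g%s)\n",
              attr(x, "final_loocv_r"), attr(x, "threshold"),
              if (attr(x, "relative")) " relative" else ""))
  print.data.frame(x)
  invisible(x)
}
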