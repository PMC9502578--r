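#' Specify a CI regression model
#'
#' Three model families are supported: ordinary least-squares `linear`
#' regression, a `forest` of regression CARTs, and the voting `ensemble`
#' whose prediction is the weighted mean of exactly those two components
#' (equal weights by default). The forest is grown by the package's own
#' deterministic engine: `n_trees` bootstrap trees, every feature considered
#' at every split (`mtry = NULL`), nodes split while at least `2 * min_node`
#' samples remain, split ties broken by lowest feature index then lowest
#' threshold. A seed is mandatory so that forest and ensemble fits are exactly
#' reproducible.
#'
#' @param kind `"ensemble"`, `"linear"` or `"forest"`.
#' @param n_trees number of trees (>= 1); default 100.
#' @param seed integer seed driving the forest's internal RNG.
#' @param mtry features considered per split; `NULL` means all.
#' @param min_node minimum samples per leaf; default 5.
#' @param bootstrap grow each tree on a bootstrap resample (default) or on the
#'   full sample (`FALSE`, e.g. to grow a single exact-interpolation tree).
#' @param ensemble_weights two nonnegative weights (linear, forest) summing
#'   to 1.
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("ensemble", "linear", "forest"),
                       n_trees = 100, seed = NULL, mtry = NULL, min_node = 5,
                       bootstrap = TRUE, ensemble_weights = c(0.5, 0.5)) {
  kind <- match.arg(kind)
  stopifnot(n_trees >= 1, min_node >= 1,
            length(ensemble_weights) == 2, all(ensemble_weights >= 0))
  if (abs(sum(ensemble_weights) - 1) > 1e-12)
    stop("ensemble_weights must sum to 1")
  if (kind != "linear" && is.null(seed))
    stop("a seed is required for forest and ensemble models")
  structure(list(kind = kind, n_trees = as.integer(n_trees),
                 seed = if (!is.null(seed)) as.integer(seed),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 min_node = as.integer(min_node),
                 bootstrap = isTRUE(bootstrap),
                 ensemble_weights = as.numeric(ensemble_weights)),
            class = "model_spec")
}

# Core fit on a bare matrix; all user-facing entry points funnel through here
# so the LOOCV loop pays no validation overhead.
fit_core <- function(X, y, spec) {
  fm <- list(spec = spec)
  if (spec$kind %in% c("linear", "ensemble"))
    fm$linear <- cpp_ols(X, y)
  if (spec$kind %in% c("forest", "ensemble"))
    fm$forest <- cpp_forest_fit(X, y, spec$n_trees,
                                if (is.null(spec$mtry)) ncol(X) else spec$mtry,
                                spec$min_node, spec$bootstrap,
                                as.double(spec$seed %||% 0L))
  fm
}

predict_core <- function(fm, X) {
  spec <- fm$spec
  lin <- if (!is.null(fm$linear))
    drop(cbind(1, X) %*% fm$linear$coefficients)
  fst <- if (!is.null(fm$forest)) cpp_forest_predict(fm$forest, X)
  switch(spec$kind,
         linear = lin,
         forest = fst,
         ensemble = spec$ensemble_weights[1] * lin +
                    spec$ensemble_weights[2] * fst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a CI regression model
#'
#' Fits the family requested by the [model_spec()] on the given (normalized)
#' training table, restricted to `features`. The linear component is ordinary
#' least squares with intercept; an ensemble stores both components, and its
#' stored linear coefficients are identical to a pure linear fit on the same
#' inputs.
#'
#' @param table a [descriptor_table()] with `ci` present; should be normalized
#'   (a raw table is accepted but downstream consistency is the caller's
#'   responsibility).
#' @param features character vector of feature names to use.
#' @param spec a [model_spec()].
#' @return A `ci_model` with components, normalization slot (filled by the
#'   training workflow) and training references.
#' @export
fit_ci_model <- function(table, features, spec = model_spec(seed = 1)) {
  stopifnot(inherits(table, "descriptor_table"), inherits(spec, "model_spec"))
  if (is.null(table$ci)) stop("training requires target column `ci`")
  miss <- setdiff(features, table$feature_names)
  if (length(miss))
    stop("features not in table: ", paste(miss, collapse = ", "))
  n <- nrow(table$values)
  if (n < 3) stop("need at least 3 chemicals to fit")
  if (length(features) > n - 2)
    warning("more features (", length(features), ") than n - 2 = ", n - 2,
            "; fit may be unstable")
  X <- table$values[, features, drop = FALSE]
  fm <- fit_core(X, table$ci, spec)
  fm$feature_names <- features
  fm$training_ids <- table$chemical_ids
  fm$training_values <- X
  fm$training_ci <- table$ci
  fm$normalization <- NULL
  class(fm) <- "ci_model"
  fm
}

#' Predict clearance-index values
#'
#' @param object a fitted `ci_model`.
#' @param table a [descriptor_table()] containing all model features. If the
#'   model carries normalization parameters and the table is not flagged
#'   normalized, the parameters are applied first (`auto_normalize`).
#' @param auto_normalize apply the model's stored normalization to raw tables.
#' @param ... unused.
#' @return Named numeric vector of predicted CI, aligned to chemical ids.
#' @export
predict.ci_model <- function(object, table, auto_normalize = TRUE, ...) {
  stopifnot(inherits(table, "descriptor_table"))
  miss <- setdiff(object$feature_names, table$feature_names)
  if (length(miss))
    stop("table lacks model features: ", paste(miss, collapse = ", "))
  if (!table$normalized && auto_normalize && !is.null(object$normalization))
    table <- normalize_for_model(object, table)
  X <- table$values[, object$feature_names, drop = FALSE]
  p <- predict_core(object, X)
  names(p) <- table$chemical_ids
  p
}

#' @export
print.ci_model <- function(x, ...) {
  cat("<ci_model> kind =", x$spec$kind, "|", length(x$feature_names),
      "features |", length(x$training_ids), "training chemicals\n")
  if (!is.null(x$linear)) {
    cat("  linear coefficients:\n")
    print(stats::setNames(x$linear$coefficients,
                          c("(Intercept)", x$feature_names)))
  }
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For each chemical i, fits the model on the other n - 1 chemicals and
#' predicts i; returns out-of-fold predictions aligned to chemical ids. Every
#' fold reuses the spec's seed so that candidate evaluations during feature
#' selection are comparable. By default the table is used as given (the
#' workflow normalizes once on the full training set before selection);
#' `strict = TRUE` refits the normalizer within each fold, treating the
#' table's values as raw.
#'
#' @param table a [descriptor_table()] with `ci`; n >= 3.
#' @param features feature names to use.
#' @param spec a [model_spec()].
#' @param strict refit normalization inside each fold.
#' @return Named numeric vector of out-of-fold predictions.
#' @export
loocv <- function(table, features, spec = model_spec(seed = 1),
                  strict = FALSE) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$ci)) stop("loocv requires target column `ci`")
  n <- nrow(table$values)
  if (n < 3) stop("need at least 3 chemicals for LOOCV")
  miss <- setdiff(features, table$feature_names)
  if (length(miss))
    stop("features not in table: ", paste(miss, collapse = ", "))
  X <- table$values[, features, drop = FALSE]
  preds <- loocv_core(X, table$ci, spec, strict = strict,
                      ids = table$chemical_ids)
  names(preds) <- table$chemical_ids
  preds
}

loocv_core <- function(X, y, spec, strict = FALSE, ids = NULL) {
  n <- nrow(X)
  if (!strict) {
    # single C++ pass; reproduces the explicit fit/predict fold loop exactly.
    # On failure, fall through to the R loop, which names the offending fold.
    kind <- match(spec$kind, c("linear", "forest", "ensemble")) - 1L
    preds <- tryCatch(
      cpp_loocv(X, y, kind, spec$n_trees,
                if (is.null(spec$mtry)) ncol(X) else spec$mtry,
                spec$min_node, spec$bootstrap,
                as.double(spec$seed %||% 0L),
                spec$ensemble_weights[1], spec$ensemble_weights[2]),
      error = function(e) NULL)
    if (!is.null(preds)) return(preds)
  }
  preds <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    Xte <- X[i, , drop = FALSE]
    if (strict) {
      mu <- colMeans(Xtr)
      s <- sqrt(colMeans(sweep(Xtr, 2, mu)^2))
      if (any(s == 0)) stop("constant feature within LOOCV fold")
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, s, "/")
    }
    fm <- tryCatch(fit_core(Xtr, ytr, spec), error = function(e)
      stop("LOOCV fold leaving out ",
           if (!is.null(ids)) ids[i] else paste("row", i), ": ",
           conditionMessage(e), call. = FALSE))
    preds[i] <- predict_core(fm, Xte)
  }
  preds
}

#' Rank the features of an ensemble model
#'
#' Features are ranked by absolute linear coefficient (descending) and by
#' forest impurity importance (descending); the overall ranking is the rank of
#' the sum of the two ranks, with ties sharing the smaller rank.
#'
#' @param model an ensemble `ci_model`.
#' @return A data.frame with coefficients, importances, the two per-component
#'   ranks and the overall ranking.
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "ci_model"))
  if (model$spec$kind != "ensemble")
    stop("feature ranking requires an ensemble model")
  coef <- model$linear$coefficients[-1]
  imp <- model$forest$importance
  rank_desc <- function(x) rank(-x, ties.method = "min")
  r_lin <- rank_desc(abs(coef))
  r_for <- rank_desc(imp)
  data.frame(feature = model$feature_names,
             linear_coefficient = as.numeric(coef),
             rank_by_coefficient = as.integer(r_lin),
             forest_importance = as.numeric(imp),
             rank_by_importance = as.integer(r_for),
             overall_ranking = as.integer(rank(r_lin + r_for,
                                               ties.method = "min")),
             stringsAsFactors = FALSE)
}

#' Save a fitted model as JSON
#'
#' The artifact stores the spec, selected features, normalization parameters,
#' linear coefficients, seed and the training data itself; forests are refit
#' deterministically on load rather than serialized opaquely, so the file is
#' portable, human-readable and exactly reproducible.
#'
#' @param model a `ci_model`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ci_model"))
  obj <- list(
    format = "ciperm_model", version = 1L,
    spec = unclass(model$spec),
    feature_names = model$feature_names,
    normalization = if (!is.null(model$normalization))
      list(center = as.list(model$normalization$center),
           scale = as.list(model$normalization$scale),
           mode = model$normalization$mode),
    linear_coefficients = if (!is.null(model$linear))
      as.numeric(model$linear$coefficients),
    training = list(ids = model$training_ids,
                    ci = as.numeric(model$training_ci),
                    # row-major flat vector; reshaped on load
                    values = as.numeric(t(model$training_values)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path path written by [save_model()].
#' @return A `ci_model`; forest components are refit deterministically from
#'   the stored training data and seed.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ciperm_model"))
    stop("not a ciperm model file: ", path)
  spec <- do.call(model_spec, c(
    list(kind = obj$spec$kind, n_trees = obj$spec$n_trees,
         seed = obj$spec$seed, min_node = obj$spec$min_node,
         bootstrap = obj$spec$bootstrap,
         ensemble_weights = obj$spec$ensemble_weights),
    if (!is.null(obj$spec$mtry)) list(mtry = obj$spec$mtry)))
  X <- matrix(as.numeric(obj$training$values),
              nrow = length(obj$training$ids),
              ncol = length(obj$feature_names), byrow = TRUE,
              dimnames = list(obj$training$ids, obj$feature_names))
  tab <- descriptor_table(X, chemical_ids = obj$training$ids,
                          ci = obj$training$ci, normalized = TRUE)
  model <- fit_ci_model(tab, obj$feature_names, spec)
  if (!is.null(obj$normalization))
    model$normalization <- structure(
      list(center = unlist(obj$normalization$center),
           scale = unlist(obj$normalization$scale),
           mode = obj$normalization$mode),
      class = "normalization_params")
  if (!is.null(obj$linear_coefficients) &&
      max(abs(model$linear$coefficients - obj$linear_coefficients)) > 1e-8)
    stop("stored linear coefficients disagree with the refit; corrupt file?")
  model
}
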