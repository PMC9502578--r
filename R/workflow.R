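#' Train the full CI prediction workflow
#'
#' Runs the complete training pipeline in the canonical order:
#' uninformative-feature removal, z-score normalization (parameters from the
#' training table only), LOOCV-driven sequential forward selection, the final
#' model fit, and applicability-domain derivation from the training LOOCV
#' errors. When `out_dir` is given, every artifact is written there as
#' deterministic JSON/CSV (rerunning with the same inputs and seed produces
#' byte-identical files).
#'
#' @param table the raw training [descriptor_table()]; must carry `ci`.
#' @param spec a [model_spec()] for selection and the final model.
#' @param filter a [filter_config()].
#' @param selection_threshold minimum LOOCV-r gain to accept a feature.
#' @param ad_threshold minimum r gain to accept an exclusion rule.
#' @param tree_control an [ad_tree_control()].
#' @param max_features cap on selected features (default `min(n - 2, 30)`).
#' @param out_dir optional directory for artifacts.
#' @return A list with `filter_report`, `normalization`, `trace`, `model`
#'   (normalization attached), `ad`, `loocv_predictions` and `evaluation`
#'   (fitting/LOOCV reports, full and within-AD).
#' @export
run_train <- function(table, spec = model_spec(seed = 1),
                      filter = filter_config(), selection_threshold = 0.01,
                      ad_threshold = 0.01, tree_control = ad_tree_control(),
                      max_features = NULL, out_dir = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$ci)) stop("training requires target column `ci`")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage `", name, "`: ", conditionMessage(e), call. = FALSE))
  }

  filtered <- stage("filter", remove_useless_features(table, filter))
  params <- stage("normalize", fit_normalizer(filtered$table))
  norm_table <- stage("normalize", apply_normalizer(filtered$table, params))
  trace <- stage("select",
                 sequential_forward_select(norm_table, spec,
                                           threshold = selection_threshold,
                                           max_features = max_features))
  feats <- selected_features(trace)
  model <- stage("fit", fit_ci_model(norm_table, feats, spec))
  model$normalization <- params
  cv <- stage("loocv", loocv(norm_table, feats, spec))
  ad <- stage("ad", derive_ad(norm_table, feats, cv,
                              threshold = ad_threshold,
                              tree_control = tree_control,
                              normalization = params))

  flags <- apply_ad(ad, norm_table)
  fitting <- evaluate_model(model, norm_table, "ci")
  loocv_eval <- evaluate_model(model, norm_table, "ci", predictions = cv)
  inside <- flags$in_ad
  sub <- subset_table(norm_table, chemicals = inside)
  evaluation <- list(
    fitting = fitting,
    loocv = loocv_eval,
    fitting_within_ad = evaluate_model(model, sub, "ci"),
    loocv_within_ad = evaluate_model(model, sub, "ci",
                                     predictions = cv[inside]))

  result <- list(filter_report = filtered$report, normalization = params,
                 trace = trace, model = model, ad = ad,
                 loocv_predictions = cv, evaluation = evaluation)
  if (!is.null(out_dir)) write_train_artifacts(result, out_dir)
  result
}

# Normalize a (possibly raw) table with the model's stored parameters,
# first dropping columns the training filter removed: a raw prediction
# table legitimately carries descriptors that never made it past filtering
# and therefore have no normalization parameters.
normalize_for_model <- function(model, table) {
  if (table$normalized || is.null(model$normalization)) return(table)
  covered <- intersect(table$feature_names, names(model$normalization$center))
  miss <- setdiff(model$feature_names, covered)
  if (length(miss))
    stop("table lacks model features: ", paste(miss, collapse = ", "))
  apply_normalizer(subset_table(table, features = covered),
                   model$normalization)
}

write_train_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = I(17),
    null = "null", pretty = TRUE)
  wj(unclass(result$filter_report), "filter_report.json")
  wj(list(center = as.list(result$normalization$center),
          scale = as.list(result$normalization$scale),
          mode = result$normalization$mode), "normalization_params.json")
  tr <- result$trace
  wj(list(steps = as.data.frame(tr), features = attr(tr, "features"),
          threshold = attr(tr, "threshold"),
          final_loocv_r = attr(tr, "final_loocv_r")), "selection_trace.json")
  utils::write.csv(as.data.frame(tr),
                   file.path(out_dir, "selection_trace.csv"),
                   row.names = FALSE)
  save_model(result$model, file.path(out_dir, "model.json"))
  write_ad_model(result$ad, file.path(out_dir, "ad_model.json"))
  ev <- lapply(result$evaluation, function(e)
    list(pearson_r = e$pearson_r, mae = e$mae, n = e$n))
  wj(c(ev, list(loocv_predictions = as.list(result$loocv_predictions))),
     "evaluation_train.json")
  wj(list(stages = c("filter", "normalize", "select", "fit", "loocv", "ad"),
          selection_threshold = attr(tr, "threshold"),
          ad_improvements = result$ad$improvement_log,
          n_rules = length(result$ad$rules),
          ad_training_coverage = result$ad$training_coverage,
          n_features_selected = attr(tr, "accepted_count"),
          n_features_surviving = result$filter_report$n_surviving),
     "run_log.json")
  invisible(out_dir)
}

#' Predict a table with a trained model and applicability domain
#'
#' Normalizes the table with the model's stored training parameters (unless
#' already normalized), predicts CI, and flags each chemical against the
#' applicability domain. The table's observed CI, if any, is never read.
#'
#' @param model a `ci_model` with normalization attached (from
#'   [run_train()]).
#' @param table a [descriptor_table()] of chemicals to predict.
#' @param ad optional `ad_model`; when `NULL`, `in_ad` is `NA` (unassessed).
#' @param path optional CSV output path (via [write_predictions()]).
#' @return A data.frame of prediction records.
#' @export
run_predict <- function(model, table, ad = NULL, path = NULL) {
  stopifnot(inherits(model, "ci_model"))
  table <- normalize_for_model(model, table)
  pred <- predict(model, table)
  if (is.null(ad)) {
    rec <- prediction_records(table$chemical_ids, pred)
  } else {
    flags <- apply_ad(ad, table)
    rec <- prediction_records(table$chemical_ids, pred, flags$in_ad,
                              flags$matched_rules)
  }
  if (!is.null(path)) write_predictions(rec, path)
  rec
}

#' Evaluate a trained model on a table, overall and within the domain
#'
#' @param model a `ci_model` with normalization attached.
#' @param table a [descriptor_table()] carrying the chosen target.
#' @param against `"ci"` or `"ci_min"`.
#' @param ad optional `ad_model`; when given, a second report restricted to
#'   within-domain chemicals is included.
#' @return A list with `full` and (when `ad` is given) `within_ad`
#'   evaluation reports plus the coverage.
#' @export
run_evaluate <- function(model, table, against = c("ci", "ci_min"),
                         ad = NULL) {
  against <- match.arg(against)
  table <- normalize_for_model(model, table)
  out <- list(full = evaluate_model(model, table, against))
  if (!is.null(ad)) {
    flags <- apply_ad(ad, table)
    out$coverage <- attr(flags, "coverage")
    if (any(flags$in_ad))
      out$within_ad <- evaluate_model(
        model, subset_table(table, chemicals = flags$in_ad), against)
  }
  out
}

#' Split a table into training and test sets
#'
#' Random split utility mirroring the usual QSAR practice of holding out an
#' independent test set (e.g. 66/21 of 87 chemicals).
#'
#' @param table a [descriptor_table()].
#' @param n_test number of test chemicals.
#' @param seed integer seed.
#' @return A list with `train` and `test` descriptor tables.
#' @export
split_table <- function(table, n_test, seed) {
  stopifnot(inherits(table, "descriptor_table"),
            n_test >= 1, n_test < nrow(table$values))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sample.int(nrow(table$values), n_test)
  list(train = subset_table(table, chemicals = -idx),
       test = subset_table(table, chemicals = idx))
}

#' Read a workflow configuration file
#'
#' YAML (or JSON) configuration holding the column mapping, filter
#' thresholds, model spec, selection/AD thresholds and seed used by the
#' command-line interface (`inst/cli/ciperm.R`).
#'
#' @param path path to a YAML or JSON file.
#' @return A named list with `filter`, `spec`, `tree_control`,
#'   `selection_threshold`, `ad_threshold` and `schema` components.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- list(schema = raw$schema %||% list(id_col = "id", ci_col = "CI"))
  cfg$filter <- do.call(filter_config, raw$filter %||% list())
  spec_args <- raw$model %||% list(kind = "ensemble", seed = raw$seed %||% 1)
  if (is.null(spec_args$seed)) spec_args$seed <- raw$seed %||% 1
  cfg$spec <- do.call(model_spec, spec_args)
  cfg$tree_control <- do.call(ad_tree_control, raw$ad_tree %||% list())
  cfg$selection_threshold <- raw$selection_threshold %||% 0.01
  cfg$ad_threshold <- raw$ad_threshold %||% 0.01
  cfg$seed <- raw$seed %||% 1
  cfg
}
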