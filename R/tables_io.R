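#' Construct a descriptor table
#'
#' The central container of the package: one row per chemical, one column per
#' numeric molecular descriptor, with an optional experimental clearance index
#' (CI) target. The CI is the permeability of a chemical across the ex vivo
#' perfused human placenta relative to antipyrine, a dimensionless nonnegative
#' ratio. `ci_min` is the lower bound of the reported CI within experimental
#' variation, and `ci_variation` the variation itself; both are optional and
#' only used for variation-aware external evaluation.
#'
#' @param values numeric matrix (chemicals x descriptors) with finite entries;
#'   column names are the feature names.
#' @param chemical_ids character vector of unique, non-empty identifiers, one
#'   per row of `values`.
#' @param ci optional numeric vector of nonnegative clearance-index values.
#' @param ci_min optional numeric vector of nonnegative minimum-CI values.
#' @param ci_variation optional numeric vector of nonnegative experimental
#'   variations.
#' @param chemical_names,smiles optional character annotations, one per row.
#' @param normalized logical flag declaring whether `values` are already
#'   z-score normalized. Loaders cannot infer this from the numbers, so it is
#'   carried as metadata set by the caller.
#'
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(values, chemical_ids = rownames(values),
                             ci = NULL, ci_min = NULL, ci_variation = NULL,
                             chemical_names = NULL, smiles = NULL,
                             normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(chemical_ids))
    stop("chemical_ids are required (or set rownames on `values`)")
  chemical_ids <- as.character(chemical_ids)
  if (length(chemical_ids) != nrow(values))
    stop("length of chemical_ids (", length(chemical_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (any(!nzchar(chemical_ids)))
    stop("chemical ids must be non-empty strings")
  dup <- unique(chemical_ids[duplicated(chemical_ids)])
  if (length(dup))
    stop("duplicated chemical ids: ", paste(dup, collapse = ", "))
  if (is.null(colnames(values)))
    stop("`values` must have column names (feature names)")
  fdup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(fdup))
    stop("duplicated feature names: ", paste(fdup, collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], " (", chemical_ids[bad[1]],
         "), column ", bad[2], " (", colnames(values)[bad[2]], ")")
  }
  check_target <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != nrow(values))
      stop("`", nm, "` must have one value per chemical")
    if (any(!is.finite(x)))
      stop("`", nm, "` contains missing or non-finite values; the workflow ",
           "does not impute")
    if (any(x < 0))
      stop("`", nm, "` must be nonnegative (CI is a nonnegative ratio)")
    x
  }
  rownames(values) <- chemical_ids
  structure(list(
    chemical_ids = chemical_ids,
    chemical_names = if (!is.null(chemical_names)) as.character(chemical_names),
    smiles = if (!is.null(smiles)) as.character(smiles),
    feature_names = colnames(values),
    values = values,
    ci = check_target(ci, "ci"),
    ci_min = check_target(ci_min, "ci_min"),
    ci_variation = check_target(ci_variation, "ci_variation"),
    normalized = isTRUE(normalized)
  ), class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x$values), " chemicals x ",
      ncol(x$values), " features", if (x$normalized) " (normalized)",
      "\n", sep = "")
  cat("  targets:",
      paste(c("ci", "ci_min", "ci_variation")[
        !vapply(x[c("ci", "ci_min", "ci_variation")], is.null, logical(1))],
        collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Subset a descriptor table by chemicals and/or features
#'
#' @param table a [descriptor_table()].
#' @param chemicals row selector (indices, logicals or ids); default all.
#' @param features column selector (indices, logicals or names); default all.
#' @return A `descriptor_table` with the selected rows/columns.
#' @export
subset_table <- function(table, chemicals = NULL, features = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  ri <- seq_along(table$chemical_ids)
  if (!is.null(chemicals)) {
    ri <- if (is.character(chemicals)) match(chemicals, table$chemical_ids)
          else ri[chemicals]
    if (anyNA(ri)) stop("unknown chemical ids in selection")
  }
  ci_cols <- if (is.null(features)) table$feature_names else features
  descriptor_table(
    table$values[ri, ci_cols, drop = FALSE],
    chemical_ids = table$chemical_ids[ri],
    ci = table$ci[ri],
    ci_min = table$ci_min[ri],
    ci_variation = table$ci_variation[ri],
    chemical_names = table$chemical_names[ri],
    smiles = table$smiles[ri],
    normalized = table$normalized
  )
}

#' Read a descriptor table from CSV
#'
#' CSV is the canonical interchange format (UTF-8, `.` decimal separator,
#' header row required) since descriptor tables are typically spreadsheet
#' exports. Every column other than the declared id/name/SMILES/target columns
#' is treated as a numeric feature; file column order is preserved exactly as
#' the feature order, and all downstream deterministic tie-breaks (e.g. in
#' forward selection) refer to this order. Missing or non-numeric entries are
#' rejected, never imputed.
#'
#' @param path path to a CSV file.
#' @param id_col name of the unique-identifier column.
#' @param ci_col,ci_min_col,ci_variation_col optional names of target columns.
#' @param name_col,smiles_col optional annotation columns.
#' @param exclude_cols additional columns to drop (not treated as features).
#' @param normalized logical; declare that stored feature values are already
#'   z-score normalized (the loader cannot tell raw from normalized values).
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, id_col = "id", ci_col = NULL,
                                  ci_min_col = NULL, ci_variation_col = NULL,
                                  name_col = NULL, smiles_col = NULL,
                                  exclude_cols = NULL, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  declared <- c(id_col, ci_col, ci_min_col, ci_variation_col, name_col,
                smiles_col, exclude_cols)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols))
    stop("declared columns absent from file: ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated chemical ids: ", paste(dup, collapse = ", "))

  grab_target <- function(col) {
    if (is.null(col)) return(NULL)
    x <- df[[col]]
    if (is.character(x)) x <- suppressWarnings(as.numeric(x))
    if (anyNA(x))
      stop("missing values in target column `", col, "` (rows ",
           paste(utils::head(which(is.na(x)), 5), collapse = ", "),
           "); no imputation is performed")
    x
  }

  feature_cols <- setdiff(names(df), declared)
  if (!length(feature_cols)) stop("no feature columns remain after mapping")
  vals <- matrix(NA_real_, nrow(df), length(feature_cols),
                 dimnames = list(ids, feature_cols))
  for (j in seq_along(feature_cols)) {
    x <- df[[feature_cols[j]]]
    if (!is.numeric(x)) {
      xi <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xi) & !is.na(x) & nzchar(trimws(as.character(x))))
      if (length(bad))
        stop("non-numeric value `", x[bad[1]], "` in feature column `",
             feature_cols[j], "`, row ", bad[1])
      x <- xi
    }
    if (anyNA(x))
      stop("missing value in feature column `", feature_cols[j], "`, row ",
           which(is.na(x))[1])
    vals[, j] <- x
  }
  descriptor_table(vals, chemical_ids = ids,
                   ci = grab_target(ci_col),
                   ci_min = grab_target(ci_min_col),
                   ci_variation = grab_target(ci_variation_col),
                   chemical_names = if (!is.null(name_col)) df[[name_col]],
                   smiles = if (!is.null(smiles_col)) df[[smiles_col]],
                   normalized = normalized)
}

#' Write a descriptor table to CSV
#'
#' @param table a [descriptor_table()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(id = table$chemical_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$chemical_names)) df$name <- table$chemical_names
  if (!is.null(table$smiles)) df$smiles <- table$smiles
  if (!is.null(table$ci)) df$CI <- table$ci
  if (!is.null(table$ci_min)) df$CI_min <- table$ci_min
  if (!is.null(table$ci_variation)) df$CI_variation <- table$ci_variation
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assemble prediction records
#'
#' @param chemical_id character ids.
#' @param predicted_ci numeric predictions.
#' @param in_ad logical applicability-domain flags; `NA` means the domain was
#'   not assessed.
#' @param matched_rules character vector of `;`-joined matched exclusion-rule
#'   ids (empty string when none). A chemical is out of domain exactly when it
#'   matched at least one rule.
#' @return A `data.frame` of prediction records.
#' @export
prediction_records <- function(chemical_id, predicted_ci, in_ad = NA,
                               matched_rules = "") {
  rec <- data.frame(chemical_id = as.character(chemical_id),
                    predicted_ci = as.numeric(predicted_ci),
                    in_ad = as.logical(in_ad),
                    matched_rules = as.character(matched_rules),
                    stringsAsFactors = FALSE)
  bad <- !is.na(rec$in_ad) & (rec$in_ad == nzchar(rec$matched_rules))
  if (any(bad))
    stop("inconsistent records: in_ad must be FALSE iff matched_rules is ",
         "non-empty (rows ", paste(which(bad), collapse = ", "), ")")
  rec
}

#' Write prediction records to CSV
#'
#' Serializes with enough digits that a write/read round trip preserves
#' predicted values beyond 10 decimal places. Unassessed applicability-domain
#' flags are written as `NA`.
#'
#' @param records a data.frame from [prediction_records()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(records, path) {
  if (!is.data.frame(records) || !nrow(records))
    stop("`records` must be a non-empty data.frame of prediction records")
  out <- records
  out$predicted_ci <- sprintf("%.12g", records$predicted_ci)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prediction records from CSV
#'
#' @param path path written by [write_predictions()].
#' @return A data.frame of prediction records.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chemical_id = "character",
                                       predicted_ci = "numeric",
                                       in_ad = "logical",
                                       matched_rules = "character"))
  df$matched_rules[is.na(df$matched_rules)] <- ""
  df
}
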