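#' Tree settings for applicability-domain rule mining
#'
#' The regression tree that mines exclusion-rule candidates is deliberately
#' shallow: depth 3 and at least 5 chemicals per leaf favour few,
#' interpretable, non-singleton rules on a ~60-90 chemical training set.
#' `cp = 0` disables cost-complexity pre-pruning so that the rule-acceptance
#' loop, not the tree, decides what is kept.
#'
#' @param max_depth maximum tree depth.
#' @param min_leaf minimum chemicals per leaf.
#' @param min_split minimum chemicals in a node to attempt a split.
#' @param cp rpart complexity parameter.
#' @return An `ad_tree_control` list.
#' @export
ad_tree_control <- function(max_depth = 3, min_leaf = 5, min_split = 10,
                            cp = 0) {
  stopifnot(max_depth >= 1, min_leaf >= 1, min_split >= 2)
  structure(list(max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf),
                 min_split = as.integer(min_split), cp = cp),
            class = "ad_tree_control")
}

#' Derive an applicability domain from training LOOCV errors
#'
#' Learns, from the training set only, conjunctive threshold rules describing
#' the descriptor-space region where the model predicts unreliably:
#' (1) the absolute LOOCV error of each training chemical becomes the target
#' of a CART regression tree grown on the model's selected features;
#' (2) each leaf yields one candidate rule — the conjunction of root-to-leaf
#' split conditions, with the leaf's mean absolute error attached;
#' (3) candidates are ranked by leaf mean error, descending;
#' (4) rules are appended to the exclusion set one at a time, a rule being
#' accepted only if the Pearson correlation between observed CI and the
#' (frozen) LOOCV predictions over the not-yet-excluded chemicals improves by
#' at least `threshold`; the loop stops at the first rejection. The tree is
#' grown once and the model is never refit.
#'
#' A chemical is out of domain if it satisfies all conditions of at least one
#' accepted rule. Thresholds are in normalized feature units; pass
#' `normalization` to embed the parameters for raw-unit display.
#'
#' @param table the normalized training [descriptor_table()] with `ci`.
#' @param features the model's selected feature names.
#' @param loocv_predictions out-of-fold predictions aligned with the table.
#' @param threshold minimum correlation improvement to accept a rule
#'   (default 0.01, the same 1% convention as feature selection).
#' @param tree_control an [ad_tree_control()].
#' @param normalization optional `normalization_params` stored for display.
#' @return An `ad_model` with accepted rules, training coverage and the
#'   per-rule improvement log.
#' @export
derive_ad <- function(table, features, loocv_predictions, threshold = 0.01,
                      tree_control = ad_tree_control(),
                      normalization = NULL) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(tree_control, "ad_tree_control"), threshold > 0)
  if (is.null(table$ci)) stop("deriving an AD requires target column `ci`")
  n <- nrow(table$values)
  pred <- as.numeric(loocv_predictions)
  if (length(pred) != n) stop("loocv_predictions not aligned with table")
  miss <- setdiff(features, table$feature_names)
  if (length(miss))
    stop("features not in table: ", paste(miss, collapse = ", "))

  err <- abs(table$ci - pred)
  if (stats::var(err) < 1e-24)
    return(structure(
      list(rules = list(), training_coverage = 1,
           improvement_log = numeric(0), n_training = n,
           baseline_r = pearson_r(table$ci, pred),
           retained_r = pearson_r(table$ci, pred),
           note = "homogeneous errors: degenerate tree (single leaf); no candidate rules",
           features = features, normalization = normalization),
      class = "ad_model"))
  df <- data.frame(.err = err, table$values[, features, drop = FALSE],
                   check.names = FALSE)
  fit <- rpart::rpart(.err ~ ., data = df, method = "anova",
                      control = rpart::rpart.control(
                        maxdepth = tree_control$max_depth,
                        minbucket = tree_control$min_leaf,
                        minsplit = tree_control$min_split,
                        cp = tree_control$cp, xval = 0,
                        maxcompete = 0, maxsurrogate = 0, usesurrogate = 0))

  empty <- function(note) structure(
    list(rules = list(), training_coverage = 1, improvement_log = numeric(0),
         n_training = n, baseline_r = pearson_r(table$ci, pred),
         retained_r = pearson_r(table$ci, pred), note = note,
         features = features, normalization = normalization),
    class = "ad_model")

  frame <- fit$frame
  if (nrow(frame) == 1)
    return(empty("degenerate tree (single leaf); no candidate rules"))

  candidates <- extract_leaf_rules(fit)
  candidates <- candidates[order(-vapply(candidates, `[[`, numeric(1),
                                         "leaf_mean_abs_error"))]

  X <- table$values
  retained <- rep(TRUE, n)
  r_cur <- pearson_r(table$ci, pred)
  baseline_r <- r_cur
  rules <- list()
  improvements <- numeric(0)
  note <- NULL
  for (cand in candidates) {
    matched <- rule_matches(cand, X)
    kept <- retained & !matched
    # leaves partition descriptor space, so eventually a candidate covers
    # everything still retained; it can never improve r and ends the loop
    if (sum(kept) < 3) {
      note <- if (!any(kept))
        "stopped: rule would exclude every remaining chemical"
      else "stopped: fewer than 3 chemicals would remain"
      break
    }
    r_new <- tryCatch(pearson_r(table$ci[kept], pred[kept]),
                      error = function(e) NA_real_)
    if (is.na(r_new) || r_new - r_cur < threshold) break  # first rejection
    cand$id <- paste0("R", length(rules) + 1L)
    rules[[cand$id]] <- cand
    improvements <- c(improvements, r_new - r_cur)
    retained <- kept
    r_cur <- r_new
  }

  structure(list(rules = rules,
                 training_coverage = sum(retained) / n,
                 improvement_log = improvements,
                 n_training = n,
                 baseline_r = baseline_r,
                 retained_r = r_cur,
                 note = note,
                 features = features,
                 normalization = normalization),
            class = "ad_model")
}

# One candidate exclusion rule per leaf: the conjunction of root-to-leaf
# split conditions. Comparators are "<=" (closed on the left) and ">";
# rpart thresholds are midpoints between observed values, so the boundary
# convention never touches training data.
extract_leaf_rules <- function(fit) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  internal <- which(frame$var != "<leaf>")
  split_row <- match(seq_along(nodes), internal)  # frame row -> splits row
  leaves <- which(frame$var == "<leaf>")
  lapply(leaves, function(li) {
    conds <- list()
    node <- nodes[li]
    while (node > 1) {
      parent <- node %/% 2L
      pi <- match(parent, nodes)
      si <- split_row[pi]
      feat <- as.character(frame$var[pi])
      thr <- fit$splits[si, "index"]
      ncat <- fit$splits[si, "ncat"]
      is_left <- node == 2L * parent
      # ncat = -1: left child is x < thr; ncat = +1: left child is x >= thr
      comparator <- if (xor(is_left, ncat > 0)) "<=" else ">"
      conds[[length(conds) + 1L]] <- list(feature = feat,
                                          comparator = comparator,
                                          threshold = as.numeric(thr))
      node <- parent
    }
    list(id = NA_character_,
         conditions = rev(conds),
         leaf_mean_abs_error = as.numeric(frame$yval[li]),
         n_train_matched = as.integer(frame$n[li]))
  })
}

rule_matches <- function(rule, X) {
  m <- rep(TRUE, nrow(X))
  for (cond in rule$conditions) {
    x <- X[, cond$feature]
    m <- m & if (cond$comparator == "<=") x <= cond$threshold
             else x > cond$threshold
  }
  m
}

format_rule <- function(rule) {
  paste(vapply(rule$conditions, function(cond)
    sprintf("%s %s %.4g", cond$feature, cond$comparator, cond$threshold),
    character(1)), collapse = " AND ")
}

#' @export
print.ad_model <- function(x, ...) {
  cat("<ad_model>", length(x$rules), "exclusion rule(s); training coverage",
      sprintf("%.2f%% (%d/%d)\n", 100 * x$training_coverage,
              round(x$training_coverage * x$n_training), x$n_training))
  for (r in x$rules)
    cat(sprintf("  %s: %s  [leaf mean abs error %.3f, n = %d]\n",
                r$id, format_rule(r), r$leaf_mean_abs_error,
                r$n_train_matched))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Apply an applicability domain to a table
#'
#' Flags each chemical as in or out of the applicability domain. A chemical
#' is out of domain exactly when it satisfies all conditions of at least one
#' exclusion rule. The observed CI of the evaluated table is never consulted:
#' domain membership depends on descriptor values alone.
#'
#' @param ad an `ad_model` from [derive_ad()].
#' @param table a normalized [descriptor_table()] containing every feature
#'   referenced by the rules.
#' @return A data.frame (`chemical_id`, `in_ad`, `matched_rules`) with the
#'   coverage (fraction in domain) as attribute `"coverage"`.
#' @export
apply_ad <- function(ad, table) {
  stopifnot(inherits(ad, "ad_model"), inherits(table, "descriptor_table"))
  used <- unique(unlist(lapply(ad$rules, function(r)
    vapply(r$conditions, `[[`, character(1), "feature"))))
  miss <- setdiff(used, table$feature_names)
  if (length(miss))
    stop("table lacks features referenced by rules: ",
         paste(miss, collapse = ", "))
  n <- nrow(table$values)
  matched <- matrix(FALSE, n, length(ad$rules))
  for (k in seq_along(ad$rules))
    matched[, k] <- rule_matches(ad$rules[[k]], table$values)
  in_ad <- !apply(matched, 1, any)
  if (!length(ad$rules)) in_ad <- rep(TRUE, n)
  ids <- names(ad$rules)
  matched_rules <- apply(matched, 1, function(m)
    paste(ids[m], collapse = ";"))
  out <- data.frame(chemical_id = table$chemical_ids, in_ad = in_ad,
                    matched_rules = matched_rules, stringsAsFactors = FALSE)
  attr(out, "coverage") <- mean(in_ad)
  out
}

#' Serialize an applicability domain to JSON
#'
#' Rules are written in human-readable form with thresholds in normalized
#' units; when the model's normalization parameters are embedded, raw-unit
#' thresholds are included for display.
#'
#' @param ad an `ad_model`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_ad_model <- function(ad, path) {
  stopifnot(inherits(ad, "ad_model"))
  rules <- lapply(ad$rules, function(r) {
    conds <- lapply(r$conditions, function(cond) {
      out <- cond
      if (!is.null(ad$normalization)) {
        mu <- ad$normalization$center[[cond$feature]]
        s <- ad$normalization$scale[[cond$feature]]
        if (!is.null(mu)) out$threshold_raw <- cond$threshold * s + mu
      }
      out
    })
    list(id = r$id, text = format_rule(r), conditions = conds,
         leaf_mean_abs_error = r$leaf_mean_abs_error,
         n_train_matched = r$n_train_matched)
  })
  obj <- list(format = "ciperm_ad", version = 1L, rules = unname(rules),
              training_coverage = ad$training_coverage,
              improvement_log = ad$improvement_log,
              n_training = ad$n_training, baseline_r = ad$baseline_r,
              retained_r = ad$retained_r, note = ad$note,
              features = ad$features,
              normalization = if (!is.null(ad$normalization))
                list(center = as.list(ad$normalization$center),
                     scale = as.list(ad$normalization$scale),
                     mode = ad$normalization$mode))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an applicability domain from JSON
#'
#' @param path path written by [write_ad_model()].
#' @return An `ad_model`.
#' @export
read_ad_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ciperm_ad"))
    stop("not a ciperm applicability-domain file: ", path)
  rules <- lapply(obj$rules, function(r)
    list(id = r$id,
         conditions = lapply(r$conditions, function(cond)
           list(feature = cond$feature, comparator = cond$comparator,
                threshold = as.numeric(cond$threshold))),
         leaf_mean_abs_error = as.numeric(r$leaf_mean_abs_error),
         n_train_matched = as.integer(r$n_train_matched)))
  names(rules) <- vapply(rules, `[[`, character(1), "id")
  structure(list(rules = rules,
                 training_coverage = as.numeric(obj$training_coverage),
                 improvement_log = as.numeric(unlist(obj$improvement_log)),
                 n_training = as.integer(obj$n_training),
                 baseline_r = as.numeric(obj$baseline_r),
                 retained_r = as.numeric(obj$retained_r),
                 note = obj$note,
                 features = as.character(unlist(obj$features)),
                 normalization = if (!is.null(obj$normalization))
                   structure(list(
                     center = unlist(obj$normalization$center),
                     scale = unlist(obj$normalization$scale),
                     mode = obj$normalization$mode),
                     class = "normalization_params")),
            class = "ad_model")
}
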