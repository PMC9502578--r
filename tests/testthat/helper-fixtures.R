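# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# A small normalized table with gaussian features and a linear + noise target.
random_table <- function(n = 12, p = 4, seed = 42, noise_sd = 0.3,
                         beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  if (is.null(beta)) beta <- c(1, rep(0.5, p - 1))
  y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  descriptor_table(X, chemical_ids = sprintf("c%02d", seq_len(n)),
                   ci = y - min(y) + 0.1, normalized = TRUE)
}

# y exactly linear in the first feature; remaining features pure noise.
exact_linear_table <- function(n = 10, p_noise = 0, seed = 1, slope = 2,
                               intercept = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (1 + p_noise)), n, 1 + p_noise)
  colnames(X) <- c("signal", if (p_noise) paste0("noise", seq_len(p_noise)))
  y <- intercept + slope * X[, 1]
  descriptor_table(X, chemical_ids = sprintf("c%02d", seq_len(n)),
                   ci = y - min(y) + 0.1, normalized = TRUE)
}

write_demo_csv <- function(path, ids = c("antipyrine", "caffeine", "urea"),
                           ci = c(1.0, 0.9, 0.6)) {
  df <- data.frame(id = ids, A = c(1.5, 2.5, 3.5), B = c(0.1, 0.2, 0.3),
                   C = c(-1, 0, 1), D = c(10, 20, 30), CI = ci)
  write.csv(df, path, row.names = FALSE)
  path
}

# Hand-built applicability domain with known rules, for apply_ad tests.
manual_ad <- function(rules) {
  structure(list(rules = rules, training_coverage = 1,
                 improvement_log = rep(0.05, length(rules)),
                 n_training = 10, baseline_r = 0.8, retained_r = 0.9,
                 note = NULL, features = unique(unlist(lapply(rules, function(r)
                   vapply(r$conditions, `[[`, character(1), "feature")))),
                 normalization = NULL),
            class = "ad_model")
}

rule <- function(id, ...) {
  conds <- list(...)
  list(id = id, conditions = conds, leaf_mean_abs_error = 1,
       n_train_matched = 1L)
}
cond <- function(feature, comparator, threshold) {
  list(feature = feature, comparator = comparator, threshold = threshold)
}
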