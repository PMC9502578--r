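test_that("homogeneous LOOCV errors give a single-leaf tree and no rules", {
  tab <- random_table(n = 20, p = 3, seed = 61)
  preds <- tab$ci + 0.1  # identical absolute error everywhere
  ad <- derive_ad(tab, tab$feature_names, preds)
  expect_length(ad$rules, 0)
  expect_equal(ad$training_coverage, 1)
  expect_match(ad$note, "single leaf")
})

test_that("a planted high-error cluster is excluded by a rule splitting the gap", {
  set.seed(62)
  n <- 60
  f <- c(rnorm(n - 8), runif(8, 3.5, 4.5))  # 8-chemical cluster beyond ~3.5
  g <- rnorm(n)
  y <- abs(1 + 0.5 * rnorm(n))
  err <- c(abs(rnorm(n - 8, 0, 0.15)), abs(rnorm(8, 1.5, 0.3)))  # 10x error
  preds <- y + err * sample(c(-1, 1), n, replace = TRUE)
  tab <- descriptor_table(cbind(f = f, g = g),
                          chemical_ids = sprintf("c%02d", 1:n), ci = y,
                          normalized = TRUE)
  ad <- derive_ad(tab, c("f", "g"), preds)
  expect_gte(length(ad$rules), 1)
  r1 <- ad$rules[[1]]
  f_conds <- Filter(function(cond) cond$feature == "f", r1$conditions)
  expect_gte(length(f_conds), 1)
  thr <- f_conds[[1]]$threshold
  expect_equal(f_conds[[1]]$comparator, ">")
  expect_gt(thr, max(f[1:(n - 8)]))  # threshold inside the gap
  expect_lt(thr, min(f[(n - 7):n]))
  flags <- apply_ad(ad, tab)
  expect_false(any(flags$in_ad[(n - 7):n]))
  expect_equal(ad$training_coverage, sum(flags$in_ad) / n)
  # each accepted rule improved the retained-set correlation by >= 0.01
  expect_true(all(ad$improvement_log >= 0.01))
  expect_gt(ad$retained_r, ad$baseline_r)
})

test_that("retained-set r is recomputed from frozen predictions, never refit", {
  set.seed(63)
  n <- 40
  f <- c(rnorm(n - 6), runif(6, 4, 5))
  y <- abs(1 + 0.4 * rnorm(n))
  preds <- y + c(abs(rnorm(n - 6, 0, 0.1)), abs(rnorm(6, 2, 0.2)))
  tab <- descriptor_table(cbind(f = f), chemical_ids = sprintf("c%02d", 1:n),
                          ci = y, normalized = TRUE)
  ad <- derive_ad(tab, "f", preds)
  flags <- apply_ad(ad, tab)
  kept <- flags$in_ad
  expect_equal(ad$retained_r, pearson_r(y[kept], preds[kept]))
})

test_that("an empty rule set keeps every chemical in domain", {
  tab <- random_table(n = 10, p = 2, seed = 64)
  ad <- manual_ad(list())
  flags <- apply_ad(ad, tab)
  expect_true(all(flags$in_ad))
  expect_equal(attr(flags, "coverage"), 1)
  expect_true(all(flags$matched_rules == ""))
})

test_that("rule matching is conjunctive within and disjunctive across rules", {
  X <- cbind(a = c(-1, 0.5, 2, 2), b = c(0, 0, 0, 5))
  tab <- descriptor_table(X, chemical_ids = c("w", "x", "y", "z"),
                          normalized = TRUE)
  ad <- manual_ad(list(
    R1 = rule("R1", cond("a", ">", 1), cond("b", ">", 2)),  # only z
    R2 = rule("R2", cond("a", "<=", -0.5))))                # only w
  flags <- apply_ad(ad, tab)
  expect_equal(flags$in_ad, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(flags$matched_rules, c("R2", "", "", "R1"))
  expect_equal(attr(flags, "coverage"), 0.5)
})

test_that("a chemical exactly on a threshold satisfies the closed <= branch", {
  X <- cbind(a = c(1.0, 1.0 + 1e-9))
  tab <- descriptor_table(X, chemical_ids = c("on", "above"),
                          normalized = TRUE)
  ad <- manual_ad(list(R1 = rule("R1", cond("a", "<=", 1.0))))
  flags <- apply_ad(ad, tab)
  expect_equal(flags$in_ad, c(FALSE, TRUE))
})

test_that("domain assessment never needs the evaluated table's observed CI", {
  set.seed(65)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f", "g")))
  no_ci <- descriptor_table(X, chemical_ids = sprintf("t%02d", 1:10),
                            normalized = TRUE)
  expect_null(no_ci$ci)
  ad <- manual_ad(list(R1 = rule("R1", cond("f", ">", 0.5))))
  flags <- apply_ad(ad, no_ci)  # works without any target column
  expect_equal(flags$in_ad, unname(X[, "f"] <= 0.5))
  expect_error(apply_ad(ad, subset_table(no_ci, features = "g")),
               "lacks features")
})

test_that("AD models survive a JSON round trip with raw-unit thresholds", {
  set.seed(66)
  n <- 50
  f <- c(rnorm(n - 7), runif(7, 3.5, 4.5))
  y <- abs(1 + 0.4 * rnorm(n))
  preds <- y + c(abs(rnorm(n - 7, 0, 0.1)), abs(rnorm(7, 1.5, 0.2)))
  tab <- descriptor_table(cbind(f = f), chemical_ids = sprintf("c%02d", 1:n),
                          ci = y, normalized = TRUE)
  params <- structure(list(center = c(f = 2), scale = c(f = 0.5),
                           mode = "sd"), class = "normalization_params")
  ad <- derive_ad(tab, "f", preds, normalization = params)
  path <- withr::local_tempfile(fileext = ".json")
  write_ad_model(ad, path)
  json <- jsonlite::read_json(path)
  expect_equal(json$format, "ciperm_ad")
  if (length(ad$rules)) {
    thr <- ad$rules[[1]]$conditions[[1]]$threshold
    expect_equal(json$rules[[1]]$conditions[[1]]$threshold_raw,
                 thr * 0.5 + 2, tolerance = 1e-12)
  }
  back <- read_ad_model(path)
  expect_equal(length(back$rules), length(ad$rules))
  expect_identical(apply_ad(back, tab)$in_ad, apply_ad(ad, tab)$in_ad)
  expect_equal(back$training_coverage, ad$training_coverage)
})

test_that("derive_ad validates its inputs", {
  tab <- random_table(n = 10, p = 2, seed = 67)
  expect_error(derive_ad(tab, tab$feature_names, rep(0.5, 9)),
               "not aligned")
  no_ci <- descriptor_table(tab$values, chemical_ids = tab$chemical_ids,
                            normalized = TRUE)
  expect_error(derive_ad(no_ci, tab$feature_names, rep(0.5, 10)),
               "target column")
  expect_error(derive_ad(tab, c("f1", "nope"), tab$ci), "not in table")
})
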