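test_that("OLS component recovers exact linear relationships and matches lm", {
  tab <- exact_linear_table(n = 10, slope = 2, intercept = 1)
  m <- fit_ci_model(tab, "signal", model_spec("linear"))
  # ci was shifted to be nonnegative; slope unchanged, intercept shifted
  expect_equal(unname(m$linear$coefficients[2]), 2, tolerance = 1e-8)
  expect_equal(unname(predict(m, tab)), unname(tab$ci), tolerance = 1e-8)

  tab2 <- random_table(n = 30, p = 5, seed = 8)
  m2 <- fit_ci_model(tab2, tab2$feature_names, model_spec("linear"))
  ref <- lm(tab2$ci ~ tab2$values)  # independent route
  expect_equal(unname(m2$linear$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
})

test_that("singular designs error and feature overload warns", {
  tab <- random_table(n = 10, p = 3, seed = 2)
  dup <- descriptor_table(cbind(tab$values, copy = tab$values[, 1]),
                          chemical_ids = tab$chemical_ids, ci = tab$ci,
                          normalized = TRUE)
  expect_error(fit_ci_model(dup, c("f1", "copy"), model_spec("linear")),
               "singular")
  tab_small <- random_table(n = 5, p = 4, seed = 3)
  expect_warning(fit_ci_model(tab_small, tab_small$feature_names,
                              model_spec("linear")),
                 "more features")
})

test_that("ensemble predictions are the weighted mean of both components", {
  tab <- random_table(n = 25, p = 4, seed = 13)
  feats <- tab$feature_names
  lin <- fit_ci_model(tab, feats, model_spec("linear"))
  fst <- fit_ci_model(tab, feats, model_spec("forest", n_trees = 30, seed = 7))
  ens <- fit_ci_model(tab, feats, model_spec("ensemble", n_trees = 30, seed = 7))
  expect_equal(predict(ens, tab),
               0.5 * predict(lin, tab) + 0.5 * predict(fst, tab),
               tolerance = 1e-12)
  # component independence: stored coefficients identical to a pure linear fit
  expect_identical(ens$linear$coefficients, lin$linear$coefficients)

  ens37 <- fit_ci_model(tab, feats,
                        model_spec("ensemble", n_trees = 30, seed = 7,
                                   ensemble_weights = c(0.3, 0.7)))
  expect_equal(predict(ens37, tab),
               0.3 * predict(lin, tab) + 0.7 * predict(fst, tab),
               tolerance = 1e-12)
  expect_error(model_spec("ensemble", seed = 1,
                          ensemble_weights = c(0.6, 0.6)), "sum to 1")
})

test_that("a single unbootstrapped tree grown to purity interpolates training data", {
  tab <- random_table(n = 18, p = 2, seed = 21, noise_sd = 1)
  m <- fit_ci_model(tab, tab$feature_names,
                    model_spec("forest", n_trees = 1, seed = 5,
                               min_node = 1, bootstrap = FALSE))
  expect_equal(unname(predict(m, tab)), unname(tab$ci), tolerance = 1e-12)
})

test_that("forest fits are reproducible from the seed and importance is sane", {
  tab <- random_table(n = 40, p = 4, seed = 31, noise_sd = 0.2,
                      beta = c(1.5, 0.2, 0, 0))
  sp <- model_spec("forest", n_trees = 100, seed = 99)
  m1 <- fit_ci_model(tab, tab$feature_names, sp)
  m2 <- fit_ci_model(tab, tab$feature_names, sp)
  expect_identical(predict(m1, tab), predict(m2, tab))
  m3 <- fit_ci_model(tab, tab$feature_names,
                     model_spec("forest", n_trees = 100, seed = 100))
  expect_false(identical(predict(m1, tab), predict(m3, tab)))
  imp <- m1$forest$importance
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_equal(which.max(imp), 1L)  # dominant feature dominates importance
})

test_that("package forest agrees statistically with an independent implementation", {
  skip_if_not_installed("ranger")
  set.seed(9)
  X <- matrix(rnorm(66 * 4), 66, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(66, 0, 0.3)
  mine <- ciperm:::cpp_forest_fit(X, y, 200L, 4L, 5L, TRUE, 11)
  fitted_mine <- ciperm:::cpp_forest_predict(mine, X)
  ref <- ranger::ranger(y ~ ., data = data.frame(X, y = y), num.trees = 200,
                        mtry = 4, min.node.size = 5, seed = 11,
                        num.threads = 1, importance = "impurity")
  fitted_ref <- predict(ref, data.frame(X))$predictions
  expect_gt(cor(fitted_mine, fitted_ref), 0.98)
  expect_equal(order(-mine$importance), order(-ref$variable.importance))
})

test_that("loocv equals an explicit fit/predict loop and names failing folds", {
  tab <- random_table(n = 15, p = 3, seed = 17)
  feats <- tab$feature_names
  for (sp in list(model_spec("linear"),
                  model_spec("ensemble", n_trees = 15, seed = 3))) {
    cv <- loocv(tab, feats, sp)
    manual <- vapply(seq_len(15), function(i) {
      fm <- ciperm:::fit_core(tab$values[-i, feats], tab$ci[-i], sp)
      ciperm:::predict_core(fm, tab$values[i, feats, drop = FALSE])
    }, numeric(1))
    expect_equal(unname(cv), manual, tolerance = 1e-12)
  }
  expect_named(loocv(tab, feats, model_spec("linear")), tab$chemical_ids)

  # fold failure names the left-out chemical: the odd-one-out column is
  # constant once c01 is dropped, making the fold design singular
  odd <- descriptor_table(
    cbind(a = rnorm(10), flag = c(1, rep(0, 9))),
    chemical_ids = sprintf("c%02d", 1:10), ci = abs(rnorm(10)),
    normalized = TRUE)
  expect_error(loocv(odd, c("a", "flag"), model_spec("linear")), "c01")
})

test_that("loocv on exactly linear data is perfect; strict mode renormalizes per fold", {
  tab <- exact_linear_table(n = 4, slope = 1.5, intercept = 0.2)
  cv <- loocv(tab, "signal", model_spec("linear"))
  expect_equal(unname(cv), unname(tab$ci), tolerance = 1e-8)
  expect_equal(pearson_r(tab$ci, cv), 1, tolerance = 1e-8)

  tab2 <- random_table(n = 12, p = 2, seed = 23)
  lax <- loocv(tab2, tab2$feature_names, model_spec("linear"))
  strict <- loocv(tab2, tab2$feature_names, model_spec("linear"),
                  strict = TRUE)
  expect_false(identical(lax, strict))
  expect_equal(unname(lax), unname(strict), tolerance = 0.5)  # same ballpark
})

test_that("pearson_r matches hand computations and is affine invariant", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson_r(a, 2 * a + 1), 1)
  expect_equal(pearson_r(a, -a), -1)
  expect_equal(pearson_r(a, c(1, 3, 2, 4)), 0.8)
  set.seed(6)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearson_r(3 * x + 2, y), pearson_r(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, -2 * y + 5), -pearson_r(x, y), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("mae and relative absolute error match their definitions", {
  expect_equal(mae(c(1, 1), c(0.5, 1.5)), 0.5)
  expect_equal(mae(c(2, 2), c(2, 2)), 0)
  # a CI observed at 1.0108 predicted as 0.6348: error 0.376, relative 0.372
  expect_equal(abs(1.0108 - 0.6348), 0.376, tolerance = 1e-12)
  expect_equal(relative_absolute_error(1.0108, 0.6348), 0.372,
               tolerance = 5e-4)
  expect_equal(relative_absolute_error(2, 2), 0)
  expect_error(relative_absolute_error(0, 1), "undefined")
})

test_that("evaluation reports cover both targets and degenerate cases", {
  tab <- random_table(n = 10, p = 2, seed = 33)
  m <- fit_ci_model(tab, tab$feature_names, model_spec("linear"))
  ev <- evaluate_model(m, tab, "ci")
  expect_equal(ev$mae, mean(abs(ev$per_chemical$absolute_error)))
  expect_equal(nrow(ev$per_chemical), 10L)

  # perfect predictions: mae 0
  ev0 <- evaluate_model(m, tab, "ci", predictions = tab$ci)
  expect_equal(ev0$mae, 0)
  expect_equal(ev0$pearson_r, 1)

  # ci_min identical to ci gives the identical report
  tab$ci_min <- tab$ci
  ev_min <- evaluate_model(m, tab, "ci_min")
  expect_equal(ev_min$pearson_r, ev$pearson_r)
  expect_equal(ev_min$mae, ev$mae)
  expect_error(evaluate_model(m, random_table(n = 10, p = 2, seed = 33),
                              "ci_min"), "no `ci_min`")

  # zero observed value: relative error NA, the rest intact
  tab$ci[1] <- 0
  ev_z <- evaluate_model(m, tab, "ci")
  expect_true(is.na(ev_z$per_chemical$relative_absolute_error[1]))
  expect_false(anyNA(ev_z$per_chemical$absolute_error))
})

test_that("feature ranking is the rank of rank sums with min-shared ties", {
  fake <- function(coefs, imps) {
    structure(list(spec = model_spec("ensemble", seed = 1),
                   feature_names = paste0("f", seq_along(coefs)),
                   linear = list(coefficients = c(0, coefs)),
                   forest = list(importance = imps),
                   training_ids = "x"),
              class = "ci_model")
  }
  # rank pairs (2,2), (1,6), (3,3), (4,1), (5,4), (6,5), (7,7)
  rk <- rank_features(fake(c(-0.6, 0.7, 0.5, 0.4, 0.3, 0.2, 0.1),
                           c(0.25, 0.02, 0.20, 0.30, 0.10, 0.05, 0.01)))
  expect_equal(rk$rank_by_coefficient[1:3], c(2L, 1L, 3L))
  expect_equal(rk$rank_by_importance[1:3], c(2L, 6L, 3L))
  # rank sums 4, 7, 6, 5, 9, 11, 14 -> overall 1, 4, 3, 2, 5, 6, 7
  expect_equal(rk$overall_ranking, c(1L, 4L, 3L, 2L, 5L, 6L, 7L))

  # pairs (2,3), (1,2), (3,1): sums 5, 3, 4 -> overall 3, 1, 2
  rk3 <- rank_features(fake(c(0.5, 0.9, 0.3), c(0.1, 0.2, 0.4)))
  expect_equal(rk3$overall_ranking, c(3L, 1L, 2L))

  # equal rank sums share the smaller overall rank:
  # pairs (1,2), (2,1), (3,3): sums 3, 3, 6 -> overall 1, 1, 3
  rk_tie <- rank_features(fake(c(0.9, 0.5, 0.3), c(0.4, 0.6, 0.2)))
  expect_equal(rk_tie$overall_ranking, c(1L, 1L, 3L))

  # single feature: all ranks 1
  rk1 <- rank_features(fake(0.7, 1))
  expect_equal(rk1$rank_by_coefficient, 1L)
  expect_equal(rk1$rank_by_importance, 1L)
  expect_equal(rk1$overall_ranking, 1L)
  m_lin <- fit_ci_model(random_table(), "f1", model_spec("linear"))
  expect_error(rank_features(m_lin), "ensemble")
})

test_that("model JSON round trip reproduces predictions exactly", {
  tab <- random_table(n = 20, p = 4, seed = 41)
  raw <- invert_normalizer(tab, fit_normalizer(tab))  # pretend-raw copy
  params <- fit_normalizer(raw)
  norm <- apply_normalizer(raw, params)
  m <- fit_ci_model(norm, c("f1", "f2"),
                    model_spec("ensemble", n_trees = 25, seed = 17))
  m$normalization <- params
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$spec, m$spec)
  expect_identical(predict(m2, norm), predict(m, norm))
  # auto-normalization on raw input survives the round trip
  expect_identical(predict(m2, raw), predict(m, raw))
})
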