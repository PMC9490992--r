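test_that("Pearson accuracy matches hand values and rejects degenerate input", {
  y <- c(0.3, -1.2, 0.5, 2.2)
  expect_equal(pearson_accuracy(y, y), 1)
  expect_equal(pearson_accuracy(y, -y), -1)
  # hand computation: cov = 4.7/3, var_x = 5/3, var_y = 4.5/3
  expect_equal(pearson_accuracy(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)),
               4.7 / sqrt(5 * 4.5), tolerance = 1e-12)
  expect_error(pearson_accuracy(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_accuracy(1:2, 1:2), "at least 3")
  expect_error(pearson_accuracy(1:4, 1:3), "length mismatch")
})

test_that("LOO produces one held-out prediction per sample", {
  b <- small_bundle(seed = 3, n_total = 120, n_transcribed = 120,
                    m = 200, g = 50)
  f <- fit_model(b, "GBLUP")
  res <- loocv(f$y_star, f$K)
  expect_equal(length(res$predictions), 120)
  expect_identical(res$scheme, "LOO")
  expect_equal(res$mean_accuracy,
               pearson_accuracy(f$y_star, res$predictions))
})

test_that("LOO under refit-per-fold equals the naive per-sample loop", {
  b <- small_bundle(seed = 5, n_total = 15, n_transcribed = 15,
                    m = 150, g = 40, maf_range = c(0.3, 0.5))
  f <- fit_model(b, "GBLUP")
  y <- f$y_star
  Km <- unclass(f$K)[names(y), names(y)]
  res <- loocv(y, f$K, vc_policy = "refit-per-fold")
  naive <- vapply(seq_along(y), function(i) {
    train <- names(y)[-i]
    vc_i <- reml_fit(y[train], Km[train, train])
    blup_predict(y, Km, train, names(y)[i], vc_i)$gebv
  }, numeric(1))
  expect_equal(unname(res$predictions), naive)
})

test_that("k-fold CV records k x replicates correlations deterministically", {
  b <- small_bundle(seed = 7, n_total = 100, n_transcribed = 25,
                    m = 200, g = 50)
  f <- fit_model(b, "GBLUP")
  res <- kfold_cv(f$y_star, f$K, k = 5, replicates = 5, seed = 99)
  expect_equal(length(res$fold_r), 25)
  expect_equal(res$mean_accuracy, mean(res$fold_r))
  # folds partition the samples, sizes exactly 20 at n = 100
  for (folds in res$folds) {
    expect_setequal(unlist(folds), names(f$y_star))
    expect_true(all(lengths(folds) == 20))
  }
  res2 <- kfold_cv(f$y_star, f$K, k = 5, replicates = 5, seed = 99)
  expect_identical(res$fold_r, res2$fold_r)
  expect_identical(res$folds, res2$folds)
  res3 <- kfold_cv(f$y_star, f$K, k = 5, replicates = 5, seed = 100)
  expect_false(identical(res$folds, res3$folds))
})

test_that("ratio grid endpoints join the pure models continuously", {
  b <- small_bundle(seed = 11, n_total = 40, n_transcribed = 40,
                    m = 200, g = 60)
  f <- fit_model(b, "GBLUP", gblup_kernel = "cosine")
  G <- f$K
  Tm <- cosine_kernel(b$expr)
  y <- f$y_star
  gs <- grid_search_ratio(G, Tm, y, grid = c(0, 0.5, 1))
  expect_equal(gs$accuracy[1], loocv(y, Tm)$mean_accuracy)   # ratio 0 = TBLUP
  expect_equal(gs$accuracy[3], loocv(y, G)$mean_accuracy)    # ratio 1 = GBLUP
  expect_equal(gs$argmax, gs$grid[which.max(gs$accuracy)])
})

test_that("default ratio grid has 99 points and argmax ties break low", {
  b <- small_bundle(seed = 13, n_total = 30, n_transcribed = 30,
                    m = 150, g = 40)
  G <- cosine_kernel(b$geno)
  Tm <- cosine_kernel(b$expr)
  adj <- adjust_phenotypes(b$pheno)
  gs <- grid_search_ratio(G, Tm, adj$y_star)
  expect_equal(length(gs$grid), 99)
  expect_equal(gs$grid[c(1, 99)], c(0.01, 0.99))
  # tie-break: identical accuracies resolve to the smaller parameter
  fake <- omixblup:::new_grid_result("ratio", c(0.2, 0.4, 0.6), c(1, 3, 3))
  expect_equal(fake$argmax, 0.4)
})

test_that("w grid defaults to 11 points and w = 1 matches cosine-GBLUP", {
  b <- small_bundle(seed = 17, n_total = 60, n_transcribed = 15,
                    m = 200, g = 50)
  adj <- adjust_phenotypes(b$pheno)
  gs <- grid_search_w(b, grid = c(0, 0.5, 1), seed = 5, replicates = 2)
  Gc <- cosine_kernel(b$geno)
  ref <- kfold_cv(adj$y_star, Gc, k = 5, replicates = 2, seed = 5)
  expect_equal(gs$accuracy[3], ref$mean_accuracy, tolerance = 1e-12)
  gs_def_grid <- seq(0, 1, by = 0.1)
  expect_equal(eval(formals(grid_search_w)$grid), gs_def_grid)
  expect_equal(length(gs_def_grid), 11)
})

test_that("permuted phenotypes give near-zero expected accuracy", {
  b <- small_bundle(seed = 19, n_total = 60, n_transcribed = 15,
                    m = 300, g = 50, maf_range = c(0.1, 0.5))
  f <- fit_model(b, "GBLUP")
  y <- f$y_star
  Km <- unclass(f$K)[names(y), names(y)]
  vc <- f$vc
  set.seed(23)
  r_perm <- replicate(50, {
    yp <- setNames(sample(y), names(y))
    gebv <- blup_predict(yp, Km, names(y)[1:45], names(y)[46:60], vc)$gebv
    pearson_accuracy(yp[46:60], gebv)
  })
  expect_lt(abs(mean(r_perm)), 2 / sqrt(60))
})

test_that("proportion sweep covers 7 sizes and full pool equals all data", {
  b <- small_bundle(seed = 29, n_total = 70, n_transcribed = 20,
                    m = 200, g = 50)
  tab <- proportion_experiment(b, w = 0.5, seed = 31, replicates = 1)
  expect_equal(nrow(tab), 7)
  expect_true(all(diff(tab$size) > 0))
  expect_true(all(diff(tab$transcribed_fraction) < 0))
  expect_equal(names(tab), c("size", "transcribed_fraction", "accuracy_wmss",
                             "accuracy_gblup", "improvement_abs",
                             "pct_improvement"))
  # the full-pool row reproduces the whole-bundle result under the same folds
  adj <- adjust_phenotypes(b$pheno)
  Hw <- omixblup:::model_kernel(b, "wmssBLUP", w = 0.5)
  ref <- kfold_cv(adj$y_star, Hw, k = 5, replicates = 1, seed = 31)
  expect_equal(tab$accuracy_wmss[7], ref$mean_accuracy, tolerance = 1e-10)
  expect_error(proportion_experiment(b, sizes = c(10, 1000)), "exceeds")
})
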