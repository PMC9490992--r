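test_that("phenotype adjustment removes exact linear fixed effects", {
  df <- data.frame(sample_id = paste0("s", 1:12),
                   age = rnorm(12, 20, 2))
  df$y <- 3 + 0.7 * df$age
  ph <- phenotype_table(df, traits = "y", covariates = c(age = "continuous"))
  adj <- adjust_phenotypes(ph)
  expect_lt(max(abs(adj$y_star)), 1e-10)
  expect_equal(unname(adj$beta), c(3, 0.7), tolerance = 1e-8)
})

test_that("intercept-only adjustment centers the trait", {
  set.seed(5)
  df <- data.frame(sample_id = paste0("s", 1:15), y = rnorm(15, 10))
  ph <- phenotype_table(df, traits = "y")
  adj <- adjust_phenotypes(ph)
  expect_equal(unname(adj$y_star), df$y - mean(df$y))
  expect_lt(abs(mean(adj$y_star)), 1e-10)
})

test_that("categorical expansion matches the normal-equations oracle", {
  set.seed(7)
  df <- data.frame(sample_id = paste0("s", 1:10),
                   batch = rep(c("b1", "b2", "b3"), length.out = 10),
                   y = rnorm(10))
  ph <- phenotype_table(df, traits = "y",
                        covariates = c(batch = "categorical"))
  adj <- adjust_phenotypes(ph)
  X <- cbind(1, df$batch == "b2", df$batch == "b3") * 1
  beta <- solve(t(X) %*% X, t(X) %*% df$y)           # normal equations
  expect_equal(unname(adj$y_star), as.numeric(df$y - X %*% beta),
               tolerance = 1e-10)
  expect_identical(adj$design_columns, c("(Intercept)", "batchb2", "batchb3"))
})

test_that("adjustment rejects collinear designs and flags missing values", {
  df <- data.frame(sample_id = paste0("s", 1:12), a = 1:12, b = 2 * (1:12),
                   y = rnorm(12))
  ph <- phenotype_table(df, traits = "y",
                        covariates = c(a = "continuous", b = "continuous"))
  expect_error(adjust_phenotypes(ph), "collinear.*b")
  df2 <- data.frame(sample_id = paste0("s", 1:12), a = rnorm(12), y = rnorm(12))
  df2$a[3] <- NA
  ph2 <- phenotype_table(df2, traits = "y", covariates = c(a = "continuous"))
  expect_warning(adj <- adjust_phenotypes(ph2), "1 sample")
  expect_equal(length(adj$y_star), 11)
})

test_that("blend_m is the convex combination with exact endpoints", {
  set.seed(11)
  ids <- paste0("s", 1:6)
  G <- relationship_matrix(random_psd(6, ids), provenance = "cosine_G")
  Tm <- relationship_matrix(random_psd(6, ids), provenance = "cosine_T")
  expect_equal(unclass(blend_m(G, Tm, 1))[1:6, 1:6],
               unclass(G)[1:6, 1:6])          # ratio 1 -> GBLUP kernel
  expect_equal(unclass(blend_m(G, Tm, 0))[1:6, 1:6],
               unclass(Tm)[1:6, 1:6])         # ratio 0 -> TBLUP kernel
  I6 <- relationship_matrix(diag(6), sample_ids = ids)
  expect_equal(unclass(blend_m(I6, I6, 0.37))[1:6, 1:6], diag(6),
               ignore_attr = TRUE)
  M <- unclass(blend_m(G, Tm, 0.3))[1:6, 1:6]
  expect_equal(M, 0.3 * unclass(G)[1:6, 1:6] + 0.7 * unclass(Tm)[1:6, 1:6])
  G2 <- relationship_matrix(random_psd(6, paste0("t", 1:6)))
  expect_error(blend_m(G, G2, 0.5), "sample IDs differ")
  expect_error(blend_m(G, Tm, 1.2), "\\[0, 1\\]")
})

test_that("blend_tw interpolates between T and G22", {
  Tm <- relationship_matrix(matrix(1.2, 1, 1, dimnames = list("a", "a")))
  G22 <- relationship_matrix(matrix(1.0, 1, 1, dimnames = list("a", "a")))
  expect_equal(unclass(blend_tw(Tm, G22, 0))[1, 1], 1.2)
  expect_equal(unclass(blend_tw(Tm, G22, 1))[1, 1], 1.0)
  expect_equal(unclass(blend_tw(Tm, G22, 0.5))[1, 1], 1.1)
  G2 <- relationship_matrix(diag(2), sample_ids = c("a", "b"))
  expect_error(blend_tw(Tm, G2, 0.5), "dimension mismatch")
})

test_that("the worked 2x2 hybrid instance is exact by both routes", {
  ids <- c("a", "b")
  G <- relationship_matrix(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(ids, ids)))
  Tm <- relationship_matrix(matrix(1.2, 1, 1, dimnames = list("b", "b")))
  H <- build_hybrid(G, Tm)
  expect_equal(unclass(H)[1:2, 1:2],
               matrix(c(1.05, 0.6, 0.6, 1.2), 2), ignore_attr = TRUE)
  Hinv <- invert_hybrid(G, Tm)
  expect_equal(Hinv, matrix(c(4/3, -2/3, -2/3, 7/6), 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # direct inversion of the constructed Hm agrees with the closed form
  expect_equal(solve(unclass(H)[1:2, 1:2]), Hinv, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("T = G22 collapses the hybrid to G exactly", {
  set.seed(13)
  ids <- sprintf("i%02d", 1:8)
  G <- relationship_matrix(random_psd(8, ids))
  G22 <- relationship_matrix(unclass(G)[6:8, 6:8], sample_ids = ids[6:8])
  H <- build_hybrid(G, G22)
  expect_identical(unclass(H)[1:8, 1:8], unclass(G)[1:8, 1:8])
  Hinv <- invert_hybrid(G, G22)
  expect_equal(Hinv, solve(unclass(G)[1:8, 1:8]), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("hybrid construction and closed-form inverse are mutually inverse", {
  set.seed(17)
  for (trial in 1:10) {
    n <- sample(10:40, 1)
    n2 <- sample(3:(n - 3), 1)
    ids <- sprintf("i%02d", 1:n)
    G <- relationship_matrix(random_psd(n, ids))
    Tm <- relationship_matrix(random_psd(n2, ids[(n - n2 + 1):n]))
    H <- build_hybrid(G, Tm)
    Hinv <- invert_hybrid(G, Tm)
    expect_lt(max(abs(Hinv %*% unclass(H)[1:n, 1:n] - diag(n))), 1e-8)
  }
})

test_that("hybrid construction validates the partition", {
  ids <- c("a", "b", "c")
  G <- relationship_matrix(random_psd(3, ids))
  T_wrong <- relationship_matrix(matrix(1, 1, 1, dimnames = list("a", "a")))
  expect_error(build_hybrid(G, T_wrong), "trailing block")
  T_alien <- relationship_matrix(matrix(1, 1, 1, dimnames = list("z", "z")))
  expect_error(build_hybrid(G, T_alien), "absent from G")
})

test_that("REML recovers heritability and reports the h2 identity", {
  g <- simulate_genotypes(200, 1000, seed = 23)
  K <- vanraden_g(g)
  Km <- unclass(K)[1:200, 1:200]
  es <- eigen(Km, symmetric = TRUE)
  eigK <- reml_eigen(Km)
  set.seed(29)
  h2_hat <- replicate(100, reml_fit(simulate_y_from_kernel(es, 0.5),
                                    eigen_K = eigK)$h2)
  # sd(h2_hat) ~ 0.2 at n = 200, so 0.08 is a ~4 SE band on the mean
  expect_lt(abs(mean(h2_hat) - 0.5), 0.08)
  vc <- reml_fit(simulate_y_from_kernel(es, 0.5), Km)
  expect_equal(vc$h2, vc$sigma_g2 / (vc$sigma_g2 + vc$sigma_e2))
  expect_true(vc$converged)
})

test_that("pure noise drives h2 to the zero boundary, flagged not errored", {
  g <- simulate_genotypes(150, 500, seed = 31)
  K <- vanraden_g(g)
  set.seed(37)
  vc <- reml_fit(rnorm(150), unclass(K)[1:150, 1:150])
  expect_lt(vc$h2, 0.05)
  expect_true(vc$boundary)
  expect_true(is.na(vc$se_h2))
})

test_that("an identity kernel is rejected as non-identifiable", {
  set.seed(41)
  expect_error(reml_fit(rnorm(30), diag(30)), "non-identifiable")
})

test_that("REML standard errors are finite and plausibly scaled", {
  g <- simulate_genotypes(250, 1500, seed = 43)
  Km <- unclass(vanraden_g(g))[1:250, 1:250]
  es <- eigen(Km, symmetric = TRUE)
  set.seed(47)
  vc <- reml_fit(simulate_y_from_kernel(es, 0.4), Km)
  expect_false(vc$boundary)
  expect_true(is.finite(vc$se_h2))
  expect_gt(vc$se_h2, 0.01)
  expect_lt(vc$se_h2, 0.5)
})

test_that("BLUP prediction has the interpolation and shrinkage limits", {
  set.seed(53)
  ids <- sprintf("i%02d", 1:12)
  K <- relationship_matrix(random_psd(12, ids))
  y <- setNames(rnorm(12), ids)
  vc_small <- list(sigma_g2 = 1, sigma_e2 = 1e-10)
  expect_equal(blup_predict(y, K, ids, ids, vc_small)$gebv, y,
               tolerance = 1e-6)
  vc_big <- list(sigma_g2 = 1, sigma_e2 = 1e10)
  expect_lt(max(abs(blup_predict(y, K, ids, ids, vc_big)$gebv)), 1e-6)
})

test_that("BLUP matches the mixed-model-equations oracle and is linear", {
  set.seed(59)
  ids <- paste0("s", 1:5)
  K <- random_psd(5, ids)
  y <- setNames(rnorm(5), ids)
  vc <- list(sigma_g2 = 0.8, sigma_e2 = 0.5)
  train <- ids[1:4]; target <- ids
  pred <- blup_predict(y, relationship_matrix(K), train, target, vc)$gebv
  # MME with identity incidence on the training records:
  # (Z'Z + delta K^-1) gamma = Z'y, solved over all 5 animals
  delta <- vc$sigma_e2 / vc$sigma_g2
  Z <- diag(5)[1:4, ]
  mme <- solve(crossprod(Z) + delta * solve(K), crossprod(Z, y[train]))
  expect_equal(unname(pred), as.numeric(mme), tolerance = 1e-8)
  # linearity in y*
  y2 <- setNames(rnorm(5), ids)
  a <- 1.7; b <- -0.4
  p1 <- blup_predict(y, relationship_matrix(K), train, target, vc)$gebv
  p2 <- blup_predict(y2, relationship_matrix(K), train, target, vc)$gebv
  p12 <- blup_predict(a * y + b * y2, relationship_matrix(K), train, target, vc)$gebv
  expect_equal(p12, a * p1 + b * p2, tolerance = 1e-10)
})

test_that("model reductions: MBLUP endpoints and wmssBLUP(w = 1)", {
  full <- small_bundle(seed = 61, n_total = 50, n_transcribed = 50,
                       m = 200, g = 60)
  f_g <- fit_model(full, "GBLUP", gblup_kernel = "cosine")
  f_t <- fit_model(full, "TBLUP")
  f_m1 <- fit_model(full, "MBLUP", ratio = 1)
  f_m0 <- fit_model(full, "MBLUP", ratio = 0)
  expect_equal(f_m1$vc$sigma_g2, f_g$vc$sigma_g2, tolerance = 1e-10)
  expect_equal(f_m0$vc$sigma_g2, f_t$vc$sigma_g2, tolerance = 1e-10)
  ids <- names(f_g$y_star)
  gebv_g <- blup_predict(f_g$y_star, f_g$K, ids[1:40], ids[41:50], f_g$vc)$gebv
  gebv_m <- blup_predict(f_m1$y_star, f_m1$K, ids[1:40], ids[41:50], f_m1$vc)$gebv
  expect_equal(gebv_m, gebv_g, tolerance = 1e-10)

  part <- small_bundle(seed = 67, n_total = 60, n_transcribed = 15,
                       m = 200, g = 60)
  f_w1 <- fit_model(part, "wmssBLUP", w = 1)
  f_gc <- fit_model(part, "GBLUP", gblup_kernel = "cosine")
  expect_equal(f_w1$vc$sigma_g2, f_gc$vc$sigma_g2, tolerance = 1e-12)
  ids <- names(f_gc$y_star)
  gw <- blup_predict(f_w1$y_star, f_w1$K, ids[1:45], ids[46:60], f_w1$vc)$gebv
  gg <- blup_predict(f_gc$y_star, f_gc$K, ids[1:45], ids[46:60], f_gc$vc)$gebv
  expect_equal(gw, gg, tolerance = 1e-10)
})

test_that("MBLUP on a partially transcribed bundle points to mssBLUP", {
  part <- small_bundle(seed = 71, n_total = 40, n_transcribed = 10,
                       m = 150, g = 40)
  expect_error(fit_model(part, "MBLUP"), "mssBLUP or wmssBLUP")
  expect_error(fit_model(part, "TBLUP"), "mssBLUP or wmssBLUP")
})

test_that("all five models run end-to-end on a simulated bundle", {
  full <- small_bundle(seed = 73, n_total = 150, n_transcribed = 150,
                       m = 300, g = 80)
  part <- small_bundle(seed = 73, n_total = 150, n_transcribed = 40,
                       m = 300, g = 80)
  for (mod in c("GBLUP", "TBLUP", "MBLUP"))
    expect_s3_class(fit_model(full, mod), "omix_fit")
  for (mod in c("GBLUP", "mssBLUP", "wmssBLUP"))
    expect_s3_class(fit_model(part, mod), "omix_fit")
})
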