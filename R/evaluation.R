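#' Pearson prediction accuracy
#'
#' `r(y*, GEBV) = cov(y*, GEBV) / (sd(y*) sd(GEBV))`, the sample Pearson
#' correlation between held-out adjusted phenotypes and their predicted
#' genetic values. A constant vector makes the correlation undefined and is
#' an error, never a silent zero.
#'
#' @param y_star numeric vector of adjusted phenotypes.
#' @param gebv numeric vector of predictions, same length >= 3.
#' @return the correlation.
#' @export
pearson_accuracy <- function(y_star, gebv) {
  if (length(y_star) != length(gebv)) stop("length mismatch")
  if (length(y_star) < 3) stop("need at least 3 pairs for a correlation")
  if (stats::sd(y_star) == 0 || stats::sd(gebv) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(y_star, gebv)
}

new_cv_result <- function(scheme, k, n_replicates, seed, folds, fold_r,
                          mean_accuracy, predictions = NULL) {
  structure(list(scheme = scheme, k = k, n_replicates = n_replicates,
                 seed = seed, folds = folds, fold_r = fold_r,
                 mean_accuracy = mean_accuracy, predictions = predictions),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: mean accuracy %.4f (%d correlation(s))\n",
              x$scheme, x$mean_accuracy, length(x$fold_r)))
  invisible(x)
}

#' Leave-one-out cross-validated accuracy
#'
#' Each sample in turn is predicted from the remaining n - 1 via
#' [blup_predict()]; the accuracy is the single Pearson correlation between
#' all n held-out predictions and `y*`. Variance components are either
#' fitted once on the full data (`"fit-once-full"`, default) or refitted on
#' every n - 1 training set (`"refit-per-fold"`).
#'
#' @param y_star named numeric vector (or `adjusted_phenotypes`).
#' @param K a [relationship_matrix()] over the same samples.
#' @param vc_policy `"fit-once-full"` or `"refit-per-fold"`.
#' @return a `cv_result` with scheme `"LOO"`; `predictions` holds the n
#'   held-out GEBVs.
#' @export
loocv <- function(y_star, K, vc_policy = c("fit-once-full", "refit-per-fold")) {
  vc_policy <- match.arg(vc_policy)
  y <- if (inherits(y_star, "adjusted_phenotypes")) y_star$y_star else y_star
  ids <- names(y)
  if (is.null(ids)) stop("y* must be named by sample ID")
  n <- length(y)
  if (n < 10) stop("LOO needs at least 10 samples")
  Km <- if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K)
  Km <- Km[ids, ids]
  vc_full <- if (vc_policy == "fit-once-full") reml_fit(y, Km) else NULL
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- ids[-i]
    vc <- if (vc_policy == "refit-per-fold") {
      tryCatch(reml_fit(y[train], Km[train, train]),
               error = function(e) stop(sprintf("REML failed at LOO fold %d (%s): %s",
                                                i, ids[i], conditionMessage(e))))
    } else vc_full
    preds[i] <- blup_predict(y, Km, train, ids[i], vc)$gebv
  }
  names(preds) <- ids
  r <- pearson_accuracy(y, preds)
  new_cv_result("LOO", k = n, n_replicates = 1, seed = NA_integer_,
                folds = list(as.list(ids)), fold_r = r, mean_accuracy = r,
                predictions = preds)
}

# deterministic k-partition of ids for one replicate (consumes RNG state)
make_folds <- function(ids, k) {
  n <- length(ids)
  perm <- sample(ids)
  split(perm, rep_len(seq_len(k), n))  # sizes differ by <= 1
}

#' Replicated k-fold cross-validated accuracy
#'
#' Per replicate, samples are randomly partitioned into k folds (sizes
#' differing by at most one). Each fold is predicted from the remaining
#' folds and scored by the Pearson correlation between validation GEBVs and
#' validation `y*`; the summary accuracy is the mean of all k x replicates
#' fold-level correlations. Variance components are refitted on each fold's
#' training set by default. The whole procedure is a pure function of
#' `seed`.
#'
#' @inheritParams loocv
#' @param k number of folds (default 5).
#' @param replicates number of random replicates (default 5).
#' @param seed integer RNG seed for the fold assignments.
#' @param vc_policy `"refit-per-fold"` (default) or `"fit-once-full"`.
#' @return a `cv_result` with scheme `"kfold"` and `k * replicates`
#'   recorded fold correlations.
#' @export
kfold_cv <- function(y_star, K, k = 5, replicates = 5, seed = 1,
                     vc_policy = c("refit-per-fold", "fit-once-full")) {
  vc_policy <- match.arg(vc_policy)
  y <- if (inherits(y_star, "adjusted_phenotypes")) y_star$y_star else y_star
  ids <- names(y)
  if (is.null(ids)) stop("y* must be named by sample ID")
  n <- length(y)
  if (n < k) stop("need at least k samples")
  Km <- if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K)
  Km <- Km[ids, ids]
  vc_full <- if (vc_policy == "fit-once-full") reml_fit(y, Km) else NULL
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  folds_all <- vector("list", replicates)
  fold_r <- numeric(0)
  for (rep_i in seq_len(replicates)) {
    folds <- make_folds(ids, k)
    folds_all[[rep_i]] <- folds
    for (f in seq_len(k)) {
      test <- folds[[f]]
      train <- setdiff(ids, test)
      vc <- if (vc_policy == "refit-per-fold") {
        tryCatch(reml_fit(y[train], Km[train, train]),
                 error = function(e)
                   stop(sprintf("REML failed at replicate %d fold %d: %s",
                                rep_i, f, conditionMessage(e))))
      } else vc_full
      gebv <- blup_predict(y, Km, train, test, vc)$gebv
      fold_r <- c(fold_r, pearson_accuracy(y[test], gebv))
    }
  }
  new_cv_result("kfold", k = k, n_replicates = replicates, seed = seed,
                folds = folds_all, fold_r = fold_r,
                mean_accuracy = mean(fold_r))
}

new_grid_result <- function(parameter, grid, accuracy) {
  best <- which(accuracy == max(accuracy))[1]  # ties -> smallest parameter
  structure(list(parameter = parameter, grid = grid, accuracy = accuracy,
                 argmax = grid[best], max_accuracy = accuracy[best]),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid_search_result [%s]: %d points, argmax %s = %g (accuracy %.4f)\n",
              x$parameter, length(x$grid), x$parameter, x$argmax, x$max_accuracy))
  invisible(x)
}

#' Grid search over the MBLUP blending ratio
#'
#' Sweeps `M = ratio * G + (1 - ratio) * T` over a grid of ratios
#' (default 0.01 to 0.99 in steps of 0.01, 99 points) and records the
#' cross-validated accuracy of each blend; ties in the argmax break toward
#' the smaller ratio.
#'
#' @param G,T cosine-kernel [relationship_matrix()] objects over the same
#'   (fully transcribed) samples.
#' @param y_star named adjusted phenotypes for those samples.
#' @param grid numeric vector of ratios.
#' @param scheme `"LOO"` (default) or `"kfold"`.
#' @param seed seed for k-fold fold assignment (shared across the grid so
#'   curves are comparable).
#' @param ... further arguments to [loocv()] / [kfold_cv()].
#' @return a `grid_search_result` for parameter `"ratio"`.
#' @export
grid_search_ratio <- function(G, T, y_star, grid = seq(0.01, 0.99, by = 0.01),
                              scheme = c("LOO", "kfold"), seed = 1, ...) {
  scheme <- match.arg(scheme)
  acc <- vapply(grid, function(r) {
    M <- blend_m(G, T, ratio = r)
    if (scheme == "LOO") loocv(y_star, M, ...)$mean_accuracy
    else kfold_cv(y_star, M, seed = seed, ...)$mean_accuracy
  }, numeric(1))
  new_grid_result("ratio", grid, acc)
}

#' Grid search over the wmssBLUP weight w
#'
#' For each `w` in the grid (default 0 to 1 in steps of 0.1, 11 points;
#' matching the resolution at which reported optima are expressed) the
#' hybrid `Hm_w` is rebuilt from `Tw = (1 - w) T + w G22` and scored by
#' replicated k-fold CV under a shared seed, so the `w = 1` entry equals
#' the cosine-G GBLUP accuracy under identical folds.
#'
#' @param bundle a partially transcribed [align_samples()] bundle.
#' @param y_star named adjusted phenotypes (defaults to adjusting the
#'   bundle's trait).
#' @param grid numeric vector of weights.
#' @param seed fold-assignment seed shared across the grid.
#' @param k,replicates k-fold CV settings.
#' @param jitter_C cosine-kernel regularization.
#' @param vc_policy variance-component policy passed to [kfold_cv()].
#' @return a `grid_search_result` for parameter `"w"`.
#' @export
grid_search_w <- function(bundle, y_star = NULL, grid = seq(0, 1, by = 0.1),
                          seed = 1, k = 5, replicates = 5, jitter_C = 0.05,
                          vc_policy = "refit-per-fold") {
  stopifnot(inherits(bundle, "aligned_bundle"))
  if (is.null(y_star)) {
    adj <- adjust_phenotypes(bundle$pheno, trait = bundle$trait,
                             covariates = bundle$covariates)
    y_star <- adj$y_star
  }
  G <- cosine_kernel(bundle$geno, jitter_C = jitter_C)
  Tm <- cosine_kernel(bundle$expr, jitter_C = jitter_C)
  tid <- bundle$transcribed_ids
  G22 <- relationship_matrix(rm_values(G)[tid, tid, drop = FALSE],
                             sample_ids = tid, provenance = "cosine_G22",
                             jitter = attr(G, "jitter"))
  acc <- vapply(grid, function(w) {
    H <- build_hybrid(G, blend_tw(Tm, G22, w = w), partition = tid)
    kfold_cv(y_star, H, k = k, replicates = replicates, seed = seed,
             vc_policy = vc_policy)$mean_accuracy
  }, numeric(1))
  new_grid_result("w", grid, acc)
}

#' Transcribed-proportion experiment
#'
#' Emulates the design in which growing random subsets of the genotype-only
#' pool are combined with the (always fully included) transcribed subset:
#' for each size the genomic kernel and the hybrid `Hm_w` are rebuilt on
#' the reduced population and both wmssBLUP and the GBLUP benchmark are
#' scored by replicated k-fold CV, giving paired accuracies and the
#' improvement of wmssBLUP over GBLUP (both absolute and percentage).
#'
#' @param bundle a partially transcribed [align_samples()] bundle.
#' @param sizes integer vector of genotype-only subset sizes; default is 7
#'   evenly spaced sizes from 25% to 100% of the pool.
#' @param w wmssBLUP weight.
#' @param seed seed controlling both the subsampling and the CV folds.
#' @param k,replicates k-fold CV settings.
#' @param gblup_kernel kernel for the GBLUP benchmark (`"vanraden"` default).
#' @param jitter_C cosine-kernel regularization.
#' @param vc_policy variance-component policy passed to [kfold_cv()].
#' @return a data.frame with one row per size: `size`,
#'   `transcribed_fraction`, `accuracy_wmss`, `accuracy_gblup`,
#'   `improvement_abs` and `pct_improvement` (relative, in percent).
#' @export
proportion_experiment <- function(bundle, sizes = NULL, w = 0.5, seed = 1,
                                  k = 5, replicates = 5,
                                  gblup_kernel = c("vanraden", "cosine"),
                                  jitter_C = 0.05,
                                  vc_policy = "refit-per-fold") {
  stopifnot(inherits(bundle, "aligned_bundle"))
  gblup_kernel <- match.arg(gblup_kernel)
  pool <- setdiff(bundle$sample_ids, bundle$transcribed_ids)
  if (is.null(sizes))
    sizes <- unique(round(seq(0.25 * length(pool), length(pool), length.out = 7)))
  if (any(sizes > length(pool)))
    stop(sprintf("size exceeds the genotype-only pool (%d)", length(pool)))
  adj <- adjust_phenotypes(bundle$pheno, trait = bundle$trait,
                           covariates = bundle$covariates)
  # kernels are built once on the full population and subset per size:
  # allele frequencies and cosine normalizations come from the whole panel,
  # as when a production G matrix is computed once and indexed during CV
  tid <- bundle$transcribed_ids
  Gcos <- cosine_kernel(bundle$geno, jitter_C = jitter_C)
  Tm <- cosine_kernel(bundle$expr, jitter_C = jitter_C)
  Kg_full <- if (gblup_kernel == "vanraden") vanraden_g(bundle$geno) else Gcos
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  rows <- lapply(seq_along(sizes), function(si) {
    s <- sizes[si]
    set.seed(seed + si)
    sub_pool <- if (s == length(pool)) pool else sort(sample(pool, s))
    ids <- c(sub_pool, tid)
    y <- adj$y_star[intersect(ids, names(adj$y_star))]
    Gs <- relationship_matrix(rm_values(Gcos)[ids, ids], sample_ids = ids,
                              provenance = "cosine_G", jitter = jitter_C)
    G22 <- relationship_matrix(rm_values(Gcos)[tid, tid], sample_ids = tid,
                               provenance = "cosine_G22", jitter = jitter_C)
    Hw <- build_hybrid(Gs, blend_tw(Tm, G22, w = w), partition = tid)
    Kg <- relationship_matrix(rm_values(Kg_full)[ids, ids], sample_ids = ids,
                              provenance = attr(Kg_full, "provenance"),
                              jitter = attr(Kg_full, "jitter"))
    r_w <- kfold_cv(y, Hw, k = k, replicates = replicates, seed = seed,
                    vc_policy = vc_policy)$mean_accuracy
    r_g <- kfold_cv(y, Kg, k = k, replicates = replicates, seed = seed,
                    vc_policy = vc_policy)$mean_accuracy
    data.frame(size = s,
               transcribed_fraction = bundle$n_transcribed / length(ids),
               accuracy_wmss = r_w, accuracy_gblup = r_g,
               improvement_abs = r_w - r_g,
               pct_improvement = 100 * (r_w - r_g) / abs(r_g))
  })
  do.call(rbind, rows)
}

# restrict a bundle to a subset of sample IDs (order preserved from input)
subset_bundle <- function(bundle, ids) {
  stopifnot(all(ids %in% bundle$sample_ids))
  tids <- intersect(ids, bundle$transcribed_ids)
  ord <- c(setdiff(ids, tids), tids)
  out <- bundle
  out$geno <- bundle$geno[ord, , drop = FALSE]
  out$expr <- if (length(tids)) bundle$expr[tids, , drop = FALSE] else NULL
  ph <- bundle$pheno[match(ord, bundle$pheno$sample_id), , drop = FALSE]
  rownames(ph) <- NULL
  attr(ph, "traits") <- attr(bundle$pheno, "traits")
  attr(ph, "covariates") <- attr(bundle$pheno, "covariates")
  class(ph) <- class(bundle$pheno)
  out$pheno <- ph
  out$sample_ids <- ord
  out$transcribed_ids <- tids
  out$n_nontranscribed <- length(ord) - length(tids)
  out$n_transcribed <- length(tids)
  out
}
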