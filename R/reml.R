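#' Precompute the REML eigen-structure of a kernel
#'
#' The single-random-effect model used throughout is
#' `y* = 1 mu + g + e`, `g ~ N(0, K sigma_g^2)`, `e ~ N(0, I sigma_e^2)`.
#' The restricted likelihood depends on K only through the eigenvalues and
#' eigenvectors of the intercept-projected kernel `S K S`
#' (`S = I - 11'/n`), so when many traits or simulation replicates share
#' one K the decomposition can be computed once and passed to
#' [reml_fit()] via `eigen_K`.
#'
#' @param K a [relationship_matrix()] or symmetric numeric matrix.
#' @return a list with the n-1 retained eigenvalues (`xi`), eigenvectors
#'   (`U`), `n`, and the original kernel (`K`).
#' @export
reml_eigen <- function(K) {
  m <- if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K)
  n <- nrow(m)
  if (n < 10) stop("REML requires at least 10 samples")
  cm <- colMeans(m)
  M <- m - rep(cm, each = n)            # S K
  M <- M - rowMeans(M)                  # S K S
  M <- (M + t(M)) / 2
  ee <- eigen(M, symmetric = TRUE)
  xi <- pmax(ee$values[seq_len(n - 1)], 0)
  if (stats::sd(xi) < 1e-9 * (mean(xi) + 1e-12))
    stop("kernel is non-identifiable for REML (projected eigenvalues are all ",
         "equal, e.g. K = I): genetic and residual variance cannot be separated")
  list(xi = xi, U = ee$vectors[, seq_len(n - 1), drop = FALSE], n = n, K = m)
}

#' REML variance components for a kernel model
#'
#' Profiles the restricted log-likelihood over the variance ratio
#' `delta = sigma_e^2 / sigma_g^2` on the eigen-rotated data (one
#' eigendecomposition, then a 1-D bounded search over `log delta`:
#' log-spaced bracketing followed by [stats::optimize()] at 1e-8
#' tolerance). Returns the variance components, the heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, and asymptotic standard
#' errors from the REML Fisher information (omitted at boundary
#' estimates, where the asymptotics do not apply).
#'
#' @param y_star an `adjusted_phenotypes` object or a named numeric vector
#'   of adjusted phenotypes.
#' @param K a [relationship_matrix()] covering (at least) those samples.
#' @param eigen_K optional precomputed [reml_eigen()] structure for the
#'   samples of `y_star`, in the same order.
#' @param logdelta_range search bounds for `log(delta)`.
#' @return a `variance_components` list: `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_sigma_g2`, `se_sigma_e2`, `se_h2`, `loglik`, `converged`,
#'   `boundary`, `delta`.
#' @export
reml_fit <- function(y_star, K = NULL, eigen_K = NULL,
                     logdelta_range = c(-12, 12)) {
  y <- if (inherits(y_star, "adjusted_phenotypes")) y_star$y_star else y_star
  if (!all(is.finite(y))) stop("y* must be finite")
  if (is.null(eigen_K)) {
    if (is.null(K)) stop("supply K or eigen_K")
    if (!is.null(names(y)) && !is.null(rownames(K))) {
      if (!all(names(y) %in% rownames(K)))
        stop("samples missing from kernel: ",
             paste(setdiff(names(y), rownames(K)), collapse = ", "))
      m <- (if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K))
      K <- m[names(y), names(y), drop = FALSE]
    }
    eigen_K <- reml_eigen(K)
  }
  if (length(y) != eigen_K$n)
    stop("y* length does not match the kernel dimension")
  np <- eigen_K$n - 1
  eta2 <- as.numeric(crossprod(eigen_K$U, y))^2
  xi <- eigen_K$xi

  negll <- function(logd) {
    d <- exp(logd)
    0.5 * (np * log(sum(eta2 / (xi + d))) + sum(log(xi + d)))
  }
  grid <- seq(logdelta_range[1], logdelta_range[2], length.out = 61)
  vals <- vapply(grid, negll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-8)
  logd <- opt$minimum
  delta <- exp(logd)

  sigma_g2 <- sum(eta2 / (xi + delta)) / np
  sigma_e2 <- delta * sigma_g2
  h2 <- sigma_g2 / (sigma_g2 + sigma_e2)
  loglik <- 0.5 * (np * log(np / (2 * pi)) - np -
                     np * log(sum(eta2 / (xi + delta))) -
                     sum(log(xi + delta)))
  boundary <- (logd <= logdelta_range[1] + 1e-6) ||
              (logd >= logdelta_range[2] - 1e-6) ||
              h2 < 1e-3 || h2 > 1 - 1e-3

  se <- c(sg = NA_real_, se = NA_real_, h2 = NA_real_)
  if (!boundary && !is.null(eigen_K$K)) {
    se <- reml_se(eigen_K$K, sigma_g2, sigma_e2)
  }
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2,
                 se_sigma_g2 = se[["sg"]], se_sigma_e2 = se[["se"]],
                 se_h2 = se[["h2"]], loglik = loglik,
                 converged = TRUE, boundary = boundary, delta = delta),
            class = "variance_components")
}

# asymptotic SEs from the REML information matrix (dense; desk scale)
reml_se <- function(K, sigma_g2, sigma_e2) {
  n <- nrow(K)
  V <- sigma_g2 * K + diag(sigma_e2, n)
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) return(c(sg = NA_real_, se = NA_real_, h2 = NA_real_))
  x <- rep(1, n)
  Vx <- Vi %*% x
  P <- Vi - Vx %*% t(Vx) / sum(x * Vx)
  PK <- P %*% K
  I11 <- 0.5 * sum(PK * t(PK))
  I12 <- 0.5 * sum(PK * t(P))
  I22 <- 0.5 * sum(P * t(P))
  info <- matrix(c(I11, I12, I12, I22), 2)
  cv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cv)) return(c(sg = NA_real_, se = NA_real_, h2 = NA_real_))
  s <- sigma_g2 + sigma_e2
  grad <- c(sigma_e2, -sigma_g2) / s^2   # d h2 / d(sg2, se2)
  c(sg = sqrt(max(cv[1, 1], 0)), se = sqrt(max(cv[2, 2], 0)),
    h2 = sqrt(max(t(grad) %*% cv %*% grad, 0)))
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: sigma_g2 = %.4g (SE %.3g), sigma_e2 = %.4g (SE %.3g)\n",
              x$sigma_g2, x$se_sigma_g2, x$sigma_e2, x$se_sigma_e2))
  cat(sprintf("  h2 = %.4f (SE %.3g)%s, logLik = %.3f\n", x$h2, x$se_h2,
              if (x$boundary) " [boundary]" else "", x$loglik))
  invisible(x)
}

#' BLUP prediction of genetic values
#'
#' The conditional mean of the genetic values of the target samples given
#' the training phenotypes:
#' `gamma_hat = K[target, train] (K[train, train] + delta I)^{-1} y*_train`
#' with `delta = sigma_e^2 / sigma_g^2`. Each animal has one record
#' (identity incidence), and target may overlap train.
#'
#' @param y_star named numeric vector (or `adjusted_phenotypes`) covering
#'   at least the training samples.
#' @param K a [relationship_matrix()].
#' @param train_ids,target_ids sample ID vectors, subsets of the kernel IDs.
#' @param vc a `variance_components` object (or a list with `sigma_g2`,
#'   `sigma_e2`).
#' @return a `gebv_set` list: `sample_ids` (targets), `gebv` (named
#'   predictions), `train_ids`, `vc`.
#' @export
blup_predict <- function(y_star, K, train_ids, target_ids, vc) {
  y <- if (inherits(y_star, "adjusted_phenotypes")) y_star$y_star else y_star
  ids <- rownames(K)
  if (!all(train_ids %in% ids) || !all(target_ids %in% ids))
    stop("train/target IDs must be present in the kernel")
  if (!all(train_ids %in% names(y)))
    stop("training phenotypes incomplete")
  if (vc$sigma_g2 <= 0) {
    gebv <- stats::setNames(rep(0, length(target_ids)), target_ids)
  } else {
    delta <- vc$sigma_e2 / vc$sigma_g2
    if (!is.finite(delta)) stop("delta = sigma_e2/sigma_g2 must be finite")
    Km <- if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K)
    Ktt <- Km[train_ids, train_ids, drop = FALSE] + diag(delta, length(train_ids))
    alpha <- tryCatch(solve(Ktt, y[train_ids]),
                      error = function(e)
                        stop("singular training system; add kernel jitter or delta > 0"))
    gebv <- as.numeric(Km[target_ids, train_ids, drop = FALSE] %*% alpha)
    names(gebv) <- target_ids
  }
  structure(list(sample_ids = target_ids, gebv = gebv,
                 train_ids = train_ids, vc = vc),
            class = "gebv_set")
}

#' @export
print.gebv_set <- function(x, ...) {
  cat(sprintf("gebv_set: %d predictions from %d training samples\n",
              length(x$gebv), length(x$train_ids)))
  invisible(x)
}
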