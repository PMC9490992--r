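# shared fixture builders and independent oracles

tiny_geno <- function(dos, ids = NULL, markers = NULL) {
  dos <- as.matrix(dos)
  genotype_matrix(dos,
                  sample_ids = ids %||% paste0("s", seq_len(nrow(dos))),
                  marker_ids = markers %||% paste0("m", seq_len(ncol(dos))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random symmetric positive-definite matrix with unit-scale diagonal
random_psd <- function(n, ids = sprintf("i%02d", seq_len(n))) {
  X <- matrix(rnorm(n * (n + 5)), n)
  K <- tcrossprod(X) / (n + 5)
  K <- K + diag(0.1, n)
  dimnames(K) <- list(ids, ids)
  K
}

# brute-force VanRaden G: explicit double loop over sample pairs
naive_vanraden <- function(dos) {
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  n <- nrow(dos)
  G <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      G[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
  G
}

# brute-force cosine kernel via explicit pair loop
naive_cosine <- function(X) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      K[i, j] <- sum(X[i, ] * X[j, ]) / sqrt(sum(X[i, ]^2) * sum(X[j, ]^2))
  K
}

# simulate y with a given heritability from an eigendecomposed kernel
simulate_y_from_kernel <- function(es, h2) {
  n <- length(es$values)
  g <- es$vectors %*% (sqrt(pmax(es$values, 0)) * rnorm(n)) * sqrt(h2)
  as.numeric(g) + rnorm(n, 0, sqrt(1 - h2))
}

# small fully/partially transcribed bundles for model tests
small_bundle <- function(seed = 11, n_total = 80, n_transcribed = 20,
                         m = 300, g = 80, ...) {
  make_study_bundle(n_total = n_total, n_transcribed = n_transcribed,
                    m = m, g = g, seed = seed, ...)
}
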