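#' Per-marker allele frequencies
#'
#' The frequency of the counted allele for each marker, `p_i` = mean
#' non-missing dosage / 2. Fixed markers (p = 0 or 1) are rejected: they
#' carry no relationship information and make the VanRaden denominator
#' degenerate, so they should have been removed by [filter_snps()].
#'
#' @param geno a [genotype_matrix()].
#' @return named numeric vector of `p_i` in (0, 1).
#' @export
allele_frequencies <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- colMeans(unclass(geno), na.rm = TRUE) / 2
  fixed <- which(p <= 0 | p >= 1 | is.nan(p))
  if (length(fixed))
    stop("fixed marker(s) present (run QC first): ",
         paste(utils::head(colnames(geno)[fixed], 5), collapse = ", "))
  p
}

# mean-dosage imputation of missing calls, used only at kernel build time
impute_mean_dosage <- function(m) {
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2]]
  m
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))` where `Z` is the dosage matrix
#' centered by twice the allele frequency. Missing calls are imputed to the
#' marker mean dosage (`2 p_i`) for this computation only.
#'
#' @param geno a QC'd [genotype_matrix()] with no fixed markers.
#' @return a [relationship_matrix()] with provenance `"vanraden_G"`.
#' @export
vanraden_g <- function(geno) {
  p <- allele_frequencies(geno)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("zero VanRaden denominator: all markers fixed")
  Z <- sweep(impute_mean_dosage(unclass(geno)), 2, 2 * p)
  G <- tcrossprod(Z) / denom
  relationship_matrix(G, sample_ids = rownames(geno), provenance = "vanraden_G")
}

#' Cosine-kernel relationship matrix
#'
#' Maps any samples-by-features matrix (raw 0/1/2 SNP dosages or raw FPKM
#' expression profiles) to an n x n similarity matrix,
#' `K_ij = <x_i, x_j> / (||x_i|| ||x_j||)`, the cosine of the angle between
#' the two feature vectors. A diagonal regularization `C` is then added
#' (`K + C I`) so downstream block inversions are well conditioned; the
#' default C = 0.05 follows a grid-searched value. Off-diagonal entries lie
#' in [-1, 1] and the pre-jitter matrix is a Gram matrix of unit vectors,
#' hence positive semi-definite with unit diagonal.
#'
#' @param features numeric samples-by-features matrix (a
#'   [genotype_matrix()] or [expression_matrix()] also works; genotype
#'   missing calls are mean-imputed first).
#' @param jitter_C diagonal regularization added after kernelization
#'   (default 0.05).
#' @param log1p if `TRUE`, apply `log1p` to the features first (optional
#'   variance-stabilization for expression; off by default).
#' @param provenance provenance tag; defaults by input class.
#' @return a [relationship_matrix()].
#' @export
cosine_kernel <- function(features, jitter_C = 0.05, log1p = FALSE,
                          provenance = NULL) {
  if (is.null(provenance))
    provenance <- if (inherits(features, "expression_matrix")) "cosine_T"
                  else if (inherits(features, "genotype_matrix")) "cosine_G"
                  else "cosine"
  if (jitter_C < 0) stop("jitter_C must be >= 0")
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(features)))
  X <- unclass(as.matrix(features))
  storage.mode(X) <- "double"
  if (inherits(features, "genotype_matrix")) X <- impute_mean_dosage(X)
  if (log1p) X <- log1p(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("zero-norm feature vector for sample(s): ",
         paste(ids[zero], collapse = ", "))
  Xu <- X / nrm
  K <- tcrossprod(Xu)
  K <- pmin(pmax(K, -1), 1)
  diag(K) <- 1
  K <- K + diag(jitter_C, nrow(K))
  relationship_matrix(K, sample_ids = ids, provenance = provenance,
                      jitter = jitter_C)
}

#' Positive semi-definiteness check
#'
#' @param K symmetric matrix or [relationship_matrix()].
#' @param tol eigenvalues >= `-tol` count as non-negative (default 1e-8).
#' @return list with `psd` (logical) and `min_eigenvalue`.
#' @export
is_psd <- function(K, tol = 1e-8) {
  m <- if (inherits(K, "relationship_matrix")) rm_values(K) else as.matrix(K)
  if (max(abs(m - t(m))) > 1e-8) stop("is_psd requires a symmetric matrix")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tol, min_eigenvalue = min(ev))
}
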