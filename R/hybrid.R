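#' Blend genomic and transcriptomic kernels (MBLUP M matrix)
#'
#' `M = ratio * G + (1 - ratio) * T`, an elementwise convex combination of
#' two relationship matrices over the same samples in the same order.
#' `ratio = 1` recovers G (GBLUP), `ratio = 0` recovers T (TBLUP).
#'
#' @param G,T [relationship_matrix()] objects over identical sample IDs.
#' @param ratio blending weight on G, in \[0, 1\].
#' @return a [relationship_matrix()] with provenance `"M"`.
#' @export
blend_m <- function(G, T, ratio) {
  stopifnot(inherits(G, "relationship_matrix"), inherits(T, "relationship_matrix"))
  if (!identical(rownames(G), rownames(T)))
    stop("G and T sample IDs differ (or are ordered differently)")
  if (ratio < 0 || ratio > 1) stop("ratio must be in [0, 1]")
  M <- ratio * rm_values(G) + (1 - ratio) * rm_values(T)
  relationship_matrix(M, sample_ids = rownames(G), provenance = "M",
                      jitter = ratio * attr(G, "jitter") +
                               (1 - ratio) * attr(T, "jitter"))
}

#' Weighted transcriptomic kernel (wmssBLUP Tw matrix)
#'
#' `Tw = (1 - w) T + w G22`, where `G22` is the genomic-kernel block for the
#' transcribed samples. The weight `w` represents the proportion of genetic
#' relationships not explained by gene expression: `w = 0` keeps the pure
#' expression kernel, `w = 1` falls back to genomics only.
#'
#' @param T expression-kernel [relationship_matrix()] over the transcribed
#'   samples.
#' @param G22 genomic-kernel block for the same samples in the same order.
#' @param w weight in \[0, 1\].
#' @return a [relationship_matrix()] with provenance `"Tw"`.
#' @export
blend_tw <- function(T, G22, w) {
  stopifnot(inherits(T, "relationship_matrix"), inherits(G22, "relationship_matrix"))
  if (nrow(T) != nrow(G22))
    stop(sprintf("dimension mismatch: T is %d x %d, G22 is %d x %d",
                 nrow(T), ncol(T), nrow(G22), ncol(G22)))
  if (!identical(rownames(T), rownames(G22)))
    stop("T and G22 sample IDs differ (or are ordered differently)")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  Tw <- (1 - w) * rm_values(T) + w * rm_values(G22)
  relationship_matrix(Tw, sample_ids = rownames(T), provenance = "Tw",
                      jitter = (1 - w) * attr(T, "jitter") +
                               w * attr(G22, "jitter"))
}

check_partition <- function(G_full, T_mat, partition) {
  ids <- rownames(G_full)
  if (is.null(partition)) partition <- rownames(T_mat)
  partition <- as.character(partition)
  if (!all(partition %in% ids))
    stop("partition IDs absent from G: ",
         paste(setdiff(partition, ids), collapse = ", "))
  if (!identical(partition, rownames(T_mat)))
    stop("partition does not match the T/Tw sample IDs (same IDs, same order required)")
  idx2 <- match(partition, ids)
  if (!identical(idx2, seq.int(length(ids) - length(partition) + 1, length(ids))))
    stop("transcribed samples must form the trailing block of G ",
         "(use align_samples(): non-transcribed first, transcribed last)")
  idx2
}

#' Build the hybrid (single-step style) relationship matrix Hm
#'
#' Embeds the expression kernel `T` (or the weighted blend `Tw`) of the
#' transcribed subset into the genome-wide kernel `G`, so genotype-only
#' samples borrow transcriptomic information through their genomic
#' relationships with the transcribed block. With block 1 = genotype-only
#' and block 2 = transcribed samples:
#' \deqn{Hm_{22} = T, \quad Hm_{12} = G_{12} G_{22}^{-1} T, \quad
#'       Hm_{11} = G_{11} + G_{12} G_{22}^{-1} (T - G_{22}) G_{22}^{-1} G_{21}}
#' This is the standard single-step correction form; it is the unique form
#' consistent with the closed-form inverse implemented in
#' [invert_hybrid()], and it reduces to `Hm = G` exactly when `T = G22`.
#'
#' @param G_full genomic [relationship_matrix()] over all samples, ordered
#'   with the transcribed block last.
#' @param T_or_Tw expression-side kernel over exactly the transcribed
#'   samples (same order as the trailing block of `G_full`).
#' @param partition character vector of transcribed sample IDs; defaults to
#'   the rownames of `T_or_Tw`.
#' @return a [relationship_matrix()] with provenance `"Hm"` and attributes
#'   `block2_ids` (transcribed IDs) and `w` (if `T_or_Tw` carries one).
#' @export
build_hybrid <- function(G_full, T_or_Tw, partition = NULL) {
  stopifnot(inherits(G_full, "relationship_matrix"))
  Tm <- if (inherits(T_or_Tw, "relationship_matrix")) rm_values(T_or_Tw) else as.matrix(T_or_Tw)
  idx2 <- check_partition(G_full, T_or_Tw, partition)
  Gm <- rm_values(G_full)
  n <- nrow(Gm)
  idx1 <- setdiff(seq_len(n), idx2)
  G22 <- Gm[idx2, idx2, drop = FALSE]
  if (identical(dim(Tm), dim(G22)) && all(Tm == G22)) {
    # exact reduction: embedding the genomic block changes nothing
    out <- relationship_matrix(Gm, sample_ids = rownames(Gm),
                               provenance = "Hm", jitter = attr(G_full, "jitter"))
    attr(out, "block2_ids") <- rownames(Gm)[idx2]
    return(out)
  }
  A <- tryCatch(t(solve(G22, Gm[idx2, idx1, drop = FALSE])),  # G12 G22^-1
                error = function(e)
                  stop("singular G22 block; add diagonal jitter to the cosine kernels (jitter_C)"))
  Hm <- Gm
  if (length(idx1)) {
    Hm[idx1, idx2] <- A %*% Tm
    Hm[idx2, idx1] <- t(Hm[idx1, idx2, drop = FALSE])
    Hm[idx1, idx1] <- Gm[idx1, idx1, drop = FALSE] + A %*% (Tm - G22) %*% t(A)
  }
  Hm[idx2, idx2] <- Tm
  Hm <- (Hm + t(Hm)) / 2
  out <- relationship_matrix(Hm, sample_ids = rownames(Gm), provenance = "Hm",
                             jitter = attr(G_full, "jitter"))
  attr(out, "block2_ids") <- rownames(Gm)[idx2]
  out
}

#' Closed-form inverse of the hybrid matrix
#'
#' \deqn{Hm^{-1} = G^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & T^{-1} - G_{22}^{-1}
#' \end{bmatrix}}
#' The correction acts only on the transcribed block; when `T = G22` it
#' vanishes and the result is `G^{-1}`. Equals the direct inverse of
#' [build_hybrid()]'s output (a property exercised by the test suite).
#'
#' @inheritParams build_hybrid
#' @return plain numeric matrix, the inverse of Hm, with sample dimnames.
#' @export
invert_hybrid <- function(G_full, T_or_Tw, partition = NULL) {
  stopifnot(inherits(G_full, "relationship_matrix"))
  Tm <- if (inherits(T_or_Tw, "relationship_matrix")) rm_values(T_or_Tw) else as.matrix(T_or_Tw)
  idx2 <- check_partition(G_full, T_or_Tw, partition)
  Gm <- rm_values(G_full)
  Ginv <- tryCatch(solve(Gm), error = function(e) stop("singular G matrix"))
  G22inv <- tryCatch(solve(Gm[idx2, idx2, drop = FALSE]),
                     error = function(e) stop("singular G22 block"))
  Tinv <- tryCatch(solve(Tm), error = function(e) stop("singular T/Tw matrix"))
  Hinv <- Ginv
  Hinv[idx2, idx2] <- Hinv[idx2, idx2, drop = FALSE] + Tinv - G22inv
  Hinv <- (Hinv + t(Hinv)) / 2
  dimnames(Hinv) <- dimnames(Gm)
  Hinv
}
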