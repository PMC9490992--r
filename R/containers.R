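#' omixblup: multi-omics kernel BLUP for genomic prediction
#'
#' Kernel relationship matrices from SNP dosages and gene-expression
#' profiles, five BLUP-family prediction models (GBLUP, TBLUP, MBLUP,
#' mssBLUP, wmssBLUP), REML variance components, cross-validated accuracy,
#' and a synthetic study-design simulator.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a genotype matrix
#'
#' Samples are rows, markers are columns; entries are additive allele
#' dosages 0/1/2 with `NA` for missing calls. Missingness is preserved on
#' storage and only imputed (to the marker mean dosage) when a relationship
#' matrix is built.
#'
#' @param dosages numeric matrix, n samples x m markers, values in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids,marker_ids character vectors of unique IDs; default to
#'   the dimnames of `dosages`.
#' @param marker_meta optional data.frame of per-marker metadata
#'   (e.g. chromosome, position), one row per marker.
#' @return an object of class `genotype_matrix` (a numeric matrix with
#'   dimnames and optional `marker_meta` attribute).
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            marker_ids = colnames(dosages),
                            marker_meta = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids) || is.null(marker_ids))
    stop("genotype_matrix requires sample and marker IDs")
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ID: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != length(marker_ids))
    stop("dosage dimensions do not match ID lengths")
  storage.mode(dosages) <- "double"
  bad <- which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(dosages))
    stop(sprintf("invalid dosage %s at sample '%s', marker '%s' (must be 0/1/2/NA)",
                 format(dosages[bad[1]]), sample_ids[ij[1]], marker_ids[ij[2]]))
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  if (!is.null(marker_meta)) {
    if (nrow(marker_meta) != length(marker_ids))
      stop("marker_meta must have one row per marker")
    attr(dosages, "marker_meta") <- marker_meta
  }
  class(dosages) <- c("genotype_matrix", "matrix", "array")
  dosages
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  meta <- attr(x, "marker_meta")
  y <- NextMethod(drop = FALSE)
  if (!is.null(meta)) {
    jj <- if (missing(j)) seq_len(ncol(unclass(x))) else j
    attr(y, "marker_meta") <- meta[jj, , drop = FALSE]
  }
  class(y) <- class(x)
  y
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d missing calls)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Construct an expression matrix
#'
#' Samples are rows, genes are columns; entries are non-negative abundances
#' (FPKM units in the intended workflow).
#'
#' @param abundances numeric matrix, n samples x g genes, finite and >= 0.
#' @param sample_ids,gene_ids character vectors of unique IDs.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(abundances, sample_ids = rownames(abundances),
                              gene_ids = colnames(abundances)) {
  abundances <- as.matrix(abundances)
  if (is.null(sample_ids) || is.null(gene_ids))
    stop("expression_matrix requires sample and gene IDs")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ID: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  storage.mode(abundances) <- "double"
  if (any(!is.finite(abundances)))
    stop("expression abundances must be finite")
  if (any(abundances < 0)) {
    ij <- arrayInd(which(abundances < 0)[1], dim(abundances))
    stop(sprintf("negative abundance at sample '%s', gene '%s'",
                 sample_ids[ij[1]], gene_ids[ij[2]]))
  }
  dimnames(abundances) <- list(sample_ids, gene_ids)
  class(abundances) <- c("expression_matrix", "matrix", "array")
  abundances
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- NextMethod(drop = FALSE)
  class(y) <- class(x)
  y
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a phenotype table
#'
#' One row per sample: a `sample_id` column, one or more trait columns
#' (possibly with missing values), and named covariate columns each flagged
#' categorical or continuous.
#'
#' @param df data.frame containing `sample_id`, trait and covariate columns.
#' @param traits character vector of trait column names.
#' @param covariates named character vector mapping covariate column name to
#'   `"categorical"` or `"continuous"`; may be empty.
#' @return an object of class `phenotype_table` (a data.frame with `traits`
#'   and `covariates` attributes).
#' @export
phenotype_table <- function(df, traits, covariates = character()) {
  df <- as.data.frame(df)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs a 'sample_id' column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ID: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (length(traits) < 1) stop("at least one trait column is required")
  missing_tr <- setdiff(traits, names(df))
  if (length(missing_tr))
    stop("trait column absent: ", paste(missing_tr, collapse = ", "))
  if (length(covariates)) {
    if (is.null(names(covariates)) || any(names(covariates) == ""))
      stop("covariates must be a named vector (name -> categorical/continuous)")
    if (!all(covariates %in% c("categorical", "continuous")))
      stop("covariate kinds must be 'categorical' or 'continuous'")
    missing_cv <- setdiff(names(covariates), names(df))
    if (length(missing_cv))
      stop("covariate column absent: ", paste(missing_cv, collapse = ", "))
  }
  attr(df, "traits") <- traits
  attr(df, "covariates") <- covariates
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples, traits: %s, covariates: %s\n",
              nrow(x), paste(attr(x, "traits"), collapse = ", "),
              if (length(attr(x, "covariates")))
                paste(names(attr(x, "covariates")), collapse = ", ") else "none"))
  invisible(x)
}

#' Construct a relationship matrix
#'
#' A square symmetric sample-by-sample similarity matrix (G, T, M, Hm, ...)
#' with a provenance tag recording how it was built and the diagonal jitter
#' applied, if any.
#'
#' @param values numeric n x n matrix, symmetric to 1e-10.
#' @param sample_ids character vector of unique sample IDs.
#' @param provenance character tag, e.g. `"vanraden_G"`, `"cosine_T"`, `"Hm"`.
#' @param jitter numeric >= 0, the diagonal regularization added.
#' @return an object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, sample_ids = rownames(values),
                                provenance = "unknown", jitter = 0) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (is.null(sample_ids)) stop("relationship_matrix requires sample IDs")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ID in relationship matrix")
  if (length(sample_ids) != nrow(values)) stop("ID length mismatch")
  if (max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix is not symmetric")
  values <- (values + t(values)) / 2
  dimnames(values) <- list(sample_ids, sample_ids)
  attr(values, "provenance") <- provenance
  attr(values, "jitter") <- jitter
  class(values) <- c("relationship_matrix", "matrix", "array")
  values
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix [%s]: %d x %d, jitter = %g\n",
              attr(x, "provenance"), nrow(x), ncol(x), attr(x, "jitter")))
  invisible(x)
}

# plain numeric view (drops class/attrs)
rm_values <- function(K) {
  y <- unclass(K)
  attr(y, "provenance") <- NULL
  attr(y, "jitter") <- NULL
  y
}
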