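#' Read a genotype dosage table
#'
#' Two dialects are supported. `"plink-raw"` is the additive-dosage export
#' of PLINK (`--recode A`): space-separated, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per marker,
#' samples as rows, `NA` for missing; the IID column provides the sample ID.
#' `"simple-tsv"` is a plain TSV with markers as rows and samples as
#' columns: first column marker ID, header row of sample IDs.
#'
#' @param path file path.
#' @param dialect `"plink-raw"` or `"simple-tsv"`.
#' @return a [genotype_matrix()] with IDs in file order; missing entries are
#'   kept as `NA`, never imputed here.
#' @export
read_genotypes <- function(path, dialect = c("plink-raw", "simple-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("genotype file is empty or header-only: ", path)
  if (dialect == "plink-raw") {
    header <- strsplit(lines[1], "[ \t]+")[[1]]
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (length(header) < 7 || !identical(header[1:6], fixed))
      stop("not a plink-raw header (expected FID IID PAT MAT SEX PHENOTYPE ...): ", path)
    marker_ids <- header[-(1:6)]
    rows <- strsplit(lines[-1], "[ \t]+")
    n <- length(rows)
    sample_ids <- vapply(rows, function(r) r[2], character(1))
    dos <- matrix(NA_real_, n, length(marker_ids))
    for (i in seq_len(n)) {
      r <- rows[[i]]
      if (length(r) != length(header))
        stop(sprintf("row %d has %d fields, expected %d", i + 1, length(r), length(header)))
      v <- r[-(1:6)]
      dos[i, ] <- parse_dosage_fields(v, i + 1, marker_ids)
    }
  } else {
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    sample_ids <- header[-1]
    rows <- strsplit(lines[-1], "\t", fixed = TRUE)
    marker_ids <- vapply(rows, function(r) r[1], character(1))
    dos <- matrix(NA_real_, length(sample_ids), length(marker_ids))
    for (j in seq_along(rows)) {
      r <- rows[[j]]
      if (length(r) != length(header))
        stop(sprintf("row %d has %d fields, expected %d", j + 1, length(r), length(header)))
      dos[, j] <- parse_dosage_fields(r[-1], j + 1, sample_ids)
    }
  }
  genotype_matrix(dos, sample_ids = sample_ids, marker_ids = marker_ids)
}

parse_dosage_fields <- function(v, line, col_ids) {
  bad <- !(v %in% c("0", "1", "2", "NA"))
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("malformed dosage '%s' at line %d, column '%s' (must be 0/1/2/NA)",
                 v[k], line, col_ids[k]))
  }
  out <- suppressWarnings(as.numeric(v))
  out
}

#' Write a genotype matrix in the simple-tsv dialect
#'
#' Markers as rows, samples as columns, integer dosages, `NA` for missing.
#' `read_genotypes(write_genotypes(x), "simple-tsv")` is a lossless round
#' trip and the bytes are reproduced exactly.
#'
#' @param geno a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- unclass(geno)
  vals <- ifelse(is.na(m), "NA", format(as.integer(m), trim = TRUE, scientific = FALSE))
  dim(vals) <- dim(m)
  header <- paste(c("marker_id", rownames(m)), collapse = "\t")
  body <- vapply(seq_len(ncol(m)), function(j)
    paste(c(colnames(m)[j], vals[, j]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene-expression table
#'
#' TSV with genes as rows: first column gene ID, header row of sample IDs,
#' non-negative numeric abundances (FPKM). The matrix is transposed to the
#' internal samples-by-genes orientation.
#'
#' @param path file path.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene ID column plus samples: ", path)
  gene_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
                   !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric abundance at gene '%s', sample '%s'",
                   gene_ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]]))
    stop("non-numeric abundance values in ", path)
  }
  expression_matrix(t(vals), sample_ids = colnames(df)[-1], gene_ids = gene_ids)
}

#' Write a gene-expression table (genes x samples TSV)
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  m <- t(unclass(expr))
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format_real(m[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

format_real <- function(x) {
  out <- vapply(x, function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE),
                character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Read a phenotype + covariate table
#'
#' CSV with a header containing `sample_id`, the trait column(s), and the
#' covariate columns named by `covariate_spec`. Missing trait values are
#' retained as `NA` (flagged, never dropped).
#'
#' @param path file path.
#' @param trait trait column name (or character vector of several).
#' @param covariate_spec named character vector: covariate column ->
#'   `"categorical"` or `"continuous"`.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, trait, covariate_spec = character()) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (cv in names(covariate_spec)[covariate_spec == "continuous"])
    if (cv %in% names(df)) df[[cv]] <- as.numeric(df[[cv]])
  for (cv in names(covariate_spec)[covariate_spec == "categorical"])
    if (cv %in% names(df)) df[[cv]] <- as.character(df[[cv]])
  phenotype_table(df, traits = trait, covariates = covariate_spec)
}

#' Write a phenotype table as CSV
#'
#' @param pheno a [phenotype_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(inherits(pheno, "phenotype_table"))
  utils::write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a relationship matrix as TSV
#'
#' Sample IDs appear both as the header and as the first column; values are
#' written with 17 significant digits so the round trip is exact to well
#' below 1e-12.
#'
#' @param K a [relationship_matrix()].
#' @param path file path.
#' @return `write_kernel`: `path` invisibly; `read_kernel`: a
#'   [relationship_matrix()].
#' @export
write_kernel <- function(K, path) {
  stopifnot(inherits(K, "relationship_matrix"))
  m <- rm_values(K)
  header <- paste(c("sample_id", rownames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format_real(m[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_kernel
#' @param provenance provenance tag to attach on read.
#' @export
read_kernel <- function(path, provenance = "file") {
  if (!file.exists(path)) stop("kernel file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop(sprintf("kernel file is not square: %d rows x %d columns", nrow(m), ncol(m)))
  if (!identical(ids, colnames(m)))
    stop("kernel row IDs do not match column IDs")
  if (max(abs(m - t(m))) > 1e-8) stop("kernel file is not symmetric")
  relationship_matrix(m, sample_ids = ids, provenance = provenance)
}

#' Align genotype, expression and phenotype sources on shared sample IDs
#'
#' Produces a consistently ordered bundle covering the genotyped samples
#' that also carry phenotypes. The ordering contract places non-transcribed
#' samples first and transcribed samples (those present in the expression
#' matrix) last, so the expression kernel always occupies the trailing
#' diagonal block of any hybrid relationship matrix.
#'
#' @param geno a [genotype_matrix()].
#' @param expr an [expression_matrix()] or `NULL`; every expression sample
#'   must be genotyped.
#' @param pheno a [phenotype_table()].
#' @param trait,covariates trait name and covariate spec to carry on the
#'   bundle; default to the phenotype table's attributes.
#' @return an object of class `aligned_bundle`: a list with `geno`, `expr`,
#'   `pheno` (reordered views), `sample_ids`, `transcribed_ids`, and the
#'   block sizes `n_nontranscribed` / `n_transcribed`.
#' @export
align_samples <- function(geno, expr = NULL, pheno,
                          trait = attr(pheno, "traits")[1],
                          covariates = attr(pheno, "covariates")) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(pheno, "phenotype_table"))
  gids <- rownames(geno)
  pids <- pheno$sample_id
  shared <- gids[gids %in% pids]
  if (!length(shared)) stop("no shared sample IDs between genotypes and phenotypes")
  tids <- character()
  if (!is.null(expr)) {
    stopifnot(inherits(expr, "expression_matrix"))
    eids <- rownames(expr)
    orphan <- setdiff(eids, gids)
    if (length(orphan))
      stop("expression sample(s) absent from genotypes: ",
           paste(orphan, collapse = ", "))
    tids <- shared[shared %in% eids]
  }
  ord <- c(setdiff(shared, tids), tids)
  bundle <- list(
    geno = geno[ord, , drop = FALSE],
    expr = if (length(tids)) expr[tids, , drop = FALSE] else NULL,
    pheno = {
      ph <- pheno[match(ord, pheno$sample_id), , drop = FALSE]
      rownames(ph) <- NULL
      attr(ph, "traits") <- attr(pheno, "traits")
      attr(ph, "covariates") <- attr(pheno, "covariates")
      class(ph) <- class(pheno)
      ph
    },
    sample_ids = ord,
    transcribed_ids = tids,
    n_nontranscribed = length(ord) - length(tids),
    n_transcribed = length(tids),
    trait = trait,
    covariates = covariates
  )
  class(bundle) <- "aligned_bundle"
  bundle
}

#' @export
print.aligned_bundle <- function(x, ...) {
  cat(sprintf("aligned_bundle: %d samples (%d genotype-only + %d transcribed), trait '%s'\n",
              length(x$sample_ids), x$n_nontranscribed, x$n_transcribed, x$trait))
  invisible(x)
}
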