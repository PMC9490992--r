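#' Hardy-Weinberg chi-square test p-value
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the Hardy-Weinberg expectations (p^2, 2pq, q^2) at the
#' observed allele frequency. A monomorphic marker returns p = 1 by
#' convention (it cannot deviate from equilibrium).
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return the p-value.
#' @export
hwe_chisq_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' SNP and sample quality control
#'
#' Mirrors the standard PLINK-style filtering sequence: samples with a
#' genotype missing rate strictly greater than `sample_missing_max` are
#' removed first; then markers are removed that fail any of call rate <
#' `call_rate_min`, minor allele frequency < `maf_min` (computed on
#' non-missing calls after sample filtering), or Hardy-Weinberg p <
#' `hwe_p_min`. All inequalities are strict, so boundary values survive.
#' Removal counts are attributed sequentially (call rate, then MAF among
#' survivors, then HWE among survivors) so each removed marker is counted
#' once.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param call_rate_min minimum marker call rate (default 0.90).
#' @param hwe_p_min minimum Hardy-Weinberg p-value (default 1e-6).
#' @param sample_missing_max maximum per-sample missing rate (default 0.10).
#' @return list with elements `geno` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report`).
#' @export
filter_snps <- function(geno, maf_min = 0.05, call_rate_min = 0.90,
                        hwe_p_min = 1e-6, sample_missing_max = 0.10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno) == 0 || ncol(geno) == 0) stop("empty genotype matrix")
  m <- unclass(geno)

  smiss <- rowMeans(is.na(m))
  bad_samples <- smiss > sample_missing_max
  removed_samples <- rownames(m)[bad_samples]
  m2 <- m[!bad_samples, , drop = FALSE]
  if (nrow(m2) == 0) stop("all samples removed by missing-rate filter")

  call_rate <- colMeans(!is.na(m2))
  p <- colMeans(m2, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(m2)), function(j) {
    x <- m2[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_chisq_p(sum(x == 2), sum(x == 1), sum(x == 0))
  }, numeric(1))

  fail_cr <- call_rate < call_rate_min
  fail_maf <- !fail_cr & maf < maf_min
  fail_hwe <- !fail_cr & !fail_maf & hwe_p < hwe_p_min
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep))
    stop("all markers removed by QC; review maf_min/call_rate_min/hwe_p_min thresholds")

  report <- qc_report(
    n_input = ncol(m),
    n_removed_by_rule = c(
      sample_missing = length(removed_samples),
      call_rate = sum(fail_cr),
      maf = sum(fail_maf),
      hwe = sum(fail_hwe)
    ),
    n_output = sum(keep),
    removed_ids = list(samples = removed_samples,
                       markers = colnames(m2)[!keep])
  )
  geno_out <- geno[!bad_samples, keep]
  list(geno = geno_out, report = report)
}

#' Gene-level expression filter
#'
#' A gene is discarded iff its abundance is below `min_fpkm` in strictly
#' more than `max_low_prop` of the samples; a gene low in exactly that
#' proportion is retained.
#'
#' @param expr an [expression_matrix()].
#' @param min_fpkm abundance threshold (default 0.1 FPKM).
#' @param max_low_prop maximum tolerated proportion of low samples
#'   (default 0.95).
#' @return list with elements `expr` (filtered) and `report` (`qc_report`).
#' @export
filter_genes <- function(expr, min_fpkm = 0.1, max_low_prop = 0.95) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(expr) == 0 || ncol(expr) == 0) stop("empty expression matrix")
  m <- unclass(expr)
  low_prop <- colMeans(m < min_fpkm)
  drop <- low_prop > max_low_prop
  report <- qc_report(
    n_input = ncol(m),
    n_removed_by_rule = c(low_expression = sum(drop)),
    n_output = sum(!drop),
    removed_ids = list(genes = colnames(m)[drop])
  )
  list(expr = expr[, !drop], report = report)
}

#' QC report container
#'
#' @param n_input number of features entering the filter.
#' @param n_removed_by_rule named integer vector of removal counts, each
#'   removed feature counted under exactly one rule.
#' @param n_output number of features surviving.
#' @param removed_ids list of removed ID vectors.
#' @return a `qc_report` list.
#' @export
qc_report <- function(n_input, n_removed_by_rule, n_output, removed_ids) {
  marker_rules <- setdiff(names(n_removed_by_rule), "sample_missing")
  if (n_input - sum(n_removed_by_rule[marker_rules]) != n_output)
    stop("inconsistent QC accounting")
  structure(list(n_input = n_input,
                 n_removed_by_rule = n_removed_by_rule,
                 n_output = n_output,
                 removed_ids = removed_ids),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d -> %d features\n", x$n_input, x$n_output))
  for (r in names(x$n_removed_by_rule))
    cat(sprintf("  removed by %s: %d\n", r, x$n_removed_by_rule[[r]]))
  invisible(x)
}

#' Serialize a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
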