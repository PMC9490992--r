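#' Adjust phenotypes for fixed effects
#'
#' Two-stage analysis, stage one: the trait is regressed on the fixed
#' effects by ordinary least squares and the residual `y* = y - X beta_hat`
#' is carried into the random-effect models. Categorical covariates are
#' expanded to treatment-coded indicators (first level dropped), continuous
#' covariates are kept as-is, and an intercept is always included, so `y*`
#' has mean zero.
#'
#' @param pheno a [phenotype_table()].
#' @param trait trait column name; defaults to the table's first trait.
#' @param covariates named character vector (column -> categorical /
#'   continuous); defaults to the table's covariate spec. May be empty, in
#'   which case the model is intercept-only.
#' @return an `adjusted_phenotypes` list: `sample_ids`, `y_star` (named
#'   residuals), `beta` (named coefficients), `design_columns`, and
#'   `n_excluded` (samples dropped for missing trait/covariate values).
#' @export
adjust_phenotypes <- function(pheno, trait = attr(pheno, "traits")[1],
                              covariates = attr(pheno, "covariates")) {
  stopifnot(inherits(pheno, "phenotype_table"))
  if (!trait %in% names(pheno)) stop("trait column absent: ", trait)
  df <- as.data.frame(pheno)
  y <- as.numeric(df[[trait]])
  keep <- !is.na(y)
  if (length(covariates))
    for (cv in names(covariates)) keep <- keep & !is.na(df[[cv]])
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    warning(sprintf("%d sample(s) excluded for missing trait or covariate values",
                    n_excluded))
  df <- df[keep, , drop = FALSE]
  y <- y[keep]

  X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(covariates)) {
    for (cv in names(covariates)) {
      if (covariates[[cv]] == "categorical") {
        f <- factor(df[[cv]])
        if (nlevels(f) > 1) {
          mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
          colnames(mm) <- paste0(cv, levels(f)[-1])
          X <- cbind(X, mm)
        }
      } else {
        X <- cbind(X, stats::setNames(df[, cv, drop = FALSE], cv)[[1]])
        colnames(X)[ncol(X)] <- cv
      }
    }
  }
  if (nrow(X) < ncol(X) + 2)
    stop("need at least 2 more samples than design columns")
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_X, y)
  y_star <- as.numeric(y - X %*% beta)
  names(y_star) <- df$sample_id
  structure(list(sample_ids = df$sample_id,
                 y_star = y_star,
                 beta = beta,
                 design_columns = colnames(X),
                 n_excluded = n_excluded),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf("adjusted_phenotypes: %d samples, %d design columns, mean(y*) = %.2e\n",
              length(x$y_star), length(x$design_columns), mean(x$y_star)))
  invisible(x)
}
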