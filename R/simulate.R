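# Seeded RNG helper: run `expr` under a local seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# fixed fan-out of a user seed into per-stage sub-seeds (< 2^31)
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

#' Simulate a genotyped population
#'
#' Markers are in linkage equilibrium and Hardy-Weinberg proportions:
#' per-marker allele frequency `p ~ Uniform(maf_range)` and dosages
#' `Binomial(2, p)` i.i.d. across animals. Marker metadata places markers
#' on one chromosome at 3 kb spacing, mirroring the density of a
#' post-QC bovine HD panel. A pure function of `(n, m, maf_range, seed)`.
#'
#' @param n number of animals.
#' @param m number of markers.
#' @param maf_range range of drawn allele frequencies (default 0.05-0.5).
#' @param seed integer seed.
#' @return a [genotype_matrix()]; the drawn frequencies are stored in the
#'   `sim_p` attribute.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1) {
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5] with min <= max")
  with_seed(seed, {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    dos <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
    g <- genotype_matrix(dos,
                         sample_ids = sprintf("S%04d", seq_len(n)),
                         marker_ids = sprintf("M%05d", seq_len(m)),
                         marker_meta = data.frame(chrom = 1L,
                                                  pos = seq_len(m) * 3000L))
    attr(g, "sim_p") <- p
    g
  })
}

#' Simulate gene expression under partial cis-genetic control
#'
#' Each gene's log-expression is a sum of a baseline, the effects of a few
#' randomly chosen cis markers, and Gaussian environmental noise scaled so
#' the genetic fraction of its log-scale variance is `expr_h2`.
#' Exponentiation yields skewed, non-negative FPKM-like abundances. The
#' per-gene cis architecture and the genetic component of every gene (for
#' all genotyped animals) are returned as simulation truth.
#'
#' @param geno a [genotype_matrix()] (no missing calls).
#' @param g number of genes.
#' @param cis_per_gene number of cis markers per gene (default 3).
#' @param expr_h2 genetic variance fraction of log-expression, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()] over all genotyped
#'   samples) and `truth` (list: `cis` marker indices per gene, `effects`,
#'   `gv` the n x g genetic-value matrix, `expr_h2`, `seed`).
#' @export
simulate_expression <- function(geno, g, cis_per_gene = 3, expr_h2 = 0.5,
                                seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  m <- ncol(geno)
  if (cis_per_gene > m) stop("cis_per_gene exceeds the number of markers")
  if (expr_h2 < 0 || expr_h2 > 1) stop("expr_h2 must be in [0, 1]")
  Z <- scale(unclass(geno), center = TRUE, scale = FALSE)
  n <- nrow(Z)
  with_seed(seed, {
    cis <- lapply(seq_len(g), function(j) sort(sample.int(m, cis_per_gene)))
    effects <- lapply(seq_len(g), function(j) stats::rnorm(cis_per_gene))
    baseline <- stats::rnorm(g, mean = 1, sd = 1)
    gv <- matrix(0, n, g)
    loge <- matrix(0, n, g)
    for (j in seq_len(g)) {
      u <- as.numeric(Z[, cis[[j]], drop = FALSE] %*% effects[[j]])
      if (expr_h2 == 0) u <- u * 0
      vg <- stats::var(u)
      ve <- if (expr_h2 == 0) 1
            else if (expr_h2 == 1) 0
            else vg * (1 - expr_h2) / expr_h2
      gv[, j] <- u
      loge[, j] <- baseline[j] + u + stats::rnorm(n, 0, sqrt(ve))
    }
    expr <- expression_matrix(exp(loge), sample_ids = rownames(geno),
                              gene_ids = sprintf("G%04d", seq_len(g)))
    list(expr = expr,
         truth = list(cis = cis, effects = effects, gv = gv,
                      baseline = baseline, expr_h2 = expr_h2, seed = seed))
  })
}

#' Simulate a low-heritability phenotype with an expression-mediated
#' genetic component
#'
#' The true genetic value mixes a direct polygenic part (small effects on
#' all markers) with a part acting through the genetically controlled
#' components of transcript abundance (a random linear combination of the
#' FPKM-scale genetic expression values, so highly expressed genes carry
#' proportionally more weight), in proportions `1 - mediation_share` and
#' `mediation_share`; environmental noise scales the genetic fraction of
#' phenotypic variance to `h2`. Four fixed-effect covariates with known
#' coefficients (birth year and slaughter batch, categorical; birth weight
#' and fattening duration, continuous) are added so downstream phenotype
#' adjustment is exercised.
#'
#' @param geno a [genotype_matrix()].
#' @param expr_truth the `truth` element of [simulate_expression()], or
#'   `NULL` when `mediation_share = 0`.
#' @param h2 target narrow-sense heritability, in (0, 1).
#' @param mediation_share fraction of genetic variance acting through
#'   expression, in \[0, 1\].
#' @param seed integer seed.
#' @return list with `pheno` (a [phenotype_table()] with trait `trait`) and
#'   `truth` (list: `genetic_values` named per animal, `h2`,
#'   `mediation_share`, `beta` the covariate coefficients, `seed`).
#' @export
simulate_phenotype <- function(geno, expr_truth = NULL, h2 = 0.2,
                               mediation_share = 0.5, seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (mediation_share < 0 || mediation_share > 1)
    stop("mediation_share must be in [0, 1]")
  if (mediation_share > 0 && is.null(expr_truth))
    stop("expr_truth required when mediation_share > 0")
  Z <- scale(unclass(geno), center = TRUE, scale = FALSE)
  n <- nrow(Z)
  ids <- rownames(geno)
  with_seed(seed, {
    alpha <- stats::rnorm(ncol(Z))
    u_dir <- as.numeric(Z %*% alpha)
    u_dir <- u_dir / stats::sd(u_dir)
    if (mediation_share > 0) {
      # the trait responds to transcript abundance: the mediated genetic
      # value is a linear combination of the genetic components of the
      # FPKM-scale expression levels, so highly expressed genes carry more
      # weight -- the same weighting the abundance-based kernels see
      f_gen <- exp(sweep(expr_truth$gv, 2, expr_truth$baseline, "+"))
      cvec <- stats::rnorm(ncol(f_gen))
      u_med <- as.numeric(f_gen %*% cvec)
      u_med <- (u_med - mean(u_med)) / stats::sd(u_med)
    } else u_med <- numeric(n)
    g_tot <- sqrt(1 - mediation_share) * u_dir + sqrt(mediation_share) * u_med
    g_tot <- g_tot / stats::sd(g_tot)
    e <- stats::rnorm(n, 0, sqrt((1 - h2) / h2))

    year <- sample(c("2018", "2019", "2020"), n, replace = TRUE)
    batch <- sample(paste0("B", 1:4), n, replace = TRUE)
    birth_weight <- stats::rnorm(n, 30, 4)
    fattening_days <- stats::rnorm(n, 400, 30)
    beta <- list(year = c(`2018` = 0, `2019` = 0.8, `2020` = -0.5),
                 batch = c(B1 = 0, B2 = 0.6, B3 = -0.4, B4 = 1.0),
                 birth_weight = 0.05, fattening_days = 0.01)
    fixed <- beta$year[year] + beta$batch[batch] +
      beta$birth_weight * birth_weight + beta$fattening_days * fattening_days
    y <- 10 + as.numeric(fixed) + g_tot + e

    pheno <- phenotype_table(
      data.frame(sample_id = ids, trait = y, year = year, batch = batch,
                 birth_weight = birth_weight, fattening_days = fattening_days,
                 stringsAsFactors = FALSE),
      traits = "trait",
      covariates = c(year = "categorical", birth_weight = "continuous",
                     fattening_days = "continuous", batch = "categorical"))
    list(pheno = pheno,
         truth = list(genetic_values = stats::setNames(g_tot, ids),
                      h2 = h2, mediation_share = mediation_share,
                      beta = beta, seed = seed))
  })
}

#' Simulate a complete study bundle
#'
#' Miniature of the study design this package targets: a genotyped
#' population of which only a small subset is also transcribed, expression
#' partially under cis-genetic control, and a low-heritability phenotype
#' with an expression-mediated genetic component. The transcribed subset is
#' a seed-deterministic random draw. Everything is a pure function of the
#' parameters and `seed`.
#'
#' @param n_total number of genotyped animals (default 300).
#' @param n_transcribed size of the transcribed subset (default 60).
#' @param m number of markers (default 2000).
#' @param g number of genes (default 500).
#' @param h2 phenotype heritability (default 0.2, at the upper end of the
#'   low-heritability carcass traits this design emulates).
#' @param mediation_share expression-mediated fraction of genetic variance
#'   (default 0.5).
#' @param expr_h2 cis-genetic fraction of log-expression variance
#'   (default 0.5).
#' @param cis_per_gene cis markers per gene (default 3).
#' @param maf_range allele-frequency range for the simulated markers.
#' @param seed integer seed; sub-seeds for the genotype, expression,
#'   phenotype and subset-draw stages are derived from it.
#' @return an [align_samples()] bundle with a `truth` element combining the
#'   stage truths.
#' @export
make_study_bundle <- function(n_total = 300, n_transcribed = 60, m = 2000,
                              g = 500, h2 = 0.2, mediation_share = 0.5,
                              expr_h2 = 0.5, cis_per_gene = 3,
                              maf_range = c(0.05, 0.5), seed = 1) {
  if (n_transcribed > n_total) stop("n_transcribed must be <= n_total")
  geno <- simulate_genotypes(n_total, m, maf_range = maf_range,
                             seed = derive_seed(seed, 1))
  se <- simulate_expression(geno, g = g, cis_per_gene = cis_per_gene,
                            expr_h2 = expr_h2, seed = derive_seed(seed, 2))
  sp <- simulate_phenotype(geno, expr_truth = se$truth, h2 = h2,
                           mediation_share = mediation_share,
                           seed = derive_seed(seed, 3))
  tids <- with_seed(derive_seed(seed, 4),
                    sort(sample(rownames(geno), n_transcribed)))
  bundle <- align_samples(geno, se$expr[tids, , drop = FALSE], sp$pheno)
  bundle$truth <- list(seed = seed, expression = se$truth,
                       phenotype = sp$truth,
                       transcribed_ids = tids)
  bundle
}
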