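#' Fit one of the five kernel BLUP models
#'
#' Dispatches kernel construction for the requested model, adjusts the
#' trait for the bundle's fixed effects, and estimates variance components
#' by REML:
#' \describe{
#'   \item{GBLUP}{genomic kernel over all samples: VanRaden G (default) or
#'     cosine G per `gblup_kernel`.}
#'   \item{TBLUP}{cosine kernel of expression; requires every sample
#'     transcribed.}
#'   \item{MBLUP}{`M = ratio * G_cos + (1 - ratio) * T`; requires every
#'     sample transcribed.}
#'   \item{mssBLUP}{hybrid `Hm` embedding T into the cosine G of all
#'     samples.}
#'   \item{wmssBLUP}{hybrid `Hm_w` built from `Tw = (1 - w) T + w G22`.}
#' }
#'
#' @param bundle an [align_samples()] bundle (e.g. from
#'   [make_study_bundle()]).
#' @param model one of `"GBLUP"`, `"TBLUP"`, `"MBLUP"`, `"mssBLUP"`,
#'   `"wmssBLUP"`.
#' @param ratio MBLUP blending weight on G (default 0.5).
#' @param w wmssBLUP weight on G22 (default 0.5).
#' @param gblup_kernel kernel for GBLUP: `"vanraden"` (default) or
#'   `"cosine"`.
#' @param jitter_C diagonal regularization for cosine kernels
#'   (default 0.05).
#' @return an `omix_fit` list: `model`, `K` (the fitted
#'   [relationship_matrix()]), `vc` (`variance_components`), `y_star`
#'   (named, in kernel order), `params`.
#' @export
fit_model <- function(bundle, model = c("GBLUP", "TBLUP", "MBLUP",
                                        "mssBLUP", "wmssBLUP"),
                      ratio = 0.5, w = 0.5,
                      gblup_kernel = c("vanraden", "cosine"),
                      jitter_C = 0.05) {
  model <- match.arg(model)
  gblup_kernel <- match.arg(gblup_kernel)
  stopifnot(inherits(bundle, "aligned_bundle"))
  K <- model_kernel(bundle, model, ratio = ratio, w = w,
                    gblup_kernel = gblup_kernel, jitter_C = jitter_C)
  adj <- adjust_phenotypes(bundle$pheno, trait = bundle$trait,
                           covariates = bundle$covariates)
  ids <- intersect(rownames(K), names(adj$y_star))
  y <- adj$y_star[ids]
  vc <- reml_fit(y, K[ids, ids])
  structure(list(model = model, K = K, vc = vc, y_star = y,
                 params = list(ratio = ratio, w = w,
                               gblup_kernel = gblup_kernel,
                               jitter_C = jitter_C)),
            class = "omix_fit")
}

# kernel construction shared by fit_model and the experiment drivers
model_kernel <- function(bundle, model, ratio = 0.5, w = 0.5,
                         gblup_kernel = "vanraden", jitter_C = 0.05) {
  fully_transcribed <- bundle$n_nontranscribed == 0 && bundle$n_transcribed > 0
  if (model %in% c("TBLUP", "MBLUP") && !fully_transcribed)
    stop(model, " requires expression for every sample; for a partially ",
         "transcribed bundle use mssBLUP or wmssBLUP")
  if (model %in% c("mssBLUP", "wmssBLUP") && bundle$n_transcribed == 0)
    stop(model, " requires a transcribed subset")
  switch(model,
    GBLUP = if (gblup_kernel == "vanraden") vanraden_g(bundle$geno)
            else cosine_kernel(bundle$geno, jitter_C = jitter_C),
    TBLUP = cosine_kernel(bundle$expr, jitter_C = jitter_C),
    MBLUP = blend_m(cosine_kernel(bundle$geno, jitter_C = jitter_C),
                    cosine_kernel(bundle$expr, jitter_C = jitter_C),
                    ratio = ratio),
    mssBLUP = {
      G <- cosine_kernel(bundle$geno, jitter_C = jitter_C)
      Tm <- cosine_kernel(bundle$expr, jitter_C = jitter_C)
      build_hybrid(G, Tm, partition = bundle$transcribed_ids)
    },
    wmssBLUP = {
      G <- cosine_kernel(bundle$geno, jitter_C = jitter_C)
      Tm <- cosine_kernel(bundle$expr, jitter_C = jitter_C)
      G22 <- relationship_matrix(
        rm_values(G)[bundle$transcribed_ids, bundle$transcribed_ids, drop = FALSE],
        sample_ids = bundle$transcribed_ids, provenance = "cosine_G22",
        jitter = attr(G, "jitter"))
      build_hybrid(G, blend_tw(Tm, G22, w = w),
                   partition = bundle$transcribed_ids)
    })
}

#' @export
print.omix_fit <- function(x, ...) {
  cat(sprintf("omix_fit: %s (n = %d), h2 = %.4f, sigma_g2 = %.4g, sigma_e2 = %.4g\n",
              x$model, length(x$y_star), x$vc$h2, x$vc$sigma_g2, x$vc$sigma_e2))
  invisible(x)
}
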