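#' Simulate a heritable phenotype on a twin cohort
#'
#' Draws per-subject values `y = X beta + u`, where the random part `u` has
#' total variance `total_var` and within-pair covariance
#' `2 Phi * h2_true * total_var` (expected genetic sharing `2 Phi` is 1 for MZ
#' and 0.5 for DZ co-twins), i.e. the phenotypic covariance model
#' `Omega = 2 Phi sigma_g^2 + I sigma_e^2`. Under this model the expected twin
#' correlations are `r_MZ = h2` and `r_DZ = h2 / 2`.
#'
#' @param cohort A `twin_cohort` (see [generate_pedigree()]).
#' @param h2_true True narrow-sense heritability, in `[0, 1]`.
#' @param mean Population mean of the phenotype (intercept).
#' @param total_var Total phenotypic variance conditional on covariates (> 0).
#' @param covariate_effects Named numeric vector of effects for cohort columns
#'   (e.g. `c(age = -0.002, mean_fd = -0.1)`); `NULL` for none.
#' @param seed Integer seed.
#' @return Numeric vector of phenotype values, one per cohort row.
#' @examples
#' ped <- generate_pedigree(50, 50, seed = 1)
#' y <- generate_phenotype(ped, h2_true = 0.6, mean = 0, total_var = 1, seed = 2)
#' @export
generate_phenotype <- function(cohort, h2_true, mean = 0, total_var = 1,
                               covariate_effects = NULL, seed = 1) {
  validate_cohort(cohort)
  if (length(h2_true) != 1L || is.na(h2_true) || h2_true < 0 || h2_true > 1) {
    stop("h2_true must be in [0, 1]")
  }
  if (!is.numeric(total_var) || total_var <= 0) stop("total_var must be > 0")
  n <- nrow(cohort)
  sigma_g2 <- h2_true * total_var
  sigma_e2 <- (1 - h2_true) * total_var
  withr_seed(seed, {
    # genetic value with cov(g1, g2) = 2*phi*sigma_g2 within a pair
    fam <- match(cohort$family_id, unique(cohort$family_id))
    n_fam <- max(fam)
    zyg_fam <- cohort$zygosity[!duplicated(cohort$family_id)]
    g_shared <- stats::rnorm(n_fam)
    g_indiv <- stats::rnorm(n)
    share <- ifelse(zyg_fam == "MZ", 1, 0.5)[fam]
    g <- sqrt(sigma_g2) * (sqrt(share) * g_shared[fam] +
                             sqrt(1 - share) * g_indiv)
    e <- stats::rnorm(n, sd = sqrt(sigma_e2))
    y <- mean + g + e
    if (!is.null(covariate_effects) && length(covariate_effects)) {
      if (is.null(names(covariate_effects)) || any(names(covariate_effects) == "")) {
        stop("covariate_effects must be a named vector")
      }
      for (cv in names(covariate_effects)) {
        if (!cv %in% names(cohort)) stop("covariate not in cohort: ", cv)
        y <- y + covariate_effects[[cv]] * cohort[[cv]]
      }
    }
    y
  })
}
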