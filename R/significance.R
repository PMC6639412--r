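#' Family-block sign-flip permutation test for group-level connectivity
#'
#' One-sample location test of the mean Fisher-z per connection against zero,
#' honouring the twin-family dependence: the null distribution is built by
#' flipping the sign of all members of a family jointly (whole-block sign
#' flips), which preserves the within-family covariance while the null of no
#' connectivity makes the family blocks exchangeable in sign.
#'
#' @param z_by_subject Numeric subjects x connections matrix (one Fisher-z
#'   value per subject per connection); a vector is treated as one connection.
#' @param cohort A `twin_cohort` aligned with the rows of `z_by_subject`.
#' @param n_perm Number of sign-flip draws (default 10000).
#' @param seed Integer seed (mandatory).
#' @return Numeric vector of two-sided permutation p-values, one per
#'   connection; the smallest attainable p is `1/(n_perm + 1)`.
#' @export
block_permutation_test <- function(z_by_subject, cohort, n_perm = 10000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.vector(z_by_subject)) z_by_subject <- matrix(z_by_subject, ncol = 1)
  validate_cohort(cohort)
  if (nrow(z_by_subject) != nrow(cohort)) {
    stop("z_by_subject must have one row per cohort subject")
  }
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  fam <- match(cohort$family_id, unique(cohort$family_id))
  n_fam <- max(fam)
  n <- nrow(cohort)
  # per-family sums: flipping a family's sign flips its whole contribution
  fam_sums <- rowsum(z_by_subject, fam)
  obs <- abs(colSums(fam_sums)) / n
  withr_seed(seed, {
    exceed <- integer(ncol(z_by_subject))
    block <- 100L
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      signs <- matrix(sample(c(-1, 1), b * n_fam, replace = TRUE), b, n_fam)
      null_stats <- abs(signs %*% fam_sums) / n
      exceed <- exceed + colSums(null_stats >= rep(obs, each = b) - 1e-12)
      done <- done + b
    }
    (1 + exceed) / (n_perm + 1)
  })
}

#' Benjamini-Hochberg screening of connection p-values
#'
#' Step-up FDR adjustment; connections whose adjusted p-value exceeds `q`
#' are excluded from downstream heritability averaging.
#'
#' @param p_raw Vector of raw p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return A data frame with `p_raw`, `p_fdr` and logical `keep`
#'   (`p_fdr <= q`), preserving names of `p_raw`.
#' @export
bh_fdr <- function(p_raw, q = 0.05) {
  if (length(p_raw) == 0) stop("empty p-value vector")
  if (any(is.na(p_raw)) || any(p_raw <= 0) || any(p_raw > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  out <- data.frame(p_raw = p_raw, p_fdr = p_fdr, keep = p_fdr <= q)
  rownames(out) <- names(p_raw)
  out
}
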