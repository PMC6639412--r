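#' Kinship (2 Phi) matrix from a twin pedigree
#'
#' @param cohort A `twin_cohort`.
#' @return n x n matrix of expected genetic sharing `2 Phi`: 1 on the
#'   diagonal, 1 between MZ co-twins, 0.5 between DZ co-twins, 0 otherwise.
#' @export
kinship_from_pedigree <- function(cohort) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  K <- diag(n)
  dimnames(K) <- list(cohort$subject_id, cohort$subject_id)
  fam <- split(seq_len(n), cohort$family_id)
  for (idx in fam) {
    share <- if (cohort$zygosity[idx[1]] == "MZ") 1 else 0.5
    K[idx[1], idx[2]] <- K[idx[2], idx[1]] <- share
  }
  K
}

#' Rank-based inverse normal (Blom) transform
#'
#' Maps values to normal quantiles `qnorm((rank - 3/8) / (n + 1/4))`; ties
#' receive their average rank. Used on connectivity phenotypes prior to
#' variance-components fitting so the residual kurtosis stays in the normal
#' range.
#'
#' @param x Numeric vector, length >= 3, not all equal.
#' @return Transformed vector, order-isomorphic to `x`.
#' @export
inverse_normal <- function(x) {
  if (length(x) < 3) stop("need at least 3 values")
  if (length(unique(x)) == 1) stop("all values identical: ranks undefined")
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' AE variance-components heritability by maximum likelihood
#'
#' Fits the twin AE model with phenotypic covariance
#' `Omega = 2 Phi sigma_g^2 + I sigma_e^2` and simultaneous fixed covariate
#' effects, by maximizing the multivariate-normal log-likelihood
#' family-block-wise. Writing `h2 = sigma_g^2 / sigma_p^2`, the covariance is
#' `sigma_p^2 * W(h2)` with `W = (1 - h2) I + h2 * 2 Phi`; for fixed `h2`
#' both `beta` (GLS) and `sigma_p^2` have closed forms, leaving a
#' one-dimensional bounded profile likelihood in `h2` that is maximized
#' deterministically (coarse grid bracket + golden-section refinement).
#' Significance is the likelihood-ratio statistic `2(Le - L0)` against the
#' `sigma_g^2 = 0` model, referred to a 50:50 mixture of a point mass at zero
#' and a chi-square(1) distribution.
#'
#' @param y Numeric phenotype vector (one value per subject).
#' @param X Covariate design matrix (an intercept column is appended when
#'   absent); `NULL` for intercept only.
#' @param K Kinship matrix `2 Phi` as from [kinship_from_pedigree()]; twin
#'   pairs and singletons supported. For large cohorts pass `cohort`
#'   instead, which encodes the same pair structure without materializing
#'   the n x n matrix.
#' @param cohort Optional `twin_cohort` supplying the family blocks in
#'   place of `K`.
#' @param ci Compute a 95% profile-likelihood interval for `h2`?
#' @param tol Convergence tolerance on `h2` for the profile maximization.
#' @param p_zero_convention p-value at a zero LRT statistic: `"one"`
#'   (conservative, default) or `"half"`.
#' @return An object of class `ae_fit`: list with `h2`, `sigma_g2`,
#'   `sigma_e2`, `sigma_p2`, `beta`, `loglik_e`, `loglik_0`, `lrt_stat`,
#'   `p_mixture`, `converged`, and `ci` (when requested).
#' @examples
#' ped <- generate_pedigree(100, 60, seed = 1)
#' y <- generate_phenotype(ped, h2_true = 0.5, seed = 2)
#' fit <- fit_ae(y, K = kinship_from_pedigree(ped))
#' fit$h2
#' @export
fit_ae <- function(y, X = NULL, K = NULL, cohort = NULL, ci = FALSE,
                   tol = 1e-7, p_zero_convention = c("one", "half")) {
  p_zero_convention <- match.arg(p_zero_convention)
  n <- length(y)
  if (is.null(K) && is.null(cohort)) stop("supply K or cohort")
  if (!is.null(cohort)) {
    validate_cohort(cohort)
    if (nrow(cohort) != n) stop("cohort must have one row per value of y")
  } else if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
    stop("K must be an n x n kinship matrix matching y")
  }
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X must have one row per subject")
    if (!any(apply(X, 2, function(v) all(v == v[1]) && v[1] != 0))) {
      X <- cbind(`(Intercept)` = 1, X)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("X must be full rank")
  if (!is.null(cohort)) {
    # pair structure straight from the family blocks
    fam <- split(seq_len(n), cohort$family_id)
    i1 <- vapply(fam, `[`, integer(1), 1)
    i2 <- vapply(fam, `[`, integer(1), 2)
    phi2 <- ifelse(cohort$zygosity[i1] == "MZ", 1, 0.5)
    singles <- integer(0)
  } else {
    # pair structure from the off-diagonal of K (each subject in <= 1 pair)
    Koff <- K
    diag(Koff) <- 0
    up <- which(Koff > 0 & upper.tri(Koff), arr.ind = TRUE)
    deg <- tabulate(c(up[, 1], up[, 2]), nbins = n)
    if (any(deg > 1)) stop("kinship must encode twin pairs only (one relative max)")
    i1 <- up[, 1]; i2 <- up[, 2]
    phi2 <- Koff[up]
    singles <- setdiff(seq_len(n), c(i1, i2))
  }
  A <- X[i1, , drop = FALSE]; B <- X[i2, , drop = FALSE]
  yA <- y[i1]; yB <- y[i2]
  Xs <- X[singles, , drop = FALSE]; ys <- y[singles]
  XtXs <- crossprod(Xs); Xtys <- crossprod(Xs, ys); ss_s <- sum(ys^2)

  proflik <- function(h2) {
    kap <- phi2 * h2
    w <- 1 / (1 - kap^2)
    wk <- w * kap
    XtWX <- crossprod(A, A * w) + crossprod(B, B * w) -
      crossprod(A, B * wk) - crossprod(B, A * wk) + XtXs
    XtWy <- crossprod(A, w * yA) + crossprod(B, w * yB) -
      crossprod(A, wk * yB) - crossprod(B, wk * yA) + Xtys
    beta <- solve(XtWX, XtWy)
    rA <- yA - drop(A %*% beta); rB <- yB - drop(B %*% beta)
    rs <- ys - drop(Xs %*% beta)
    q <- sum(w * (rA^2 + rB^2) - 2 * wk * rA * rB) + sum(rs^2)
    logdet <- sum(log1p(-kap^2))
    sigma_p2 <- q / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma_p2) + logdet + n)
    list(ll = ll, beta = beta, sigma_p2 = sigma_p2)
  }
  ll_only <- function(h2) proflik(h2)$ll

  upper <- 1 - 1e-8
  grid <- c(seq(0, 0.95, by = 0.05), upper)
  gll <- vapply(grid, ll_only, numeric(1))
  best <- which.max(gll)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(ll_only, interval = c(lo, hi), maximum = TRUE,
                         tol = tol)
  h2_hat <- opt$maximum
  ll_hat <- opt$objective
  # snap to the boundary when it is at least as good
  for (b in c(0, upper)) {
    llb <- gll[match(b, grid)]
    if (llb >= ll_hat - 1e-10) { h2_hat <- b; ll_hat <- llb }
  }
  at <- proflik(h2_hat)
  ll0 <- ll_only(0)
  lrt <- max(0, 2 * (ll_hat - ll0))
  h2_rep <- if (h2_hat >= upper) 1 else h2_hat
  out <- list(
    h2 = h2_rep,
    sigma_g2 = h2_rep * at$sigma_p2,
    sigma_e2 = (1 - h2_rep) * at$sigma_p2,
    sigma_p2 = at$sigma_p2,
    beta = stats::setNames(drop(at$beta), colnames(X)),
    loglik_e = ll_hat,
    loglik_0 = ll0,
    lrt_stat = lrt,
    p_mixture = mixture_lrt_pvalue(lrt, zero_convention = p_zero_convention),
    converged = TRUE
  )
  if (ci) {
    thresh <- ll_hat - stats::qchisq(0.95, df = 1) / 2
    f <- function(h) ll_only(h) - thresh
    lo_ci <- if (f(0) >= 0) 0 else
      stats::uniroot(f, c(0, h2_hat), tol = 1e-6)$root
    hi_ci <- if (f(upper) >= 0) 1 else
      stats::uniroot(f, c(min(h2_hat, upper - 1e-9), upper), tol = 1e-6)$root
    out$ci <- c(lower = lo_ci, upper = hi_ci)
  }
  class(out) <- "ae_fit"
  out
}

#' @export
print.ae_fit <- function(x, ...) {
  cat(sprintf("AE variance-components fit: h2 = %.3f (sigma_g2 = %.4g, sigma_e2 = %.4g)\n",
              x$h2, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  LRT = %.3f, p (50:50 chi-square mixture) = %.4g\n",
              x$lrt_stat, x$p_mixture))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% profile CI: [%.3f, %.3f]\n", x$ci["lower"], x$ci["upper"]))
  }
  invisible(x)
}

#' p-value of the boundary likelihood-ratio statistic
#'
#' The LRT statistic for `sigma_g^2 = 0` is asymptotically a 50:50 mixture of
#' a point mass at zero and a chi-square with 1 df, so
#' `p = 0.5 * P(chi2_1 >= stat)` for positive statistics.
#'
#' @param lrt_stat Non-negative LRT statistic.
#' @param zero_convention p-value returned at `stat = 0`: `"one"`
#'   (the observation sits in the boundary point mass; conservative,
#'   default) or `"half"`.
#' @return p-value in (0, 1].
#' @export
mixture_lrt_pvalue <- function(lrt_stat, zero_convention = c("one", "half")) {
  zero_convention <- match.arg(zero_convention)
  if (is.na(lrt_stat)) stop("lrt_stat must be a number")
  if (lrt_stat < -1e-8) stop("negative LRT statistic")
  lrt_stat <- max(0, lrt_stat)
  if (lrt_stat == 0) {
    return(if (zero_convention == "one") 1 else 0.5)
  }
  0.5 * stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)
}

#' Heritability of many phenotypes at once
#'
#' Applies the inverse normal transform (optional) and [fit_ae()] to every
#' column of a phenotype matrix.
#'
#' @param pheno Subjects x phenotypes numeric matrix.
#' @param cohort A `twin_cohort` aligned with the rows.
#' @param covariates Cohort columns used as fixed covariates.
#' @param inverse_normalize Apply [inverse_normal()] per phenotype first?
#' @return Data frame with one row per phenotype: `phenotype_id`, `h2`,
#'   `sigma_g2`, `sigma_e2`, `lrt_stat`, `p`.
#' @export
heritability_table <- function(pheno, cohort,
                               covariates = c("age", "sex", "mean_fd",
                                              "recon_version"),
                               inverse_normalize = TRUE) {
  validate_cohort(cohort)
  pheno <- as.matrix(pheno)
  if (nrow(pheno) != nrow(cohort)) stop("pheno rows must match cohort")
  X <- cohort_design(cohort, covariates)
  res <- lapply(seq_len(ncol(pheno)), function(j) {
    yj <- pheno[, j]
    if (inverse_normalize) yj <- inverse_normal(yj)
    fit <- fit_ae(yj, X = X[, -1, drop = FALSE], cohort = cohort)
    data.frame(phenotype_id = colnames(pheno)[j] %||% as.character(j),
               h2 = fit$h2, sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
               lrt_stat = fit$lrt_stat, p = fit$p_mixture,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
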