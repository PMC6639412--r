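#' Intraclass correlation ICC(3,1) between two session days
#'
#' Two-way mixed-effects, single-rater, consistency form:
#' `(BMS - EMS) / (BMS + (k - 1) EMS)` with `k = 2` sessions, where BMS and
#' EMS are the between-subject and residual mean squares of the two-way
#' (subject x session) ANOVA. Consistency ICC is invariant to a constant
#' offset between the days.
#'
#' @param day1,day2 Equal-length numeric vectors (length >= 3), paired by
#'   subject.
#' @return The ICC(3,1) value (<= 1).
#' @export
icc_3_1 <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("day1 and day2 must be paired")
  n <- length(day1)
  if (n < 3) stop("need at least 3 subjects")
  k <- 2
  Y <- cbind(day1, day2)
  subj_means <- rowMeans(Y)
  sess_means <- colMeans(Y)
  grand <- mean(Y)
  if (stats::var(subj_means) == 0) stop("zero between-subject variance")
  bms <- k * sum((subj_means - grand)^2) / (n - 1)
  jms <- n * sum((sess_means - grand)^2) / (k - 1)
  sse <- sum((Y - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), sess_means) + grand)^2)
  ems <- sse / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

#' ICC(3,1) for every connection and its per-area average
#'
#' @param z_day1,z_day2 Subjects x connections Fisher-z matrices for session
#'   day 1 (runs 1-2) and day 2 (runs 3-4).
#' @param keep Optional logical vector over connections (the FDR screen);
#'   area averages use kept connections only.
#' @return List with `icc` (named vector per connection) and `area_icc`
#'   (data frame `area`, `mean_icc`, `n_connections`).
#' @export
icc_table <- function(z_day1, z_day2, keep = NULL) {
  stopifnot(identical(dim(z_day1), dim(z_day2)))
  ids <- colnames(z_day1)
  icc <- vapply(seq_along(ids), function(j) icc_3_1(z_day1[, j], z_day2[, j]),
                numeric(1))
  names(icc) <- ids
  if (is.null(keep)) keep <- rep(TRUE, length(ids))
  prof <- area_profile(icc, keep = keep)
  list(icc = icc,
       area_icc = data.frame(area = prof$area, mean_icc = prof$mean,
                             n_connections = prof$n, stringsAsFactors = FALSE))
}

#' Mantel test between two symmetric area x area matrices
#'
#' Statistic: squared Pearson correlation (R^2) of the vectorized
#' lower-triangle entries, restricted to positions where both matrices are
#' defined (masked entries are `NA`, e.g. connections dropped by the FDR
#' screen). The null is built by jointly permuting the rows and columns of
#' `m2` (its `NA` pattern travels with it); `p = (1 + #{R2_null >= R2_obs}) /
#' (n_perm + 1)`.
#'
#' @param m1,m2 Symmetric numeric matrices over the same areas; diagonals
#'   are ignored.
#' @param n_perm Number of label permutations (default 5000).
#' @param seed Integer seed.
#' @return List with `r2` and `p`.
#' @export
mantel_test <- function(m1, m2, n_perm = 5000, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!all(dim(m1) == dim(m2))) stop("matrices must share dimensions")
  R <- nrow(m1)
  if (R < 3) stop("need at least 3 areas")
  lower <- lower.tri(m1)
  r2_of <- function(a, b) {
    va <- a[lower]; vb <- b[lower]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(va[ok], vb[ok])^2
  }
  obs <- r2_of(m1, m2)
  if (is.na(obs)) stop("fewer than 3 jointly defined entries")
  withr_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(R)
      r2p <- r2_of(m1, m2[idx, idx])
      if (!is.na(r2p) && r2p >= obs - 1e-12) exceed <- exceed + 1L
    }
    list(r2 = obs, p = (1 + exceed) / (n_perm + 1))
  })
}

#' Assemble a symmetric area x area matrix from per-connection values
#'
#' @param values Named vector over `"A|B"` connection ids.
#' @param areas Area labels defining matrix order.
#' @param keep Optional logical mask over the same ids; dropped connections
#'   become `NA`.
#' @return Symmetric matrix with `NA` diagonal.
#' @export
connection_matrix <- function(values, areas, keep = NULL) {
  M <- matrix(NA_real_, length(areas), length(areas),
              dimnames = list(areas, areas))
  ep <- connection_endpoints(names(values))
  vals <- values
  if (!is.null(keep)) vals[!keep] <- NA_real_
  M[cbind(ep[, 1], ep[, 2])] <- vals
  M[cbind(ep[, 2], ep[, 1])] <- vals
  M
}
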