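#' Regress nuisance signals out of ROI time series
#'
#' Ordinary least-squares projection of each ROI column onto the orthogonal
#' complement of the nuisance column space (motion realignment parameters and
#' their derivatives, plus an intercept added if absent). Rank-deficient
#' nuisance columns are dropped with a warning.
#'
#' @param series Numeric T x R matrix of ROI time series.
#' @param nuisance Numeric T x C matrix of nuisance regressors; an intercept
#'   column is appended when none is present.
#' @return T x R matrix of residuals, orthogonal to the retained nuisance
#'   columns.
#' @export
regress_nuisance <- function(series, nuisance = NULL) {
  series <- as.matrix(series)
  T_ <- nrow(series)
  if (is.null(nuisance)) {
    nuisance <- matrix(1, T_, 1)
  } else {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != T_) stop("series and nuisance must have equal rows")
    has_intercept <- any(apply(nuisance, 2, function(x) stats::sd(x) == 0 && x[1] != 0))
    if (!has_intercept) nuisance <- cbind(1, nuisance)
  }
  if (T_ <= ncol(nuisance) + 2) stop("too few time points for the nuisance model")
  qrX <- qr(nuisance)
  if (qrX$rank < ncol(nuisance)) {
    warning(sprintf("nuisance matrix rank-deficient: dropped %d column(s)",
                    ncol(nuisance) - qrX$rank))
  }
  series - qr.fitted(qrX, series)
}

#' Fisher r-to-z connectivity matrix from residual time series
#'
#' Concatenates per-run residuals and computes the Fisher z-transformed
#' (`atanh`) Pearson correlation between every pair of ROI columns.
#'
#' @param residuals Either a single T x R residual matrix or a list of
#'   per-run residual matrices (concatenated row-wise; each run is assumed
#'   already nuisance-regressed and hence demeaned).
#' @return Symmetric R x R matrix of Fisher-z values with `NA` diagonal,
#'   classed `conn_matrix`.
#' @export
fisher_z_matrix <- function(residuals) {
  if (is.list(residuals)) residuals <- do.call(rbind, residuals)
  residuals <- as.matrix(residuals)
  if (nrow(residuals) <= ncol(residuals)) {
    stop("need more total time points than areas")
  }
  sds <- apply(residuals, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(residuals)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(residuals)
  off <- abs(r) >= 1 - 1e-12
  diag(off) <- FALSE
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("|r| = 1 between '%s' and '%s': Fisher z undefined",
                 colnames(r)[ij[1]], colnames(r)[ij[2]]))
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  class(z) <- c("conn_matrix", class(z))
  z
}

#' Per-subject connectivity tables from simulated or loaded time series
#'
#' For each subject: per-run nuisance regression (motion parameters), then
#' Fisher-z correlation over the concatenated residuals, for the full scan
#' (`all`), session day 1 (runs 1-2) and session day 2 (runs 3-4).
#'
#' @param ts A list as returned by [generate_timeseries()] (`series`,
#'   `motion`, `areas`), or an equivalent structure loaded from TSVs.
#' @param regress_per_run Regress nuisance within each run before
#'   concatenation (default `TRUE`); otherwise on the concatenated data.
#' @param sessions Which session aggregates to compute.
#' @return A list of subjects x connections Fisher-z matrices, one per
#'   session, with columns named by [connection_ids()].
#' @export
connectivity_tables <- function(ts, regress_per_run = TRUE,
                                sessions = c("all", "day1", "day2")) {
  sessions <- match.arg(sessions, several.ok = TRUE)
  areas <- ts$areas
  ids <- connection_ids(areas)
  subjects <- names(ts$series)
  n_runs <- length(ts$series[[1]])
  run_sets <- list(all = seq_len(n_runs),
                   day1 = seq_len(min(2L, n_runs)),
                   day2 = if (n_runs >= 3) 3:min(4L, n_runs) else integer(0))
  out <- lapply(sessions, function(s) {
    matrix(NA_real_, length(subjects), length(ids),
           dimnames = list(subjects, ids))
  })
  names(out) <- sessions
  for (subj in subjects) {
    runs <- ts$series[[subj]]
    mots <- ts$motion[[subj]]
    resid_runs <- if (regress_per_run) {
      lapply(seq_along(runs), function(k) regress_nuisance(runs[[k]], mots[[k]]))
    } else NULL
    for (s in sessions) {
      rs <- run_sets[[s]]
      if (!length(rs)) stop("session ", s, " has no runs")
      resid <- if (regress_per_run) {
        do.call(rbind, resid_runs[rs])
      } else {
        regress_nuisance(do.call(rbind, runs[rs]), do.call(rbind, mots[rs]))
      }
      z <- fisher_z_matrix(resid)
      out[[s]][subj, ] <- z[lower.tri(z)][match_lower(areas, ids)]
    }
  }
  out
}

# index mapping so that lower-triangle vectorization (column-major) lines up
# with connection_ids order
match_lower <- function(areas, ids) {
  R <- length(areas)
  lt <- which(lower.tri(diag(R)), arr.ind = TRUE)
  lt_ids <- paste(areas[lt[, 2]], areas[lt[, 1]], sep = "|")
  match(ids, lt_ids)
}

#' Long-format connectivity table
#'
#' @param z_mat Subjects x connections matrix of Fisher-z values.
#' @param session Session label to attach.
#' @return Data frame `subject_id`, `session`, `area_a`, `area_b`, `z`.
#' @export
connectivity_long <- function(z_mat, session = "all") {
  ep <- connection_endpoints(colnames(z_mat))
  data.frame(
    subject_id = rep(rownames(z_mat), times = ncol(z_mat)),
    session = session,
    area_a = rep(ep[, 1], each = nrow(z_mat)),
    area_b = rep(ep[, 2], each = nrow(z_mat)),
    z = as.vector(z_mat),
    stringsAsFactors = FALSE
  )
}
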