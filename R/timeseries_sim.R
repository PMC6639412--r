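#' Simulate ROI time series with a target connectivity structure
#'
#' For each subject and run, draws a multivariate Gaussian series whose
#' population correlation matrix is the nearest positive-definite matrix to
#' `tanh(subject_z)` (eigenvalue clipping repair), plus 12 motion-regressor
#' columns (6 "realignment parameters" of smoothed noise and their backward
#' differences) whose amplitude scales with the subject's mean framewise
#' displacement. The empirical Fisher z of a generated series converges to
#' the target as the number of time points grows (sampling variance
#' `1/(T-3)` per run).
#'
#' @param cohort A `twin_cohort`.
#' @param subject_z Numeric matrix, subjects x connections, of target Fisher-z
#'   values; connection columns must be named `"A|B"` over the `areas` labels
#'   (see [connection_ids()]).
#' @param areas Character vector of area labels (defines column order).
#' @param n_timepoints Time points per run (T).
#' @param n_runs Number of runs per subject (default 4, split into session
#'   days 1-2 and 3-4 downstream).
#' @param seed Integer seed.
#' @param pd_tol Maximum admissible Frobenius distance between the target
#'   correlation matrix and its positive-definite repair, relative to the
#'   Frobenius norm of the target; beyond it the offending subject's
#'   connections are flagged as non-embeddable.
#' @return A list with `series` (list by subject of lists by run of T x R
#'   matrices), `motion` (same shape, T x 12 matrices), `areas`, and
#'   `flagged` (data frame of subjects whose target matrix needed a repair
#'   beyond `pd_tol`; empty when all targets embed).
#' @export
generate_timeseries <- function(cohort, subject_z, areas, n_timepoints = 1200,
                                n_runs = 4, seed = 1, pd_tol = 0.1) {
  validate_cohort(cohort)
  R <- length(areas)
  if (n_timepoints < 10 * R) stop("n_timepoints must be at least 10 * n_areas")
  ids <- connection_ids(areas)
  if (!all(ids %in% colnames(subject_z))) stop("subject_z must have one column per area pair")
  if (nrow(subject_z) != nrow(cohort)) stop("subject_z must have one row per subject")
  if (any(!is.finite(subject_z))) stop("subject_z must be finite (|r| < 1)")
  withr_seed(seed, {
    series <- vector("list", nrow(cohort))
    motion <- vector("list", nrow(cohort))
    names(series) <- names(motion) <- cohort$subject_id
    flagged <- list()
    for (s in seq_len(nrow(cohort))) {
      C <- diag(R)
      dimnames(C) <- list(areas, areas)
      C[lower.tri(C)] <- tanh(subject_z[s, ids])
      C <- C + t(C) - diag(R)
      rep_out <- nearest_pd_correlation(C)
      if (rep_out$rel_dist > pd_tol) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          subject_id = cohort$subject_id[s], rel_frobenius = rep_out$rel_dist)
      }
      L <- chol(rep_out$mat)
      series[[s]] <- lapply(seq_len(n_runs), function(run) {
        x <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R) %*% L
        colnames(x) <- areas
        x
      })
      motion[[s]] <- lapply(seq_len(n_runs), function(run) {
        simulate_motion(n_timepoints, cohort$mean_fd[s])
      })
    }
    flagged <- if (length(flagged)) do.call(rbind, flagged) else
      data.frame(subject_id = character(), rel_frobenius = numeric())
    if (nrow(flagged)) {
      warning(sprintf("%d subject(s) had non-embeddable target correlations (flagged)",
                      nrow(flagged)))
    }
    list(series = series, motion = motion, areas = areas, flagged = flagged)
  })
}

# 6 smoothed-noise realignment parameters + their backward differences.
# Amplitude proportional to mean framewise displacement.
simulate_motion <- function(n_timepoints, mean_fd) {
  raw <- matrix(stats::rnorm(n_timepoints * 6), n_timepoints, 6)
  sm <- apply(raw, 2, function(x) stats::filter(x, rep(1 / 10, 10), sides = 1))
  sm[is.na(sm)] <- 0
  params <- mean_fd * sm
  derivs <- rbind(0, diff(params))
  out <- cbind(params, derivs)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_d"))
  out
}

#' Nearest positive-definite correlation matrix by eigenvalue clipping
#'
#' Clips eigenvalues at a floor and rescales to unit diagonal; reports the
#' relative Frobenius distance of the repair.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @param eig_floor Eigenvalue floor (default 1e-6).
#' @return List with `mat` (repaired correlation matrix) and `rel_dist`
#'   (Frobenius distance of the repair relative to `||C||_F`).
#' @export
nearest_pd_correlation <- function(C, eig_floor = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(list(mat = C, rel_dist = 0))
  v <- pmax(e$values, eig_floor)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(C)
  list(mat = M, rel_dist = norm(M - C, "F") / max(norm(C, "F"), .Machine$double.eps))
}

#' Canonical connection identifiers for a set of areas
#'
#' @param areas Character vector of area labels.
#' @return Character vector `"A|B"` for every unordered area pair, with `A`
#'   before `B` in the order given by `areas`.
#' @export
connection_ids <- function(areas) {
  if (length(areas) < 2) stop("need at least 2 areas")
  idx <- utils::combn(length(areas), 2)
  paste(areas[idx[1, ]], areas[idx[2, ]], sep = "|")
}

#' Write simulated time series and motion regressors as TSVs
#'
#' One `<subject>_run<k>_ts.tsv` (T rows, one named column per area) and one
#' `<subject>_run<k>_motion.tsv` (T rows, 12 motion columns) per subject and
#' run.
#'
#' @param ts A list from [generate_timeseries()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_timeseries_tsvs <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subj in names(ts$series)) {
    for (k in seq_along(ts$series[[subj]])) {
      utils::write.table(ts$series[[subj]][[k]],
                         file.path(dir, sprintf("%s_run%d_ts.tsv", subj, k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ts$motion[[subj]][[k]],
                         file.path(dir, sprintf("%s_run%d_motion.tsv", subj, k)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_timeseries_tsvs
#' @param subjects Subject identifiers to load.
#' @param n_runs Runs per subject.
#' @export
read_timeseries_tsvs <- function(dir, subjects, n_runs = 4) {
  series <- motion <- stats::setNames(vector("list", length(subjects)),
                                      subjects)
  for (subj in subjects) {
    series[[subj]] <- lapply(seq_len(n_runs), function(k)
      as.matrix(utils::read.delim(
        file.path(dir, sprintf("%s_run%d_ts.tsv", subj, k)))))
    motion[[subj]] <- lapply(seq_len(n_runs), function(k)
      as.matrix(utils::read.delim(
        file.path(dir, sprintf("%s_run%d_motion.tsv", subj, k)))))
  }
  areas <- colnames(series[[1]][[1]])
  list(series = series, motion = motion, areas = areas)
}

# split "A|B" ids into a 2-column matrix of endpoint labels
connection_endpoints <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed connection id")
  matrix(unlist(parts), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("area_a", "area_b")))
}
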