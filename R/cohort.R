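#' Generate a synthetic twin cohort pedigree
#'
#' Creates a cohort of monozygotic (MZ) and dizygotic (DZ) twin pairs with the
#' covariates used throughout the pipeline: age (identical within a pair,
#' uniform over 22--36 years), sex (shared within MZ pairs, independent within
#' DZ pairs), mean framewise displacement (log-normal, independent across
#' co-twins) and MR reconstruction software version (shared within a pair).
#'
#' @param n_mz Number of monozygotic twin pairs (non-negative integer).
#' @param n_dz Number of dizygotic twin pairs (non-negative integer).
#' @param seed Integer seed; the cohort is reproducible for a fixed seed.
#' @return A `twin_cohort` data frame with one row per subject and columns
#'   `subject_id`, `family_id`, `zygosity` (`"MZ"`/`"DZ"`), `age` (years),
#'   `sex` (0/1), `mean_fd` (mm), `recon_version` (0/1).
#' @examples
#' ped <- generate_pedigree(123, 67, seed = 1)
#' nrow(ped)                 # 380 subjects
#' length(unique(ped$family_id))  # 190 families
#' @export
generate_pedigree <- function(n_mz, n_dz, seed) {
  if (length(n_mz) != 1L || length(n_dz) != 1L || is.na(n_mz) || is.na(n_dz) ||
      n_mz < 0 || n_dz < 0 || n_mz != round(n_mz) || n_dz != round(n_dz)) {
    stop("n_mz and n_dz must be single non-negative integers")
  }
  if (n_mz + n_dz == 0) stop("at least one twin pair is required")
  n_fam <- as.integer(n_mz + n_dz)
  withr_seed(seed, {
    zyg_fam <- rep(c("MZ", "DZ"), times = c(n_mz, n_dz))
    age_fam <- stats::runif(n_fam, 22, 36)
    recon_fam <- stats::rbinom(n_fam, 1L, 0.5)
    sex_fam1 <- stats::rbinom(n_fam, 1L, 0.5)
    # MZ co-twins share sex; DZ co-twins draw independently
    sex_fam2 <- ifelse(zyg_fam == "MZ", sex_fam1, stats::rbinom(n_fam, 1L, 0.5))
    mean_fd <- stats::rlnorm(2L * n_fam, meanlog = log(0.12), sdlog = 0.35)
    fam_id <- sprintf("F%04d", seq_len(n_fam))
    cohort <- data.frame(
      subject_id = sprintf("S%04d", seq_len(2L * n_fam)),
      family_id = rep(fam_id, each = 2L),
      zygosity = rep(zyg_fam, each = 2L),
      age = round(rep(age_fam, each = 2L), 1),
      sex = as.integer(rbind(sex_fam1, sex_fam2)),
      mean_fd = mean_fd,
      recon_version = rep(recon_fam, each = 2L),
      stringsAsFactors = FALSE
    )
    class(cohort) <- c("twin_cohort", "data.frame")
    validate_cohort(cohort)
  })
}

#' Validate a twin cohort table
#'
#' Checks the structural invariants required downstream: exactly two members
#' per family, constant zygosity within a family, unique subject identifiers,
#' and strictly positive mean framewise displacement.
#'
#' @param cohort A data frame with the `twin_cohort` columns.
#' @return The validated cohort, invisibly classed as `twin_cohort`.
#' @export
validate_cohort <- function(cohort) {
  req <- c("subject_id", "family_id", "zygosity", "age", "sex", "mean_fd",
           "recon_version")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$subject_id)) stop("duplicate subject_id in cohort")
  sizes <- table(cohort$family_id)
  if (any(sizes != 2L)) {
    bad <- names(sizes)[sizes != 2L]
    stop("every family must have exactly 2 members; offending: ",
         paste(bad, collapse = ", "))
  }
  if (!all(cohort$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  zyg_per_fam <- tapply(cohort$zygosity, cohort$family_id,
                        function(z) length(unique(z)))
  if (any(zyg_per_fam != 1L)) stop("zygosity must be constant within a family")
  if (any(!is.finite(cohort$mean_fd)) || any(cohort$mean_fd <= 0)) {
    stop("mean_fd must be finite and > 0")
  }
  if (!inherits(cohort, "twin_cohort")) {
    class(cohort) <- c("twin_cohort", class(cohort))
  }
  invisible(cohort)
}

#' @export
print.twin_cohort <- function(x, ...) {
  n_fam <- length(unique(x$family_id))
  n_mz <- sum(x$zygosity == "MZ") / 2
  cat(sprintf("Twin cohort: %d subjects, %d families (%d MZ, %d DZ pairs)\n",
              nrow(x), n_fam, n_mz, n_fam - n_mz))
  NextMethod()
}

# Run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Design matrix of standard connectivity covariates (with intercept)
cohort_design <- function(cohort,
                          covariates = c("age", "sex", "mean_fd", "recon_version")) {
  X <- cbind(`(Intercept)` = rep(1, nrow(cohort)))
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort: ", cv)
    X <- cbind(X, cohort[[cv]])
    colnames(X)[ncol(X)] <- cv
  }
  X
}
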