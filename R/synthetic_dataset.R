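#' Default ground-truth parameters of the synthetic study conditions
#'
#' The generative two-component curve is non-monotonic with its maximum in
#' the lower third of the level range (near level 3 of 10), rising
#' significantly over early visual cortex and declining thereafter, and
#' stays within (0, h_max) over the whole hierarchy; connection mean Fisher-z decays with graph distance between the
#' endpoint areas; day-to-day reliability follows a saturating profile tied
#' to the short-term component; anatomical heritability declines linearly
#' with level. Values are stated (and motivated) in the methods vignette.
#'
#' @return Named list of generative parameters.
#' @export
default_truth <- function() {
  list(
    h_max = 0.5, a1 = 0.3, b1 = 1.2, a2 = 0.005, b2 = 0.4,
    total_var = 0.03,
    z_base = 0.4, z_decay = 0.2, z_floor = 0.05,
    covariate_effects = c(age = -0.002, sex = 0.02, mean_fd = -0.10,
                          recon_version = 0.01),
    icc_asymptote = 0.8, icc_drop = 0.25, icc_rate = 0.8,
    anat = list(
      thickness = list(h2_0 = 0.60, slope = 0.040, mean = 2.5, var = 0.04),
      volume    = list(h2_0 = 0.65, slope = 0.045, mean = 1.0, var = 0.04)
    ),
    anat_covariate_effects = c(age = -0.005, sex = 0.10),
    h2_clamp = c(0.01, 0.99)
  )
}

#' Generate per-subject connectivity phenotypes with known ground truth
#'
#' Builds, for every connection of the area graph, a per-subject Fisher-z
#' phenotype whose heritability is the mean of the two-component curve
#' evaluated at the hierarchical levels of the connection's endpoints
#' (so a noiseless per-area average is an affine function of the curve
#' at that area's own level), whose
#' population mean decays with the graph distance between the endpoints, and
#' whose two session-day replicates scatter around the subject value with a
#' day-to-day ICC following the target reliability profile (the day average
#' equals the subject value exactly, so the generative heritability curve is
#' preserved).
#'
#' @param cohort A `twin_cohort`.
#' @param graph An `area_graph`.
#' @param levels Named hierarchical levels covering the graph's areas (see
#'   [hierarchy_levels_multi()]).
#' @param truth Ground-truth parameter list (see [default_truth()]).
#' @param seed Integer seed.
#' @param h2_profile Optional function mapping an area's hierarchical level
#'   to its heritability contribution, overriding the two-component curve
#'   (e.g. a linear profile for null-calibration studies); a connection's
#'   heritability is the mean of its two endpoint values.
#' @return List with matrices `z_all`, `z_day1`, `z_day2` (subjects x
#'   connections) and a `truth` data frame per connection (`h2_true`,
#'   `z_mean`, `icc_true`, `eta_bar`).
#' @export
generate_connectivity_dataset <- function(cohort, graph, levels,
                                          truth = default_truth(), seed = 1,
                                          h2_profile = NULL) {
  validate_cohort(cohort)
  areas <- graph$areas
  if (!all(areas %in% names(levels))) stop("levels must cover all graph areas")
  ids <- connection_ids(areas)
  ep <- connection_endpoints(ids)
  D <- igraph::distances(graph$graph)
  eta_bar <- (levels[ep[, 1]] + levels[ep[, 2]]) / 2
  gdist <- D[cbind(ep[, 1], ep[, 2])]
  f <- if (is.null(h2_profile)) {
    function(e) two_component_curve(e, truth$a1, truth$b1, truth$a2,
                                    truth$b2, truth$h_max)
  } else h2_profile
  # each endpoint contributes its level-specific genetic determination;
  # a connection's heritability is the mean of the two endpoint values,
  # so an area's mean over its connections stays affine in its own value
  h2_raw <- (f(levels[ep[, 1]]) + f(levels[ep[, 2]])) / 2
  h2_conn <- pmin(pmax(h2_raw, truth$h2_clamp[1]), truth$h2_clamp[2])
  z_mean <- truth$z_base * exp(-truth$z_decay * gdist) + truth$z_floor
  icc_true <- truth$icc_asymptote - truth$icc_drop * exp(-truth$icc_rate * eta_bar)
  n <- nrow(cohort)
  withr_seed(seed, {
    conn_seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
    day_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  })
  z_all <- matrix(NA_real_, n, length(ids),
                  dimnames = list(cohort$subject_id, ids))
  for (j in seq_along(ids)) {
    z_all[, j] <- generate_phenotype(
      cohort, h2_true = h2_conn[j], mean = z_mean[j],
      total_var = truth$total_var,
      covariate_effects = truth$covariate_effects, seed = conn_seeds[j])
  }
  # day replicates: day1 = z + u, day2 = z - u with var(u) chosen so the
  # day-to-day correlation of the latent part matches the target ICC
  withr_seed(day_seed, {
    var_u <- truth$total_var * (1 - icc_true) / (1 + icc_true)
    U <- matrix(stats::rnorm(n * length(ids)), n, length(ids)) *
      rep(sqrt(var_u), each = n)
    z_day1 <- z_all + U
    z_day2 <- z_all - U
  })
  dimnames(z_day1) <- dimnames(z_day2) <- dimnames(z_all)
  list(z_all = z_all, z_day1 = z_day1, z_day2 = z_day2,
       truth = data.frame(connection = ids, h2_true = unname(h2_conn),
                          z_mean = unname(z_mean), icc_true = unname(icc_true),
                          eta_bar = unname(eta_bar),
                          stringsAsFactors = FALSE))
}

#' Generate per-area anatomical phenotypes with declining heritability
#'
#' Cortical-thickness- and gray-matter-volume-like per-area scalars whose
#' true heritability decreases linearly with hierarchical level (floored at
#' 0.05), with age and sex covariate effects.
#'
#' @param cohort A `twin_cohort`.
#' @param levels Named hierarchical levels per area.
#' @param truth Ground-truth parameter list.
#' @param seed Integer seed.
#' @return List of subjects x areas matrices (`thickness`, `volume`) plus a
#'   `truth` data frame (`area`, `h2_thickness`, `h2_volume`).
#' @export
generate_anatomy_dataset <- function(cohort, levels, truth = default_truth(),
                                     seed = 1) {
  validate_cohort(cohort)
  areas <- names(levels)
  n <- nrow(cohort)
  withr_seed(seed, {
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * length(areas)),
                    ncol = 2)
  })
  out <- list()
  h2s <- list()
  for (ph in c("thickness", "volume")) {
    pars <- truth$anat[[ph]]
    h2 <- pmax(pars$h2_0 - pars$slope * as.numeric(levels), 0.05)
    M <- matrix(NA_real_, n, length(areas),
                dimnames = list(cohort$subject_id, areas))
    col <- if (ph == "thickness") 1 else 2
    for (j in seq_along(areas)) {
      M[, j] <- generate_phenotype(cohort, h2_true = h2[j], mean = pars$mean,
                                   total_var = pars$var,
                                   covariate_effects = truth$anat_covariate_effects,
                                   seed = seeds[j, col])
    }
    out[[ph]] <- M
    h2s[[ph]] <- h2
  }
  out$truth <- data.frame(area = areas, h2_thickness = h2s$thickness,
                          h2_volume = h2s$volume, stringsAsFactors = FALSE)
  out
}
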