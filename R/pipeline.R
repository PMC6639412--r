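#' Full gradient analysis of per-subject connectivity tables
#'
#' Runs the downstream stages on subjects x connections Fisher-z matrices:
#' family-block permutation screening with BH-FDR, covariate-adjusted AE
#' heritability per kept connection, per-connection ICC(3,1) across session
#' days with the heritability-vs-ICC Mantel control, per-area averaging,
#' linear and quadratic level regressions with the nested F comparison, the
#' early-visual slope test, and the two-component plasticity fit.
#'
#' @param z_all Subjects x connections Fisher-z matrix (full scan).
#' @param cohort A `twin_cohort` aligned with the rows.
#' @param graph An `area_graph` covering the connection endpoints.
#' @param roots Root areas (one per hemisphere/component) for hierarchical
#'   levels.
#' @param z_day1,z_day2 Optional session-day matrices for reliability.
#' @param q_fdr FDR level of the connection screen.
#' @param n_perm Sign-flip draws for the screen.
#' @param n_perm_mantel Permutations of the Mantel control test.
#' @param covariates Cohort columns used as heritability covariates.
#' @param h_max Ceiling of the two-component model.
#' @param level_offset Offset added to hierarchical levels.
#' @param loss Robust loss of the two-component fit.
#' @param seed Integer seed governing both permutation tests.
#' @return List of class `connherit_result` with elements `screen`,
#'   `heritability`, `levels`, `profile` (heritability per area), `fit_lin`,
#'   `fit_quad`, `nested`, `early_slope`, `two_component`, and when day
#'   matrices are given `icc`, `area_icc`, `mantel`, `icc_profile`,
#'   `icc_slope`, `component_icc`.
#' @export
analyze_connectivity <- function(z_all, cohort, graph, roots,
                                 z_day1 = NULL, z_day2 = NULL,
                                 q_fdr = 0.05, n_perm = 10000,
                                 n_perm_mantel = 5000,
                                 covariates = c("age", "sex", "mean_fd",
                                                "recon_version"),
                                 h_max = 0.5, level_offset = 0L,
                                 loss = "soft_l1", seed) {
  if (missing(seed)) stop("seed is mandatory")
  validate_cohort(cohort)
  levels <- hierarchy_levels_multi(graph, roots, level_offset = level_offset)
  p_raw <- block_permutation_test(z_all, cohort, n_perm = n_perm, seed = seed)
  names(p_raw) <- colnames(z_all)
  screen <- bh_fdr(p_raw, q = q_fdr)
  keep <- screen$keep
  herit <- heritability_table(z_all[, keep, drop = FALSE], cohort,
                              covariates = covariates)
  h2_by_conn <- stats::setNames(rep(NA_real_, ncol(z_all)), colnames(z_all))
  h2_by_conn[herit$phenotype_id] <- herit$h2
  profile <- area_profile(h2_by_conn, keep = keep, levels = levels)
  fit_lin <- fit_polynomial(profile, 1)
  fit_quad <- fit_polynomial(profile, 2)
  out <- list(
    screen = screen,
    heritability = herit,
    levels = levels,
    profile = profile,
    fit_lin = fit_lin,
    fit_quad = fit_quad,
    nested = nested_f_test(fit_lin, fit_quad),
    early_slope = try_or_null(early_visual_slope(profile)),
    two_component = fit_two_component(profile, h_max = h_max, loss = loss)
  )
  if (!is.null(z_day1) && !is.null(z_day2)) {
    rel <- icc_table(z_day1, z_day2, keep = keep)
    h2_mat <- connection_matrix(h2_by_conn, graph$areas, keep = keep)
    icc_mat <- connection_matrix(rel$icc, graph$areas, keep = keep)
    out$icc <- rel$icc
    out$area_icc <- rel$area_icc
    out$mantel <- mantel_test(h2_mat, icc_mat, n_perm = n_perm_mantel,
                              seed = seed + 1L)
    icc_profile <- area_profile(rel$icc, keep = keep, levels = levels)
    out$icc_profile <- icc_profile
    icc_lin <- fit_polynomial(icc_profile, 1)
    out$icc_slope <- list(t = icc_lin$slope_t, df = icc_lin$slope_df,
                          p = icc_lin$slope_p)
    if (isTRUE(out$two_component$converged)) {
      out$component_icc <- compare_components(icc_profile, out$two_component)
    }
  }
  class(out) <- "connherit_result"
  out
}

#' Short- versus long-term component comparison for a target profile
#'
#' Fits the intercept-only short- and long-component models
#' ([component_intercept_fit()]) to a target area profile and compares them
#' by Akaike weight.
#'
#' @param target An `area_profile` with `eta`.
#' @param fixed A converged two-component fit of the heritability profile.
#' @return List with `short`, `long` (each with `beta`, `aic`), `weights`
#'   (named: short, long) and `rel_likelihood_short_vs_long`.
#' @export
compare_components <- function(target, fixed) {
  short <- component_intercept_fit(target, fixed, "short")
  long <- component_intercept_fit(target, fixed, "long")
  aw <- akaike_weights(c(short = short$aic, long = long$aic))
  list(short = short, long = long, weights = aw$weights,
       rel_likelihood_short_vs_long = exp(-(short$aic - long$aic) / 2))
}

#' Per-area anatomical heritability and its gradient
#'
#' Heritability of each area's anatomical scalar (age and sex covariates),
#' the linear level regression with slope t-test, the early-visual slope,
#' and the component comparison against a fixed two-component fit.
#'
#' @param pheno Subjects x areas matrix of an anatomical phenotype.
#' @param cohort A `twin_cohort`.
#' @param levels Named hierarchical levels per area.
#' @param fixed Optional converged two-component fit for the component
#'   comparison.
#' @return List with `heritability` (per-area table), `profile`, `fit_lin`,
#'   `slope` (t, df, p), `early_slope`, and `components` when `fixed` given.
#' @export
analyze_anatomy <- function(pheno, cohort, levels, fixed = NULL) {
  herit <- heritability_table(pheno, cohort, covariates = c("age", "sex"))
  prof <- data.frame(area = herit$phenotype_id, mean = herit$h2,
                     sem = NA_real_, n = 1L, stringsAsFactors = FALSE)
  prof <- prof[prof$area %in% names(levels), , drop = FALSE]
  prof$eta <- as.numeric(levels[prof$area])
  class(prof) <- c("area_profile", "data.frame")
  fit_lin <- fit_polynomial(prof, 1)
  out <- list(heritability = herit, profile = prof, fit_lin = fit_lin,
              slope = list(t = fit_lin$slope_t, df = fit_lin$slope_df,
                           p = fit_lin$slope_p),
              early_slope = try_or_null(early_visual_slope(prof)))
  if (!is.null(fixed) && isTRUE(fixed$converged)) {
    out$components <- compare_components(prof, fixed)
  }
  out
}

try_or_null <- function(expr) {
  out <- try(expr, silent = TRUE)
  if (inherits(out, "try-error")) NULL else out
}

#' @export
print.connherit_result <- function(x, ...) {
  cat(sprintf("Connectivity gradient analysis: %d/%d connections kept (FDR)\n",
              sum(x$screen$keep), nrow(x$screen)))
  cat(sprintf("  linear:    R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$fit_lin$r2, x$fit_lin$df1, x$fit_lin$df2, x$fit_lin$F,
              x$fit_lin$p))
  cat(sprintf("  quadratic: R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$fit_quad$r2, x$fit_quad$df1, x$fit_quad$df2, x$fit_quad$F,
              x$fit_quad$p))
  cat(sprintf("  nested F(%d, %d) = %.2f, p = %.3g\n",
              x$nested$df1, x$nested$df2, x$nested$F, x$nested$p))
  if (!is.null(x$early_slope)) {
    cat(sprintf("  early-visual slope: t(%d) = %.2f, p = %.3g\n",
                x$early_slope$df, x$early_slope$t, x$early_slope$p))
  }
  print(x$two_component)
  invisible(x)
}

#' Validate the on-disk inputs of a pipeline run
#'
#' Schema checks on the pedigree, edge list, optional connectivity table and
#' optional anatomical tables, plus cross-file subject/area consistency.
#' Problems are collected and reported together.
#'
#' @param paths Named list with `pedigree`, `edges`, and optionally
#'   `connectivity`, `anatomy` (named vector of paths).
#' @return Character vector of problems (empty when the bundle is valid).
#' @export
validate_inputs <- function(paths) {
  probs <- character(0)
  note <- function(msg) probs <<- c(probs, msg)
  cohort <- NULL
  graph <- NULL
  if (is.null(paths$pedigree) || !file.exists(paths$pedigree)) {
    note("pedigree file missing")
  } else {
    ped <- utils::read.delim(paths$pedigree, stringsAsFactors = FALSE)
    cohort <- try(validate_cohort(ped), silent = TRUE)
    if (inherits(cohort, "try-error")) {
      note(paste("pedigree invalid:", conditionMessage(attr(cohort, "condition"))))
      cohort <- NULL
    }
  }
  if (is.null(paths$edges) || !file.exists(paths$edges)) {
    note("edge list missing")
  } else {
    graph <- try(read_edges_tsv(paths$edges), silent = TRUE)
    if (inherits(graph, "try-error")) {
      note(paste("edge list invalid:", conditionMessage(attr(graph, "condition"))))
      graph <- NULL
    }
  }
  if (!is.null(paths$connectivity) && file.exists(paths$connectivity)) {
    conn <- utils::read.delim(paths$connectivity, stringsAsFactors = FALSE)
    req <- c("subject_id", "session", "area_a", "area_b", "z")
    miss <- setdiff(req, names(conn))
    if (length(miss)) {
      note(paste("connectivity table missing columns:",
                 paste(miss, collapse = ", ")))
    } else {
      if (!is.null(cohort) && !all(conn$subject_id %in% cohort$subject_id)) {
        note("connectivity table has subjects absent from the pedigree")
      }
      if (!is.null(graph) &&
          !all(c(conn$area_a, conn$area_b) %in% graph$areas)) {
        note("connectivity table has areas absent from the edge list")
      }
    }
  }
  for (nm in names(paths$anatomy %||% character(0))) {
    f <- paths$anatomy[[nm]]
    if (!file.exists(f)) { note(paste("anatomy file missing:", nm)); next }
    tab <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (!"subject_id" %in% names(tab)) {
      note(paste("anatomy table", nm, "lacks subject_id"))
    } else if (!is.null(cohort) && !all(tab$subject_id %in% cohort$subject_id)) {
      note(paste("anatomy table", nm, "has unknown subjects"))
    }
  }
  probs
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates connectivity (when time series are given) or loads a
#' connectivity table, then screening, heritability, reliability, hierarchy
#' and the gradient/plasticity models, writing all stage outputs plus a run
#' manifest to `out_dir`.
#'
#' @param config Either a path to a YAML file or a named list with entries:
#'   `pedigree`, `edges`, `roots`, one of `connectivity` (long TSV with
#'   sessions) — and optionally `anatomy` (named paths); `q_fdr`
#'   (default 0.05), `n_perm` (default 10000), `n_perm_mantel` (default
#'   5000), `h_max` (0.5), `level_offset` (0), `loss` (`"soft_l1"`),
#'   `covariates`, `seed` (mandatory), `out_dir`.
#' @return The `connherit_result` (with `anatomy` results attached),
#'   invisibly; side effect: TSV/JSON outputs under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set an explicit seed")
  q_fdr <- config$q_fdr %||% 0.05
  if (q_fdr <= 0 || q_fdr >= 1) stop("q_fdr must lie in (0, 1)")
  probs <- validate_inputs(config)
  if (length(probs)) stop("input validation failed:\n  ",
                          paste(probs, collapse = "\n  "))
  if (is.null(config$connectivity) || !file.exists(config$connectivity)) {
    stop("config must point to a connectivity table (long TSV)")
  }
  cohort <- validate_cohort(utils::read.delim(config$pedigree,
                                              stringsAsFactors = FALSE))
  graph <- read_edges_tsv(config$edges)
  roots <- config$roots %||% grep("V1$", graph$areas, value = TRUE)
  conn <- utils::read.delim(config$connectivity, stringsAsFactors = FALSE)
  z_mats <- long_to_matrices(conn, cohort, graph)
  res <- analyze_connectivity(
    z_mats$all, cohort, graph, roots,
    z_day1 = z_mats$day1, z_day2 = z_mats$day2,
    q_fdr = q_fdr,
    n_perm = config$n_perm %||% 10000,
    n_perm_mantel = config$n_perm_mantel %||% 5000,
    covariates = config$covariates %||% c("age", "sex", "mean_fd",
                                          "recon_version"),
    h_max = config$h_max %||% 0.5,
    level_offset = config$level_offset %||% 0L,
    loss = config$loss %||% "soft_l1",
    seed = config$seed)
  if (!is.null(config$anatomy)) {
    res$anatomy <- lapply(config$anatomy, function(f) {
      tab <- utils::read.delim(f, stringsAsFactors = FALSE)
      M <- as.matrix(tab[match(cohort$subject_id, tab$subject_id),
                         setdiff(names(tab), "subject_id"), drop = FALSE])
      rownames(M) <- cohort$subject_id
      analyze_anatomy(M, cohort, res$levels, fixed = res$two_component)
    })
  }
  if (!is.null(config$out_dir)) write_result_bundle(res, config)
  invisible(res)
}

# subjects x connections matrices (all/day1/day2) from a long table
long_to_matrices <- function(conn, cohort, graph) {
  ids_all <- connection_ids(graph$areas)
  out <- list()
  for (s in unique(conn$session)) {
    sub <- conn[conn$session == s, , drop = FALSE]
    cid <- ifelse(match(sub$area_a, graph$areas) < match(sub$area_b, graph$areas),
                  paste(sub$area_a, sub$area_b, sep = "|"),
                  paste(sub$area_b, sub$area_a, sep = "|"))
    ids <- intersect(ids_all, unique(cid))
    M <- matrix(NA_real_, nrow(cohort), length(ids),
                dimnames = list(cohort$subject_id, ids))
    M[cbind(match(sub$subject_id, cohort$subject_id), match(cid, ids))] <- sub$z
    if (anyNA(M)) stop("connectivity table is incomplete for session ", s)
    out[[s]] <- M
  }
  out
}

write_result_bundle <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(config$out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  screen <- cbind(connection = rownames(res$screen), res$screen)
  wt(screen, "screen.tsv")
  wt(res$heritability, "heritability.tsv")
  wt(data.frame(area = names(res$levels), eta = as.integer(res$levels)),
     "levels.tsv")
  wt(as.data.frame(res$profile), "area_heritability.tsv")
  if (!is.null(res$icc)) {
    ep <- connection_endpoints(names(res$icc))
    wt(data.frame(area_a = ep[, 1], area_b = ep[, 2], icc = unname(res$icc)),
       "icc.tsv")
    wt(res$area_icc, "area_icc.tsv")
  }
  fits <- list(
    linear = res$fit_lin[c("beta", "r2", "F", "df1", "df2", "p")],
    quadratic = res$fit_quad[c("beta", "r2", "F", "df1", "df2", "p")],
    nested = res$nested,
    early_slope = res$early_slope,
    two_component = res$two_component[c("a1", "b1", "a2", "b2", "h_max",
                                        "r2", "converged")],
    mantel = res$mantel,
    icc_slope = res$icc_slope,
    component_icc = if (!is.null(res$component_icc))
      list(weights = as.list(res$component_icc$weights),
           rel_likelihood_short_vs_long =
             res$component_icc$rel_likelihood_short_vs_long),
    anatomy = if (!is.null(res$anatomy)) lapply(res$anatomy, function(a) {
      list(slope = a$slope, early_slope = a$early_slope,
           weights = if (!is.null(a$components))
             as.list(a$components$weights))
    })
  )
  jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("connherit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = config[setdiff(names(config), "out_dir")]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' One-command synthetic demonstration
#'
#' Generates a small twin cohort and synthetic ROI time series on a reduced
#' area graph, then runs every pipeline stage end to end (time series ->
#' connectivity -> screen -> heritability -> reliability -> hierarchy ->
#' gradient fits), optionally writing the full output bundle.
#'
#' @param seed Integer seed.
#' @param out_dir Optional output directory for the TSV/JSON bundle.
#' @param n_mz,n_dz Twin-pair counts (default 40 + 20).
#' @param n_timepoints Time points per run (default 300).
#' @param n_perm Sign-flip draws of the screen (reduced default for the
#'   demo).
#' @return The `connherit_result`, invisibly.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_mz = 40, n_dz = 20,
                     n_timepoints = 300, n_perm = 2000) {
  cohort <- generate_pedigree(n_mz, n_dz, seed = seed)
  fix <- visual_graph_fixture()
  keep_areas <- paste0("lh_", c("V1", "V2v", "V2d", "V3v", "V3d", "hV4",
                                "V3a", "V3b", "LO1", "LO2", "IPS0", "IPS1"))
  sub_edges <- fix$edges[fix$edges$area_a %in% keep_areas &
                           fix$edges$area_b %in% keep_areas, ]
  graph <- generate_area_graph(sub_edges)
  levels <- hierarchy_levels_multi(graph, "lh_V1")
  ds <- generate_connectivity_dataset(cohort, graph, levels, seed = seed + 1L)
  ts <- generate_timeseries(cohort, ds$z_all, graph$areas,
                            n_timepoints = n_timepoints, n_runs = 4,
                            seed = seed + 2L)
  zt <- connectivity_tables(ts)
  res <- analyze_connectivity(zt$all, cohort, graph, roots = "lh_V1",
                              z_day1 = zt$day1, z_day2 = zt$day2,
                              n_perm = n_perm, n_perm_mantel = 1000,
                              seed = seed + 3L)
  if (!is.null(out_dir)) {
    cfg <- list(out_dir = out_dir, seed = seed)
    write_result_bundle(res, cfg)
    wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                            sep = "\t", quote = FALSE,
                                            row.names = FALSE)
    wt(as.data.frame(unclass(cohort)), "pedigree.tsv")
    write_edges_tsv(graph, file.path(out_dir, "edges.tsv"))
    wt(connectivity_long(zt$all, "all"), "connectivity.tsv")
    jsonlite::write_json(default_truth(), file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
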