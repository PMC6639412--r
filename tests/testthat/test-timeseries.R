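make_z_matrix <- function(cohort, areas, z_vals) {
  ids <- connection_ids(areas)
  matrix(rep(z_vals, each = nrow(cohort)), nrow(cohort), length(ids),
         dimnames = list(cohort$subject_id, ids))
}

test_that("generated series reproduce their target correlation", {
  ped <- generate_pedigree(1, 0, seed = 1)
  areas <- c("A", "B")

  zero <- make_z_matrix(ped, areas, 0)
  ts0 <- generate_timeseries(ped, zero, areas, n_timepoints = 100000,
                             n_runs = 1, seed = 4)
  r0 <- cor(ts0$series[[1]][[1]])[1, 2]
  expect_lt(abs(r0), 0.02)

  half <- make_z_matrix(ped, areas, atanh(0.5))
  ts5 <- generate_timeseries(ped, half, areas, n_timepoints = 100000,
                             n_runs = 1, seed = 5)
  r5 <- cor(ts5$series[[1]][[1]])[1, 2]
  expect_equal(r5, 0.5, tolerance = 0.02)
})

test_that("inconsistent pairwise targets are flagged as non-embeddable", {
  ped <- generate_pedigree(1, 0, seed = 1)
  areas <- c("A", "B", "C")
  z <- make_z_matrix(ped, areas, atanh(c(0.9, 0.9, -0.9)))
  expect_warning(
    ts <- generate_timeseries(ped, z, areas, n_timepoints = 200, n_runs = 1,
                              seed = 2),
    "non-embeddable")
  expect_equal(sort(unique(ts$flagged$subject_id)), sort(ped$subject_id))
  # the repaired matrix is still a valid correlation matrix
  C <- cor(ts$series[[1]][[1]])
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("positive-definite repair is idempotent on valid matrices", {
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.3; C[1, 3] <- C[3, 1] <- 0.2
  out <- nearest_pd_correlation(C)
  expect_identical(out$mat, C)
  expect_equal(out$rel_dist, 0)
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  rep_ <- nearest_pd_correlation(bad)
  expect_true(min(eigen(rep_$mat, symmetric = TRUE)$values) > 0)
  expect_equal(diag(rep_$mat), rep(1, 3))
  expect_gt(rep_$rel_dist, 0)
})

test_that("motion regressors scale with mean framewise displacement", {
  ped <- generate_pedigree(0, 2, seed = 8)
  ped$mean_fd <- c(0.05, 0.05, 0.5, 0.5)
  areas <- c("A", "B")
  z <- make_z_matrix(ped, areas, 0.2)
  ts <- generate_timeseries(ped, z, areas, n_timepoints = 400, n_runs = 2,
                            seed = 3)
  expect_equal(dim(ts$motion[[1]][[1]]), c(400, 12))
  amp <- vapply(ts$motion, function(runs) mean(abs(runs[[1]][, 1:6])),
                numeric(1))
  expect_gt(mean(amp[3:4]), mean(amp[1:2]) * 3)
  # reproducibility
  ts2 <- generate_timeseries(ped, z, areas, n_timepoints = 400, n_runs = 2,
                             seed = 3)
  expect_identical(ts$series[[2]][[1]], ts2$series[[2]][[1]])
})

test_that("time series round-trip through per-run TSVs", {
  ped <- generate_pedigree(1, 1, seed = 9)
  areas <- c("A", "B")
  z <- make_z_matrix(ped, areas, 0.3)
  ts <- generate_timeseries(ped, z, areas, n_timepoints = 40, n_runs = 2,
                            seed = 10)
  dir <- tempfile("ts")
  write_timeseries_tsvs(ts, dir)
  expect_length(list.files(dir), 4 * 2 * 2)  # 4 subjects x 2 runs x 2 files
  back <- read_timeseries_tsvs(dir, ped$subject_id, n_runs = 2)
  expect_equal(back$areas, areas)
  expect_equal(back$series[[ped$subject_id[3]]][[2]],
               ts$series[[ped$subject_id[3]]][[2]],
               tolerance = 1e-6, ignore_attr = TRUE)
  zt <- connectivity_tables(back, sessions = "all")
  expect_true(all(is.finite(zt$all)))
})

test_that("timeseries preconditions are enforced", {
  ped <- generate_pedigree(1, 0, seed = 1)
  areas <- c("A", "B", "C")
  z <- make_z_matrix(ped, areas, 0.1)
  expect_error(generate_timeseries(ped, z, areas, n_timepoints = 20,
                                   n_runs = 1, seed = 1),
               "10 \\* n_areas")
})
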