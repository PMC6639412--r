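test_that("pedigree generation matches the cohort composition", {
  ped <- generate_pedigree(123, 67, seed = 1)
  expect_equal(nrow(ped), 380)
  expect_equal(length(unique(ped$family_id)), 190)
  expect_equal(sum(ped$zygosity == "MZ"), 246)

  one <- generate_pedigree(1, 0, seed = 1)
  expect_equal(nrow(one), 2)
  expect_equal(unique(one$zygosity), "MZ")
  expect_equal(length(unique(one$family_id)), 1)

  dz <- generate_pedigree(0, 5, seed = 7)
  expect_equal(nrow(dz), 10)
  expect_true(all(dz$zygosity == "DZ"))
})

test_that("pedigree invariants hold and generation is reproducible", {
  ped <- generate_pedigree(40, 25, seed = 3)
  expect_true(all(table(ped$family_id) == 2))
  expect_false(anyDuplicated(ped$subject_id) > 0)
  expect_true(all(ped$mean_fd > 0))
  expect_true(all(ped$age >= 22 & ped$age <= 36))
  # co-twins share age, recon version; MZ co-twins share sex
  by_fam <- split(ped, ped$family_id)
  expect_true(all(vapply(by_fam, function(f) f$age[1] == f$age[2], logical(1))))
  expect_true(all(vapply(by_fam, function(f)
    f$recon_version[1] == f$recon_version[2], logical(1))))
  mz <- Filter(function(f) f$zygosity[1] == "MZ", by_fam)
  expect_true(all(vapply(mz, function(f) f$sex[1] == f$sex[2], logical(1))))

  expect_identical(ped, generate_pedigree(40, 25, seed = 3))
  expect_false(identical(ped$mean_fd, generate_pedigree(40, 25, seed = 4)$mean_fd))
})

test_that("invalid pedigree arguments and structures are rejected", {
  expect_error(generate_pedigree(-1, 5, seed = 1), "non-negative")
  expect_error(generate_pedigree(0, 0, seed = 1), "at least one")
  ped <- generate_pedigree(2, 2, seed = 1)
  bad <- rbind(ped, ped[1, ])
  bad$subject_id[nrow(bad)] <- "S9999"
  expect_error(validate_cohort(bad), "exactly 2 members")
  dup <- ped; dup$subject_id[2] <- dup$subject_id[1]
  expect_error(validate_cohort(dup), "duplicate")
})

test_that("phenotype generation follows the kinship covariance model", {
  ped <- generate_pedigree(60, 40, seed = 2)
  # full genetic determination: MZ co-twins identical (no covariates)
  y <- generate_phenotype(ped, h2_true = 1, seed = 5)
  mz <- ped$zygosity == "MZ"
  y_mz <- matrix(y[mz], nrow = 2)
  expect_equal(y_mz[1, ], y_mz[2, ], tolerance = 1e-12)

  # no genetic variance: within-pair correlations near zero at large n
  big <- generate_pedigree(2000, 2000, seed = 9)
  y0 <- generate_phenotype(big, h2_true = 0, seed = 6)
  m <- matrix(y0[big$zygosity == "MZ"], nrow = 2)
  d <- matrix(y0[big$zygosity == "DZ"], nrow = 2)
  expect_lt(abs(cor(m[1, ], m[2, ])), 0.06)
  expect_lt(abs(cor(d[1, ], d[2, ])), 0.06)
})

test_that("twin correlations approach rMZ = h2 and rDZ = h2/2", {
  big <- generate_pedigree(5000, 5000, seed = 21)
  y <- generate_phenotype(big, h2_true = 0.6, seed = 22)
  m <- matrix(y[big$zygosity == "MZ"], nrow = 2)
  d <- matrix(y[big$zygosity == "DZ"], nrow = 2)
  # bounds are 3 Monte-Carlo standard errors of a correlation at n = 5000
  expect_lt(abs(cor(m[1, ], m[2, ]) - 0.6), 0.03)
  expect_lt(abs(cor(d[1, ], d[2, ]) - 0.3), 0.04)
  # empirical within-pair covariance matches 2*Phi*sigma_g2 within 3 SE
  expect_lt(abs(cov(m[1, ], m[2, ]) - 0.6), 0.05)
  expect_lt(abs(cov(d[1, ], d[2, ]) - 0.3), 0.05)
})

test_that("phenotype arguments are validated and covariates applied", {
  ped <- generate_pedigree(5, 5, seed = 1)
  expect_error(generate_phenotype(ped, h2_true = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(generate_phenotype(ped, h2_true = 0.5, total_var = 0, seed = 1),
               "total_var")
  y0 <- generate_phenotype(ped, 0.5, seed = 3)
  y1 <- generate_phenotype(ped, 0.5, covariate_effects = c(age = 1), seed = 3)
  expect_equal(y1 - y0, ped$age, tolerance = 1e-12)
})
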