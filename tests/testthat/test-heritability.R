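test_that("kinship matrix encodes expected genetic sharing", {
  mz <- generate_pedigree(1, 0, seed = 1)
  K <- kinship_from_pedigree(mz)
  expect_equal(K[1, 2], 1)
  dz <- generate_pedigree(0, 1, seed = 1)
  expect_equal(kinship_from_pedigree(dz)[1, 2], 0.5)
  both <- generate_pedigree(1, 1, seed = 1)
  K2 <- kinship_from_pedigree(both)
  expect_equal(diag(K2), rep(1, 4), ignore_attr = TRUE)
  expect_equal(K2[1:2, 3:4], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_identical(K2, t(K2))
})

test_that("inverse normal transform follows the Blom formula", {
  x <- c(3.2, -1, 0.5, 10, 2)
  got <- inverse_normal(x)
  want <- qnorm((rank(x) - 3 / 8) / (5 + 1 / 4))
  expect_equal(got, want, tolerance = 1e-12)
  # median of an odd-length distinct vector maps to 0
  expect_equal(got[order(x)][3], 0, tolerance = 1e-12)
  # order isomorphism
  set.seed(8)
  y <- rnorm(50)
  expect_identical(order(inverse_normal(y)), order(y))
  expect_error(inverse_normal(rep(2, 10)), "identical")
  expect_error(inverse_normal(c(1, 2)), "at least 3")
})

test_that("mixture LRT p-values follow the 50:50 chi-square mixture", {
  expect_equal(mixture_lrt_pvalue(0), 1)
  expect_equal(mixture_lrt_pvalue(0, zero_convention = "half"), 0.5)
  # 2.706 and 3.841 are the 90% / 95% chi-square(1) quantiles to 3 decimals
  expect_equal(mixture_lrt_pvalue(2.706), 0.05, tolerance = 1e-3)
  expect_equal(mixture_lrt_pvalue(3.841), 0.025, tolerance = 1e-3)
  expect_error(mixture_lrt_pvalue(-1), "negative")
})

test_that("AE fit recovers heritability and matches the Falconer moments", {
  big <- generate_pedigree(5000, 5000, seed = 31)
  y <- generate_phenotype(big, h2_true = 0.6, seed = 32)
  fit <- fit_ae(y, cohort = big)
  m <- matrix(y[big$zygosity == "MZ"], nrow = 2)
  d <- matrix(y[big$zygosity == "DZ"], nrow = 2)
  falconer <- 2 * (cor(m[1, ], m[2, ]) - cor(d[1, ], d[2, ]))
  # the moment and ML estimators target the same quantity but differ by
  # O(sampling error); 0.05 is ~2 SE of their difference at this n
  expect_lt(abs(fit$h2 - falconer), 0.05)
  expect_lt(abs(fit$h2 - 0.6), 0.05)
  expect_gt(fit$lrt_stat, 0)
  expect_lt(fit$p_mixture, 1e-10)
})

test_that("AE fit is scale-equivariant and stable to orthogonal covariates", {
  ped <- generate_pedigree(80, 60, seed = 41)
  y <- generate_phenotype(ped, h2_true = 0.5, seed = 42)
  K <- kinship_from_pedigree(ped)
  f1 <- fit_ae(y, K = K)
  f2 <- fit_ae(3 * y, K = K)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  expect_equal(f2$sigma_g2, 9 * f1$sigma_g2, tolerance = 1e-5)
  expect_equal(f2$sigma_e2, 9 * f1$sigma_e2, tolerance = 1e-5)
  expect_equal(f2$lrt_stat, f1$lrt_stat, tolerance = 1e-6)
  # a covariate orthogonal to y barely moves the estimate (not exactly:
  # GLS orthogonality is in the W-inner product, not the Euclidean one)
  set.seed(43)
  x_orth <- residuals(lm(rnorm(nrow(ped)) ~ y))
  f3 <- fit_ae(y, X = cbind(x_orth), K = K)
  expect_lt(abs(f3$h2 - f1$h2), 0.02)
})

test_that("boundary null yields near-zero estimates and LRT point mass", {
  ped <- generate_pedigree(100, 60, seed = 51)
  K <- kinship_from_pedigree(ped)
  stats0 <- vapply(1:40, function(i) {
    y <- generate_phenotype(ped, h2_true = 0, seed = 100 + i)
    f <- fit_ae(y, K = K)
    c(f$h2, f$lrt_stat)
  }, numeric(2))
  # about half of null replicates land exactly on the boundary
  frac_zero <- mean(stats0[2, ] < 1e-6)
  expect_gt(frac_zero, 0.25)
  expect_lt(frac_zero, 0.8)
  expect_lt(mean(stats0[1, ]), 0.15)
})

test_that("simultaneous covariate estimation recovers the effects", {
  ped <- generate_pedigree(123, 67, seed = 61)
  eff <- c(age = -0.02, sex = 0.5, mean_fd = -1.0)
  y <- generate_phenotype(ped, h2_true = 0.6, covariate_effects = eff,
                          seed = 62)
  X <- cbind(age = ped$age, sex = ped$sex, mean_fd = ped$mean_fd)
  fit <- fit_ae(y, X = X, K = kinship_from_pedigree(ped), ci = TRUE)
  expect_equal(unname(fit$beta["age"]), -0.02, tolerance = 0.02)
  expect_equal(unname(fit$beta["sex"]), 0.5, tolerance = 0.35)
  expect_equal(fit$h2, 0.6, tolerance = 0.2)
  expect_true(fit$ci["lower"] <= fit$h2 && fit$h2 <= fit$ci["upper"])
  expect_error(fit_ae(y, X = cbind(X, age2 = ped$age), K = kinship_from_pedigree(ped)),
               "full rank")
})

test_that("heritability_table handles many phenotypes with the screen set", {
  ped <- generate_pedigree(40, 30, seed = 71)
  ph <- sapply(c(0.2, 0.7), function(h2)
    generate_phenotype(ped, h2, seed = round(h2 * 100)))
  colnames(ph) <- c("low", "high")
  tab <- heritability_table(ph, ped, covariates = c("age", "mean_fd"))
  expect_equal(tab$phenotype_id, c("low", "high"))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
  expect_true(all(tab$p > 0 & tab$p <= 1))
})
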