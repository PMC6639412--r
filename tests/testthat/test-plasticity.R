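test_that("area profiles average each endpoint's kept connections", {
  v <- c("A|B" = 0.2, "A|C" = 0.4, "B|C" = 0.6)
  prof <- area_profile(v)
  expect_equal(prof$mean[prof$area == "A"], 0.3)
  expect_equal(prof$mean[prof$area == "B"], 0.4)
  # constant values give every area that constant
  vc <- setNames(rep(0.5, 3), names(v))
  expect_true(all(area_profile(vc)$mean == 0.5))
  # brute-force enumeration on a random 10-area instance
  set.seed(21)
  areas <- paste0("R", 1:10)
  ids <- connection_ids(areas)
  vals <- setNames(runif(length(ids)), ids)
  keep <- runif(length(ids)) > 0.3
  prof2 <- suppressWarnings(area_profile(vals, keep = keep))
  ep <- do.call(rbind, strsplit(names(vals), "|", fixed = TRUE))
  for (a in prof2$area) {
    sel <- keep & (ep[, 1] == a | ep[, 2] == a)
    expect_equal(prof2$mean[prof2$area == a], mean(vals[sel]), tolerance = 1e-12)
    expect_equal(prof2$n[prof2$area == a], sum(sel))
  }
  # an area with no kept connections is excluded with a warning
  expect_warning(area_profile(v, keep = c(TRUE, FALSE, FALSE)),
                 "no kept connections.*C")
})

test_that("polynomial fits match the closed-form normal equations", {
  prof <- data.frame(area = letters[1:5], mean = c(2.1, 2.9, 4.2, 4.8, 6.1),
                     eta = 0:4)
  f1 <- fit_polynomial(prof, 1)
  X <- cbind(1, prof$eta)
  expect_equal(unname(f1$beta), drop(ols_brute(prof$mean, X)), tolerance = 1e-12)
  X2 <- cbind(1, prof$eta, prof$eta^2)
  f2 <- fit_polynomial(prof, 2)
  expect_equal(unname(f2$beta), drop(ols_brute(prof$mean, X2)), tolerance = 1e-12)
  # exactly linear data: R2 = 1
  lin <- data.frame(area = letters[1:6], mean = 1 + 0.5 * (0:5), eta = 0:5)
  expect_equal(suppressWarnings(fit_polynomial(lin, 1))$r2, 1,
               tolerance = 1e-12)
  expect_error(fit_polynomial(data.frame(mean = 1:5, eta = rep(2, 5)), 1),
               "constant")
})

test_that("the nested F-test equals the textbook partial-F oracle", {
  set.seed(22)
  prof <- data.frame(area = paste0("a", 1:10), eta = 0:9,
                     mean = 0.4 - 0.01 * (0:9) + 0.004 * (0:9)^2 + rnorm(10, sd = 0.02))
  f1 <- fit_polynomial(prof, 1); f2 <- fit_polynomial(prof, 2)
  got <- nested_f_test(f1, f2)
  oracle <- anova(lm(mean ~ eta, prof), lm(mean ~ eta + I(eta^2), prof))
  expect_equal(got$F, oracle$F[2], tolerance = 1e-10)
  expect_equal(got$p, oracle$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(got$df2, oracle$Res.Df[2])
  # noiseless quadratic: F = Inf, p = 0
  quad <- data.frame(area = paste0("q", 1:8), eta = 0:7,
                     mean = 1 + 0.2 * (0:7) - 0.05 * (0:7)^2)
  nf <- nested_f_test(fit_polynomial(quad, 1),
                      suppressWarnings(fit_polynomial(quad, 2)))
  expect_equal(nf$F, Inf)
  expect_equal(nf$p, 0)
})

test_that("early-visual slope uses the 10-area set with df = 8", {
  areas <- c(default_early_set(), "lh_hV4", "rh_hV4")
  set.seed(23)
  prof <- data.frame(area = areas,
                     eta = c(rep(c(0, 1, 1, 2, 2), 2), 3, 3),
                     mean = 0.2 + 0.1 * c(rep(c(0, 1, 1, 2, 2), 2), 3, 3) +
                       rnorm(12, sd = 0.01))
  out <- early_visual_slope(prof)
  expect_equal(out$df, 8)
  expect_lt(out$p, 0.001)
  expect_gt(out$slope, 0)
  expect_error(early_visual_slope(prof[1:2, ]), "fewer than 3")
})

test_that("two-component fit recovers noiseless parameters exactly", {
  eta <- 0:10
  truth <- c(a1 = 0.25, b1 = 0.8, a2 = 0.001, b2 = 0.6)
  prof <- data.frame(area = paste0("x", eta), eta = eta,
                     mean = two_component_curve(eta, 0.25, 0.8, 0.001, 0.6))
  for (loss in c("soft_l1", "ols")) {
    fit <- fit_two_component(prof, loss = loss)
    expect_true(fit$converged)
    expect_equal(c(fit$a1, fit$b1, fit$a2, fit$b2), unname(truth),
                 tolerance = 1e-4)
    expect_equal(fit$r2, 1, tolerance = 1e-8)
  }
  expect_error(fit_two_component(prof[1:4, ]), ">= 6 areas")
})

test_that("component shapes are monotone and capped by h_max", {
  eta <- seq(0, 8, by = 0.5)
  c1 <- 0.25 * exp(-0.8 * eta)
  c2 <- 0.001 * exp(0.6 * eta)
  expect_true(all(diff(c1) < 0))
  expect_true(all(diff(c2) > 0))
  expect_true(all(two_component_curve(eta, 0.25, 0.8, 0.001, 0.6) <= 0.5))
})

test_that("intercept-only component fits identify the generating component", {
  eta <- 0:9
  fixed <- list(a1 = 0.25, b1 = 0.8, a2 = 0.004, b2 = 0.45, h_max = 0.5,
                converged = TRUE)
  class(fixed) <- "two_component_fit"
  # target generated exactly as 0.6 - c1
  target <- data.frame(area = paste0("t", eta), eta = eta,
                       mean = 0.6 - 0.25 * exp(-0.8 * eta))
  short <- component_intercept_fit(target, fixed, "short")
  expect_equal(short$beta, 0.6, tolerance = 1e-12)
  expect_equal(short$rss, 0, tolerance = 1e-20)
  long <- component_intercept_fit(target, fixed, "long")
  expect_gt(long$rss, short$rss)
  # monotone decreasing anatomy-like target prefers the long component
  anat <- data.frame(area = paste0("t", eta), eta = eta,
                     mean = 0.6 - 0.004 * exp(0.45 * eta))
  s2 <- component_intercept_fit(anat, fixed, "short")
  l2 <- component_intercept_fit(anat, fixed, "long")
  w <- akaike_weights(c(short = s2$aic, long = l2$aic))$weights
  expect_gt(w[["long"]], 0.99)
})

test_that("Akaike weights follow the closed form and its invariance", {
  w <- akaike_weights(c(10, 10))
  expect_equal(unname(w$weights), c(0.5, 0.5))
  w2 <- akaike_weights(c(8, 10))
  expect_equal(w2$rel_likelihood[2, 1], exp(-1), tolerance = 1e-12)
  w3 <- akaike_weights(c(0, 9.22))
  expect_lt(w3$weights[2], 0.01)
  expect_equal(akaike_weights(c(100, 102, 105))$weights,
               akaike_weights(c(0, 2, 5))$weights, tolerance = 1e-12)
  expect_error(akaike_weights(c(1, NA)), "NaN|NA")
  expect_error(akaike_weights(3), "at least 2")
})
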