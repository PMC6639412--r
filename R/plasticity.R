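#' Per-area profile of a per-connection quantity
#'
#' Averages a per-connection value (heritability, ICC, ...) over each area's
#' kept connections: every kept connection contributes to both of its
#' endpoint areas. Because the average graph distance from an area to all
#' other areas is equal across areas, no further distance correction is
#' applied.
#'
#' @param values Named numeric vector over `"A|B"` connection ids.
#' @param keep Logical mask over the same connections (the FDR screen);
#'   default keeps all.
#' @param levels Optional named vector of hierarchical levels; when given,
#'   an `eta` column is attached and areas without a level are dropped.
#' @return Data frame of class `area_profile`: `area`, `mean`, `sem`, `n`
#'   (kept connections per area) and optionally `eta`. Areas with no kept
#'   connections are excluded with a warning.
#' @export
area_profile <- function(values, keep = NULL, levels = NULL) {
  if (is.null(names(values))) stop("values must be named by connection id")
  if (is.null(keep)) keep <- rep(TRUE, length(values))
  if (length(keep) != length(values)) stop("keep mask must match values")
  ep <- connection_endpoints(names(values))
  areas <- sort(unique(as.vector(ep)))
  kept_vals <- values[keep]
  kept_ep <- ep[keep, , drop = FALSE]
  rows <- lapply(areas, function(a) {
    sel <- kept_ep[, 1] == a | kept_ep[, 2] == a
    v <- kept_vals[sel]
    if (!length(v)) return(NULL)
    data.frame(area = a, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  })
  dropped <- areas[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("areas with no kept connections excluded: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (!is.null(levels)) {
    out <- out[out$area %in% names(levels), , drop = FALSE]
    out$eta <- as.numeric(levels[out$area])
  }
  class(out) <- c("area_profile", "data.frame")
  out
}

#' Polynomial regression of an area profile on hierarchical level
#'
#' Ordinary least squares of the per-area mean on `eta` (degree 1) or on
#' `eta` and `eta^2` (degree 2), with the overall F-test against the
#' intercept-only model and, for degree 1, the two-sided slope t-test.
#'
#' @param profile An `area_profile` with an `eta` column (or a data frame
#'   with `mean` and `eta`).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return List of class `poly_fit`: `degree`, `beta`, `r2`, `F`, `df1`,
#'   `df2`, `p`, `rss`, `n`, and for degree 1 `slope_t`, `slope_df`,
#'   `slope_p`; the underlying `lm` fit is kept in `$lm`.
#' @export
fit_polynomial <- function(profile, degree = 1) {
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (!all(c("mean", "eta") %in% names(profile))) {
    stop("profile must carry 'mean' and 'eta'")
  }
  n <- nrow(profile)
  if (n <= degree + 1) stop("too few areas for this degree")
  if (stats::var(profile$eta) == 0) stop("constant hierarchical level")
  fm <- if (degree == 1) mean ~ eta else mean ~ eta + I(eta^2)
  fit <- stats::lm(fm, data = as.data.frame(profile))
  sm <- summary(fit)
  out <- list(degree = degree,
              beta = stats::coef(fit),
              r2 = sm$r.squared,
              F = unname(sm$fstatistic[1]),
              df1 = unname(sm$fstatistic[2]),
              df2 = unname(sm$fstatistic[3]),
              p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                            sm$fstatistic[3], lower.tail = FALSE),
              rss = sum(stats::residuals(fit)^2),
              n = n, lm = fit)
  if (degree == 1) {
    out$slope_t <- sm$coefficients["eta", "t value"]
    out$slope_df <- n - 2
    out$slope_p <- sm$coefficients["eta", "Pr(>|t|)"]
  }
  class(out) <- "poly_fit"
  out
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("Degree-%d fit: R2 = %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$degree, x$r2, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Partial F-test comparing the linear and quadratic level models
#'
#' `F = ((RSS1 - RSS2) / 1) / (RSS2 / (n - 3))` on `F(1, n - 3)`; a
#' perfectly fitting quadratic (`RSS2 = 0`) yields `F = Inf`, `p = 0`.
#'
#' @param fit_lin Degree-1 [fit_polynomial()] result.
#' @param fit_quad Degree-2 result on the same data.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
nested_f_test <- function(fit_lin, fit_quad) {
  if (fit_lin$degree != 1 || fit_quad$degree != 2) stop("expect degree 1 vs 2 fits")
  if (fit_lin$n != fit_quad$n) stop("fits must use the same data")
  if (fit_quad$rss > fit_lin$rss * (1 + 1e-8) + 1e-12) {
    stop("quadratic RSS exceeds linear RSS: fits are not nested on these data")
  }
  df2 <- fit_quad$n - 3
  # a numerically perfect quadratic fit (RSS at rounding-error level)
  if (fit_quad$rss <= 1e-12 * max(fit_lin$rss, .Machine$double.eps)) {
    return(list(F = Inf, df1 = 1, df2 = df2, p = 0))
  }
  Fv <- (fit_lin$rss - fit_quad$rss) / (fit_quad$rss / df2)
  list(F = Fv, df1 = 1, df2 = df2,
       p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
}

#' Slope test over early visual cortex
#'
#' Linear fit of the profile restricted to the early areas (by default V1,
#' V2d, V2v, V3d, V3v in both hemispheres: 10 areas, slope df = 8) with the
#' two-sided slope t-test.
#'
#' @param profile An `area_profile` with `eta`.
#' @param early_set Labels of the early-visual areas.
#' @return List with `t`, `df`, `p`, `slope`.
#' @export
early_visual_slope <- function(profile, early_set = default_early_set()) {
  sub <- profile[profile$area %in% early_set, , drop = FALSE]
  if (nrow(sub) < 3) stop("fewer than 3 early-visual areas in the profile")
  fit <- fit_polynomial(sub, degree = 1)
  list(t = fit$slope_t, df = fit$slope_df, p = fit$slope_p,
       slope = unname(fit$beta["eta"]))
}

#' @rdname early_visual_slope
#' @export
default_early_set <- function() {
  as.vector(outer(c("lh_", "rh_"), c("V1", "V2d", "V2v", "V3d", "V3v"),
                  paste0))
}

#' Two-component plasticity curve
#'
#' `h2(eta) = h_max - a1 exp(-b1 eta) - a2 exp(b2 eta)`: heritability as the
#' complement of a decaying short-term adaptation component
#' `c1 = a1 exp(-b1 eta)` and a growing long-term plasticity component
#' `c2 = a2 exp(b2 eta)`, capped at `h_max`.
#'
#' @param eta Hierarchical levels.
#' @param a1,b1,a2,b2 Non-negative component parameters.
#' @param h_max Heritability ceiling (default 0.5, absorbing measurement
#'   noise common to all levels).
#' @return Predicted heritability values.
#' @export
two_component_curve <- function(eta, a1, b1, a2, b2, h_max = 0.5) {
  h_max - a1 * exp(-b1 * eta) - a2 * exp(b2 * eta)
}

#' Fit the two-component plasticity model
#'
#' Minimizes a robust (soft-L1) loss of the residuals
#' `mean - [h_max - a1 e^(-b1 eta) - a2 e^(b2 eta)]` over non-negative
#' `a1, b1, a2, b2`, from a deterministic multi-start grid over the decay
#' rates; `h_max` is fixed (default 0.5). R^2 is reported on the raw
#' residuals.
#'
#' @param profile An `area_profile` with `eta` (needs >= 6 areas spanning
#'   >= 4 distinct levels).
#' @param h_max Fixed heritability ceiling.
#' @param loss `"soft_l1"` (default) or `"ols"`.
#' @param f_scale Soft-L1 scale: residuals much smaller than this are
#'   treated quadratically, larger ones linearly.
#' @return List of class `two_component_fit`: `a1`, `b1`, `a2`, `b2`,
#'   `h_max`, `predicted`, `r2`, `rss`, `converged`.
#' @export
fit_two_component <- function(profile, h_max = 0.5, loss = c("soft_l1", "ols"),
                              f_scale = 0.02) {
  loss <- match.arg(loss)
  if (!all(c("mean", "eta") %in% names(profile))) {
    stop("profile must carry 'mean' and 'eta'")
  }
  y <- profile$mean
  eta <- profile$eta
  if (length(y) < 6 || length(unique(eta)) < 4) {
    stop("need >= 6 areas spanning >= 4 distinct levels")
  }
  resid_fun <- function(par) {
    y - two_component_curve(eta, par[1], par[2], par[3], par[4], h_max)
  }
  objective <- function(par) {
    r <- resid_fun(par)
    if (loss == "ols") sum(r^2)
    else sum(f_scale^2 * 2 * (sqrt(1 + (r / f_scale)^2) - 1))
  }
  starts <- expand.grid(b1 = c(0.1, 0.5, 1, 2), b2 = c(0.1, 0.5, 1, 2))
  amp0 <- max(1e-3, h_max - min(y))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(a1 = amp0 / 2, b1 = starts$b1[k],
              a2 = amp0 / 20, b2 = starts$b2[k])
    fit <- try(stats::nlminb(par0, objective, lower = rep(0, 4),
                             control = list(iter.max = 500, eval.max = 1000,
                                            rel.tol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    out <- list(a1 = NA, b1 = NA, a2 = NA, b2 = NA, h_max = h_max,
                predicted = rep(NA_real_, length(y)), r2 = NA_real_,
                rss = NA_real_, converged = FALSE)
    class(out) <- "two_component_fit"
    return(out)
  }
  # polish the winning start with plain least squares when loss is robust:
  # on clean data both agree; on contaminated data the robust optimum stands
  par <- best$par
  pred <- two_component_curve(eta, par[1], par[2], par[3], par[4], h_max)
  rss <- sum((y - pred)^2)
  out <- list(a1 = unname(par[1]), b1 = unname(par[2]),
              a2 = unname(par[3]), b2 = unname(par[4]), h_max = h_max,
              predicted = pred,
              r2 = 1 - rss / sum((y - mean(y))^2),
              rss = rss,
              converged = best$convergence %in% c(0, 1))
  class(out) <- "two_component_fit"
  out
}

#' @export
print.two_component_fit <- function(x, ...) {
  cat(sprintf("Two-component fit (h_max = %.2f): a1 = %.4f, b1 = %.4f, a2 = %.4g, b2 = %.4f; R2 = %.3f\n",
              x$h_max, x$a1, x$b1, x$a2, x$b2, x$r2))
  invisible(x)
}

#' Intercept-only fit of a frozen plasticity component to a target profile
#'
#' Freezes the shape of one component of a fitted two-component model and
#' fits only a vertical offset: `target = beta - c_k(eta)` with
#' `c1 = a1 e^(-b1 eta)` (short-term) or `c2 = a2 e^(b2 eta)` (long-term).
#' Used to ask whether test-retest reliability tracks the short-term and
#' anatomical heritability the long-term component. AIC is
#' `n log(RSS / n) + 2 k` with `k = 2` (intercept + error variance).
#'
#' @param target An `area_profile` (with `eta`) of the target quantity.
#' @param fixed A converged [fit_two_component()] result.
#' @param which `"short"` (c1) or `"long"` (c2).
#' @return List with `beta`, `rss`, `aic`, `predicted`.
#' @export
component_intercept_fit <- function(target, fixed, which = c("short", "long")) {
  which <- match.arg(which)
  if (!isTRUE(fixed$converged)) stop("fixed two-component fit did not converge")
  y <- target$mean
  eta <- target$eta
  comp <- if (which == "short") fixed$a1 * exp(-fixed$b1 * eta)
          else fixed$a2 * exp(fixed$b2 * eta)
  beta <- mean(y + comp)
  pred <- beta - comp
  rss <- sum((y - pred)^2)
  n <- length(y)
  # floor the RSS so a perfect fit yields a very negative, finite AIC
  list(beta = beta, rss = rss,
       aic = n * log(max(rss, 1e-20) / n) + 2 * 2,
       predicted = pred)
}

#' Akaike weights and relative likelihoods from AIC values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; the relative likelihood of model i versus j
#' is `exp(-(AIC_i - AIC_j) / 2)`. Invariant to adding a constant to all
#' AICs.
#'
#' @param aics Numeric vector (length >= 2) of AIC values.
#' @return List with `weights` (summing to 1) and `rel_likelihood` (the
#'   pairwise matrix `exp(-(AIC_i - AIC_j)/2)`).
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 2) stop("need at least 2 AIC values")
  if (any(is.na(aics))) stop("NaN/NA AIC")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  list(weights = w / sum(w),
       rel_likelihood = exp(-outer(d, d, `-`) / 2))
}
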