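# Statistical engine: site-random-intercept Gaussian mixed models fitted
# by ML with likelihood-ratio tests, Moran's I residual diagnostics with
# permutation p-values, and Wilcoxon-Mann-Whitney comparisons.

#' Fit a site-random-intercept mixed model
#'
#' Gaussian random-intercept model y ~ rice + (1 | site), fitted by
#' maximum likelihood (not REML) so that nested models can be compared by
#' likelihood-ratio test.  Point counts within a site share a random
#' intercept, absorbing spatial correlation among nearby points.  An
#' optional Poisson GLMM is available for count responses.
#'
#' @param y response per point count.
#' @param rice logical/0-1 rice-field indicator per point count.
#' @param site site id per point count.
#' @param include_fixed set `FALSE` to fit the intercept-only null model.
#' @param family `"gaussian"` or `"poisson"` (log link, for richness
#'   counts).
#' @return Object of class `lmm_fit`: `estimate`, `se`, `site_sd`,
#'   `resid_sd`, `loglik`, `n_par`, `converged`, `singular`, `flagged`,
#'   plus the underlying `model` and `data`.
#' @export
fit_lmm <- function(y, rice, site, include_fixed = TRUE,
                    family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  d <- data.frame(y = y, rice = as.logical(rice), site = factor(site))
  if (nrow(d) < 4) stop("need at least 4 observations")
  if (length(unique(d$site)) < 2) stop("need at least 2 sites")

  if (stats::sd(d$y) == 0) {
    k <- if (include_fixed) 4 else 3
    return(structure(list(estimate = if (include_fixed) 0 else NA_real_,
                          se = NA_real_, site_sd = 0, resid_sd = 0,
                          loglik = NA_real_, n_par = k, converged = FALSE,
                          singular = TRUE, flagged = TRUE,
                          model = NULL, data = d, family = family),
                     class = "lmm_fit"))
  }

  form <- if (include_fixed) y ~ rice + (1 | site) else y ~ 1 + (1 | site)
  fit <- tryCatch({
    if (family == "gaussian") {
      lme4::lmer(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      lme4::glmer(form, data = d, family = stats::poisson())
    }
  }, error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          site_sd = NA_real_, resid_sd = NA_real_,
                          loglik = NA_real_, n_par = NA_integer_,
                          converged = FALSE, singular = NA, flagged = TRUE,
                          model = NULL, data = d, family = family),
                     class = "lmm_fit"))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  site_sd <- vc$sdcor[vc$grp == "site"][1]
  resid_sd <- if (family == "gaussian") vc$sdcor[vc$grp == "Residual"][1] else NA_real_
  co <- stats::coef(summary(fit))
  est <- if (include_fixed) co["riceTRUE", "Estimate"] else NA_real_
  se <- if (include_fixed) co["riceTRUE", "Std. Error"] else NA_real_
  singular <- lme4::isSingular(fit)
  structure(list(estimate = est, se = se, site_sd = site_sd,
                 resid_sd = resid_sd,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_par = attr(stats::logLik(fit), "df"),
                 converged = TRUE, singular = singular, flagged = singular,
                 model = fit, data = d, family = family),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("site-random-intercept model (", x$family, ", ML): rice effect =",
      round(x$estimate, 4), "+/-", round(x$se, 4),
      "; site SD =", round(x$site_sd, 4),
      "; logLik =", round(x$loglik, 2),
      if (x$flagged) "[flagged]", "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' chi^2 = 2 (logLik_full - logLik_reduced), clamped at zero; df = the
#' difference in parameter counts; p from the chi-squared distribution.
#' Both fits must be maximum-likelihood fits to the same data.
#'
#' @param full,reduced `lmm_fit` objects, reduced nested in full.
#' @return List `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (nrow(full$data) != nrow(reduced$data)) {
    stop("models were fitted to different data")
  }
  df <- full$n_par - reduced$n_par
  if (is.na(df) || df < 0) stop("models are not properly nested (df < 0)")
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  # df = 0 (e.g. full identical to reduced): no evidence either way
  p <- if (df == 0) 1 else stats::pchisq(chisq, df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Test a rice-field effect with a site-random-effect LRT
#'
#' Convenience wrapper: fits y ~ rice + (1|site) and the intercept-only
#' null, returns the likelihood-ratio test together with both fits.
#'
#' @inheritParams fit_lmm
#' @return List `chisq`, `df`, `p`, `estimate`, `full`, `reduced`.
#' @export
rice_effect_test <- function(y, rice, site, family = "gaussian") {
  full <- fit_lmm(y, rice, site, include_fixed = TRUE, family = family)
  reduced <- fit_lmm(y, rice, site, include_fixed = FALSE, family = family)
  if (!full$converged || !reduced$converged) {
    return(list(chisq = NA_real_, df = 1, p = NA_real_,
                estimate = full$estimate, full = full, reduced = reduced))
  }
  out <- lrt(full, reduced)
  out$estimate <- full$estimate
  out$full <- full
  out$reduced <- reduced
  out
}

#' Spatial weight matrices for Moran's I
#'
#' @param coords 2-column matrix of planar coordinates.
#' @param scheme `"knn"` (row-standardised k-nearest-neighbour adjacency)
#'   or `"inverse_distance"`.
#' @param k neighbours for `"knn"`.
#' @param max_weight cap applied to inverse-distance weights of (near-)
#'   coincident points (with a warning).
#' @return n x n weight matrix with zero diagonal.
#' @export
spatial_weights <- function(coords, scheme = c("knn", "inverse_distance"),
                            k = 8, max_weight = 1e6) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 locations")
  D <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    k <- min(k, n - 1)
    for (i in seq_len(n)) {
      nb <- order(D[i, -i])[seq_len(k)]
      idx <- seq_len(n)[-i][nb]
      W[i, idx] <- 1
    }
    W <- W / rowSums(W)
  } else {
    W <- 1 / D
    diag(W) <- 0
    if (any(is.infinite(W))) {
      warning("coincident points: inverse-distance weights capped at ",
              max_weight)
      W[is.infinite(W)] <- max_weight
    }
  }
  W
}

#' Moran's I with a permutation test
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2, with S0 the sum of weights; E\[I\] = -1/(n-1) under no spatial
#' autocorrelation.  The p-value is two-sided from random permutations of
#' the values over the locations.
#'
#' @param values numeric vector (e.g. model residuals), non-constant.
#' @param coords 2-column coordinate matrix (ignored if `W` supplied).
#' @param scheme,k passed to [spatial_weights()].
#' @param W optional precomputed weight matrix.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List `I`, `expected`, `p`, `n`, `scheme`.
#' @export
morans_i <- function(values, coords = NULL, scheme = "knn", k = 8,
                     W = NULL, n_perm = 999, seed = 1) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  if (stats::sd(x) == 0) stop("values are constant; Moran's I undefined")
  if (is.null(W)) W <- spatial_weights(coords, scheme, k = k)
  stopifnot(nrow(W) == n, ncol(W) == n)

  s0 <- sum(W)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * drop(zc %*% W %*% zc) / sum(zc^2)
  }
  I <- stat(x)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(x[sample.int(n)]),
                 numeric(1))
  expected <- -1 / (n - 1)
  # two-sided: how extreme is the observed deviation from E[I]
  p <- (1 + sum(abs(perm - expected) >= abs(I - expected))) / (n_perm + 1)
  list(I = I, expected = expected, p = p, n = n,
       scheme = if (is.null(coords)) "supplied W" else scheme)
}

#' Moran's I test on the residuals of a mixed-model fit
#'
#' Residuals of point counts are tested for spatial autocorrelation at the
#' supplied coordinates (site centroids when point-level coordinates are
#' all a site has).
#'
#' @param fit an `lmm_fit`.
#' @param coords coordinates of the fit's observations (rows in the same
#'   order as the data passed to [fit_lmm()]).
#' @inheritParams morans_i
#' @return A [morans_i()] result.
#' @export
residual_moran <- function(fit, coords, scheme = "knn", k = 8,
                           n_perm = 999, seed = 1) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (is.null(fit$model)) stop("fit has no underlying model (flagged fit)")
  morans_i(stats::residuals(fit$model), coords, scheme = scheme, k = k,
           n_perm = n_perm, seed = seed)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Group-1 statistic convention: W = (rank sum of `x`) - n1 (n1 + 1) / 2,
#' so 0 <= W <= n1 n2, W = 0 when every `x` is below every `y` and
#' W = n1 n2 for the reverse.  The p-value is exact when n1 * n2 <= 400
#' and there are no ties, otherwise a normal approximation with tie
#' correction is used.
#'
#' @param x,y numeric vectors for the two groups (x = group 1).
#' @return Object of class `wilcoxon_result`: `W`, `p`, `n1`, `n2`,
#'   `exact`, `note`.
#' @export
wilcoxon_mw <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) * length(y) <= 400
  note <- NULL
  if (stats::sd(c(x, y)) == 0) {
    # fully tied input: no evidence of a shift
    return(structure(list(W = length(x) * length(y) / 2, p = 1,
                          n1 = length(x), n2 = length(y), exact = FALSE,
                          note = "all values tied"),
                     class = "wilcoxon_result"))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact))
  structure(list(W = unname(ht$statistic), p = ht$p.value,
                 n1 = length(x), n2 = length(y), exact = exact,
                 note = note),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon-Mann-Whitney: W =", x$W, ", p =", signif(x$p, 4),
      "(n1 =", x$n1, ", n2 =", paste0(x$n2, ")"),
      if (!is.null(x$note)) paste0("[", x$note, "]"), "\n")
  invisible(x)
}

#' Mean FD_freq SES test against zero
#'
#' Tests whether communities are on average functionally non-random:
#' mixed-model intercept test of SES ~ 1 + (1 | site), falling back to a
#' one-sample t-test when the mixed model is singular or sites are
#' unavailable.
#'
#' @param ses numeric SES values per point count.
#' @param site site ids (optional).
#' @return List `mean`, `se`, `t`, `p`, `method`.
#' @export
ses_zero_test <- function(ses, site = NULL) {
  ok <- is.finite(ses)
  ses <- ses[ok]
  if (!is.null(site)) site <- site[ok]
  if (!is.null(site) && length(unique(site)) >= 2) {
    fit <- tryCatch(
      lmerTest::lmer(ses ~ 1 + (1 | site),
                     data = data.frame(ses = ses, site = factor(site)),
                     REML = FALSE),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit)) {
      co <- stats::coef(summary(fit))
      return(list(mean = co[1, "Estimate"], se = co[1, "Std. Error"],
                  t = co[1, "t value"], p = co[1, ncol(co)],
                  method = "mixed-model intercept"))
    }
  }
  tt <- stats::t.test(ses)
  list(mean = unname(tt$estimate), se = stats::sd(ses) / sqrt(length(ses)),
       t = unname(tt$statistic), p = tt$p.value, method = "one-sample t")
}
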