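# Half-normal point-transect detection functions with covariates on the
# log-sigma scale, AIC subset selection, per-point detection probabilities,
# count-to-density conversion and the native/non-native detectability bias
# test.

#' Disc-averaged half-normal detection probability
#'
#' Probability that an individual present within the truncation radius `w`
#' is detected, under the half-normal distance-detection curve
#' g(r) = exp(-r^2 / (2 sigma^2)) and uniform-in-area placement (radial
#' density 2r/w^2).  Closed form:
#' p = (2 sigma^2 / w^2) (1 - exp(-w^2 / (2 sigma^2))).
#'
#' @param sigma half-normal scale parameter (m); vectorised.
#' @param w truncation radius (m).
#' @return Detection probability in (0, 1].
#' @export
halfnormal_p <- function(sigma, w = 100) {
  if (any(sigma <= 0) || any(w <= 0)) {
    stop("halfnormal_p requires sigma > 0 and w > 0")
  }
  z <- w^2 / (2 * sigma^2)
  # expm1 keeps precision when sigma >> w (p -> 1)
  -(expm1(-z)) / z
}

detection_covariates <- function() c("emergent", "trees_bushes", "flock_size")

# Design matrix for the log-sigma linear predictor. Availability proportions
# enter raw in [0,1]; flock size is log-transformed (right-skewed count).
detection_design <- function(obs_cov, covariates) {
  X <- matrix(1, nrow = nrow(obs_cov), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    x <- switch(cv,
                emergent = obs_cov$emergent,
                trees_bushes = obs_cov$trees_bushes,
                flock_size = log(obs_cov$flock_size),
                stop("unknown detection covariate: ", cv))
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

# Negative log conditional likelihood of the truncated point-transect
# half-normal: f(r | x) = g(r) r / integral_0^w g(s) s ds, with
# integral = sigma^2 (1 - exp(-w^2/(2 sigma^2))).
halfnormal_negloglik <- function(beta, r, X, w) {
  log_sigma <- drop(X %*% beta)
  sigma2 <- exp(2 * log_sigma)
  z <- w^2 / (2 * sigma2)
  log_norm <- 2 * log_sigma + log(-expm1(-z))
  -sum(-r^2 / (2 * sigma2) + log(r) - log_norm)
}

#' Fit a half-normal detection function to one species' distances
#'
#' Maximises the conditional (truncated) point-transect likelihood with
#' sigma = exp(beta0 + beta' x), where x may include the availability of
#' emergent vegetation and of trees and bushes at the point-count location
#' (both can obscure birds) and the log flock size (larger groups are
#' easier to detect).
#'
#' @param observations data.frame with columns `distance_m`, `flock_size`,
#'   `emergent`, `trees_bushes` (one row per detected flock; the two
#'   availability columns are the point-count grid proportions).
#' @param covariates subset of `c("emergent", "trees_bushes",
#'   "flock_size")` entering the log-sigma linear predictor.
#' @param w truncation radius (m).
#' @param min_detections minimum number of detections required to fit.
#' @param species_id optional label stored in the fit.
#' @return Object of class `detection_fit`: coefficients on the log-sigma
#'   scale, log-likelihood, AIC, number of detections.
#' @export
fit_halfnormal <- function(observations, covariates = character(0), w = 100,
                           min_detections = 20, species_id = NA_character_) {
  r <- observations$distance_m
  if (length(r) < min_detections) {
    stop("insufficient detections to fit a detection function (",
         length(r), " < ", min_detections, ")")
  }
  if (any(r < 0 | r > w)) stop("distances outside [0, w]")
  degenerate <- all(r < w * 1e-6)
  r <- pmax(r, w * 1e-6)  # log(r) guard; zero distances carry no shape information
  X <- detection_design(observations, covariates)
  k <- ncol(X)
  # the profile in log sigma flattens as sigma -> Inf, which strands
  # line-search optimizers; bracket the intercept first
  b0 <- stats::optimize(function(b) halfnormal_negloglik(
    c(b, rep(0, k - 1)), r, X, w), c(log(w) - 7, log(w) + 3), tol = 1e-10)
  if (k == 1) {
    beta <- stats::setNames(b0$minimum, colnames(X))
    ll <- -b0$objective
  } else {
    start <- c(b0$minimum, rep(0, k - 1))
    opt <- stats::optim(start, halfnormal_negloglik, r = r, X = X, w = w,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    polish <- tryCatch(
      stats::optim(opt$par, halfnormal_negloglik, r = r, X = X, w = w,
                   method = "BFGS", control = list(maxit = 200)),
      error = function(e) opt)
    if (polish$value <= opt$value) opt <- polish
    if (opt$convergence != 0 && !degenerate) {
      stop("detection function fit did not converge (optim code ",
           opt$convergence, ", species ", species_id, ")")
    }
    beta <- stats::setNames(opt$par, colnames(X))
    ll <- -opt$value
  }
  structure(list(species_id = species_id,
                 coefficients = beta,
                 covariates = covariates,
                 w = w,
                 loglik = ll,
                 aic = 2 * k - 2 * ll,
                 n_detections = length(r),
                 degenerate = degenerate),
            class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat("half-normal detection fit",
      if (!is.na(x$species_id)) paste0("[", x$species_id, "]"),
      "- n =", x$n_detections, ", AIC =", round(x$aic, 2), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict sigma from a detection fit
#'
#' @param object a `detection_fit`.
#' @param newdata data.frame holding the fit's covariates (`flock_size`
#'   where used; missing flock sizes default to the fitting sample's mean
#'   on the log scale, the value used for per-point predictions).
#' @param ... unused.
#' @return Vector of sigma values (m).
#' @export
predict_sigma <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  if ("flock_size" %in% object$covariates && is.null(nd$flock_size)) {
    nd$flock_size <- exp(object$mean_log_flock %||% 0)
  }
  X <- detection_design(nd, object$covariates)
  exp(drop(X %*% object$coefficients))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' AIC selection over all simplifications of the global detection model
#'
#' Fits every subset of the global covariate set (intercept always
#' included; 8 models for the default three covariates) and returns the
#' minimum-AIC fit.  AIC ties (difference below 1e-6) are broken toward
#' fewer parameters.
#'
#' @inheritParams fit_halfnormal
#' @param global_covariates covariates of the global model.
#' @return The selected `detection_fit`, with the full AIC table attached
#'   as attribute `aic_table`.
#' @export
select_model <- function(observations,
                         global_covariates = detection_covariates(),
                         w = 100, min_detections = 20,
                         species_id = NA_character_) {
  subsets <- list(character(0))
  for (cv in global_covariates) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, cv)))
  }
  fits <- vector("list", length(subsets))
  errs <- character(0)
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(
      fit_halfnormal(observations, subsets[[i]], w = w,
                     min_detections = min_detections, species_id = species_id),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("no detection submodel could be fitted for species ", species_id,
         ": ", errs[1])
  }
  aic <- vapply(fits[ok], function(f) f$aic, numeric(1))
  npar <- vapply(fits[ok], function(f) length(f$coefficients), numeric(1))
  # tie-break toward fewer parameters
  best <- order(round(aic / 1e-6) * 1e-6, npar)[1]
  fit <- fits[ok][[best]]
  fit$mean_log_flock <- mean(log(observations$flock_size))
  attr(fit, "aic_table") <- data.frame(
    model = vapply(subsets[ok], function(s)
      if (length(s) == 0) "1" else paste(s, collapse = "+"), character(1)),
    k = npar, aic = aic, delta_aic = aic - min(aic))
  fit
}

# Per-flock covariate rows for one species' observations, joining the
# point-count availability grid.
species_detection_data <- function(dataset, species_id) {
  obs <- dataset$observations[dataset$observations$species_id == species_id, ,
                              drop = FALSE]
  pc <- dataset$point_counts
  idx <- match(obs$point_id, pc$point_id)
  data.frame(point_id = obs$point_id,
             distance_m = obs$distance_m,
             flock_size = obs$flock_size,
             emergent = pc$avail_emergent[idx],
             trees_bushes = pc$avail_trees_bushes[idx],
             stringsAsFactors = FALSE)
}

#' Fit AIC-selected detection functions for every sufficiently recorded species
#'
#' @param dataset a `survey_dataset`.
#' @param min_detections species with fewer detected flocks are left
#'   unmodelled (and excluded from density analyses), mirroring field
#'   practice for sparsely recorded species.
#' @inheritParams select_model
#' @return List with `fits` (named list of `detection_fit`) and
#'   `unmodelled` (character vector of species left out, with counts as
#'   names attribute).
#' @export
fit_all_species <- function(dataset, min_detections = 20,
                            global_covariates = detection_covariates(),
                            w = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (is.null(w)) w <- dataset$truncation_m
  fits <- list()
  unmodelled <- character(0)
  for (sp in dataset$species$species_id) {
    dd <- species_detection_data(dataset, sp)
    if (nrow(dd) < min_detections) {
      unmodelled <- c(unmodelled, sp)
      next
    }
    fit <- tryCatch(
      select_model(dd, global_covariates, w = w,
                   min_detections = min_detections, species_id = sp),
      error = function(e) NULL)
    if (is.null(fit)) unmodelled <- c(unmodelled, sp) else fits[[sp]] <- fit
  }
  list(fits = fits, unmodelled = unmodelled)
}

#' Predict per-point detection probabilities
#'
#' For each fitted species, predicts the disc-averaged detection
#' probability at every point-count location from the location's emergent
#' and trees-and-bushes availability (flock size, where selected, is held
#' at the species' mean log flock size).
#'
#' @param dataset a `survey_dataset`.
#' @param fits named list of `detection_fit` (from [fit_all_species()]).
#' @return data.frame `point_id`, `species_id`, `sigma`, `p`.
#' @export
predict_detection <- function(dataset, fits) {
  pc <- dataset$point_counts
  if (length(fits) == 0) {
    return(data.frame(point_id = character(), species_id = character(),
                      sigma = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(names(fits), function(sp) {
    fit <- fits[[sp]]
    nd <- data.frame(emergent = pc$avail_emergent,
                     trees_bushes = pc$avail_trees_bushes,
                     flock_size = exp(fit$mean_log_flock %||% 0))
    sigma <- predict_sigma(fit, nd)
    data.frame(point_id = pc$point_id, species_id = sp,
               sigma = sigma, p = halfnormal_p(sigma, fit$w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detectability-corrected densities per point count and species
#'
#' Density = total individuals counted (sum of flock sizes) divided by the
#' predicted detection probability at that point-count location.  Species
#' without a detection fit are omitted (and listed in the `omitted`
#' attribute).  Densities are per surveyed disc; zero counts give zero
#' density.
#'
#' @param dataset a `survey_dataset`.
#' @param fits named list of `detection_fit`.
#' @param p_floor detection probabilities below this floor are capped (with
#'   a warning and a `capped` flag) to avoid exploding densities.
#' @return data.frame `point_id`, `species_id`, `count`, `p`, `density`,
#'   `capped`.
#' @export
estimate_density <- function(dataset, fits, p_floor = 1e-3) {
  preds <- predict_detection(dataset, fits)
  obs <- dataset$observations
  if (nrow(preds) == 0) {
    out <- data.frame(point_id = character(), species_id = character(),
                      count = numeric(), p = numeric(), density = numeric(),
                      capped = logical(), stringsAsFactors = FALSE)
    attr(out, "omitted") <- unique(obs$species_id)
    return(out)
  }
  key <- paste(preds$point_id, preds$species_id)
  counts <- tapply(obs$flock_size, paste(obs$point_id, obs$species_id), sum)
  cnt <- counts[key]
  cnt[is.na(cnt)] <- 0
  capped <- preds$p < p_floor
  if (any(capped)) {
    warning(sum(capped), " detection probabilit(ies) below the ", p_floor,
            " floor were capped")
  }
  p_eff <- pmax(preds$p, p_floor)
  out <- data.frame(point_id = preds$point_id,
                    species_id = preds$species_id,
                    count = as.numeric(cnt),
                    p = preds$p,
                    density = as.numeric(cnt) / p_eff,
                    capped = capped,
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- setdiff(unique(obs$species_id), names(fits))
  out
}

#' Test for a native/non-native detectability bias between habitats
#'
#' Models the predicted detection probability of each species at each point
#' count as a function of non-native status, rice-field status and their
#' interaction, with a site random intercept.  A significant interaction
#' indicates detectability differs between habitats differently for native
#' and non-native species, which would bias presence/density contrasts.
#'
#' @param dataset a `survey_dataset`.
#' @param predictions data.frame from [predict_detection()].
#' @return List with `estimate`, `t`, `p` for the interaction term, the
#'   fitted `model`, and `random_effect` (FALSE when a single site forced a
#'   plain linear model).
#' @export
detectability_bias_test <- function(dataset, predictions) {
  sp <- dataset$species
  pc <- dataset$point_counts
  d <- predictions
  d$nonnative <- sp$status[match(d$species_id, sp$species_id)] == "nonnative"
  idx <- match(d$point_id, pc$point_id)
  d$rice <- pc$is_rice[idx]
  d$site_id <- pc$site_id[idx]
  if (sum(tapply(d$nonnative, d$species_id, any)) < 1 ||
      length(unique(d$species_id[d$nonnative])) < 2 ||
      length(unique(d$species_id[!d$nonnative])) < 2) {
    stop("bias test needs at least two species of each status")
  }
  single_site <- length(unique(d$site_id)) < 2
  if (single_site) {
    fit <- stats::lm(p ~ nonnative * rice, data = d)
    co <- summary(fit)$coefficients
  } else {
    fit <- tryCatch(
      lmerTest::lmer(p ~ nonnative * rice + (1 | site_id), data = d,
                     REML = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit)) {
      warning("mixed model singular or failed; falling back to a linear ",
              "model without the site random effect")
      fit <- stats::lm(p ~ nonnative * rice, data = d)
      single_site <- TRUE
      co <- summary(fit)$coefficients
    } else {
      co <- stats::coef(summary(fit))
    }
  }
  row <- grep(":", rownames(co))
  list(estimate = co[row, "Estimate"],
       t = co[row, "t value"],
       p = co[row, ncol(co)],
       model = fit,
       random_effect = !single_site)
}
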