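test_that("disc-averaged half-normal p matches numerical integration", {
  for (sigma in c(1, 5, 10, 40, 100, 1000, 1e5)) {
    expect_equal(halfnormal_p(sigma, 100), halfnormal_p_numeric(sigma, 100),
                 tolerance = 1e-8)
  }
  expect_equal(halfnormal_p(1e6, 100), 1, tolerance = 1e-6)
  expect_equal(halfnormal_p(100, 100), 0.78694, tolerance = 1e-5)
  expect_equal(halfnormal_p(10, 100), 0.02, tolerance = 1e-4)
  expect_error(halfnormal_p(-1, 100), "sigma")
  expect_error(halfnormal_p(10, 0), "w")
})

test_that("half-normal p is strictly increasing in sigma", {
  sigmas <- exp(seq(log(1), log(1e5), length.out = 60))
  p <- halfnormal_p(sigmas, 100)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("sigma is recovered from simulated detections", {
  set.seed(101)
  r <- simulate_detected_distances(500, sigma = 40, w = 100)
  fit <- fit_halfnormal(data.frame(distance_m = r, flock_size = 1),
                        covariates = character(0), w = 100)
  sigma_hat <- exp(fit$coefficients[["(Intercept)"]])
  expect_lt(abs(sigma_hat - 40) / 40, 0.10)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
})

test_that("the fitted likelihood beats perturbed parameters", {
  set.seed(7)
  r <- simulate_detected_distances(300, sigma = 35, w = 100)
  fit <- fit_halfnormal(data.frame(distance_m = r, flock_size = 1), w = 100)
  nll <- function(b) guildfill:::halfnormal_negloglik(
    b, r, matrix(1, length(r), 1), 100)
  at_mle <- nll(fit$coefficients)
  for (delta in c(-0.2, -0.05, 0.05, 0.2)) {
    expect_gt(nll(fit$coefficients + delta), at_mle)
  }
})

test_that("all-zero distances hit the lower bound and are flagged", {
  fit <- fit_halfnormal(data.frame(distance_m = rep(0, 30), flock_size = 1),
                        w = 100, min_detections = 20)
  expect_true(fit$degenerate)
  expect_lt(exp(fit$coefficients[["(Intercept)"]]), 1)
})

test_that("too few detections raise an insufficiency error", {
  expect_error(
    fit_halfnormal(data.frame(distance_m = c(10, 20), flock_size = 1),
                   w = 100, min_detections = 20),
    "insufficient")
})

test_that("AIC selection keeps a real covariate and drops a null one", {
  set.seed(202)
  n <- 500
  with_effect <- 0
  without_effect <- 0
  n_rep <- 10
  for (rep in seq_len(n_rep)) {
    emergent <- stats::runif(n)
    # strong emergent effect on log sigma
    sigma <- 40 * exp(-1.2 * emergent)
    r <- vapply(sigma, function(s) simulate_detected_distances(1, s), numeric(1))
    dd <- data.frame(distance_m = r, flock_size = 1,
                     emergent = emergent, trees_bushes = stats::runif(n))
    sel <- select_model(dd, c("emergent", "trees_bushes"), w = 100)
    if ("emergent" %in% sel$covariates) with_effect <- with_effect + 1

    r0 <- simulate_detected_distances(n, 40)
    dd0 <- data.frame(distance_m = r0, flock_size = 1,
                      emergent = emergent, trees_bushes = stats::runif(n))
    sel0 <- select_model(dd0, c("emergent", "trees_bushes"), w = 100)
    if (length(sel0$covariates) == 0) without_effect <- without_effect + 1
  }
  expect_gte(with_effect / n_rep, 0.8)
  expect_gte(without_effect / n_rep, 0.5)  # intercept-only selected most often
})

test_that("AIC ties break toward fewer parameters", {
  set.seed(11)
  r <- simulate_detected_distances(100, 40)
  dd <- data.frame(distance_m = r, flock_size = 1,
                   emergent = 0.3, trees_bushes = 0.3)  # constant covariates
  # constant covariates make submodels equivalent up to reparameterisation;
  # optim reaches the same likelihood, so AIC separates them by k alone
  sel <- select_model(dd, c("emergent"), w = 100)
  expect_length(sel$covariates, 0)
})

test_that("density follows the count / p definition", {
  ds <- toy_dataset()
  fit <- structure(list(species_id = "A",
                        coefficients = c("(Intercept)" = log(1e6)),
                        covariates = character(0), w = 100,
                        loglik = 0, aic = 2, n_detections = 2,
                        degenerate = FALSE, mean_log_flock = 0),
                   class = "detection_fit")
  dens <- estimate_density(ds, list(A = fit))
  # p ~ 1 everywhere, so density equals the summed flock sizes
  expect_equal(dens$density[dens$point_id == "P1" & dens$species_id == "A"], 3,
               tolerance = 1e-4)
  expect_equal(dens$density[dens$point_id == "P3" & dens$species_id == "A"], 0)
  expect_true(all(dens$density >= dens$count - 1e-9))
  expect_identical(setdiff(attr(dens, "omitted"), "A"), "B")
})

test_that("species below the detection minimum are left unmodelled", {
  sim <- generate_survey(tiny_config(), seed = 10)
  res <- fit_all_species(sim$dataset, min_detections = 20)
  counts <- table(sim$dataset$observations$species_id)
  for (sp in names(res$fits)) expect_gte(counts[[sp]], 20)
  for (sp in res$unmodelled) {
    n <- if (sp %in% names(counts)) counts[[sp]] else 0
    expect_lt(n, 20)
  }
  dens <- suppressWarnings(estimate_density(sim$dataset, res$fits))
  expect_false(any(res$unmodelled %in% dens$species_id))
})

test_that("density recovery: corrected densities are unbiased for the truth", {
  cfg <- tiny_config(25, 8)
  sim <- generate_survey(cfg, seed = 77)
  expect_gte(nrow(sim$dataset$point_counts), 200)
  res <- fit_all_species(sim$dataset, min_detections = 20)
  sp <- "NON01"
  skip_if(is.null(res$fits[[sp]]))
  dens <- suppressWarnings(estimate_density(sim$dataset, res$fits))
  d <- dens[dens$species_id == sp, ]
  truth <- sim$truth$individuals[d$point_id, sp]
  err <- d$density - truth
  se <- stats::sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 1e-8)
})

test_that("bias test returns the interaction and degrades gracefully", {
  sim <- generate_survey(tiny_config(20, 6), seed = 55)
  res <- fit_all_species(sim$dataset, min_detections = 20)
  preds <- predict_detection(sim$dataset, res$fits)
  bt <- tryCatch(detectability_bias_test(sim$dataset, preds),
                 warning = function(w) suppressWarnings(
                   detectability_bias_test(sim$dataset, preds)))
  expect_true(is.finite(bt$t))
  expect_true(bt$p >= 0 && bt$p <= 1)

  # single site: falls back to a plain linear model
  one <- sim$dataset
  keep <- one$point_counts$site_id == one$point_counts$site_id[1]
  one$point_counts <- one$point_counts[keep, ]
  one$observations <- one$observations[
    one$observations$point_id %in% one$point_counts$point_id, ]
  preds1 <- predict_detection(one, res$fits)
  has_both <- length(unique(one$point_counts$is_rice)) == 2
  skip_if_not(has_both)
  bt1 <- detectability_bias_test(one, preds1)
  expect_false(bt1$random_effect)
})

test_that("a constructed native-higher-in-rice dataset gives the reported sign", {
  # detection probabilities constructed so that native p is elevated only in
  # rice fields: the nonnative:rice interaction must be negative (equivalently
  # the native:rice effect positive, native species detected better in rice)
  set.seed(3)
  species <- data.frame(species_id = c("n1", "n2", "x1", "x2"),
                        common_name = c("n1", "n2", "x1", "x2"),
                        status = c("native", "native", "nonnative", "nonnative"),
                        body_mass_g = c(25, 30, 14, 16))
  pc <- data.frame(site_id = rep(sprintf("S%d", 1:10), each = 8),
                   point_id = sprintf("P%02d", 1:80),
                   year = 2011L,
                   habitat_class = rep(c("rice", "agriculture"), 40),
                   x = runif(80), y = runif(80),
                   avail_forbs = 0.2, avail_rough_grass = 0.2,
                   avail_emergent = 0.2, avail_trees_bushes = 0.2)
  obs <- data.frame(point_id = character(), species_id = character(),
                    distance_m = numeric(), flock_size = integer(),
                    activity = character(), resource_used = character())
  ds <- survey_dataset(species, pc, obs)
  preds <- expand.grid(point_id = pc$point_id,
                       species_id = species$species_id,
                       stringsAsFactors = FALSE)
  native <- preds$species_id %in% c("n1", "n2")
  rice <- pc$habitat_class[match(preds$point_id, pc$point_id)] == "rice"
  preds$sigma <- 40
  preds$p <- 0.5 + 0.2 * (native & rice) + rnorm(nrow(preds), 0, 0.02)
  # no between-site variance was built in, so the singular-fit fallback
  # to a plain linear model is the expected path here
  bt <- suppressWarnings(detectability_bias_test(ds, preds))
  expect_lt(bt$estimate, 0)
  expect_lt(bt$p, 0.05)
})
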