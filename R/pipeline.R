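# End-to-end orchestration: import -> detectability -> densities ->
# resource selection -> functional diversity / SES -> habitat gradients ->
# mixed-model inference, with seeds and a JSON manifest.

#' Run the full analysis pipeline
#'
#' Executes, in order: dataset validation; per-species half-normal
#' detection-function fitting with AIC model selection; per-point
#' detection probabilities, the native/non-native detectability bias test
#' and detectability-corrected densities; Jacobs-index resource selection
#' for feeding and shelter with native vs non-native comparisons;
#' Gower-distance trait dendrogram (linkage chosen by cophenetic
#' correlation), branch-length FD per point count, null-model SES and the
#' packing correlation; habitat-gradient group profiles and the position
#' of maximal divergence; and site-random-effect likelihood-ratio tests of
#' rice-field effects on group density, richness and FD, with Moran's I
#' residual diagnostics.  Stages needing inputs that are absent (traits,
#' quadrats, gradient scores) are skipped and recorded in the manifest.
#'
#' @param dataset a `survey_dataset`.
#' @param traits optional [trait_table()] covering (at least) the dataset's
#'   species; required for the functional-diversity stage.
#' @param gradient_scores optional species x habitat association score
#'   matrix for the gradient stage.
#' @param gradients list of [gradient()] objects; defaults to
#'   [default_gradients()].
#' @param min_detections minimum detections to fit a detection function.
#' @param availability_mode `"occupied"` or `"all"` (see [availability()]).
#' @param null_model `"frequency"` or `"uniform"` (see [null_ses()]).
#' @param n_iter null-model iterations.
#' @param seed RNG seed governing every stochastic stage.
#' @param moran_k neighbours for the Moran's I weight matrix.
#' @param n_perm Moran permutation count.
#' @param out_dir optional directory; when given, result tables are
#'   written as CSVs plus a `manifest.json`.
#' @return List of class `guildfill_run` with elements `validation`,
#'   `detection`, `densities`, `selection`, `fd`, `gradients`,
#'   `inference`, `quadrats`, `manifest`.
#' @export
run_pipeline <- function(dataset, traits = NULL, gradient_scores = NULL,
                         gradients = default_gradients(),
                         min_detections = 20,
                         availability_mode = "occupied",
                         null_model = "frequency", n_iter = 1000,
                         seed = 1, moran_k = 8, n_perm = 999,
                         out_dir = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  stage <- "validate"
  res <- list()
  manifest <- list(seed = seed, min_detections = min_detections,
                   availability_mode = availability_mode,
                   null_model = null_model, n_iter = n_iter,
                   truncation_m = dataset$truncation_m,
                   n_sites = length(unique(dataset$point_counts$site_id)),
                   n_point_counts = nrow(dataset$point_counts),
                   n_observations = nrow(dataset$observations),
                   stages = character(0))
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)

  res$validation <- tryCatch(validate_survey(dataset), error = fail)
  if (nrow(res$validation) > 0) {
    stop("pipeline stage 'validate' failed: dataset has ",
         nrow(res$validation), " invariant violation(s)", call. = FALSE)
  }
  manifest$stages <- c(manifest$stages, stage)

  stage <- "detectability"
  res$detection <- tryCatch({
    all_fits <- fit_all_species(dataset, min_detections = min_detections)
    preds <- predict_detection(dataset, all_fits$fits)
    bias <- tryCatch(detectability_bias_test(dataset, preds),
                     error = function(e) NULL)
    list(fits = all_fits$fits, unmodelled = all_fits$unmodelled,
         predictions = preds, bias_test = bias)
  }, error = fail)
  manifest$stages <- c(manifest$stages, stage)

  stage <- "density"
  dens <- tryCatch(estimate_density(dataset, res$detection$fits), error = fail)
  res$densities <- dens
  dataset <- attach_densities(dataset, dens)
  manifest$stages <- c(manifest$stages, stage)

  stage <- "resource_selection"
  res$selection <- tryCatch({
    tabs <- lapply(c(feeding = "feeding", shelter = "shelter"), function(a)
      selection_table(dataset, a, availability_mode = availability_mode))
    comps <- list()
    for (a in names(tabs)) {
      for (r in resource_classes()) {
        cmp <- tryCatch(compare_selection(tabs[[a]], r), error = function(e) NULL)
        if (!is.null(cmp)) comps[[paste(a, r, sep = ".")]] <- cmp
      }
    }
    list(tables = tabs, comparisons = comps)
  }, error = fail)
  manifest$stages <- c(manifest$stages, stage)

  pc <- dataset$point_counts
  site <- pc$site_id
  rice <- pc$is_rice
  native_sp <- dataset$species$species_id[dataset$species$status == "native"]
  nonnative_sp <- dataset$species$species_id[dataset$species$status == "nonnative"]

  stage <- "functional_diversity"
  if (!is.null(traits)) {
    res$fd <- tryCatch({
      d <- gower_distance(traits)
      model <- select_linkage(d)
      presence_all <- build_community_matrix(dataset, "presence")
      presence_nat <- build_community_matrix(dataset, "presence",
                                             species = native_sp)
      ses_all <- null_ses(presence_all, model, null = null_model,
                          n_iter = n_iter, seed = seed)
      ses_nat <- null_ses(presence_nat, model, null = null_model,
                          n_iter = n_iter, seed = seed + 1)
      packing <- tryCatch(packing_correlation(ses_all), error = function(e) NULL)
      zero_test <- tryCatch(ses_zero_test(ses_nat$ses, site),
                            error = function(e) NULL)
      list(dendrogram = model, ses_all = ses_all, ses_native = ses_nat,
           packing = packing, ses_zero_test = zero_test)
    }, error = fail)
    manifest$stages <- c(manifest$stages, stage)
    manifest$linkage <- res$fd$dendrogram$linkage
    manifest$cophenetic_r <- res$fd$dendrogram$coph_corr
  }

  stage <- "habitat_gradients"
  if (!is.null(gradient_scores)) {
    res$gradients <- tryCatch({
      lapply(gradients, function(g) {
        prof <- group_profile(gradient_scores, g, dataset$species)
        list(profile = prof, max_divergence = max_divergence_position(prof))
      })
    }, error = fail)
    manifest$stages <- c(manifest$stages, stage)
  }

  stage <- "inference"
  res$inference <- tryCatch({
    dmat <- build_community_matrix(dataset, "density")
    pres <- build_community_matrix(dataset, "presence")
    tests <- list()
    run_test <- function(y) tryCatch(rice_effect_test(y, rice, site),
                                     error = function(e) NULL)
    nat_fitted <- intersect(native_sp, colnames(dmat)[colnames(dmat) %in%
                              names(res$detection$fits)])
    non_fitted <- intersect(nonnative_sp, names(res$detection$fits))
    tests$native_density <- run_test(rowSums(dmat[, nat_fitted, drop = FALSE]))
    tests$nonnative_density <- run_test(rowSums(dmat[, non_fitted, drop = FALSE]))
    tests$native_richness <- run_test(rowSums(pres[, intersect(native_sp,
                                colnames(pres)), drop = FALSE]))
    tests$nonnative_richness <- run_test(rowSums(pres[, intersect(nonnative_sp,
                                colnames(pres)), drop = FALSE]))
    if (!is.null(res$fd)) {
      tests$native_fd <- run_test(res$fd$ses_native$fd_obs)
      tests$all_fd <- run_test(res$fd$ses_all$fd_obs)
      tests$native_fd_ses <- run_test(res$fd$ses_native$ses)
    }
    for (r in resource_classes()) {
      tests[[paste0("avail_", r)]] <- run_test(pc[[paste0("avail_", r)]])
    }
    moran <- lapply(tests, function(t) {
      if (is.null(t) || is.null(t$full$model)) return(NULL)
      tryCatch(residual_moran(t$full, cbind(pc$x, pc$y), k = moran_k,
                              n_perm = n_perm, seed = seed),
               error = function(e) NULL)
    })
    list(tests = tests, residual_moran = moran)
  }, error = fail)
  manifest$stages <- c(manifest$stages, stage)

  stage <- "quadrats"
  if (!is.null(dataset$quadrats)) {
    res$quadrats <- tryCatch({
      qs <- quadrat_summary(dataset)
      list(summary = qs,
           cwm_test = wilcoxon_mw(
             qs$cwm_capacity_g[qs$habitat == "rice_margin"],
             qs$cwm_capacity_g[qs$habitat == "other_grassland"]),
           richness_test = wilcoxon_mw(
             qs$plant_richness[qs$habitat == "rice_margin"],
             qs$plant_richness[qs$habitat == "other_grassland"]))
    }, error = fail)
    manifest$stages <- c(manifest$stages, stage)
  }

  res$manifest <- manifest
  class(res) <- "guildfill_run"
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.guildfill_run <- function(x, ...) {
  cat("guildfill pipeline run:", length(x$manifest$stages), "stages (",
      paste(x$manifest$stages, collapse = ", "), ")\n")
  invisible(x)
}

# Serialise a pipeline run to CSV tables plus a JSON manifest.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(out_dir, name), row.names = FALSE)
  if (length(run$detection$fits) > 0) {
    wcsv(do.call(rbind, lapply(run$detection$fits, function(f)
      data.frame(species_id = f$species_id,
                 model = paste(if (length(f$covariates) == 0) "1"
                               else f$covariates, collapse = "+"),
                 n_detections = f$n_detections,
                 loglik = f$loglik, aic = f$aic))), "fits.csv")
  }
  wcsv(run$detection$predictions, "predictions.csv")
  wcsv(run$densities, "densities.csv")
  wcsv(do.call(rbind, run$selection$tables), "selection.csv")
  if (!is.null(run$fd)) {
    wcsv(run$fd$ses_all, "fd_all.csv")
    wcsv(run$fd$ses_native, "fd_native.csv")
    write_dendrogram_newick(run$fd$dendrogram,
                            file.path(out_dir, "dendrogram.nwk"))
  }
  if (!is.null(run$gradients)) {
    wcsv(do.call(rbind, lapply(run$gradients, `[[`, "profile")), "profiles.csv")
  }
  if (!is.null(run$quadrats)) wcsv(run$quadrats$summary, "cwm.csv")
  tests <- run$inference$tests
  ok <- !vapply(tests, is.null, logical(1))
  wcsv(data.frame(response = names(tests)[ok],
                  chisq = vapply(tests[ok], `[[`, numeric(1), "chisq"),
                  df = vapply(tests[ok], `[[`, numeric(1), "df"),
                  p = vapply(tests[ok], `[[`, numeric(1), "p"),
                  estimate = vapply(tests[ok], `[[`, numeric(1), "estimate")),
       "results.csv")
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Guild summary statistics from survey and trait tables
#'
#' Computes the descriptive statistics used to characterise the guild:
#' per-species occupancy (point counts present, split by rice/other), the
#' native vs non-native body-mass comparison (group means, SEs, their
#' difference and the rank-sum test, native group first) and, when a trait
#' table is supplied, the average-linkage cophenetic correlation of the
#' trait dendrogram.
#'
#' @param dataset a `survey_dataset`.
#' @param traits optional [trait_table()].
#' @return List `occupancy` (data.frame), `body_mass` (list), and
#'   optionally `cophenetic_r`.
#' @export
guild_summary <- function(dataset, traits = NULL) {
  pres <- build_community_matrix(dataset, "presence")
  pc <- dataset$point_counts
  occ <- data.frame(
    species_id = colnames(pres),
    n_point_counts = colSums(pres),
    n_rice = colSums(pres[pc$is_rice, , drop = FALSE]),
    n_other = colSums(pres[!pc$is_rice, , drop = FALSE]),
    n_sites = vapply(colnames(pres), function(s)
      length(unique(pc$site_id[pres[, s] > 0])), numeric(1)),
    row.names = NULL)
  occ$total_point_counts <- nrow(pres)

  sp <- dataset$species
  mn <- sp$body_mass_g[sp$status == "native"]
  mx <- sp$body_mass_g[sp$status == "nonnative"]
  se <- function(v) stats::sd(v) / sqrt(length(v))
  body_mass <- list(native_mean = mean(mn), native_se = se(mn),
                    nonnative_mean = mean(mx), nonnative_se = se(mx),
                    difference = mean(mn) - mean(mx),
                    test = wilcoxon_mw(mn, mx))
  out <- list(occupancy = occ, body_mass = body_mass)
  if (!is.null(traits)) {
    model <- select_linkage(gower_distance(traits))
    out$cophenetic_r <- model$coph_corr
    out$linkage <- model$linkage
  }
  out
}
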