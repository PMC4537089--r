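# Synthetic survey generator with known ground truth: point-count surveys,
# trait tables, quadrat vegetation data and habitat-association scores
# emulating the structure of the rice-field study system.

#' Scenario configuration for the survey generator
#'
#' @param species_pool data.frame, one row per species, with columns
#'   `species_id`, `common_name`, `status`, `body_mass_g`, `lambda_rice`,
#'   `lambda_other` (expected flocks per point count by habitat),
#'   `sigma0` (baseline half-normal scale, m), `beta_emergent`,
#'   `beta_trees_bushes`, `beta_flock` (log-sigma covariate effects),
#'   `mean_flock` (expected flock size, >= 1).
#' @param resource_probs named list per species; each element a list with
#'   `feeding` and `shelter` probability vectors over
#'   `c(resource_classes(), "none")` (each summing to 1).
#' @param activity_probs length-3 probability vector over
#'   `c("feeding", "shelter", "other")`.
#' @param n_rice_sites,n_other_sites numbers of sites with and without
#'   rice fields.
#' @param points_mean,points_sd,points_range per-site point-count number:
#'   drawn from a rounded normal clipped to the range.
#' @param rice_fraction probability a point at a rice site falls in a rice
#'   field (the rest sample the adjacent open habitats).
#' @param availability_beta list habitat_class -> 2-column matrix (rows =
#'   vegetation classes, columns = Beta shape1/shape2) governing grid
#'   availability proportions; proportions are snapped to k/49.
#' @param site_sd SD of the lognormal site effect multiplying every
#'   species' expected flock count at that site.
#' @param truncation_m survey radius (m).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(species_pool, resource_probs, activity_probs,
                            n_rice_sites, n_other_sites,
                            points_mean = 7.5, points_sd = 3.3,
                            points_range = c(1, 16),
                            rice_fraction = 0.5,
                            availability_beta,
                            site_sd = 0.4,
                            truncation_m = 100) {
  stopifnot(all(species_pool$lambda_rice >= 0),
            all(species_pool$lambda_other >= 0),
            all(species_pool$sigma0 > 0),
            all(species_pool$mean_flock >= 1))
  res_levels <- c(resource_classes(), "none")
  for (sp in species_pool$species_id) {
    rp <- resource_probs[[sp]]
    if (is.null(rp)) stop("no resource probabilities for species ", sp)
    for (act in c("feeding", "shelter")) {
      p <- rp[[act]][res_levels]
      if (any(is.na(p)) || abs(sum(p) - 1) > 1e-8) {
        stop("resource probabilities for ", sp, "/", act,
             " must cover ", paste(res_levels, collapse = ","),
             " and sum to 1")
      }
    }
  }
  stopifnot(abs(sum(activity_probs) - 1) < 1e-8)
  structure(list(species_pool = species_pool,
                 resource_probs = resource_probs,
                 activity_probs = activity_probs,
                 n_rice_sites = n_rice_sites,
                 n_other_sites = n_other_sites,
                 points_mean = points_mean, points_sd = points_sd,
                 points_range = points_range,
                 rice_fraction = rice_fraction,
                 availability_beta = availability_beta,
                 site_sd = site_sd,
                 truncation_m = truncation_m),
            class = "scenario_config")
}

# Snap a proportion onto the 49-cell recording grid.
snap_grid <- function(p, cells = 49) round(p * cells) / cells

#' Generate a synthetic point-count survey with ground truth
#'
#' Simulation model: each site carries a lognormal quality effect; the
#' number of flocks of each species at each point is Poisson(lambda_habitat
#' x site effect); flock sizes are 1 + Poisson(mean_flock - 1); flocks are
#' placed uniformly in area over the 100 m disc (radial density 2r/w^2, so
#' r = w sqrt(U)); a flock at distance r is detected with probability
#' exp(-r^2 / (2 sigma^2)) with sigma = sigma0 exp(beta' x) depending on
#' the point's emergent and trees-and-bushes availability and the log
#' flock size; detected flocks receive an activity and a used resource
#' drawn from the configured multinomials, restricted to the resources
#' locally available on the grid.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed; identical seeds give identical output.
#' @return List `dataset` (a `survey_dataset`) and `truth` (list with
#'   per-point true abundance matrices `individuals` and `flocks`, the
#'   per-point sigma matrix, and the generating config).
#' @export
generate_survey <- function(config, seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  sp <- config$species_pool
  w <- config$truncation_m
  res_levels <- c(resource_classes(), "none")

  if (all(sp$lambda_rice == 0) && all(sp$lambda_other == 0)) {
    warning("all expected densities are zero; the survey will hold no observations")
  }

  n_sites <- config$n_rice_sites + config$n_other_sites
  sites <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    has_rice = rep(c(TRUE, FALSE), c(config$n_rice_sites, config$n_other_sites)),
    cx = stats::runif(n_sites, 0, 300), # km-scale landscape
    cy = stats::runif(n_sites, 0, 300),
    effect = exp(stats::rnorm(n_sites, 0, config$site_sd)))

  pcs <- list()
  for (i in seq_len(n_sites)) {
    npt <- round(stats::rnorm(1, config$points_mean, config$points_sd))
    npt <- min(max(npt, config$points_range[1]), config$points_range[2])
    hab <- if (sites$has_rice[i]) {
      ifelse(stats::runif(npt) < config$rice_fraction, "rice",
             sample(c("agriculture", "river", "wetland"), npt, replace = TRUE,
                    prob = c(0.5, 0.2, 0.3)))
    } else {
      sample(c("agriculture", "river", "wetland"), npt, replace = TRUE,
             prob = c(0.5, 0.2, 0.3))
    }
    avail <- t(vapply(hab, function(h) {
      ab <- config$availability_beta[[h]]
      snap_grid(stats::rbeta(nrow(ab), ab[, 1], ab[, 2]))
    }, numeric(length(resource_classes()))))
    colnames(avail) <- availability_columns()
    pcs[[i]] <- data.frame(
      site_id = sites$site_id[i],
      point_id = sprintf("%s_P%02d", sites$site_id[i], seq_len(npt)),
      year = 2011L,
      habitat_class = hab,
      x = sites$cx[i] + stats::runif(npt, -1, 1),
      y = sites$cy[i] + stats::runif(npt, -1, 1),
      avail, stringsAsFactors = FALSE, row.names = NULL)
  }
  pc <- do.call(rbind, pcs)
  npts <- nrow(pc)

  true_ind <- true_flk <- sig_mat <- matrix(
    0, nrow = npts, ncol = nrow(sp),
    dimnames = list(pc$point_id, sp$species_id))

  obs <- list()
  site_eff <- sites$effect[match(pc$site_id, sites$site_id)]
  for (j in seq_len(nrow(sp))) {
    lambda <- ifelse(pc$habitat_class == "rice",
                     sp$lambda_rice[j], sp$lambda_other[j]) * site_eff
    nfl <- stats::rpois(npts, lambda)
    true_flk[, j] <- nfl
    rp <- config$resource_probs[[sp$species_id[j]]]
    for (i in which(nfl > 0)) {
      sizes <- 1 + stats::rpois(nfl[i], max(sp$mean_flock[j] - 1, 0))
      true_ind[i, j] <- sum(sizes)
      r <- w * sqrt(stats::runif(nfl[i]))
      sigma <- sp$sigma0[j] * exp(sp$beta_emergent[j] * pc$avail_emergent[i] +
                                  sp$beta_trees_bushes[j] * pc$avail_trees_bushes[i] +
                                  sp$beta_flock[j] * log(sizes))
      detected <- stats::runif(nfl[i]) < exp(-r^2 / (2 * sigma^2))
      if (!any(detected)) next
      for (f in which(detected)) {
        act <- sample(activity_levels(), 1, prob = config$activity_probs)
        if (act == "other") {
          res <- "none"
        } else {
          p <- rp[[act]][res_levels]
          local <- c(pc$avail_forbs[i], pc$avail_rough_grass[i],
                     pc$avail_emergent[i], pc$avail_trees_bushes[i], 1) > 0
          p <- p * local
          res <- if (sum(p) == 0) "none" else
            sample(res_levels, 1, prob = p / sum(p))
        }
        obs[[length(obs) + 1]] <- data.frame(
          point_id = pc$point_id[i],
          species_id = sp$species_id[j],
          distance_m = r[f],
          flock_size = sizes[f],
          activity = act,
          resource_used = res,
          stringsAsFactors = FALSE)
      }
    }
    sig_mat[, j] <- sp$sigma0[j] * exp(sp$beta_emergent[j] * pc$avail_emergent +
                                       sp$beta_trees_bushes[j] * pc$avail_trees_bushes)
  }
  observations <- if (length(obs) > 0) do.call(rbind, obs) else
    data.frame(point_id = character(), species_id = character(),
               distance_m = numeric(), flock_size = integer(),
               activity = character(), resource_used = character(),
               stringsAsFactors = FALSE)

  species <- sp[, c("species_id", "common_name", "status", "body_mass_g")]
  dataset <- survey_dataset(species, pc, observations,
                            truncation_m = w)
  truth <- list(individuals = true_ind, flocks = true_flk, sigma = sig_mat,
                site_effects = stats::setNames(sites$effect, sites$site_id),
                resource_probs = config$resource_probs,
                config = config)
  list(dataset = dataset, truth = truth)
}

#' Generate a mixed-type trait table
#'
#' Emulates the structure of the study's trait matrix: five continuous
#' morphometric variables (log-normal: culmen length, bill length-depth
#' ratio, tarsus length, wing length, body mass) and ordinal scored
#' variables grouped into diet, feeding agility/height/habitat, food
#' plants, nest location/height and nesting-season months.
#'
#' @param n_native,n_nonnative species counts (>= 1 total).
#' @param seed RNG seed.
#' @param nonnative_lighter draw non-native body masses from a lighter
#'   distribution (as for small estrildid finches vs native finches and
#'   sparrows).
#' @return A [trait_table()]; row names are `NAT01...`/`NON01...` codes.
#' @export
generate_traits <- function(n_native, n_nonnative, seed = 1,
                            nonnative_lighter = TRUE) {
  if (n_native + n_nonnative < 1) stop("need at least one species")
  set.seed(seed)
  ids <- c(sprintf("NAT%02d", seq_len(n_native)),
           sprintf("NON%02d", seq_len(n_nonnative)))
  status <- rep(c("native", "nonnative"), c(n_native, n_nonnative))
  n <- length(ids)

  mass_mu <- ifelse(status == "nonnative" & nonnative_lighter,
                    log(15), log(27))
  vals <- data.frame(
    culmen_mm = stats::rlnorm(n, log(11), 0.2),
    bill_ratio = stats::rlnorm(n, log(1.6), 0.15),
    tarsus_mm = stats::rlnorm(n, log(17), 0.15),
    wing_mm = stats::rlnorm(n, log(75), 0.2),
    body_mass_g = stats::rlnorm(n, mass_mu, 0.25),
    row.names = ids)

  ordinal_groups <- list(
    adult_diet = c("seeds", "green_plants", "invertebrates"),
    nestling_diet = c("seeds", "green_plants", "invertebrates"),
    feeding_agility = c("upside_down", "vertical_stem", "bent_stem"),
    feeding_height = c("ground", "herb_layer", "tree_layer"),
    feeding_habitat = c("weeds", "cultivated", "trees"),
    food_plants = c("grasses", "composites"),
    nest_location = c("ground", "dry_low_veg", "wet_low_veg", "tree",
                      "hole", "cliff"),
    nest_height = "nest_height",
    nesting_month = tolower(month.abb))
  for (grp in names(ordinal_groups)) {
    for (cat in ordinal_groups[[grp]]) {
      vals[[paste(grp, cat, sep = "_")]] <-
        sample(0:3, n, replace = TRUE, prob = c(0.35, 0.3, 0.2, 0.15))
    }
  }
  kinds <- c(rep("continuous", 5),
             rep("ordinal", ncol(vals) - 5))
  names(kinds) <- names(vals)
  levels <- stats::setNames(rep(list(0:3), sum(kinds == "ordinal")),
                            names(kinds)[kinds == "ordinal"])
  tt <- trait_table(vals, kinds = kinds, levels = levels)
  attr(tt, "status") <- stats::setNames(status, ids)
  tt
}

#' Generate quadrat vegetation data
#'
#' Rice-field margins are grass-dominated with fewer forb species and
#' lower plant weight-holding capacities than grassland in adjacent open
#' habitats; quadrats record percent cover per plant species.
#'
#' @param n_rice,n_other quadrat counts per habitat.
#' @param richness_rice,richness_other mean plant species richness per
#'   quadrat (must be >= 1).
#' @param capacity_grass_g,capacity_forb_g mean weight-holding capacity of
#'   the grass and forb species pools (g).
#' @param grass_fraction_rice,grass_fraction_other probability a plant
#'   drawn into a quadrat is a grass.
#' @param seed RNG seed.
#' @return data.frame in the long quadrat format of [survey_dataset()].
#' @export
generate_quadrats <- function(n_rice = 34, n_other = 22,
                              richness_rice = 3, richness_other = 4.5,
                              capacity_grass_g = 2.5, capacity_forb_g = 5.5,
                              grass_fraction_rice = 0.8,
                              grass_fraction_other = 0.45,
                              seed = 1) {
  if (richness_rice < 1 || richness_other < 1) {
    stop("mean quadrat richness must be at least 1")
  }
  set.seed(seed)
  pool <- data.frame(
    plant_species = c(sprintf("grass%02d", 1:12), sprintf("forb%02d", 1:12)),
    form = rep(c("grass", "forb"), each = 12),
    capacity_g = c(stats::rlnorm(12, log(capacity_grass_g), 0.3),
                   stats::rlnorm(12, log(capacity_forb_g), 0.3)))
  make <- function(idx, habitat, rich_mean, grass_frac) {
    rich <- 1 + stats::rpois(1, max(rich_mean - 1, 0))
    forms <- ifelse(stats::runif(rich) < grass_frac, "grass", "forb")
    picked <- unlist(lapply(unique(forms), function(f) {
      sub <- pool[pool$form == f, ]
      sample(sub$plant_species, min(sum(forms == f), nrow(sub)))
    }))
    cover <- stats::rexp(length(picked)) * 100
    data.frame(quadrat_id = sprintf("Q%s%02d",
                                    if (habitat == "rice_margin") "R" else "O",
                                    idx),
               habitat = habitat,
               point_id = NA_character_,
               plant_species = picked,
               cover_pct = cover,
               capacity_g = pool$capacity_g[match(picked, pool$plant_species)],
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(seq_len(n_rice), make, habitat = "rice_margin",
                   rich_mean = richness_rice, grass_frac = grass_fraction_rice),
            lapply(seq_len(n_other), make, habitat = "other_grassland",
                   rich_mean = richness_other, grass_frac = grass_fraction_other))
  do.call(rbind, rows)
}

#' Generate habitat-association score tables with programmed divergence
#'
#' Native species are scored as associated with dry, open and wooded
#' habitats; non-native species with rice fields, ditches and wetland
#' vegetation — so the native/non-native profiles diverge maximally at the
#' gradient positions holding rice fields.
#'
#' @param species_table data.frame with `species_id` and `status`.
#' @param seed RNG seed.
#' @return Species x habitat integer score matrix over the habitats of
#'   [default_gradients()].
#' @export
generate_gradient_scores <- function(species_table, seed = 1) {
  set.seed(seed)
  habitats <- c("extensive_wetland", "reedbed", "river", "ditch",
                "rice_field", "wet_grassland", "damp_scrub",
                "dry_grassland", "arable", "scrub", "woodland")
  nonnative_pref <- c(rice_field = 2, ditch = 2, reedbed = 1,
                      extensive_wetland = 1, wet_grassland = 1, arable = 1)
  native_pref <- c(dry_grassland = 2, arable = 2, scrub = 1, woodland = 1,
                   damp_scrub = 1, wet_grassland = 1)
  m <- matrix(0L, nrow = nrow(species_table), ncol = length(habitats),
              dimnames = list(species_table$species_id, habitats))
  for (i in seq_len(nrow(species_table))) {
    pref <- if (species_table$status[i] == "nonnative") nonnative_pref
            else native_pref
    for (h in names(pref)) {
      # occasional one-step demotion mimics between-species variation
      m[i, h] <- max(0L, min(2L, pref[[h]] - sample(c(1L, 0L, 0L, 0L), 1)))
    }
  }
  m
}

#' The paper-like synthetic preset
#'
#' Encodes the study conditions as the generator's defaults: 51 sites with
#' rice fields plus 10 without; up to 16 point counts per site (mean 7.5,
#' SD 3.3); 4 non-native and 13 native seed-eating species; non-native
#' species denser in rice fields and preferring emergent vegetation for
#' shelter and rough grass for feeding, native species denser outside rice
#' fields and preferring trees and bushes for shelter and forbs for
#' feeding; rice fields with few trees and bushes, similar emergent
#' vegetation and fewer forbs than the adjacent open habitats; non-native
#' body masses drawn lighter than natives.
#'
#' @param n_rice_sites,n_other_sites override the site numbers (e.g. to
#'   scale a simulation study down); defaults are the study design.
#' @return A [scenario_config()].
#' @export
paper_like_config <- function(n_rice_sites = 51, n_other_sites = 10) {
  n_non <- 4; n_nat <- 13
  ids <- c(sprintf("NON%02d", seq_len(n_non)), sprintf("NAT%02d", seq_len(n_nat)))
  status <- rep(c("nonnative", "native"), c(n_non, n_nat))
  # heterogeneous native pool: 6 common, 7 scarcer species
  lambda_other_nat <- c(rep(0.8, 6), rep(0.15, 7))
  pool <- data.frame(
    species_id = ids,
    common_name = ids,
    status = status,
    body_mass_g = round(c(stats::qlnorm(seq(0.2, 0.8, length.out = n_non),
                                        log(15), 0.25),
                          stats::qlnorm(seq(0.1, 0.9, length.out = n_nat),
                                        log(27), 0.3)), 1),
    lambda_rice = c(rep(1.1, n_non), lambda_other_nat * 0.55),
    lambda_other = c(rep(0.45, n_non), lambda_other_nat),
    sigma0 = c(rep(38, n_non), rep(42, n_nat)),
    beta_emergent = -0.4,
    beta_trees_bushes = -0.4,
    beta_flock = 0,
    mean_flock = c(rep(3, n_non), rep(2, n_nat)),
    stringsAsFactors = FALSE)

  res_levels <- c(resource_classes(), "none")
  non_probs <- list(
    feeding = stats::setNames(c(0.25, 0.55, 0.05, 0.02, 0.13), res_levels),
    shelter = stats::setNames(c(0.02, 0.05, 0.75, 0.08, 0.10), res_levels))
  nat_probs <- list(
    feeding = stats::setNames(c(0.55, 0.25, 0.02, 0.08, 0.10), res_levels),
    shelter = stats::setNames(c(0.02, 0.05, 0.13, 0.70, 0.10), res_levels))
  resource_probs <- stats::setNames(
    lapply(status, function(s) if (s == "nonnative") non_probs else nat_probs),
    ids)

  beta_shapes <- function(mean, conc = 8) c(mean * conc, (1 - mean) * conc)
  availability_beta <- list(
    rice = rbind(forbs = beta_shapes(0.10),
                 rough_grass = beta_shapes(0.25),
                 emergent = beta_shapes(0.30),
                 trees_bushes = beta_shapes(0.05)),
    agriculture = rbind(forbs = beta_shapes(0.25),
                        rough_grass = beta_shapes(0.25),
                        emergent = beta_shapes(0.10),
                        trees_bushes = beta_shapes(0.30)),
    river = rbind(forbs = beta_shapes(0.15),
                  rough_grass = beta_shapes(0.20),
                  emergent = beta_shapes(0.35),
                  trees_bushes = beta_shapes(0.35)),
    wetland = rbind(forbs = beta_shapes(0.15),
                    rough_grass = beta_shapes(0.25),
                    emergent = beta_shapes(0.45),
                    trees_bushes = beta_shapes(0.15)))

  scenario_config(species_pool = pool,
                  resource_probs = resource_probs,
                  activity_probs = c(0.5, 0.35, 0.15),
                  n_rice_sites = n_rice_sites,
                  n_other_sites = n_other_sites,
                  availability_beta = availability_beta,
                  site_sd = 0.4)
}
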