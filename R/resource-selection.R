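# Jacobs-index resource selection and community-weighted mean
# weight-holding capacity.

#' Jacobs selectivity index
#'
#' J = (u - a) / (u + a - 2ua), contrasting use against availability.
#' J = 0 means use proportional to availability, +1 exclusive selection,
#' -1 complete avoidance.  Unlike the raw ratio u/a, J is bounded and
#' symmetric around indifference.
#'
#' @param u proportion of a species' activity observations using the
#'   resource, in \[0, 1\]; vectorised.
#' @param a availability of the resource, strictly inside (0, 1):
#'   selection is undefined for resources that are absent or ubiquitous.
#' @return Jacobs index in \[-1, 1\].
#' @export
jacobs_index <- function(u, a) {
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (any(a <= 0 | a >= 1)) {
    stop("selection is undefined for availability a outside (0, 1)")
  }
  pmin(1, pmax(-1, (u - a) / (u + a - 2 * u * a)))
}

#' Availability of a resource for a species
#'
#' Mean availability proportion of a vegetation class over a set of point
#' counts.  Default mode `"occupied"` averages over the point counts where
#' the species was recorded: conditioning on occupancy separates resource
#' selection from the role of the resource in driving occupancy.  Mode
#' `"all"` averages over every point count (occupancy effects included).
#' Per-point proportions are averaged unweighted; grid cells are not
#' pooled.
#'
#' @param dataset a `survey_dataset`.
#' @param species_id species code.
#' @param resource one of [resource_classes()].
#' @param mode `"occupied"` or `"all"`.
#' @return Availability in \[0, 1\].
#' @export
availability <- function(dataset, species_id, resource,
                         mode = c("occupied", "all")) {
  mode <- match.arg(mode)
  stopifnot(resource %in% resource_classes())
  pc <- dataset$point_counts
  if (mode == "occupied") {
    occ <- unique(dataset$observations$point_id[
      dataset$observations$species_id == species_id])
    if (length(occ) == 0) {
      stop("species '", species_id, "' was not recorded in any point count; ",
           "occupied-mode availability is undefined")
    }
    pc <- pc[pc$point_id %in% occ, , drop = FALSE]
  }
  mean(pc[[paste0("avail_", resource)]])
}

#' Jacobs-index selection table for one activity
#'
#' For each species x resource class, computes u (the proportion of that
#' species' flocks recorded doing the activity that were using the
#' resource), a (availability conditioned on occupied point counts by
#' default) and the Jacobs index.  Each recorded flock is one selection
#' event; flock size does not weight u unless `weight_by_flock = TRUE`.
#'
#' @param dataset a `survey_dataset`.
#' @param activity `"feeding"` or `"shelter"` ("other" activity carries no
#'   resource-selection information and is excluded).
#' @param availability_mode passed to [availability()].
#' @param min_obs species with fewer activity observations are flagged
#'   (`reliable = FALSE`) but not dropped.
#' @param weight_by_flock weight use proportions by flock size.
#' @return data.frame `species_id`, `status`, `activity`, `resource`, `u`,
#'   `a`, `J`, `n_obs`, `reliable`.
#' @export
selection_table <- function(dataset, activity = c("feeding", "shelter"),
                            availability_mode = c("occupied", "all"),
                            min_obs = 5, weight_by_flock = FALSE) {
  activity <- match.arg(activity)
  availability_mode <- match.arg(availability_mode)
  obs <- dataset$observations
  obs <- obs[obs$activity == activity, , drop = FALSE]
  rows <- list()
  for (sp in unique(obs$species_id)) {
    o <- obs[obs$species_id == sp, , drop = FALSE]
    wts <- if (weight_by_flock) o$flock_size else rep(1, nrow(o))
    n <- nrow(o)
    for (res in resource_classes()) {
      a <- tryCatch(availability(dataset, sp, res, availability_mode),
                    error = function(e) NA_real_)
      u <- sum(wts[o$resource_used == res]) / sum(wts)
      J <- if (!is.na(a) && a > 0 && a < 1) jacobs_index(u, a) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        species_id = sp,
        status = dataset$species$status[match(sp, dataset$species$species_id)],
        activity = activity, resource = res,
        u = u, a = a, J = J, n_obs = n,
        reliable = n >= min_obs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(species_id = character(), status = character(),
                      activity = character(), resource = character(),
                      u = numeric(), a = numeric(), J = numeric(),
                      n_obs = integer(), reliable = logical()))
  }
  do.call(rbind, rows)
}

#' Compare Jacobs indices between native and non-native species
#'
#' Wilcoxon-Mann-Whitney rank-sum comparison of per-species Jacobs indices
#' for one resource x activity, native group first (group-1 statistic
#' convention; see [wilcoxon_mw()]).
#'
#' @param table output of [selection_table()].
#' @param resource resource class to compare.
#' @param activity activity to compare (defaults to the table's activity).
#' @param reliable_only drop species flagged unreliable before testing.
#' @return A `wilcoxon_result` (see [wilcoxon_mw()]).
#' @export
compare_selection <- function(table, resource, activity = NULL,
                              reliable_only = FALSE) {
  d <- table[table$resource == resource & !is.na(table$J), , drop = FALSE]
  if (!is.null(activity)) d <- d[d$activity == activity, , drop = FALSE]
  if (reliable_only) d <- d[d$reliable, , drop = FALSE]
  x <- d$J[d$status == "native"]
  y <- d$J[d$status == "nonnative"]
  wilcoxon_mw(x, y)
}

#' Community-weighted mean weight-holding capacity of a quadrat
#'
#' CWM = sum(cover_k * capacity_k) / sum(cover_k) over the plant species
#' present in the quadrat.  Weight-holding capacity is the mass (g) a
#' plant's seed head supports before drooping to the ground, which governs
#' which bird body masses can perch and feed on it.  Invariant to
#' rescaling cover (percent vs proportion).
#'
#' @param quadrat data.frame rows for one quadrat with columns
#'   `plant_species`, `cover_pct`, `capacity_g`.
#' @return List `quadrat_id`, `habitat`, `cwm_capacity_g`.
#' @export
cwm_capacity <- function(quadrat) {
  q <- quadrat[quadrat$cover_pct > 0, , drop = FALSE]
  if (nrow(q) == 0 || sum(q$cover_pct) <= 0) {
    stop("quadrat has no positive plant cover; CWM undefined")
  }
  miss <- is.na(q$capacity_g)
  if (any(miss)) {
    stop("missing weight-holding capacity for covered species: ",
         paste(q$plant_species[miss], collapse = ", "))
  }
  list(quadrat_id = unique(quadrat$quadrat_id)[1],
       habitat = unique(quadrat$habitat)[1],
       cwm_capacity_g = sum(q$cover_pct * q$capacity_g) / sum(q$cover_pct))
}

#' CWM capacity and plant richness for every quadrat in a dataset
#'
#' @param dataset a `survey_dataset` with quadrats.
#' @return data.frame `quadrat_id`, `habitat`, `point_id`, `plant_richness`,
#'   `cwm_capacity_g`.
#' @export
quadrat_summary <- function(dataset) {
  q <- dataset$quadrats
  if (is.null(q)) stop("dataset has no quadrat table")
  ids <- unique(q$quadrat_id)
  out <- lapply(ids, function(id) {
    qq <- q[q$quadrat_id == id, , drop = FALSE]
    cwm <- cwm_capacity(qq)
    data.frame(quadrat_id = id, habitat = cwm$habitat,
               point_id = qq$point_id[1],
               plant_richness = sum(qq$cover_pct > 0),
               cwm_capacity_g = cwm$cwm_capacity_g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
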