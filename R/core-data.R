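# Core data model: survey datasets, trait tables, quadrats, and their
# tabular readers/writers.  All higher-level modules consume these objects.

#' Vegetation resource classes recorded on the 49-cell availability grid
#' @export
resource_classes <- function() c("forbs", "rough_grass", "emergent", "trees_bushes")

#' Habitat classes assigned to point-count locations
#' @export
habitat_classes <- function() c("rice", "agriculture", "river", "wetland")

#' Activities recorded for each observed flock
#' @export
activity_levels <- function() c("feeding", "shelter", "other")

availability_columns <- function() paste0("avail_", resource_classes())

#' Assemble a survey dataset
#'
#' Bundles the three core survey tables (plus optional quadrat vegetation
#' data) into a single validated object.  A survey consists of sites, each
#' holding one or more 100 m radius point counts; every point count carries
#' the proportion of its resource-recording grid occupied by each of four
#' vegetation classes; every observation is one individual or flock with a
#' distance, activity and the resource it was using.
#'
#' @param species data.frame with columns `species_id`, `common_name`,
#'   `status` (`"native"` or `"nonnative"`), `body_mass_g`.
#' @param point_counts data.frame with columns `site_id`, `point_id`,
#'   `year`, `habitat_class`, `x`, `y` and the four availability columns
#'   `avail_forbs`, `avail_rough_grass`, `avail_emergent`,
#'   `avail_trees_bushes` (proportions in \[0, 1\]).
#' @param observations data.frame with columns `point_id`, `species_id`,
#'   `distance_m`, `flock_size`, `activity`, `resource_used` (a resource
#'   class or `"none"`).
#' @param quadrats optional long-format data.frame with columns
#'   `quadrat_id`, `habitat` (`"rice_margin"` or `"other_grassland"`),
#'   `point_id`, `plant_species`, `cover_pct`, `capacity_g`.
#' @param truncation_m truncation radius in metres; observations beyond it
#'   are rejected (with a message reporting how many).
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(species, point_counts, observations,
                           quadrats = NULL, truncation_m = 100) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  point_counts <- as.data.frame(point_counts, stringsAsFactors = FALSE)
  observations <- as.data.frame(observations, stringsAsFactors = FALSE)

  check_columns(species, c("species_id", "common_name", "status", "body_mass_g"),
                "species")
  check_columns(point_counts,
                c("site_id", "point_id", "year", "habitat_class", "x", "y",
                  availability_columns()),
                "point_counts")
  check_columns(observations,
                c("point_id", "species_id", "distance_m", "flock_size",
                  "activity", "resource_used"),
                "observations")
  if (!is.null(quadrats)) {
    quadrats <- as.data.frame(quadrats, stringsAsFactors = FALSE)
    check_columns(quadrats,
                  c("quadrat_id", "habitat", "point_id", "plant_species",
                    "cover_pct", "capacity_g"),
                  "quadrats")
    quadrats$point_id <- as.character(quadrats$point_id)
  }

  point_counts$is_rice <- point_counts$habitat_class == "rice"

  far <- observations$distance_m > truncation_m
  if (any(far)) {
    message(sum(far), " observation(s) beyond the ", truncation_m,
            " m truncation radius rejected")
    observations <- observations[!far, , drop = FALSE]
  }

  bad_sp <- setdiff(observations$species_id, species$species_id)
  if (length(bad_sp) > 0) {
    stop("observations reference unknown species code(s): ",
         paste(sort(bad_sp), collapse = ", "))
  }

  structure(list(species = species,
                 point_counts = point_counts,
                 observations = observations,
                 quadrats = quadrats,
                 densities = NULL,
                 truncation_m = truncation_m),
            class = "survey_dataset")
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("table '", what, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:",
      length(unique(x$point_counts$site_id)), "sites,",
      nrow(x$point_counts), "point counts,",
      nrow(x$observations), "observations,",
      nrow(x$species), "species",
      if (!is.null(x$quadrats)) paste0("(", nrow(x$quadrats), " quadrat rows)"),
      "\n")
  invisible(x)
}

#' Read a survey dataset from CSV files
#'
#' Reads the canonical CSV dialect (UTF-8, header row; see
#' [survey_dataset()] for the column contract).  Supplementary tables
#' deposited with other column headers can be imported by supplying a
#' `column_map`: a named list (or YAML file path) per table mapping
#' canonical names to the file's names.
#'
#' @param point_count_path,observation_path,species_path CSV file paths.
#' @param quadrat_path optional quadrat CSV.
#' @param column_map optional list with elements `point_counts`,
#'   `observations`, `species`, `quadrats`, each a named character vector
#'   `canonical = file_column`; or path to a YAML file with that structure.
#' @inheritParams survey_dataset
#' @return A `survey_dataset`.
#' @export
read_survey <- function(point_count_path, observation_path, species_path,
                        quadrat_path = NULL, column_map = NULL,
                        truncation_m = 100) {
  if (is.character(column_map) && length(column_map) == 1) {
    column_map <- yaml::read_yaml(column_map)
  }
  read_one <- function(path, table) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    map <- column_map[[table]]
    if (!is.null(map)) {
      map <- unlist(map)
      missing <- setdiff(map, names(df))
      if (length(missing) > 0) {
        stop("table '", table, "': mapped column(s) absent from file: ",
             paste(missing, collapse = ", "))
      }
      names(df)[match(map, names(df))] <- names(map)
    }
    df
  }
  survey_dataset(
    species = read_one(species_path, "species"),
    point_counts = read_one(point_count_path, "point_counts"),
    observations = read_one(observation_path, "observations"),
    quadrats = if (!is.null(quadrat_path)) read_one(quadrat_path, "quadrats"),
    truncation_m = truncation_m
  )
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey()]; re-reading the written files reproduces the
#' dataset exactly.
#'
#' @param dataset a `survey_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_survey <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(point_counts = file.path(dir, "point_counts.csv"),
             observations = file.path(dir, "observations.csv"),
             species = file.path(dir, "species.csv"))
  pc <- dataset$point_counts
  pc$is_rice <- NULL  # derived on read
  utils::write.csv(pc, paths["point_counts"], row.names = FALSE)
  utils::write.csv(dataset$observations, paths["observations"], row.names = FALSE)
  utils::write.csv(dataset$species, paths["species"], row.names = FALSE)
  if (!is.null(dataset$quadrats)) {
    paths["quadrats"] <- file.path(dir, "quadrats.csv")
    utils::write.csv(dataset$quadrats, paths["quadrats"], row.names = FALSE)
  }
  invisible(paths)
}

#' Validate a survey dataset
#'
#' Checks every dataset invariant (availability proportions in \[0, 1\],
#' distances within the truncation radius, flock sizes at least 1, factor
#' levels, referential integrity, positive body masses) and reports
#' violations without mutating the dataset.
#'
#' @param dataset a `survey_dataset`.
#' @return data.frame with columns `table`, `id`, `problem`; zero rows when
#'   the dataset is fully valid.
#' @export
validate_survey <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  probs <- list()
  add <- function(table, id, problem) {
    probs[[length(probs) + 1]] <<- data.frame(
      table = table, id = as.character(id), problem = problem,
      stringsAsFactors = FALSE)
  }

  sp <- dataset$species
  bad <- !sp$status %in% c("native", "nonnative")
  for (i in which(bad)) add("species", sp$species_id[i], "status not native/nonnative")
  for (i in which(!(sp$body_mass_g > 0))) add("species", sp$species_id[i],
                                              "body_mass_g not positive")

  pc <- dataset$point_counts
  for (col in availability_columns()) {
    out <- pc[[col]] < 0 | pc[[col]] > 1 | is.na(pc[[col]])
    for (i in which(out)) add("point_counts", pc$point_id[i],
                              paste0(col, " availability out of [0,1]"))
  }
  bad_hab <- !pc$habitat_class %in% habitat_classes()
  for (i in which(bad_hab)) add("point_counts", pc$point_id[i],
                                paste0("unknown habitat_class '", pc$habitat_class[i], "'"))
  if (anyDuplicated(pc$point_id)) {
    for (id in unique(pc$point_id[duplicated(pc$point_id)]))
      add("point_counts", id, "duplicated point_id")
  }

  obs <- dataset$observations
  for (i in which(obs$distance_m < 0 | obs$distance_m > dataset$truncation_m))
    add("observations", obs$point_id[i], "distance outside [0, truncation]")
  for (i in which(obs$flock_size < 1))
    add("observations", obs$point_id[i], "flock_size < 1")
  bad_act <- !obs$activity %in% activity_levels()
  for (i in which(bad_act)) add("observations", obs$point_id[i],
                                paste0("unknown activity '", obs$activity[i], "'"))
  bad_res <- !obs$resource_used %in% c(resource_classes(), "none")
  for (i in which(bad_res)) add("observations", obs$point_id[i],
                                paste0("unknown resource '", obs$resource_used[i], "'"))
  unknown_pt <- setdiff(obs$point_id, pc$point_id)
  for (id in unknown_pt) add("observations", id,
                             paste0("observation references unknown point '", id, "'"))
  unknown_sp <- setdiff(obs$species_id, sp$species_id)
  for (id in unknown_sp) add("observations", id,
                             paste0("observation references unknown species '", id, "'"))

  if (!is.null(dataset$quadrats)) {
    q <- dataset$quadrats
    for (i in which(q$cover_pct < 0)) add("quadrats", q$quadrat_id[i],
                                          "negative cover")
    for (i in which(q$capacity_g < 0)) add("quadrats", q$quadrat_id[i],
                                           "negative weight-holding capacity")
    bad_h <- !q$habitat %in% c("rice_margin", "other_grassland")
    for (i in which(bad_h)) add("quadrats", q$quadrat_id[i],
                                paste0("unknown quadrat habitat '", q$habitat[i], "'"))
  }

  if (length(probs) == 0) {
    data.frame(table = character(), id = character(), problem = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, probs)
  }
}

#' Attach detectability-corrected densities to a dataset
#'
#' @param dataset a `survey_dataset`.
#' @param density_table output of [estimate_density()].
#' @return The dataset with densities attached, enabling
#'   `build_community_matrix(value = "density")`.
#' @export
attach_densities <- function(dataset, density_table) {
  stopifnot(inherits(dataset, "survey_dataset"))
  check_columns(density_table, c("point_id", "species_id", "count", "density"),
                "densities")
  dataset$densities <- as.data.frame(density_table, stringsAsFactors = FALSE)
  dataset
}

#' Build a point-count x species community matrix
#'
#' @param dataset a `survey_dataset`.
#' @param value `"presence"` for a binary matrix (any flock of the species
#'   recorded at the point), or `"density"` for detectability-corrected
#'   densities (requires [attach_densities()] to have been run).
#' @param species optional character vector restricting the columns (e.g.
#'   native species only); defaults to all species in the dataset.
#' @return Numeric matrix, rows = point counts, columns = species.
#' @export
build_community_matrix <- function(dataset, value = c("presence", "density"),
                                   species = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  value <- match.arg(value)
  if (is.null(species)) species <- dataset$species$species_id
  pts <- dataset$point_counts$point_id
  m <- matrix(0, nrow = length(pts), ncol = length(species),
              dimnames = list(pts, species))

  if (value == "presence") {
    obs <- dataset$observations
    obs <- obs[obs$species_id %in% species, , drop = FALSE]
    if (nrow(obs) > 0) {
      m[cbind(match(obs$point_id, pts), match(obs$species_id, species))] <- 1
    }
  } else {
    if (is.null(dataset$densities)) {
      stop("density community matrix requested before densities were attached; ",
           "run estimate_density() and attach_densities() first")
    }
    d <- dataset$densities
    d <- d[d$species_id %in% species & d$point_id %in% pts, , drop = FALSE]
    if (nrow(d) > 0) {
      m[cbind(match(d$point_id, pts), match(d$species_id, species))] <- d$density
    }
  }
  m
}

#' Construct a species trait table
#'
#' Holds a species x trait value matrix together with per-trait metadata:
#' the measurement kind (continuous, ordinal or categorical) and, for
#' ordinal traits, the ordered level set.  Missing values are permitted and
#' handled by pairwise deletion in [gower_distance()].
#'
#' @param values data.frame of trait values with row names (or a
#'   `species_id` column) identifying species.  Ordinal traits are coded as
#'   integers/levels from their declared level set.
#' @param kinds named character vector, one of `"continuous"`, `"ordinal"`,
#'   `"categorical"` per trait column.  Defaults to `"continuous"` for
#'   numeric columns and `"categorical"` otherwise.
#' @param levels named list of ordered level sets for ordinal traits;
#'   defaults to the sorted unique observed values.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values, kinds = NULL, levels = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if ("species_id" %in% names(values)) {
    rownames(values) <- values$species_id
    values$species_id <- NULL
  }
  if (is.null(kinds)) {
    kinds <- vapply(values, function(v) if (is.numeric(v)) "continuous"
                    else "categorical", character(1))
  }
  kinds <- kinds[names(values)]
  stopifnot(all(kinds %in% c("continuous", "ordinal", "categorical")))
  if (is.null(levels)) levels <- list()
  for (tr in names(values)[kinds == "ordinal"]) {
    if (is.null(levels[[tr]])) levels[[tr]] <- sort(unique(stats::na.omit(values[[tr]])))
    bad <- !is.na(values[[tr]]) & !values[[tr]] %in% levels[[tr]]
    if (any(bad)) {
      stop("ordinal trait '", tr, "' has value(s) outside its level set: ",
           paste(unique(values[[tr]][bad]), collapse = ", "))
    }
  }
  all_missing <- apply(values, 1, function(r) all(is.na(r)))
  if (any(all_missing)) {
    stop("species with no non-missing traits: ",
         paste(rownames(values)[all_missing], collapse = ", "))
  }
  structure(list(values = values, kinds = kinds, levels = levels),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x$values), "species x", ncol(x$values), "traits (",
      sum(x$kinds == "continuous"), "continuous,",
      sum(x$kinds == "ordinal"), "ordinal,",
      sum(x$kinds == "categorical"), "categorical )\n")
  invisible(x)
}

#' Read a trait table from CSV
#'
#' @param path CSV with a `species_id` column and one column per trait.
#' @param kinds,levels see [trait_table()].
#' @return A `trait_table`.
#' @export
read_traits <- function(path, kinds = NULL, levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  trait_table(utils::read.csv(path, stringsAsFactors = FALSE),
              kinds = kinds, levels = levels)
}

#' Write a trait table to CSV
#' @param traits a `trait_table`.
#' @param path output CSV path.
#' @export
write_traits <- function(traits, path) {
  df <- cbind(species_id = rownames(traits$values), traits$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
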