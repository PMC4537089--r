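# Habitat-association scoring along ordered environmental gradients.

#' Define an ordered environmental gradient
#'
#' A gradient is an ordered set of categories together with a mapping from
#' habitat types to category positions.  A habitat may span several
#' positions (its scores then count at each).
#'
#' @param name gradient name (e.g. `"wet_dry"`, `"open_closed"`).
#' @param categories character vector of ordered category labels.
#' @param habitat_map named list: habitat type -> character vector of the
#'   categories it occupies.
#' @return Object of class `gradient`.
#' @export
gradient <- function(name, categories, habitat_map) {
  stopifnot(is.character(categories), length(categories) >= 2,
            !anyDuplicated(categories))
  for (h in names(habitat_map)) {
    bad <- setdiff(habitat_map[[h]], categories)
    if (length(bad) > 0) {
      stop("habitat '", h, "' maps to unknown categor(ies): ",
           paste(bad, collapse = ", "))
    }
    if (length(habitat_map[[h]]) == 0) {
      stop("habitat '", h, "' maps to no category")
    }
  }
  structure(list(name = name, categories = categories,
                 habitat_map = habitat_map),
            class = "gradient")
}

#' The two standard gradients
#'
#' Hydrological gradient (4 ordered categories from extensive wetland to
#' dry habitats) and structural openness gradient (6 ordered categories
#' from low-growing vegetation to forest), with a habitat-to-position
#' mapping for the broad habitat types used in the association tables.
#' The mapping is the package's own transcription choice and can be
#' replaced wholesale via [gradient()].
#'
#' @return Named list of two `gradient` objects.
#' @export
default_gradients <- function() {
  wet_dry <- gradient(
    "wet_dry",
    c("extensive_wetland", "linear_fragmented_wetland", "damp", "dry"),
    list(extensive_wetland = "extensive_wetland",
         reedbed = "extensive_wetland",
         river = "linear_fragmented_wetland",
         ditch = "linear_fragmented_wetland",
         rice_field = "linear_fragmented_wetland",
         wet_grassland = "damp",
         damp_scrub = "damp",
         dry_grassland = "dry",
         arable = "dry",
         scrub = "dry",
         woodland = "dry"))
  open_closed <- gradient(
    "open_closed",
    c("low_vegetation", "low_and_taller_matrix", "tall_nonwoody",
      "nonwoody_dominated_matrix", "woody_dominated_matrix", "forest"),
    list(dry_grassland = "low_vegetation",
         wet_grassland = "low_vegetation",
         arable = "low_and_taller_matrix",
         rice_field = "low_and_taller_matrix",
         ditch = "tall_nonwoody",
         reedbed = "tall_nonwoody",
         extensive_wetland = "tall_nonwoody",
         river = "nonwoody_dominated_matrix",
         scrub = "woody_dominated_matrix",
         damp_scrub = "woody_dominated_matrix",
         woodland = "forest"))
  list(wet_dry = wet_dry, open_closed = open_closed)
}

#' Read a gradient definition from YAML
#'
#' YAML structure: `name`, `categories` (ordered list), `habitat_map`
#' (habitat -> category or list of categories).
#'
#' @param path YAML file.
#' @return A `gradient`.
#' @export
read_gradient <- function(path) {
  y <- yaml::read_yaml(path)
  gradient(y$name, unlist(y$categories),
           lapply(y$habitat_map, unlist))
}

#' Association score of a species at one gradient position
#'
#' Habitat-association scores (0 = no association, 1 = weak, 2 = strong)
#' are coded per habitat type; the overall score at a gradient position is
#' the maximum score across all habitats mapped to that position (0 when
#' no scored habitat maps there).
#'
#' @param species species id (a row of `scores`).
#' @param position a category label of `grad`.
#' @param scores matrix/data.frame species x habitat of integer scores in
#'   \{0, 1, 2\}.
#' @param grad a `gradient`.
#' @return Integer score in \{0, 1, 2\}.
#' @export
position_score <- function(species, position, scores, grad) {
  if (!position %in% grad$categories) {
    stop("unknown gradient position '", position, "'")
  }
  habs <- names(grad$habitat_map)[vapply(grad$habitat_map,
                                         function(cats) position %in% cats,
                                         logical(1))]
  habs <- intersect(habs, colnames(scores))
  if (length(habs) == 0) return(0L)
  vals <- as.numeric(scores[species, habs])
  if (all(is.na(vals))) return(0L)
  as.integer(max(vals, na.rm = TRUE))
}

#' Per-species profile along a gradient
#'
#' @param scores species x habitat score matrix.
#' @param grad a `gradient`.
#' @return Matrix species x gradient positions of scores.
#' @export
gradient_profile <- function(scores, grad) {
  out <- matrix(0L, nrow = nrow(scores), ncol = length(grad$categories),
                dimnames = list(rownames(scores), grad$categories))
  for (sp in rownames(scores)) {
    for (pos in grad$categories) {
      out[sp, pos] <- position_score(sp, pos, scores, grad)
    }
  }
  out
}

#' Group mean +/- SE association profiles for native and non-native species
#'
#' @param scores species x habitat score matrix (rownames = species ids).
#' @param grad a `gradient`.
#' @param species_table data.frame with `species_id` and `status`.
#' @return data.frame `gradient`, `position`, `order`, `group`, `mean`,
#'   `se`, `n` (SE is `NA`, flagged, for single-species groups).
#' @export
group_profile <- function(scores, grad, species_table) {
  prof <- gradient_profile(scores, grad)
  status <- species_table$status[match(rownames(prof),
                                       species_table$species_id)]
  rows <- list()
  for (grp in c("native", "nonnative")) {
    sub <- prof[which(status == grp), , drop = FALSE]
    if (nrow(sub) == 0) stop("no species in group '", grp, "'")
    for (j in seq_along(grad$categories)) {
      v <- sub[, j]
      rows[[length(rows) + 1]] <- data.frame(
        gradient = grad$name, position = grad$categories[j], order = j,
        group = grp, mean = mean(v),
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Gradient position(s) where native and non-native profiles diverge most
#'
#' @param profiles output of [group_profile()].
#' @return data.frame of the position(s) attaining the maximal absolute
#'   difference between group means (all tied positions returned), with
#'   the difference (`nonnative - native`).
#' @export
max_divergence_position <- function(profiles) {
  nat <- profiles[profiles$group == "native", ]
  non <- profiles[profiles$group == "nonnative", ]
  non <- non[match(nat$position, non$position), ]
  diff <- non$mean - nat$mean
  mx <- max(abs(diff))
  at <- which(abs(diff) == mx)
  data.frame(gradient = nat$gradient[at], position = nat$position[at],
             order = nat$order[at], difference = diff[at],
             stringsAsFactors = FALSE)
}
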