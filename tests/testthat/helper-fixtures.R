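# Shared fixtures and independent oracles, all built in code.

# Small two-habitat scenario for fast pipeline tests.
tiny_config <- function(n_rice_sites = 6, n_other_sites = 3) {
  paper_like_config(n_rice_sites = n_rice_sites, n_other_sites = n_other_sites)
}

# Minimal hand-built survey: 2 sites, 3 points, 2 species.
toy_dataset <- function() {
  species <- data.frame(
    species_id = c("A", "B"),
    common_name = c("species A", "species B"),
    status = c("native", "nonnative"),
    body_mass_g = c(25, 14))
  pc <- data.frame(
    site_id = c("S1", "S1", "S2"),
    point_id = c("P1", "P2", "P3"),
    year = 2011L,
    habitat_class = c("rice", "agriculture", "wetland"),
    x = c(0, 1, 10), y = c(0, 1, 10),
    avail_forbs = c(0.2, 0.4, 0.1),
    avail_rough_grass = c(0.3, 0.3, 0.3),
    avail_emergent = c(0.2, 0.4, 0.5),
    avail_trees_bushes = c(0.1, 0.3, 0.2))
  obs <- data.frame(
    point_id = c("P1", "P1", "P2"),
    species_id = c("A", "B", "A"),
    distance_m = c(10, 50, 30),
    flock_size = c(3L, 1L, 2L),
    activity = c("feeding", "shelter", "feeding"),
    resource_used = c("forbs", "emergent", "forbs"))
  survey_dataset(species, pc, obs)
}

# Dendrogram model for the worked 3-leaf tree: A,B merge at height 1,
# C joins at height 2 (total branch length 5).
toy_tree_model <- function() {
  d <- matrix(c(0, 1, 2,
                1, 0, 2,
                2, 2, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  build_dendrogram(as.dist(d), "average")
}

# Independent FD oracle: union of tip-to-tip paths on the ape phylo
# rendering of the same hclust tree.  as.phylo halves node heights, which
# cancels in the FD ratio.
fd_path_union_oracle <- function(community, model) {
  phy <- ape::as.phylo(model$hclust)
  tips <- match(community, phy$tip.label)
  if (length(tips) < 2) return(0)
  edges_used <- integer(0)
  for (i in seq_along(tips)[-1]) {
    for (j in seq_len(i - 1)) {
      nodes <- ape::nodepath(phy, tips[i], tips[j])
      for (k in seq_along(nodes)[-1]) {
        e <- which((phy$edge[, 1] == nodes[k - 1] & phy$edge[, 2] == nodes[k]) |
                   (phy$edge[, 1] == nodes[k] & phy$edge[, 2] == nodes[k - 1]))
        edges_used <- union(edges_used, e)
      }
    }
  }
  sum(phy$edge.length[edges_used]) / sum(phy$edge.length)
}

# Naive double-loop Moran's I.
moran_oracle <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Draw detected distances from a truncated half-normal point-transect
# process: uniform-in-area placement thinned by exp(-r^2 / (2 sigma^2)).
simulate_detected_distances <- function(n, sigma, w = 100) {
  out <- numeric(0)
  while (length(out) < n) {
    r <- w * sqrt(stats::runif(2 * n))
    keep <- stats::runif(2 * n) < exp(-r^2 / (2 * sigma^2))
    out <- c(out, r[keep])
  }
  out[seq_len(n)]
}

# Numerical-integration oracle for the disc-averaged detection probability.
halfnormal_p_numeric <- function(sigma, w = 100) {
  stats::integrate(function(r) exp(-r^2 / (2 * sigma^2)) * 2 * r / w^2,
                   0, w, rel.tol = 1e-12)$value
}
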