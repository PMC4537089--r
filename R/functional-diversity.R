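# Dendrogram-based functional diversity: Gower distance on mixed traits,
# hierarchical clustering with linkage selected by cophenetic correlation,
# branch-length FD per community, randomisation null models and
# standardised effect sizes.

#' Gower distance on a mixed-type trait table
#'
#' Per-trait dissimilarity between species i and j: continuous and ordinal
#' traits (ordinals treated as equally spaced ranks) contribute
#' |x_i - x_j| / range; categorical traits contribute 0/1 mismatch.  The
#' distance is the mean over the traits where both species have values
#' (pairwise deletion).  Traits with zero range carry no information and
#' are excluded with a warning.
#'
#' @param traits a [trait_table()].
#' @param weights optional named per-trait weights (e.g. to weight trait
#'   groups equally rather than each member variable equally); defaults to
#'   equal weights per variable.
#' @return A `dist` object over the species.
#' @export
gower_distance <- function(traits, weights = NULL) {
  stopifnot(inherits(traits, "trait_table"))
  vals <- traits$values
  n <- nrow(vals)
  if (n < 2) stop("Gower distance needs at least 2 species")

  # numeric encoding: ordinal -> rank position in declared level set
  enc <- matrix(NA_real_, n, ncol(vals),
                dimnames = list(rownames(vals), names(vals)))
  categorical <- traits$kinds == "categorical"
  for (j in seq_along(vals)) {
    tr <- names(vals)[j]
    v <- vals[[j]]
    if (traits$kinds[j] == "ordinal") {
      enc[, j] <- match(v, traits$levels[[tr]])
    } else if (traits$kinds[j] == "continuous") {
      enc[, j] <- as.numeric(v)
    } else {
      enc[, j] <- as.numeric(factor(v))
    }
  }

  rng <- apply(enc, 2, function(x) diff(range(x, na.rm = TRUE)))
  zero <- !categorical & (rng == 0 | !is.finite(rng))
  zero_cat <- categorical & apply(enc, 2, function(x)
    length(unique(stats::na.omit(x))) < 2)
  drop <- zero | zero_cat
  if (any(drop)) {
    warning("trait(s) with zero range excluded from Gower distance: ",
            paste(names(vals)[drop], collapse = ", "))
  }
  keep <- which(!drop)
  if (length(keep) == 0) stop("no informative traits remain")

  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, ncol(vals)), names(vals))
  }
  wts <- weights[names(vals)]

  D <- matrix(0, n, n, dimnames = list(rownames(vals), rownames(vals)))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      num <- 0
      den <- 0
      for (j in keep) {
        xi <- enc[i, j]; xk <- enc[k, j]
        if (is.na(xi) || is.na(xk)) next
        dj <- if (categorical[j]) as.numeric(xi != xk)
              else abs(xi - xk) / rng[j]
        num <- num + wts[j] * dj
        den <- den + wts[j]
      }
      if (den == 0) {
        stop("species pair sharing no traits: ",
             rownames(vals)[i], " / ", rownames(vals)[k])
      }
      D[i, k] <- D[k, i] <- num / den
    }
  }
  stats::as.dist(D)
}

#' Build a trait dendrogram with a given linkage
#'
#' Agglomerative clustering of the species pool, plus the cophenetic
#' correlation (Pearson r between the lower-triangle input distances and
#' the tree's cophenetic distances) measuring how faithfully the tree
#' represents the distance matrix, and the edge decomposition used by
#' branch-length functional diversity.
#'
#' @param d a `dist` (e.g. from [gower_distance()]).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return Object of class `dendrogram_model` with elements `hclust`,
#'   `linkage`, `coph_corr`, `labels`, `edge_lengths`, `edge_leaves`
#'   (edges x species incidence matrix) and `total_length`.  With only two
#'   species the cophenetic correlation is undefined and reported as 1
#'   with `coph_flagged = TRUE`.
#' @export
build_dendrogram <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) stop("dendrogram needs at least 2 species")
  hc <- stats::hclust(d, method = linkage)
  coph_flagged <- n == 2
  coph <- if (coph_flagged) 1 else
    stats::cor(as.vector(d), as.vector(stats::cophenetic(hc)))

  edges <- dendrogram_edges(hc)
  structure(list(hclust = hc,
                 linkage = linkage,
                 coph_corr = coph,
                 coph_flagged = coph_flagged,
                 labels = hc$labels,
                 edge_lengths = edges$lengths,
                 edge_leaves = edges$leaves,
                 total_length = sum(edges$lengths)),
            class = "dendrogram_model")
}

# Decompose an hclust tree into edges (child -> parent merge), each with a
# length (height difference) and the set of leaves below it.
dendrogram_edges <- function(hc) {
  n <- length(hc$labels)
  nm <- nrow(hc$merge)
  leaf_below <- vector("list", nm)  # per merge node
  lengths <- numeric(0)
  leaves <- matrix(FALSE, nrow = 0, ncol = n)
  node_height <- hc$height
  for (k in seq_len(nm)) {
    below_k <- rep(FALSE, n)
    for (child in hc$merge[k, ]) {
      if (child < 0) {
        child_set <- rep(FALSE, n)
        child_set[-child] <- TRUE
        child_h <- 0
      } else {
        child_set <- leaf_below[[child]]
        child_h <- node_height[child]
      }
      lengths <- c(lengths, node_height[k] - child_h)
      leaves <- rbind(leaves, child_set)
      below_k <- below_k | child_set
    }
    leaf_below[[k]] <- below_k
  }
  colnames(leaves) <- hc$labels
  list(lengths = lengths, leaves = leaves)
}

#' @export
print.dendrogram_model <- function(x, ...) {
  cat("dendrogram_model:", length(x$labels), "species,", x$linkage,
      "linkage, cophenetic r =", round(x$coph_corr, 3),
      ", total branch length =", round(x$total_length, 4), "\n")
  invisible(x)
}

#' Select the linkage with the highest cophenetic correlation
#'
#' Fits single, complete and average linkage and returns the model whose
#' cophenetic distances correlate best with the input distances; ties go
#' to average linkage.
#'
#' @param d a `dist`.
#' @return The selected `dendrogram_model`, with the per-linkage
#'   correlations attached as attribute `coph_table`.
#' @export
select_linkage <- function(d) {
  methods <- c("average", "single", "complete")  # average first wins ties
  models <- lapply(methods, function(m) build_dendrogram(d, m))
  cc <- vapply(models, function(m) m$coph_corr, numeric(1))
  best <- models[[which.max(cc)]]
  attr(best, "coph_table") <- stats::setNames(cc, methods)
  best
}

#' Export a dendrogram model as newick
#'
#' @param model a `dendrogram_model`.
#' @param path optional file; when omitted the newick string is returned.
#' @export
write_dendrogram_newick <- function(model, path = NULL) {
  phy <- ape::as.phylo(model$hclust)
  if (is.null(path)) ape::write.tree(phy) else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Branch-length functional diversity of a community
#'
#' FD = (total length of the branch segments connecting the community's
#' leaves within the full-pool dendrogram) / (total branch length of the
#' full dendrogram).  An edge contributes iff the community species below
#' it are a non-empty proper subset of the community, i.e. the edge lies
#' on a path between two community members.  FD(full pool) = 1;
#' FD(singleton) = 0 (a single species spans no branches);
#' FD(empty) = 0 with a flag.
#'
#' @param community character vector of species ids (subset of the pool),
#'   or a logical/0-1 vector over the pool's species.
#' @param model a `dendrogram_model` built on the full species pool.
#' @return FD in \[0, 1\].
#' @export
fd <- function(community, model) {
  stopifnot(inherits(model, "dendrogram_model"))
  if (is.character(community)) {
    bad <- setdiff(community, model$labels)
    if (length(bad) > 0) stop("species not in the dendrogram pool: ",
                              paste(bad, collapse = ", "))
    memb <- model$labels %in% community
  } else {
    stopifnot(length(community) == length(model$labels))
    memb <- as.logical(community > 0)
  }
  drop(fd_matrix(matrix(as.numeric(memb), nrow = 1,
                        dimnames = list(NULL, model$labels)), model))
}

#' Branch-length FD for every row of a community matrix
#'
#' Vectorised form of [fd()]: rows are communities over the model's
#' species pool (columns matched by name).
#'
#' @param communities numeric/logical matrix, rows = communities, columns
#'   named by species.
#' @param model a `dendrogram_model`.
#' @return Numeric vector of FD values, one per row.
#' @export
fd_matrix <- function(communities, model) {
  C <- (communities > 0) * 1
  if (is.null(colnames(C))) stop("community matrix must have species column names")
  pool <- model$labels
  M <- matrix(0, nrow = nrow(C), ncol = length(pool),
              dimnames = list(rownames(C), pool))
  shared <- intersect(colnames(C), pool)
  M[, shared] <- C[, shared, drop = FALSE]
  S <- rowSums(M)
  # below[r, e]: community species of row r lying below edge e
  below <- M %*% t(model$edge_leaves * 1)
  on_path <- (below > 0) & (below < S)  # non-empty proper subset
  drop(on_path %*% model$edge_lengths) / model$total_length
}

#' Null-model standardised effect sizes of functional diversity
#'
#' For each community (row of a presence matrix), repeatedly draws the
#' same number of species from the pool — uniformly, or weighted by each
#' species' observed occurrence frequency across point counts — computes
#' the branch-length FD of each random community, and standardises the
#' observed FD: SES = (FD_obs - mean(FD_null)) / sd(FD_null).  SES < 0
#' indicates functional under-dispersion (habitat filtering, tighter
#' species packing), SES > 0 over-dispersion.  Weighted sampling without
#' replacement draws species sequentially with renormalised weights.
#' Because the null distribution depends only on the richness (the pool
#' and weights are fixed), null draws are generated once per distinct
#' richness value.
#'
#' @param presence binary point-count x species matrix (columns named by
#'   species; see [build_community_matrix()]).
#' @param model a `dendrogram_model` over the full species pool.
#' @param null `"frequency"` (draw weighted by observed number of point
#'   counts in which each species was recorded) or `"uniform"`.
#' @param n_iter number of null draws per community.
#' @param seed RNG seed.
#' @return data.frame `point_id`, `richness`, `fd_obs`, `null_mean`,
#'   `null_sd`, `ses`, `flagged` (TRUE where the null has zero spread,
#'   e.g. richness equal to the pool size, leaving SES undefined).
#' @export
null_ses <- function(presence, model, null = c("frequency", "uniform"),
                     n_iter = 1000, seed = 1) {
  null <- match.arg(null)
  pool <- model$labels
  P <- matrix(0, nrow = nrow(presence), ncol = length(pool),
              dimnames = list(rownames(presence), pool))
  shared <- intersect(colnames(presence), pool)
  P[, shared] <- (presence[, shared, drop = FALSE] > 0) * 1

  freq <- colSums(P)
  weights <- if (null == "frequency") {
    if (all(freq == 0)) stop("frequency null requires at least one occurrence")
    w <- freq
    w[w == 0] <- 0  # never-recorded pool members cannot be drawn
    w
  } else rep(1, length(pool))

  richness <- rowSums(P)
  fd_obs <- fd_matrix(P, model)

  set.seed(seed)
  null_stats <- list()
  for (S in sort(unique(richness[richness > 0]))) {
    if (sum(weights > 0) < S) {
      stop("richness ", S, " exceeds the number of drawable pool species")
    }
    draws <- matrix(0, nrow = n_iter, ncol = length(pool),
                    dimnames = list(NULL, pool))
    for (it in seq_len(n_iter)) {
      picked <- sample.int(length(pool), size = S, replace = FALSE,
                           prob = weights)
      draws[it, picked] <- 1
    }
    v <- fd_matrix(draws, model)
    null_stats[[as.character(S)]] <- c(mean = mean(v), sd = stats::sd(v))
  }

  mu <- sd0 <- rep(NA_real_, length(richness))
  for (i in seq_along(richness)) {
    if (richness[i] > 0) {
      st <- null_stats[[as.character(richness[i])]]
      mu[i] <- st["mean"]; sd0[i] <- st["sd"]
    } else {
      mu[i] <- 0; sd0[i] <- 0
    }
  }
  flagged <- !is.na(sd0) & sd0 == 0
  ses <- ifelse(flagged, NA_real_, (fd_obs - mu) / sd0)
  data.frame(point_id = rownames(P) %||% as.character(seq_len(nrow(P))),
             richness = richness, fd_obs = fd_obs,
             null_mean = mu, null_sd = sd0, ses = ses, flagged = flagged,
             null_model = null,
             stringsAsFactors = FALSE)
}

#' Species-packing correlation of SES with richness
#'
#' Pearson correlation between the standardised effect size of functional
#' diversity and species richness across communities.  A negative
#' correlation indicates species packing increases with richness (richer
#' communities hold more functionally similar species than the null
#' expects).
#'
#' @param ses_table output of [null_ses()].
#' @return List `r`, `p`, `n` (htest kept as `test`).
#' @export
packing_correlation <- function(ses_table) {
  ok <- is.finite(ses_table$ses)
  x <- ses_table$ses[ok]
  s <- ses_table$richness[ok]
  if (length(x) < 3) stop("need at least 3 finite SES values")
  if (stats::sd(x) == 0 || stats::sd(s) == 0) {
    stop("SES or richness is constant; correlation undefined")
  }
  ct <- stats::cor.test(x, s)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), test = ct)
}
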