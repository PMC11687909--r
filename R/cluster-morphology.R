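# Unsupervised morphology grouping: k-means on z-scored
# (compactness, eccentricity, solidity), k chosen by mean silhouette over
# a small range, and rule-based naming of the clusters as circular /
# protruded / elongated / mixed.

morph_cols <- c("compactness", "eccentricity", "solidity")

#' k-means fit with multiple restarts
#'
#' Lloyd-type k-means (via [stats::kmeans()]) with `nstart` random
#' restarts, keeping the solution with the lowest within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param features numeric matrix or data frame (rows = cells).
#' @param k number of clusters.
#' @param seed integer seed (local to this call).
#' @param nstart number of restarts.
#' @return List with `centroids` (k x p), `assignments` (1..k),
#'   `tot_withinss`.
#' @export
kmeans_fit <- function(features, k, seed = 0L, nstart = 25L) {
  x <- as.matrix(features)
  if (nrow(x) < k) stop_macmot("need at least k rows")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    # duplicate-point degeneracy: still return a valid partition over the
    # distinct rows, padding centroids by repetition
    ids <- match(asplit(x, 1L), asplit(unique(x), 1L))
    centroids <- unique(x)[rep_len(seq_len(n_distinct), k), , drop = FALSE]
    return(list(centroids = centroids, assignments = ids, tot_withinss = 0))
  }
  km <- local_seed(seed, kmeans(x, centers = k, nstart = nstart, iter.max = 200L))
  list(centroids = km$centers, assignments = km$cluster,
       tot_withinss = km$tot.withinss)
}

mean_silhouette <- function(x, assignments) {
  if (length(unique(assignments)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(assignments, dist(x))
  list(mean = mean(sil[, "sil_width"]),
       min_by_cluster = tapply(sil[, "sil_width"], sil[, "cluster"], min),
       widths = sil[, "sil_width"])
}

#' Select the number of morphology clusters by silhouette
#'
#' Fits k-means for each k in `k_range` and computes the mean silhouette
#' width. The selected k maximizes the mean silhouette; among candidates
#' within `tie_tol` of the maximum, k values whose silhouette plots show
#' negative widths (points assigned to the wrong cluster) or grossly
#' uneven cluster sizes are penalized, mirroring the usual visual
#' silhouette-plot criteria.
#'
#' @param features numeric matrix/data frame (typically z-scored
#'   morphology descriptors).
#' @param k_range candidate k values.
#' @param seed integer seed.
#' @param tie_tol near-tie band on the mean silhouette.
#' @return List with `k` (the selection), `silhouette_by_k`, and a
#'   `diagnostics` data frame (mean width, minimum width, negative-width
#'   flag, cluster-size entropy per k).
#' @export
select_k <- function(features, k_range = 2:5, seed = 0L, tie_tol = 0.02) {
  x <- as.matrix(features)
  if (nrow(x) <= max(k_range)) stop_macmot("need more rows than max(k_range)")
  rows <- lapply(k_range, function(k) {
    fit <- kmeans_fit(x, k, seed = seed + k)
    s <- mean_silhouette(x, fit$assignments)
    sizes <- tabulate(fit$assignments, k)
    p <- sizes / sum(sizes)
    data.frame(k = k, mean_width = s$mean,
               min_width = min(s$min_by_cluster),
               has_negative = any(s$min_by_cluster < 0),
               size_entropy = -sum(p * log(p)) / log(k))
  })
  diag <- do.call(rbind, rows)
  best <- max(diag$mean_width)
  cand <- diag[diag$mean_width >= best - tie_tol, , drop = FALSE]
  clean <- cand[!cand$has_negative & cand$size_entropy >= 0.5, , drop = FALSE]
  pick <- if (nrow(clean)) clean else cand
  k_star <- pick$k[which.max(pick$mean_width)]
  list(k = k_star,
       silhouette_by_k = setNames(diag$mean_width, diag$k),
       diagnostics = diag)
}

#' Name morphology clusters by their centroid signatures
#'
#' Rule-based naming on the cluster centroids (z-scored descriptor
#' space): the circular cluster has the highest compactness and solidity
#' with the lowest eccentricity; the elongated cluster the highest
#' eccentricity with above-average solidity; the protruded cluster the
#' lowest compactness and solidity; anything left is mixed (ambiguous,
#' overlapping or transitional cells). If the rules produce an
#' inconsistent assignment (e.g. featureless input), every cluster is
#' named `"mixed"` with a warning.
#'
#' @param centroids k x 3 matrix of cluster centroids with columns
#'   `compactness`, `eccentricity`, `solidity` (z-scored).
#' @return Character vector of names, one per cluster.
#' @export
name_clusters <- function(centroids) {
  z <- as.matrix(centroids)[, morph_cols, drop = FALSE]
  k <- nrow(z)
  if (!all(is.finite(z)) || nrow(unique(z)) < k) {
    warning("cluster centroids are degenerate; naming all clusters 'mixed'")
    return(rep("mixed", k))
  }
  names_out <- rep("mixed", k)
  avail <- seq_len(k)
  pick <- function(score, set) set[which.max(score[set])]
  circ <- pick(z[, "compactness"] + z[, "solidity"] - z[, "eccentricity"], avail)
  names_out[circ] <- "circular"; avail <- setdiff(avail, circ)
  if (length(avail)) {
    elo <- pick(z[, "eccentricity"] + z[, "solidity"], avail)
    names_out[elo] <- "elongated"; avail <- setdiff(avail, elo)
  }
  if (length(avail)) {
    pro <- pick(-(z[, "compactness"] + z[, "solidity"]), avail)
    names_out[pro] <- "protruded"; avail <- setdiff(avail, pro)
  }
  # consistency: the rules must agree with the raw orderings they encode
  ok <- TRUE
  if (all(c("circular", "protruded") %in% names_out))
    ok <- ok && z[match("circular", names_out), "solidity"] >
      z[match("protruded", names_out), "solidity"]
  if (all(c("elongated", "protruded") %in% names_out))
    ok <- ok && z[match("elongated", names_out), "eccentricity"] >
      z[match("protruded", names_out), "eccentricity"]
  if (!ok) {
    warning("cluster naming rules conflict; naming all clusters 'mixed'")
    return(rep("mixed", k))
  }
  names_out
}

#' Cluster cells by morphology
#'
#' z-scores the three shape descriptors, selects k by silhouette (unless
#' given), fits k-means and names the clusters. z-scoring makes the
#' result invariant to affine rescaling of the raw descriptor units.
#'
#' @param feature_table data frame with columns `compactness`,
#'   `eccentricity`, `solidity` (e.g. from [macrophage_cohort()] or
#'   [feature_table()]).
#' @param k fixed number of clusters, or `NULL` to select by silhouette.
#' @param k_range candidate k values when selecting.
#' @param seed integer seed.
#' @return Object of class `morph_clusters`: `k`, `assignments`,
#'   `cluster_names` (per cluster), `centroids` (z-space), `centroids_raw`,
#'   `silhouette_by_k`, `diagnostics`, `scaling`, and `table` (the input
#'   with `cluster` and `cluster_name` columns appended).
#' @export
cluster_morphology <- function(feature_table, k = NULL, k_range = 2:5,
                               seed = 0L) {
  miss <- setdiff(morph_cols, names(feature_table))
  if (length(miss)) stop_macmot("missing feature columns: ",
                                paste(miss, collapse = ", "))
  x <- as.matrix(feature_table[, morph_cols])
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0] <- 1
  z <- scale(x, center = ctr, scale = scl)
  sel <- NULL
  if (is.null(k)) {
    sel <- select_k(z, k_range = k_range, seed = seed)
    k <- sel$k
  }
  fit <- kmeans_fit(z, k, seed = seed + k)
  nm <- name_clusters(fit$centroids)
  raw <- sweep(sweep(fit$centroids, 2L, scl, "*"), 2L, ctr, "+")
  tab <- feature_table
  tab$cluster <- fit$assignments
  tab$cluster_name <- nm[fit$assignments]
  structure(list(
    k = k, assignments = fit$assignments, cluster_names = nm,
    centroids = fit$centroids, centroids_raw = raw,
    silhouette_by_k = if (is.null(sel)) NULL else sel$silhouette_by_k,
    diagnostics = if (is.null(sel)) NULL else sel$diagnostics,
    scaling = list(center = ctr, scale = scl),
    table = tab
  ), class = "morph_clusters")
}

#' @export
print.morph_clusters <- function(x, ...) {
  cat("morph_clusters: k =", x$k, "\n")
  tb <- table(x$table$cluster_name)
  print(tb)
  invisible(x)
}
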