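# Group-median affective space, complete-linkage clustering with
# silhouette validation, and the per-participant cluster-dispersion
# statistic.

#' Group-level affective space
#'
#' Elementwise median (by default) of the participants' scaled DSVs.
#' The median is preferred because dissimilarity data tend to be
#' right-skewed; the mean is available for comparison.
#'
#' @param scaled_dsvs Matrix (participants x pairs) or list of
#'   equal-length DSVs, each scaled to `[0, 1]`.
#' @param stat `"median"` (default) or `"mean"`.
#' @return List of class `group_space` with `median_dsv`,
#'   `n_participants`, `stat`.
#' @export
group_median <- function(scaled_dsvs, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  m <- as_dsv_matrix(scaled_dsvs)
  agg <- if (stat == "median") {
    apply(m, 2L, median)
  } else {
    colMeans(m)
  }
  structure(list(median_dsv = agg, n_participants = nrow(m), stat = stat),
            class = "group_space")
}

as_dsv_matrix <- function(scaled_dsvs) {
  if (is.list(scaled_dsvs) && !is.data.frame(scaled_dsvs)) {
    len <- vapply(scaled_dsvs, length, integer(1L))
    if (length(unique(len)) != 1L) {
      stop_invalid("all DSVs must have equal length")
    }
    m <- do.call(rbind, scaled_dsvs)
  } else {
    m <- as.matrix(scaled_dsvs)
  }
  if (nrow(m) < 1L) stop_invalid("need at least one DSV")
  m
}

# Accept a group_space, a DSV, or a square DSM and return the DSM.
as_dsm <- function(x) {
  if (inherits(x, "group_space")) x <- x$median_dsv
  if (is.matrix(x) && nrow(x) == ncol(x)) return(as.matrix(x))
  dsv_to_dsm(x)
}

#' Complete-linkage dendrogram of an affective space
#'
#' Agglomerative hierarchical clustering with the complete-linkage
#' (maximum) merge rule on the pair dissimilarities; merge heights are
#' monotonically nondecreasing.
#'
#' @param space A `group_space`, DSV, or square DSM.
#' @return An `hclust` object.
#' @export
complete_linkage <- function(space) {
  dsm <- as_dsm(space)
  if (anyNA(dsm)) stop_invalid("dissimilarities must not contain NA")
  hclust(as.dist(dsm), method = "complete")
}

#' Cut a dendrogram into k clusters
#'
#' Cluster labels are integers 1..k in order of first appearance along
#' the canonical item order; cuts at successive k are nested
#' refinements.
#'
#' @param dendrogram An `hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster assignments, named by item.
#' @export
cut_dendrogram <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  if (k < 1L || k > n) stop_invalid("k must be between 1 and %d", n)
  cutree(dendrogram, k = k)
}

#' Mean silhouette of a clustering
#'
#' For each item, `a` is its mean dissimilarity to co-members and `b`
#' the smallest mean dissimilarity to any other cluster; the item's
#' silhouette is `(b - a) / max(a, b)` (0 for singletons), and the
#' index is the mean over items, in `[-1, 1]`.
#'
#' @param space A `group_space`, DSV, or square DSM.
#' @param assignment Cluster assignment vector (length n).
#' @return Mean silhouette width.
#' @export
silhouette_index <- function(space, assignment) {
  dsm <- as_dsm(space)
  n <- nrow(dsm)
  if (length(assignment) != n) {
    stop_invalid("assignment length must match the number of items")
  }
  labels <- unique(assignment)
  k <- length(labels)
  if (k < 2L) stop_invalid("silhouette is undefined for k < 2")
  if (k > n - 1L) stop_invalid("silhouette requires k <= n - 1")
  # Mean dissimilarity from every item to every cluster.
  sums <- rowsum(t(dsm), assignment) # cluster x item sums
  sizes <- as.vector(table(assignment)[rownames(sums)])
  s <- vapply(seq_len(n), function(i) {
    own <- as.character(assignment[i])
    size_own <- sizes[match(own, rownames(sums))]
    if (size_own == 1L) return(0)
    a <- sums[own, i] / (size_own - 1L)
    others <- setdiff(rownames(sums), own)
    b <- min(sums[others, i] / sizes[match(others, rownames(sums))])
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

#' Silhouette profile over candidate cluster counts
#'
#' Cuts the complete-linkage dendrogram at each `k` in `k_range` and
#' records the mean silhouette.  Selected cluster counts are the
#' "upticks" of the profile -- local maxima with `s(k) > s(k - 1)` and
#' `s(k) >= s(k + 1)` -- plus always the global maximum.
#'
#' @param space A `group_space`, DSV, or square DSM.
#' @param k_range Candidate cluster counts (default `2:15`, clipped to
#'   `n - 1`).
#' @return List of class `silhouette_profile` with `k`, `silhouette`,
#'   `selected_k`.
#' @export
scan_k <- function(space, k_range = 2:15) {
  dsm <- as_dsm(space)
  n <- nrow(dsm)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop_invalid("k_range must contain values in [2, n - 1]")
  dend <- complete_linkage(dsm)
  sil <- vapply(k_range, function(k) {
    silhouette_index(dsm, cut_dendrogram(dend, k))
  }, numeric(1L))
  m <- length(sil)
  is_uptick <- vapply(seq_len(m), function(i) {
    up <- i > 1L && sil[i] > sil[i - 1L]
    down_ok <- i == m || sil[i] >= sil[i + 1L]
    up && down_ok
  }, logical(1L))
  selected <- sort(unique(c(k_range[which.max(sil)], k_range[is_uptick])))
  structure(list(k = k_range, silhouette = sil, selected_k = selected,
                 dendrogram = dend),
            class = "silhouette_profile")
}

#' A validated cluster solution
#'
#' @param space A `group_space`, DSV, or square DSM.
#' @param k Number of clusters.
#' @param labels Optional descriptive names, one per cluster (in
#'   cluster-number order); cluster semantics ("erotic", "medical",
#'   ...) are human judgments supplied by the analyst, never inferred.
#' @return List of class `cluster_solution` with `k`, `assignment`,
#'   `silhouette_mean`, `labels`.
#' @export
cluster_solution <- function(space, k, labels = NULL) {
  dsm <- as_dsm(space)
  dend <- complete_linkage(dsm)
  assignment <- cut_dendrogram(dend, k)
  if (!is.null(labels)) {
    if (length(labels) != k) stop_invalid("need exactly %d labels", k)
    assignment <- setNames(labels[assignment], names(assignment))
  }
  sil <- if (k >= 2L && k <= nrow(dsm) - 1L) {
    silhouette_index(dsm, assignment)
  } else {
    NA_real_
  }
  structure(list(k = as.integer(k), assignment = assignment,
                 silhouette_mean = sil, labels = labels),
            class = "cluster_solution")
}

#' Cluster dispersion for one participant
#'
#' The participant's dispersion of cluster `c` is the median of their
#' dissimilarities over all within-cluster item pairs, divided by the
#' cardinality of the cluster (its number of items):
#' `median(D_c) / |c|`.  Larger values indicate a less cohesive
#' cluster in that participant's affective space.  The median (rather
#' than the mean) is used because dissimilarity data tend to be
#' skewed.
#'
#' @param participant_dsv The participant's scaled DSV.
#' @param assignment Cluster assignment vector over items.
#' @param cluster Label of the cluster to evaluate (>= 2 items).
#' @return The dispersion statistic (nonnegative scalar).
#' @export
dispersion <- function(participant_dsv, assignment, cluster) {
  n <- length(assignment)
  if (length(participant_dsv) != choose(n, 2L)) {
    stop_invalid("DSV length does not match the assignment's item count")
  }
  members <- which(assignment == cluster)
  if (length(members) < 2L) {
    stop_invalid("dispersion is undefined for singleton cluster '%s'", cluster)
  }
  ij <- pair_index(length(members))
  pos <- pair_position(members[ij[, 1L]], members[ij[, 2L]], n)
  median(participant_dsv[pos]) / length(members)
}

#' Participant-by-cluster dispersion table
#'
#' Applies the group-level cluster assignment uniformly to every
#' participant's scaled DSV, so dispersions are comparable across
#' participants (same stimuli in every cluster).
#'
#' @param scaled_dsvs Matrix (participants x pairs) or list of scaled
#'   DSVs.
#' @param solution A `cluster_solution`, or a bare assignment vector.
#' @param participant_ids Optional row ids.
#' @return `data.frame` with `participant_id` and one dispersion
#'   column per cluster (clusters with >= 2 items).
#' @export
dispersion_table <- function(scaled_dsvs, solution,
                             participant_ids = NULL) {
  m <- as_dsv_matrix(scaled_dsvs)
  assignment <- if (inherits(solution, "cluster_solution")) {
    solution$assignment
  } else {
    solution
  }
  sizes <- table(assignment)
  clusters <- names(sizes)[sizes >= 2L]
  if (!length(clusters)) stop_invalid("no cluster has >= 2 items")
  ids <- participant_ids %||% rownames(m) %||%
    sprintf("p%03d", seq_len(nrow(m)))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (cl in clusters) {
    out[[paste0("cluster_", cl)]] <- apply(m, 1L, dispersion,
                                           assignment = assignment,
                                           cluster = cl)
  }
  out
}
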