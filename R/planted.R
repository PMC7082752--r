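# Planted affective spaces: latent item configurations per participant
# whose cluster spreads depend linearly on trait z-scores.  These are
# the ground truth against which the whole pipeline is validated.

#' Effect specification for planted cluster dispersion
#'
#' Describes how a participant's trait z-scores modulate the spread of
#' each planted cluster.  For cluster `c` and participant `i` the
#' latent spread is
#' `spread = baseline + sum_t slope[c, t] * z_i(t) + e`,
#' with `e ~ N(0, noise_sd^2)`, floored at `floor_frac * baseline` so
#' that distances stay positive.
#'
#' The defaults encode the package's reference condition: Neuroticism
#' increases and Conscientiousness decreases the spread of the
#' fear/violence cluster, with slopes and noise chosen so that the two
#' standardized effects are about 0.35 each and jointly explain about a
#' quarter of the spread variance.
#'
#' @param slopes Named list: one element per affected cluster label,
#'   each a named numeric vector of per-trait slopes (latent distance
#'   units per trait SD).  `NULL` plants no trait effect.
#' @param baseline Baseline cluster spread (latent units), a single
#'   value or a named per-cluster vector; cluster labels missing from
#'   a named vector fall back to the mean baseline.
#' @param noise_sd Standard deviation of the spread noise (> 0).
#' @param floor_frac Lower floor for the spread, as a fraction of the
#'   baseline.
#' @return An object of class `effect_spec`.
#' @examples
#' effect_spec(slopes = list(fear_violence = c(N = 0.025, C = -0.025)))
#' @export
effect_spec <- function(slopes = list(fear_violence = c(N = 0.025, C = -0.025)),
                        baseline = c(nature_people_sports = 0.25,
                                     erotic = 0.30,
                                     fear_violence = 0.18,
                                     medical = 0.18),
                        noise_sd = 0.06, floor_frac = 0.1) {
  if (any(noise_sd <= 0)) stop_invalid("noise_sd must be > 0")
  if (any(baseline <= 0)) stop_invalid("baseline must be > 0")
  facs <- big_five_factors()
  for (cl in names(slopes)) {
    sl <- slopes[[cl]]
    if (is.null(names(sl)) || !all(names(sl) %in% facs)) {
      stop_invalid("slopes for cluster '%s' must be named by traits %s",
                   cl, paste(facs, collapse = ", "))
    }
  }
  structure(list(slopes = slopes, baseline = baseline,
                 noise_sd = noise_sd, floor_frac = floor_frac),
            class = "effect_spec")
}

#' Default item partition for a stimulus set
#'
#' Maps the nine default categories onto the four affective clusters the
#' package's reference condition plants: an erotic cluster, a
#' fear/violence cluster, a medical cluster (accident imagery) and a
#' generic positive cluster.  The first two-way split of this partition
#' (positive vs. negative) is the planted coarse structure.  Unknown
#' categories fall back to one cluster per category.
#'
#' @param stimuli A stimulus set.
#' @return Named character vector: item_id -> cluster label.
#' @export
default_partition <- function(stimuli) {
  validate_stimulus_set(stimuli)
  map <- c(animals = "nature_people_sports",
           people = "nature_people_sports",
           nature = "nature_people_sports",
           food = "nature_people_sports",
           household = "nature_people_sports",
           erotic = "erotic",
           accidents = "medical",
           violence = "fear_violence",
           war = "fear_violence")
  lab <- map[stimuli$category]
  lab[is.na(lab)] <- stimuli$category[is.na(lab)]
  setNames(as.character(lab), stimuli$item_id)
}

#' Default latent cluster centers
#'
#' Places cluster centroids in the 2D latent space (valence-like axis
#' first, arousal-like axis second) so that positive and negative
#' superclusters are separated along the first axis and their
#' subclusters along the second, giving the two-level (2-in-4)
#' hierarchical geometry the analysis is designed to detect.
#'
#' @param cluster_labels Character vector of cluster labels.
#' @param d Latent dimensionality (extra dimensions get center 0).
#' @return Matrix with one row per cluster label.
#' @export
default_cluster_centers <- function(cluster_labels, d = 2L) {
  known <- rbind(
    nature_people_sports = c(2.6,  0.95),
    erotic               = c(2.6, -0.95),
    fear_violence        = c(-2.6,  0.90),
    medical              = c(-2.6, -0.90)
  )
  labels <- unique(cluster_labels)
  centers <- matrix(0, nrow = length(labels), ncol = max(2L, d),
                    dimnames = list(labels, NULL))
  unknown <- setdiff(labels, rownames(known))
  centers[intersect(labels, rownames(known)), 1:2] <-
    known[intersect(labels, rownames(known)), ]
  if (length(unknown)) {
    theta <- 2 * pi * (seq_along(unknown) - 0.5) / length(unknown) + pi / 7
    centers[unknown, 1:2] <- 1.3 * cbind(cos(theta), sin(theta))
  }
  centers[, seq_len(d), drop = FALSE]
}

#' Plant per-participant affective spaces
#'
#' For each participant, draws item coordinates in a latent space
#' (default 2D: valence-like and arousal-like axes) around fixed
#' cluster centroids, with per-cluster spread
#' `baseline + sum slope * z(trait) + noise`, floored at a small
#' positive value.  The true dissimilarity matrix is the Euclidean
#' distance matrix of the latent coordinates, so downstream estimators
#' can be validated by round trip.
#'
#' @param stimuli A stimulus set.
#' @param traits A trait table (one planted space per row).
#' @param effects An [effect_spec()].
#' @param partition Named item -> cluster label vector; defaults to
#'   [default_partition()].
#' @param centers Cluster-center matrix; defaults to
#'   [default_cluster_centers()].
#' @param d Latent dimensionality (default 2).
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return List of `planted_space` objects with elements
#'   `participant_id`, `latent_coords`, `true_dsm`, `partition`,
#'   `spread` (realized per-cluster spreads).
#' @export
make_planted_spaces <- function(stimuli, traits, effects = effect_spec(),
                                partition = default_partition(stimuli),
                                centers = NULL, d = 2L, seed = NULL) {
  validate_stimulus_set(stimuli)
  validate_trait_table(traits)
  if (nrow(stimuli) < 1L || nrow(traits) < 1L) {
    stop_invalid("stimuli and traits must be nonempty")
  }
  if (!all(stimuli$item_id %in% names(partition))) {
    stop_invalid("partition must cover every item")
  }
  partition <- partition[stimuli$item_id]
  labels <- unique(partition)
  bad <- setdiff(names(effects$slopes), labels)
  if (length(bad)) {
    stop_invalid("effect references unknown cluster(s): %s",
                 paste(bad, collapse = ", "))
  }
  if (is.null(centers)) centers <- default_cluster_centers(labels, d)
  if (!all(labels %in% rownames(centers))) {
    stop_invalid("centers must provide a row for every cluster label")
  }

  baseline <- effects$baseline
  if (is.null(names(baseline))) {
    baseline <- setNames(rep(baseline[1L], length(labels)), labels)
  } else {
    fallback <- mean(baseline)
    baseline <- setNames(ifelse(labels %in% names(baseline),
                                baseline[labels], fallback), labels)
  }
  z <- trait_zscores(traits)
  n_items <- nrow(stimuli)

  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(traits)), function(i) {
    spread <- vapply(labels, function(cl) {
      s <- baseline[[cl]]
      sl <- effects$slopes[[cl]]
      if (!is.null(sl)) s <- s + sum(sl * z[i, names(sl)])
      s <- s + rnorm(1L, 0, effects$noise_sd)
      max(s, effects$floor_frac * baseline[[cl]])
    }, numeric(1L))
    coords <- matrix(0, n_items, d)
    for (cl in labels) {
      idx <- which(partition == cl)
      coords[idx, ] <- matrix(rep(centers[cl, seq_len(d)], each = length(idx)),
                              ncol = d) +
        matrix(rnorm(length(idx) * d, 0, spread[[cl]]), ncol = d)
    }
    rownames(coords) <- stimuli$item_id
    dsm <- as.matrix(dist(coords))
    structure(list(participant_id = traits$participant_id[i],
                   latent_coords = coords,
                   true_dsm = dsm,
                   partition = partition,
                   spread = spread),
              class = "planted_space")
  })
}
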