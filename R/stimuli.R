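# Stimulus sets: emotionally charged items with normative valence and
# arousal ratings, organised into semantic categories.

# Default category prototypes on the 9-point valence/arousal scales.
# Positive and negative categories sit on opposite sides of the valence
# axis, and within each side the prototypes split again along arousal,
# so that a coarse positive/negative partition and a finer 4-way
# partition are both present in the generated material.  The centers are
# configuration values, not normative claims about any picture database.
.default_category_prototypes <- function() {
  data.frame(
    category = c("animals", "people", "nature", "food", "household",
                 "erotic", "accidents", "violence", "war"),
    valence  = c(7.0, 7.2, 7.4, 6.9, 5.8, 6.6, 2.6, 2.2, 2.0),
    arousal  = c(4.0, 3.8, 3.4, 4.2, 2.9, 6.4, 5.4, 6.3, 6.5),
    stringsAsFactors = FALSE
  )
}

# Prototypes for a non-default number of categories: evenly spaced on a
# circle in valence/arousal space, centred at (5, 5).
.circle_prototypes <- function(n_categories) {
  theta <- 2 * pi * (seq_len(n_categories) - 1L) / n_categories
  data.frame(
    category = sprintf("cat%02d", seq_len(n_categories)),
    valence  = 5 + 3 * cos(theta),
    arousal  = 5 + 3 * sin(theta),
    stringsAsFactors = FALSE
  )
}

#' Generate a stimulus set
#'
#' Creates an ordered set of `n_categories * per_category` items, each
#' with a category label and normative valence/arousal ratings on the
#' 1--9 scale.  Ratings are drawn around fixed per-category prototype
#' centers with Gaussian jitter and clamped to the rating scale.  The
#' row order of the returned table is canonical: it fixes the element
#' order of every dissimilarity vector (DSV) derived from the set.
#'
#' The default configuration (9 categories, 6 items each) yields the
#' 54-item set used throughout the package, whose DSV has
#' `choose(54, 2) == 1431` elements.
#'
#' @param n_categories Number of categories (default 9).
#' @param per_category Items per category (default 6).
#' @param seed Integer seed; the set is deterministic given the seed.
#' @param jitter_sd Standard deviation of the rating jitter around the
#'   category prototype (rating-scale units).
#'
#' @return A `data.frame` of class `stimulus_set` with columns
#'   `item_id`, `category`, `valence`, `arousal`.
#' @examples
#' stim <- make_stimulus_set(seed = 1)
#' nrow(stim)          # 54
#' table(stim$category)
#' @export
make_stimulus_set <- function(n_categories = 9L, per_category = 6L,
                              seed = NULL, jitter_sd = 0.35) {
  if (n_categories < 1L || per_category < 1L) {
    stop_invalid("n_categories and per_category must be positive counts")
  }
  if (!is.null(seed)) set.seed(seed)
  proto <- if (n_categories == 9L) {
    .default_category_prototypes()
  } else if (n_categories < 9L) {
    .default_category_prototypes()[seq_len(n_categories), , drop = FALSE]
  } else {
    .circle_prototypes(n_categories)
  }
  n <- n_categories * per_category
  category <- rep(proto$category, each = per_category)
  valence <- rep(proto$valence, each = per_category) +
    rnorm(n, 0, jitter_sd)
  arousal <- rep(proto$arousal, each = per_category) +
    rnorm(n, 0, jitter_sd)
  out <- data.frame(
    item_id  = sprintf("img%02d_%s", seq_len(n), category),
    category = category,
    valence  = pmin(pmax(valence, 1), 9),
    arousal  = pmin(pmax(arousal, 1), 9),
    stringsAsFactors = FALSE
  )
  class(out) <- c("stimulus_set", "data.frame")
  out
}

validate_stimulus_set <- function(stimuli) {
  req <- c("item_id", "category", "valence", "arousal")
  if (!all(req %in% names(stimuli))) {
    stop_invalid("stimulus set must have columns %s",
                 paste(req, collapse = ", "))
  }
  if (anyDuplicated(stimuli$item_id)) {
    stop_invalid("stimulus item_ids must be unique")
  }
  invisible(stimuli)
}
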