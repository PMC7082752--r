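# Adaptive multi-arrangement protocol: lift-the-weakest trial selection
# and evidence accounting over item pairs.

#' Create an empty evidence matrix
#'
#' Evidence accumulates per item pair over a session; a pair's evidence
#' grows each time the two items are arranged together, by the squared
#' on-screen distance between them (larger separations are measured
#' more reliably relative to placement noise).
#'
#' @param item_ids Character vector of item ids.
#' @return A zero `n x n` matrix with `item_ids` dimnames.
#' @export
empty_evidence <- function(item_ids) {
  n <- length(item_ids)
  matrix(0, n, n, dimnames = list(item_ids, item_ids))
}

#' Select the next trial subset (lift-the-weakest)
#'
#' Picks the item pair with the globally least accumulated evidence
#' (ties broken by lowest pair index in row-major order) and then fills
#' the remaining slots greedily: each added item is the one whose pairs
#' with the current subset have the largest summed evidence deficit
#' (`max(threshold - evidence, 0)`); among equal-deficit candidates the
#' one with the least accumulated evidence toward the subset wins, then
#' the lowest item index.  Once no candidate completes any
#' deficient pair, no further items are added (beyond a minimum trial
#' size of 3): keeping late trials small is what lets the arena rescale
#' magnify the separations of still-unresolved tight pairs.  With
#' all-zero evidence the rule yields items `1..max_items`.
#'
#' @param evidence Square evidence matrix.
#' @param max_items Maximum subset size per trial.
#' @param threshold Target evidence per pair; defines the deficit.
#' @return Integer vector of item indices (ascending), length
#'   `min(max_items, n_items)`.
#' @export
select_next_trial <- function(evidence, max_items, threshold = 0.5) {
  n <- nrow(evidence)
  if (is.null(n) || n < 2L) {
    stop_invalid("evidence matrix must cover at least 2 items")
  }
  if (max_items < 2L) stop_invalid("max_items must be at least 2")
  size <- min(max_items, n)
  idx <- pair_index(n)
  ev <- evidence[idx]
  weakest <- idx[which.min(ev), ] # which.min = first minimum = lowest
                                  # row-major pair index
  subset <- as.integer(weakest)
  deficit <- pmax(threshold - evidence, 0)
  diag(deficit) <- 0
  candidates <- setdiff(seq_len(n), subset)
  while (length(subset) < size) {
    gain <- colSums(deficit[subset, candidates, drop = FALSE])
    if (max(gain) <= 0 && length(subset) >= 3L) break
    best <- which(gain == max(gain))
    if (length(best) > 1L) {
      # Among equal-deficit candidates prefer the one with the least
      # accumulated evidence toward the current subset: evidence grows
      # with squared separation, so this favors close neighbors of the
      # weak pair and lets successive trials zoom into tight clusters.
      acc <- colSums(evidence[subset, candidates[best], drop = FALSE])
      best <- best[which.min(acc)] # first min = lowest index
    }
    pick <- candidates[best[1L]]
    subset <- c(subset, pick)
    candidates <- setdiff(candidates, pick)
  }
  sort(subset)
}

#' Accumulate evidence from one trial
#'
#' Each within-trial pair's evidence increases by the squared distance
#' between the two items in the trial's arena coordinates; a pair
#' placed at identical coordinates carries no scale information and
#' contributes zero.  All other pairs are unchanged.
#'
#' @param evidence Square evidence matrix.
#' @param trial A trial record: list with `item_ids` (or integer
#'   `items`) and a 2-column `coords` matrix.
#' @return The updated evidence matrix.
#' @export
update_evidence <- function(evidence, trial) {
  items <- trial_item_indices(trial, rownames(evidence))
  coords <- as.matrix(trial$coords)
  if (length(items) != nrow(coords)) {
    stop_invalid("trial coords must have one row per item")
  }
  if (length(items) < 2L) return(evidence)
  d2 <- as.matrix(dist(coords))^2
  evidence[items, items] <- evidence[items, items] + d2
  diag(evidence) <- 0
  evidence
}

# Resolve a trial's items to integer indices into `item_ids`.
trial_item_indices <- function(trial, item_ids) {
  if (!is.null(trial$items)) {
    items <- as.integer(trial$items)
    if (any(items < 1L) || any(items > length(item_ids))) {
      stop_invalid("trial refers to unknown item index")
    }
  } else {
    items <- match(trial$item_ids, item_ids)
    if (anyNA(items)) {
      stop_invalid("trial refers to unknown item id(s): %s",
                   paste(trial$item_ids[is.na(items)], collapse = ", "))
    }
  }
  items
}
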