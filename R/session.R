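# Simulated multi-arrangement sessions on planted affective spaces.

#' Protocol parameters for a multi-arrangement session
#'
#' @param max_items Maximum items shown per trial (default 10, the
#'   usual visibility limit of the task).
#' @param threshold Evidence each pair must accumulate before the
#'   session terminates.
#' @param placement_noise_sd SD of the Gaussian placement noise, in
#'   arena-radius units (0.05 = 5% of the arena radius).
#' @param max_trials Trial-count cap; exceeding it raises a
#'   configuration error (the protocol cannot terminate).
#' @return An object of class `arrangement_protocol`.
#' @export
arrangement_protocol <- function(max_items = 10L, threshold = 0.5,
                                 placement_noise_sd = 0.05,
                                 max_trials = 2000L) {
  if (max_items < 3L) {
    stop_invalid("max_items must be >= 3 (a 2-item trial carries only one unconstrained distance)")
  }
  if (threshold <= 0) stop_invalid("threshold must be > 0")
  if (placement_noise_sd < 0) stop_invalid("placement_noise_sd must be >= 0")
  structure(list(max_items = as.integer(max_items), threshold = threshold,
                 placement_noise_sd = placement_noise_sd,
                 max_trials = as.integer(max_trials)),
            class = "arrangement_protocol")
}

# Arrange a subset in the unit-radius arena: classical MDS of the true
# dissimilarities restricted to the subset, rescaled to fill the arena,
# plus isotropic Gaussian placement noise in arena units.
.arrange_subset <- function(true_dsm, items, noise_sd) {
  d_sub <- true_dsm[items, items]
  coords <- suppressWarnings(cmdscale(as.dist(d_sub), k = 2L))
  if (is.null(dim(coords)) || ncol(coords) < 2L) {
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  }
  r <- max(sqrt(rowSums(coords^2)))
  if (r > 0) coords <- coords / r
  if (noise_sd > 0) {
    coords <- coords + matrix(rnorm(length(coords), 0, noise_sd),
                              ncol = 2L)
    r <- max(sqrt(rowSums(coords^2)))
    if (r > 1) coords <- coords / r
  }
  unname(coords)
}

#' Simulate a full multi-arrangement session
#'
#' Repeatedly applies [select_next_trial()] to the running evidence
#' matrix; each selected subset is placed in the arena by classical MDS
#' of the planted dissimilarities restricted to the subset, rescaled
#' into the unit-radius arena, with Gaussian placement noise.  The
#' session terminates when every item pair's evidence reaches the
#' protocol threshold.
#'
#' Because each subset is rescaled to fill the arena, trials devoted to
#' a tight cluster magnify its internal distances, which is what lets
#' the adaptive protocol resolve fine structure and terminate.
#'
#' @param space A `planted_space` (or any list with `true_dsm` and
#'   optionally `participant_id`).
#' @param protocol An [arrangement_protocol()].
#' @param seed Integer seed.
#' @return A `session_log`: list with `participant_id`, `item_ids`,
#'   `trials` (each a list with `trial_index`, `item_ids`, `items`,
#'   `coords`), and the final `evidence` matrix.
#' @export
simulate_session <- function(space, protocol = arrangement_protocol(),
                             seed = NULL) {
  true_dsm <- space$true_dsm
  item_ids <- rownames(true_dsm) %||% sprintf("item%03d", seq_len(nrow(true_dsm)))
  n <- nrow(true_dsm)
  if (n < 2L) stop_invalid("need at least 2 items to run a session")
  if (!is.null(seed)) set.seed(seed)

  evidence <- empty_evidence(item_ids)
  trials <- vector("list", 64L)
  t_i <- 0L
  repeat {
    idx <- pair_index(n)
    if (min(evidence[idx]) >= protocol$threshold) break
    if (t_i >= protocol$max_trials) {
      stop_invalid(paste0(
        "session did not terminate within %d trials; ",
        "protocol threshold %.3g appears unreachable"),
        protocol$max_trials, protocol$threshold)
    }
    items <- select_next_trial(evidence, protocol$max_items,
                               protocol$threshold)
    coords <- .arrange_subset(true_dsm, items,
                              protocol$placement_noise_sd)
    t_i <- t_i + 1L
    trial <- list(trial_index = t_i, item_ids = item_ids[items],
                  items = items, coords = coords)
    if (t_i > length(trials)) trials <- c(trials, vector("list", t_i))
    trials[[t_i]] <- trial
    evidence <- update_evidence(evidence, trial)
  }
  structure(list(participant_id = space$participant_id %||% "sim",
                 item_ids = item_ids,
                 trials = trials[seq_len(t_i)],
                 evidence = evidence),
            class = "session_log")
}

#' Simulate sessions for a whole cohort
#'
#' @param spaces List of planted spaces.
#' @param protocol An [arrangement_protocol()].
#' @param seed Integer seed; participant `i` uses `seed + i`.
#' @return List of `session_log` objects.
#' @export
simulate_cohort_sessions <- function(spaces,
                                     protocol = arrangement_protocol(),
                                     seed = NULL) {
  lapply(seq_along(spaces), function(i) {
    simulate_session(spaces[[i]], protocol,
                     seed = if (is.null(seed)) NULL else seed + i)
  })
}
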