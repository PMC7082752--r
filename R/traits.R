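# Big Five personality trait tables (NEO-FFI style T-scores).

#' Big Five trait factor labels
#'
#' Canonical order of the five-factor model traits: Neuroticism,
#' Extraversion, Openness, Agreeableness, Conscientiousness.
#' @export
big_five_factors <- function() c("N", "E", "O", "A", "C")

#' Simulate a table of Big Five T-scores
#'
#' Draws `n_participants` rows from a multivariate Gaussian with mean
#' 50 and standard deviation 10 in every trait (the T-score convention
#' of age/gender-normed NEO-FFI scores) and the requested trait
#' intercorrelation structure.
#'
#' @param n_participants Number of rows.
#' @param trait_correlation 5x5 correlation matrix (symmetric, positive
#'   semi-definite, unit diagonal).  Defaults to identity; the package
#'   makes no claim about population trait intercorrelations.
#' @param seed Integer seed.
#' @param mean,sd T-score location and scale (defaults 50 and 10).
#'
#' @return A `data.frame` of class `trait_table` with columns
#'   `participant_id`, `N`, `E`, `O`, `A`, `C`.
#' @examples
#' tt <- make_trait_table(58, seed = 2)
#' colMeans(tt[big_five_factors()])
#' @export
make_trait_table <- function(n_participants,
                             trait_correlation = diag(5),
                             seed = NULL, mean = 50, sd = 10) {
  if (n_participants < 1L) {
    stop_invalid("n_participants must be a positive count")
  }
  R <- as.matrix(trait_correlation)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) {
    stop_invalid("trait_correlation must be symmetric")
  }
  if (nrow(R) != 5L || ncol(R) != 5L) {
    stop_invalid("trait_correlation must be 5 x 5")
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop_invalid("trait_correlation must have unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_invalid("trait_correlation must be positive semi-definite")
  }
  if (!is.null(seed)) set.seed(seed)
  scores <- MASS::mvrnorm(n_participants, mu = rep(mean, 5L),
                          Sigma = sd^2 * R)
  scores <- matrix(scores, ncol = 5L)
  colnames(scores) <- big_five_factors()
  out <- data.frame(
    participant_id = sprintf("p%03d", seq_len(n_participants)),
    scores,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trait_table", "data.frame")
  out
}

validate_trait_table <- function(traits) {
  facs <- big_five_factors()
  if (!all(facs %in% names(traits))) {
    stop_invalid("trait table must have columns %s",
                 paste(facs, collapse = ", "))
  }
  if (any(!complete.cases(traits[facs]))) {
    stop_invalid("trait table rows used for analysis must be complete")
  }
  invisible(traits)
}

# Nominal z-scores of a trait table: (T - 50) / 10.  Used when planting
# effects, so that a configured slope is expressed per population SD.
trait_zscores <- function(traits, mean = 50, sd = 10) {
  facs <- big_five_factors()
  z <- as.matrix(traits[facs])
  (z - mean) / sd
}
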