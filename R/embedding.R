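# Classical MDS embedding of the group-median affective space and the
# partial-correlation logic used to label its dimensions with valence
# and arousal.

#' Classical (Torgerson) multidimensional scaling of a DSM
#'
#' Double-centers the squared dissimilarities and eigendecomposes the
#' resulting Gram matrix; coordinates are the top-`d` eigenvectors
#' scaled by the square roots of their eigenvalues, ordered by
#' decreasing eigenvalue.  Variance explained per dimension is its
#' eigenvalue divided by the sum of the *positive* eigenvalues
#' (non-Euclidean DSMs produce negative eigenvalues, which carry no
#' representable variance and are excluded from the denominator).
#'
#' @param dsm Square symmetric dissimilarity matrix (or `group_space`
#'   or DSV).
#' @param d Number of dimensions to return; if fewer positive
#'   eigenvalues exist, the embedding is truncated with a warning.
#' @return List of class `affect_embedding` with `coords` (item x d
#'   matrix), `eigenvalues` (all n), `variance_explained` (per kept
#'   dimension), `d`.
#' @export
classical_mds <- function(dsm, d = 2L) {
  dsm <- as_dsm(dsm)
  if (d < 1L) stop_invalid("d must be >= 1")
  n <- nrow(dsm)
  fit <- suppressWarnings(cmdscale(as.dist(dsm), k = min(d, n - 1L),
                                   eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-12)
  if (d > n_pos) {
    warning(sprintf(
      "only %d positive eigenvalue(s); embedding truncated from %d to %d dimensions",
      n_pos, d, n_pos))
    d <- n_pos
  }
  coords <- as.matrix(fit$points)[, seq_len(d), drop = FALSE]
  colnames(coords) <- sprintf("dim%d", seq_len(d))
  if (!is.null(rownames(dsm))) rownames(coords) <- rownames(dsm)
  ve <- eig[seq_len(d)] / sum(eig[eig > 0])
  structure(list(coords = coords, eigenvalues = eig,
                 variance_explained = ve, d = d),
            class = "affect_embedding")
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' linear regression on `control`; the two-sided p-value uses a t
#' distribution with `n - 3` degrees of freedom.
#'
#' @param x,y,control Equal-length numeric vectors (n >= 4).
#' @return List with `r`, `p`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, control) {
  n <- length(x)
  if (length(y) != n || length(control) != n) {
    stop_invalid("x, y and control must have equal length")
  }
  if (n < 4L) stop_invalid("partial correlation needs n >= 4")
  if (anyNA(c(x, y, control)) || any(!is.finite(c(x, y, control)))) {
    stop_invalid("inputs must be finite")
  }
  rx <- stats::residuals(lm(x ~ control))
  ry <- stats::residuals(lm(y ~ control))
  if (sd(rx) < 1e-12 * max(1, sd(x)) || sd(ry) < 1e-12 * max(1, sd(y))) {
    stop_invalid("degenerate input: zero-variance residuals after removing the control")
  }
  r <- cor(rx, ry)
  df <- n - 3L
  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df)
  list(r = r, p = p, n = n, df = df)
}

#' Label embedding dimensions by valence and arousal
#'
#' For every dimension of the embedding, reports the partial
#' correlation of the item coordinates with normative valence
#' (controlling arousal) and with arousal (controlling valence),
#' together with the dimension's variance explained.  Because the sign
#' of an MDS axis is arbitrary, each dimension is flipped (if needed)
#' so that its correlation with valence is nonnegative, making reports
#' reproducible.
#'
#' @param embedding An `affect_embedding`.
#' @param stimuli The matching stimulus set (same items, same order).
#' @return List with `embedding` (sign-fixed) and `report`, a
#'   `data.frame` with one row per dimension: `dim`,
#'   `variance_explained`, `r_valence`, `p_valence`, `r_arousal`,
#'   `p_arousal`.  Rows are in variance-explained (eigenvalue) order.
#' @export
label_dimensions <- function(embedding, stimuli) {
  validate_stimulus_set(stimuli)
  coords <- embedding$coords
  if (nrow(coords) != nrow(stimuli)) {
    stop_invalid("embedding and stimulus set must have the same items")
  }
  valence <- stimuli$valence
  arousal <- stimuli$arousal
  rows <- vector("list", ncol(coords))
  for (j in seq_len(ncol(coords))) {
    if (cor(coords[, j], valence) < 0) coords[, j] <- -coords[, j]
    pv <- partial_correlation(coords[, j], valence, arousal)
    pa <- partial_correlation(coords[, j], arousal, valence)
    rows[[j]] <- data.frame(dim = j,
                            variance_explained = embedding$variance_explained[j],
                            r_valence = pv$r, p_valence = pv$p,
                            r_arousal = pa$r, p_arousal = pa$p)
  }
  embedding$coords <- coords
  list(embedding = embedding, report = do.call(rbind, rows))
}
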