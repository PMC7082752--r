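# Dissimilarity matrices (DSM) and their vectorized upper triangles
# (DSV), plus the inverse-MDS estimator that reconstructs a full DSM
# from partial 2D arrangements.

#' Vectorize a DSM
#'
#' Extracts the upper triangle of a symmetric dissimilarity matrix in
#' row-major order -- (1,2), (1,3), ..., (1,n), (2,3), ... -- the
#' canonical pair order used by every DSV in the package.  For the
#' default 54-item set this yields a 1,431-element vector.
#'
#' @param dsm Symmetric nonnegative matrix with zero diagonal.
#' @param tol Symmetry tolerance.
#' @return Named numeric vector of length `choose(n, 2)`; names are
#'   `"itemA|itemB"` pair labels when the DSM has dimnames.
#' @export
dsm_to_dsv <- function(dsm, tol = 1e-8) {
  dsm <- as.matrix(dsm)
  n <- nrow(dsm)
  if (n != ncol(dsm)) stop_invalid("DSM must be square")
  if (max(abs(dsm - t(dsm))) > tol * max(1, max(abs(dsm)))) {
    stop_invalid("DSM must be symmetric")
  }
  dsv <- t(dsm)[lower.tri(dsm)] # row-major upper triangle
  if (!is.null(rownames(dsm))) names(dsv) <- pair_labels(rownames(dsm))
  dsv
}

#' Rebuild a DSM from a DSV
#'
#' Inverse of [dsm_to_dsv()]: `dsv_to_dsm(dsm_to_dsv(m))` reproduces
#' `m` for any valid DSM.
#'
#' @param dsv Numeric vector of length `choose(n, 2)`.
#' @param item_ids Optional item ids for dimnames.
#' @return Symmetric matrix with zero diagonal.
#' @export
dsv_to_dsm <- function(dsv, item_ids = NULL) {
  m <- length(dsv)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop_invalid("DSV length %d is not a valid choose(n, 2)", m)
  }
  n <- as.integer(round(n))
  out <- matrix(0, n, n)
  tout <- matrix(0, n, n)
  tout[lower.tri(tout)] <- dsv # fills row-major upper triangle of t()
  out <- t(tout)
  out <- out + t(out)
  if (!is.null(item_ids)) dimnames(out) <- list(item_ids, item_ids)
  out
}

#' Scale a DSV to the unit interval
#'
#' Divides the vector by its maximum dissimilarity, so the largest
#' entry becomes exactly 1.  Applied per participant before group
#' aggregation, making participants' affective spaces comparable
#' despite the arbitrary global scale of arrangement data.
#'
#' @param dsv Nonnegative numeric vector with a positive maximum.
#' @return `dsv / max(dsv)`.
#' @export
scale_dsv <- function(dsv) {
  if (any(dsv < 0)) stop_invalid("DSV entries must be nonnegative")
  m <- max(dsv)
  if (!is.finite(m) || m <= 0) {
    stop_invalid("cannot scale a degenerate (all-zero) DSV")
  }
  dsv / m
}

#' Estimate a full DSM from a session by inverse MDS
#'
#' Reconstructs the complete item-pair dissimilarity structure from
#' the session's partial 2D arrangements.  Each trial observes the
#' within-subset distances only up to an arbitrary trial-specific
#' scale (every subset is rescaled to fill the arena), so the
#' estimator alternates between (1) aligning each trial to the current
#' estimate with a closed-form least-squares scale factor
#' `s_t = sum(d_t * e) / sum(d_t^2)` and (2) re-estimating each pair
#' as the evidence-weighted mean of its aligned trial distances, with
#' per-observation weight equal to the squared aligned distance.
#' Iteration stops when the relative (Frobenius) change of the
#' estimate falls below `tol`.  The final DSM is normalized to unit
#' root-mean-square dissimilarity, fixing the arbitrary global scale.
#'
#' @param session A `session_log` (or list with `trials` and
#'   `item_ids`).
#' @param n_items Number of items; defaults to `length(session$item_ids)`.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum number of alignment iterations.
#' @return List with `dsm` (unit-RMS normalized), `evidence` (summed
#'   aligned squared distances per pair), `iterations`, `converged`.
#' @export
estimate_dsm <- function(session, n_items = NULL, tol = 1e-6,
                         max_iter = 1000L) {
  item_ids <- session$item_ids %||% unique(unlist(
    lapply(session$trials, `[[`, "item_ids")))
  n <- n_items %||% length(item_ids)
  if (length(item_ids) != n) item_ids <- sprintf("item%03d", seq_len(n))
  if (!length(session$trials)) stop_invalid("session has no trials")

  # Long format: one row per within-trial pair observation.
  obs <- lapply(seq_along(session$trials), function(t_i) {
    trial <- session$trials[[t_i]]
    items <- trial_item_indices(trial, item_ids)
    if (length(items) < 2L) return(NULL)
    coords <- as.matrix(trial$coords)
    d <- as.matrix(dist(coords))
    ij <- pair_index(length(items))
    a <- pmin(items[ij[, 1L]], items[ij[, 2L]])
    b <- pmax(items[ij[, 1L]], items[ij[, 2L]])
    cbind(trial = t_i, pair = pair_position(a, b, n), d = d[ij])
  })
  obs <- do.call(rbind, obs)
  if (is.null(obs)) stop_invalid("session has no usable trials")
  pair_id <- obs[, "pair"]
  d <- obs[, "d"]
  trial_id <- obs[, "trial"]

  n_pairs <- choose(n, 2L)
  covered <- sort(unique(pair_id))
  if (length(covered) < n_pairs) {
    missing <- setdiff(seq_len(n_pairs), covered)[1L]
    ij <- pair_index(n)[missing, ]
    stop_invalid("session does not cover pair (%s, %s)",
                 item_ids[ij[1L]], item_ids[ij[2L]])
  }

  pair_f <- factor(pair_id, levels = seq_len(n_pairs))
  trial_f <- factor(trial_id)

  # Initialization: evidence-weighted mean of raw screen distances,
  # weight = squared screen distance.
  w0 <- d^2
  est <- as.vector(rowsum(w0 * d, pair_f) /
                     pmax(rowsum(w0, pair_f), .Machine$double.eps))

  # The update map is homogeneous of degree 1 in the estimate, so its
  # global scale is a free direction; the estimate is renormalized to
  # unit RMS every pass and convergence measured on that scale.
  unit_rms <- function(v) v / max(sqrt(mean(v^2)), .Machine$double.eps)
  est <- unit_rms(est)
  converged <- FALSE
  iter <- 0L
  sum_d2_t <- as.vector(rowsum(d * d, trial_f))
  for (iter in seq_len(max_iter)) {
    e_obs <- est[pair_id]
    s_t <- as.vector(rowsum(d * e_obs, trial_f)) /
      pmax(sum_d2_t, .Machine$double.eps)
    d_aligned <- s_t[as.integer(trial_f)] * d
    w <- d_aligned^2
    new_est <- as.vector(rowsum(w * d_aligned, pair_f) /
                           pmax(rowsum(w, pair_f), .Machine$double.eps))
    new_est <- unit_rms(new_est)
    delta <- sqrt(sum((new_est - est)^2)) / sqrt(sum(est^2))
    est <- new_est
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("inverse-MDS estimator did not converge in %d iterations",
                    max_iter))
  }

  # Final evidence: summed aligned squared distances per pair.
  e_obs <- est[pair_id]
  s_t <- as.vector(rowsum(d * e_obs, trial_f)) /
    pmax(sum_d2_t, .Machine$double.eps)
  w <- (s_t[as.integer(trial_f)] * d)^2
  evidence_dsv <- as.vector(rowsum(w, pair_f))

  est <- unit_rms(est)
  list(dsm = dsv_to_dsm(est, item_ids),
       evidence = dsv_to_dsm(evidence_dsv, item_ids),
       iterations = iter, converged = converged)
}
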