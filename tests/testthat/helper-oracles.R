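# Independent oracles and small fixture builders used across tests.

# Naive O(n^3) complete-linkage agglomeration: returns the sorted merge
# heights.  Written directly from the definition (merge the two
# clusters with the smallest maximum inter-cluster dissimilarity).
naive_complete_linkage_heights <- function(dsm) {
  n <- nrow(dsm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_len(a - 1L)) {
        h <- max(dsm[clusters[[a]], clusters[[b]]])
        if (h < best[1L]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1L])
    a <- best[2L]; b <- best[3L]
    clusters[[b]] <- c(clusters[[b]], clusters[[a]])
    clusters[[a]] <- NULL
  }
  heights
}

# Direct per-item silhouette evaluation, straight from the formula.
silhouette_direct <- function(dsm, assignment) {
  n <- nrow(dsm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment[i]
    mates <- setdiff(which(assignment == own), i)
    if (!length(mates)) {
      s[i] <- 0
      next
    }
    a <- mean(dsm[i, mates])
    b <- min(vapply(setdiff(unique(assignment), own), function(cl) {
      mean(dsm[i, assignment == cl])
    }, numeric(1L)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Normal-equations OLS oracle: beta = (X'X)^{-1} X'y on z-scored data
# with explicit intercept; returns betas, SEs and t stats.
ols_normal_equations <- function(y, X, subset) {
  zs <- function(v) (v - mean(v)) / sd(v)
  yz <- zs(y)
  Xz <- cbind(1, apply(X[, subset, drop = FALSE], 2, zs))
  XtX_inv <- solve(t(Xz) %*% Xz)
  beta <- XtX_inv %*% t(Xz) %*% yz
  res <- yz - Xz %*% beta
  rss <- sum(res^2)
  df <- length(y) - ncol(Xz)
  se <- sqrt(diag(XtX_inv) * rss / df)
  list(beta = drop(beta)[-1L], se = se[-1L],
       t = drop(beta)[-1L] / se[-1L], rss = rss)
}

# Closed-form first-order partial correlation.
partial_cor_recursion <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Random symmetric DSM with zero diagonal.
random_dsm <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# Tiny planted-space fixture used by several files: a small stimulus
# set with the default 4-cluster structure.
tiny_cohort <- function(n_participants = 5, seed = 1) {
  stim <- make_stimulus_set(seed = seed)
  traits <- make_trait_table(n_participants, seed = seed + 1)
  spaces <- make_planted_spaces(stim, traits, seed = seed + 2)
  list(stimuli = stim, traits = traits, spaces = spaces)
}
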