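# Internal helpers shared across modules.

## Canonical pair order: upper triangle of an n x n matrix, row-major,
## i.e. (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).  All DSVs in the
## package use this order; it is fixed by the stimulus-set ordering.

# Row-major position of pair (i, j), i < j, among the C(n, 2) pairs.
pair_position <- function(i, j, n) {
  stopifnot(all(i < j))
  (i - 1L) * n - i * (i - 1L) / 2L + (j - i)
}

# All pairs (i, j) with i < j in canonical row-major order, as a 2-column
# matrix.  t(combn(n, 2)) enumerates exactly this order.
pair_index <- function(n) {
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L))
  }
  t(utils::combn(n, 2L))
}

# Labels "itemA|itemB" for DSV elements.
pair_labels <- function(item_ids) {
  idx <- pair_index(length(item_ids))
  paste(item_ids[idx[, 1L]], item_ids[idx[, 2L]], sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Deterministic per-stage seed derived from a master seed and a stage name.
# Keeps results independent of the order in which stages are run.
derive_seed <- function(master_seed, stage) {
  chars <- utf8ToInt(stage)
  h <- (sum(chars * seq_along(chars)) * 2654435.0) %% 2147483647
  as.integer((abs(master_seed) * 97 + h) %% 2147483647)
}
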