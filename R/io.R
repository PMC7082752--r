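# Plain-text readers and writers for every artifact the pipeline
# exchanges: headered CSV for tables and square DSMs, single-column
# CSV with "itemA|itemB" pair ids for DSVs, JSON-lines for sessions.

#' @rdname affect_io
#' @param stimuli,traits,dsm,dsv,sessions Objects to write.
#' @param path File path.
#' @name affect_io
NULL

#' Read and write pipeline artifacts
#'
#' All tabular artifacts are headered CSV.  DSMs are square CSV with
#' an item-id header row and first column; DSVs are two-column CSV
#' (`pair`, `value`) with pair ids `"itemA|itemB"` in canonical
#' row-major upper-triangle order; sessions are JSON-lines with one
#' trial per line (`participant_id`, `trial_index`, `item_ids`, `x`,
#' `y` in arena units).
#'
#' @rdname affect_io
#' @export
write_stimuli <- function(stimuli, path) {
  write.csv(as.data.frame(stimuli), path, row.names = FALSE)
}

#' @rdname affect_io
#' @export
read_stimuli <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_stimulus_set(out)
  class(out) <- c("stimulus_set", "data.frame")
  out
}

#' @rdname affect_io
#' @export
write_traits <- function(traits, path) {
  write.csv(as.data.frame(traits), path, row.names = FALSE)
}

#' @rdname affect_io
#' @export
read_traits <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(out)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' @rdname affect_io
#' @export
write_dsm <- function(dsm, path) {
  df <- data.frame(item_id = rownames(dsm), as.data.frame(unname(dsm)),
                   check.names = FALSE)
  names(df)[-1L] <- rownames(dsm)
  write.csv(df, path, row.names = FALSE)
}

#' @rdname affect_io
#' @export
read_dsm <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(df[[1L]], names(df)[-1L])
  storage.mode(m) <- "double"
  m
}

#' @rdname affect_io
#' @export
write_dsv <- function(dsv, path) {
  write.csv(data.frame(pair = names(dsv) %||% seq_along(dsv),
                       value = as.numeric(dsv)),
            path, row.names = FALSE)
}

#' @rdname affect_io
#' @export
read_dsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$value, df$pair)
}

#' @rdname affect_io
#' @export
write_sessions_jsonl <- function(sessions, path) {
  if (inherits(sessions, "session_log")) sessions <- list(sessions)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in sessions) {
    for (trial in s$trials) {
      rec <- list(participant_id = s$participant_id,
                  trial_index = trial$trial_index,
                  item_ids = trial$item_ids,
                  x = round(trial$coords[, 1L], 10),
                  y = round(trial$coords[, 2L], 10))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname affect_io
#' @param item_ids Optional canonical item ordering to impose on the
#'   sessions (defaults to first-appearance order within each session).
#' @export
read_sessions_jsonl <- function(path, item_ids = NULL) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  by_pid <- split(recs, vapply(recs, `[[`, character(1L), "participant_id"))
  sessions <- lapply(names(by_pid), function(pid) {
    trials <- lapply(by_pid[[pid]], function(r) {
      list(trial_index = r$trial_index,
           item_ids = as.character(r$item_ids),
           coords = cbind(r$x, r$y))
    })
    trials <- trials[order(vapply(trials, `[[`, numeric(1L), "trial_index"))]
    ids <- item_ids %||% unique(unlist(lapply(trials, `[[`, "item_ids")))
    structure(list(participant_id = pid, item_ids = ids,
                   trials = trials),
              class = "session_log")
  })
  # preserve first-appearance participant order
  first <- vapply(recs, `[[`, character(1L), "participant_id")
  sessions[match(unique(first), names(by_pid))]
}

#' Write a dendrogram as Newick text
#'
#' @param dendrogram An `hclust` object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}
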