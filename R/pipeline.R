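# End-to-end orchestration: simulate (or load) -> estimate DSMs ->
# cluster -> dispersion -> embedding labels -> trait regression, with
# every intermediate artifact written to disk and full seed control.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis.  In simulate mode
#' the synthetic-data generator produces stimuli, traits, planted
#' spaces and arrangement sessions; in load mode `stimuli_file`,
#' `traits_file` and either `sessions_file` or `dsm_files` must point
#' at existing artifacts.  Every stochastic stage derives its own seed
#' deterministically from the master seed, so re-running any stage
#' from saved intermediates reproduces the full-run output.
#'
#' @param simulate Logical: generate synthetic data (default) or load
#'   files.
#' @param n_participants Cohort size in simulate mode.
#' @param n_categories,per_category Stimulus-set shape.
#' @param trait_correlation 5x5 trait correlation matrix.
#' @param effects An [effect_spec()].
#' @param protocol An [arrangement_protocol()].
#' @param k_range Candidate cluster counts for the silhouette scan.
#' @param k_values Cluster counts to analyze (default `c(2, 4)`).
#' @param n_iter Monte Carlo iterations per null distribution.
#' @param null_method `"permute"` or `"parametric"`.
#' @param alpha Reporting threshold for empirical p-values.
#' @param embed_dims Dimensions for the classical MDS embedding.
#' @param seed Master seed.
#' @param stimuli_file,traits_file,sessions_file Input paths for load
#'   mode.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            n_participants = 30L,
                            n_categories = 9L, per_category = 6L,
                            trait_correlation = diag(5),
                            effects = effect_spec(),
                            protocol = arrangement_protocol(),
                            k_range = 2:10, k_values = c(2L, 4L),
                            n_iter = 1000L,
                            null_method = "permute",
                            alpha = 0.05,
                            embed_dims = 3L,
                            seed = 1L,
                            stimuli_file = NULL, traits_file = NULL,
                            sessions_file = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the arguments of [pipeline_config()]; the
#' `effects` and `protocol` blocks are nested maps passed to
#' [effect_spec()] and [arrangement_protocol()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects)) raw$effects <- do.call(effect_spec, raw$effects)
  if (!is.null(raw$protocol)) {
    raw$protocol <- do.call(arrangement_protocol, raw$protocol)
  }
  if (!is.null(raw$trait_correlation)) {
    raw$trait_correlation <- matrix(unlist(raw$trait_correlation), 5L, 5L)
  }
  do.call(pipeline_config, raw)
}

.stage <- function(manifest_path, completed, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    writeLines(completed, manifest_path)
    stop_invalid("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e))
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-load, per-participant inverse-MDS estimation,
#' DSV scaling, group-median clustering with silhouette validation,
#' classical-MDS dimension labeling, per-cluster dispersion, and
#' all-subsets trait regression with both Monte Carlo nulls.  Every
#' intermediate artifact is written into `out_dir` along with a
#' `MANIFEST` of completed stages and a `report.json` summary.  Output
#' is byte-identical across runs with the same config and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report (invisibly the same content as
#'   `report.json`), as a list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(out_dir, "MANIFEST")
  completed <- character(0)
  seed <- config$seed
  done <- function(name) {
    completed <<- c(completed, name)
    writeLines(completed, manifest)
  }

  ## Stage: inputs (simulate or load)
  spaces <- NULL
  if (isTRUE(config$simulate)) {
    stimuli <- .stage(manifest, completed, "stimuli", {
      make_stimulus_set(config$n_categories, config$per_category,
                        seed = derive_seed(seed, "stimuli"))
    })
    traits <- .stage(manifest, completed, "traits", {
      make_trait_table(config$n_participants, config$trait_correlation,
                       seed = derive_seed(seed, "traits"))
    })
    spaces <- .stage(manifest, completed, "planted_spaces", {
      make_planted_spaces(stimuli, traits, config$effects,
                          seed = derive_seed(seed, "planted_spaces"))
    })
    sessions <- .stage(manifest, completed, "sessions", {
      simulate_cohort_sessions(spaces, config$protocol,
                               seed = derive_seed(seed, "sessions"))
    })
    write_stimuli(stimuli, file.path(out_dir, "stimuli.csv"))
    write_traits(traits, file.path(out_dir, "traits.csv"))
    write_sessions_jsonl(sessions, file.path(out_dir, "sessions.jsonl"))
    for (sp in spaces) {
      write_dsm(sp$true_dsm,
                file.path(out_dir, sprintf("true_dsm_%s.csv",
                                           sp$participant_id)))
    }
  } else {
    stimuli <- .stage(manifest, completed, "stimuli", {
      if (is.null(config$stimuli_file) || !file.exists(config$stimuli_file)) {
        stop_invalid("stimuli_file missing or not found")
      }
      read_stimuli(config$stimuli_file)
    })
    traits <- .stage(manifest, completed, "traits", {
      if (is.null(config$traits_file) || !file.exists(config$traits_file)) {
        stop_invalid("traits_file missing or not found")
      }
      read_traits(config$traits_file)
    })
    sessions <- .stage(manifest, completed, "sessions", {
      if (is.null(config$sessions_file) || !file.exists(config$sessions_file)) {
        stop_invalid("sessions_file missing or not found")
      }
      read_sessions_jsonl(config$sessions_file,
                          item_ids = stimuli$item_id)
    })
  }
  done("inputs")

  ## Stage: inverse-MDS estimation and scaling
  scaled <- .stage(manifest, completed, "estimate_dsm", {
    t(vapply(sessions, function(s) {
      est <- estimate_dsm(s, n_items = nrow(stimuli))
      scale_dsv(dsm_to_dsv(est$dsm))
    }, numeric(choose(nrow(stimuli), 2L))))
  })
  rownames(scaled) <- vapply(sessions, `[[`, character(1L),
                             "participant_id")
  write.csv(data.frame(participant_id = rownames(scaled),
                       scaled, check.names = FALSE),
            file.path(out_dir, "scaled_dsvs.csv"), row.names = FALSE)
  done("estimate_dsm")

  ## Stage: group space, clustering, silhouette validation
  cluster_out <- .stage(manifest, completed, "cluster", {
    space <- group_median(scaled)
    profile <- scan_k(space, config$k_range)
    solutions <- lapply(config$k_values, function(k) {
      cluster_solution(space, k)
    })
    names(solutions) <- sprintf("k%d", config$k_values)
    list(space = space, profile = profile, solutions = solutions)
  })
  write.csv(data.frame(k = cluster_out$profile$k,
                       mean_silhouette = cluster_out$profile$silhouette),
            file.path(out_dir, "silhouette_profile.csv"),
            row.names = FALSE)
  assign_df <- data.frame(item_id = stimuli$item_id)
  for (nm in names(cluster_out$solutions)) {
    assign_df[[paste0("cluster_", nm)]] <-
      unname(cluster_out$solutions[[nm]]$assignment)
  }
  write.csv(assign_df, file.path(out_dir, "assignments.csv"),
            row.names = FALSE)
  write_dendrogram_newick(cluster_out$profile$dendrogram,
                          file.path(out_dir, "dendrogram.nwk"))
  done("cluster")

  ## Stage: embedding and dimension labels
  embed_out <- .stage(manifest, completed, "embed", {
    emb <- classical_mds(cluster_out$space, d = config$embed_dims)
    label_dimensions(emb, stimuli)
  })
  write.csv(data.frame(item_id = stimuli$item_id,
                       embed_out$embedding$coords, check.names = FALSE),
            file.path(out_dir, "embedding.csv"), row.names = FALSE)
  write.csv(embed_out$report,
            file.path(out_dir, "dimension_report.csv"),
            row.names = FALSE)
  done("embed")

  ## Stage: dispersion tables and trait regression
  regress_out <- .stage(manifest, completed, "regress", {
    out <- list()
    for (nm in names(cluster_out$solutions)) {
      sol <- cluster_out$solutions[[nm]]
      disp <- dispersion_table(scaled, sol,
                               participant_ids = rownames(scaled))
      write.csv(disp,
                file.path(out_dir, sprintf("dispersion_%s.csv", nm)),
                row.names = FALSE)
      cols <- setdiff(names(disp), "participant_id")
      ok <- match(disp$participant_id, traits$participant_id)
      if (anyNA(ok)) stop_invalid("traits missing for some participants")
      tr <- traits[ok, , drop = FALSE]
      for (col in cols) {
        label <- sprintf("%s_%s", nm, sub("^cluster_", "", col))
        rep_seed <- derive_seed(seed, paste0("regress_", label))
        out[[label]] <- trait_model_selection(
          disp[[col]], tr, cluster_label = label,
          n_iter = config$n_iter, seed = rep_seed,
          method = config$null_method)
      }
    }
    out
  })
  for (label in names(regress_out)) {
    rep <- regress_out[[label]]
    jsonlite::write_json(
      selection_report_json(rep),
      file.path(out_dir, sprintf("selection_%s.json", label)),
      auto_unbox = TRUE, digits = NA)
  }
  results <- do.call(rbind, lapply(names(regress_out), function(label) {
    rep <- regress_out[[label]]
    data.frame(cluster = label,
               optimal_subset = paste(rep$optimal$subset, collapse = "+"),
               bic = rep$optimal$bic,
               p_fwer_all = rep$p_fwer_all,
               p_same = rep$p_same,
               significant = rep$p_same < config$alpha)
  }))
  write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
  done("regress")

  ## Report
  report <- list(
    config = list(simulate = config$simulate,
                  n_participants = length(sessions),
                  n_items = nrow(stimuli),
                  k_range = config$k_range,
                  k_values = config$k_values,
                  n_iter = config$n_iter,
                  null_method = config$null_method,
                  seed = seed),
    silhouette = list(k = cluster_out$profile$k,
                      mean_silhouette = cluster_out$profile$silhouette,
                      selected_k = cluster_out$profile$selected_k),
    dimensions = embed_out$report,
    selections = lapply(regress_out, selection_report_json)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  done("report")
  invisible(report)
}

# Serializable view of a selection report (drops the 31 full fit
# objects down to their essentials).
selection_report_json <- function(rep) {
  list(
    cluster = rep$cluster_label,
    n = rep$optimal$n,
    optimal = list(
      subset = rep$optimal$subset,
      intercept = rep$optimal$intercept,
      betas = as.list(rep$optimal$betas),
      std_errors = as.list(rep$optimal$std_errors),
      t_stats = as.list(rep$optimal$t_stats),
      p_values = as.list(rep$optimal$p_values),
      rss = rep$optimal$rss,
      bic = rep$optimal$bic),
    all_models = lapply(rep$fits, function(f) {
      list(subset = f$subset, bic = f$bic)
    }),
    null_min_bic = list(mean = mean(rep$null_min_bic),
                        q05 = unname(quantile(rep$null_min_bic, 0.05)),
                        n = length(rep$null_min_bic)),
    null_same_model = list(mean = mean(rep$null_same_model_bic),
                           q05 = unname(quantile(rep$null_same_model_bic, 0.05)),
                           n = length(rep$null_same_model_bic)),
    p_fwer_all = rep$p_fwer_all,
    p_same = rep$p_same,
    n_iter = rep$n_iter,
    method = rep$method,
    seed = rep$seed)
}
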