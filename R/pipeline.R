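#' Configure an end-to-end trait-network pipeline run
#'
#' Exactly one input source must be given: either paths to a trait matrix
#' and environmental table on disk, or a [synthetic_config()] to generate
#' them.
#'
#' @param trait_path,env_path CSV/TSV inputs (rows = individuals / one row
#'   per water body).
#' @param group_column Group column name in the trait file (default
#'   `"group"`).
#' @param synthetic A [synthetic_config()] used instead of file inputs.
#' @param alpha Edge significance level (default 0.05).
#' @param community_method Community detection method (default `"greedy"`).
#' @param p_remove Backward-elimination threshold (default 0.10).
#' @param output_dir Directory for all outputs.
#' @param seed Seed for any stochastic step (default 1).
#' @param cv_ranking_mode `"mean_of_groups"` or `"pooled"`.
#' @param verbose Log progress to stderr (default `TRUE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trait_path = NULL, env_path = NULL,
                            group_column = "group", synthetic = NULL,
                            alpha = 0.05, community_method = "greedy",
                            p_remove = 0.10, output_dir = "traitnet-out",
                            seed = 1L,
                            cv_ranking_mode = "mean_of_groups",
                            verbose = TRUE) {
  have_files <- !is.null(trait_path)
  if (have_files == !is.null(synthetic)) {
    rlang::abort("give exactly one of `trait_path` or `synthetic`",
                 class = "traitnet_config_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be in (0, 1)", class = "traitnet_config_error")
  }
  structure(list(trait_path = trait_path, env_path = env_path,
                 group_column = group_column, synthetic = synthetic,
                 alpha = alpha, community_method = community_method,
                 p_remove = p_remove, output_dir = output_dir,
                 seed = as.integer(seed),
                 cv_ranking_mode = cv_ranking_mode, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `synthetic:` block mirrors [synthetic_config()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(spec$synthetic)) {
    spec$synthetic <- do.call(synthetic_config, spec$synthetic)
  }
  do.call(pipeline_config, spec)
}

tn_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message("[traitnet] ", ...)
}

#' Run the full trait-network pipeline
#'
#' Stages, in order: load or generate the trait matrix and environmental
#' table; per-trait/per-group CV tables and rankings; one
#' significance-thresholded network per water body (edge list, adjacency
#' and GraphML on disk); node metrics, hub/mediator lists and global
#' topology metrics; regressions of node metrics on trait CV and topology
#' on group mean CV; Pearson screening of environmental variables followed
#' by backward multiple regression for each topology metric with at least
#' one significant driver.  A JSON manifest recording the config, package
#' version, seed and md5 checksum of every output is written last.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out, name)
    readr::write_csv(df, p)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    tn_log(config, "generating synthetic dataset (seed ",
           config$synthetic$seed, ")")
    ds <- generate(config$synthetic)
    traits <- ds$traits; env <- ds$env; group_col <- "group"
    write_synthetic(ds, file.path(out, "inputs"))
    paths <- c(paths, file.path(out, "inputs",
                                c("traits.csv", "env.csv", "truth.json")))
  } else {
    tn_log(config, "reading ", config$trait_path)
    group_col <- config$group_column
    traits <- read_trait_matrix(config$trait_path, group_col)
    env <- NULL
    if (!is.null(config$env_path)) {
      env <- readr::read_csv(config$env_path, show_col_types = FALSE)
      if (!"group" %in% names(env)) names(env)[1] <- "group"
      env$group <- as.character(env$group)
      unknown <- setdiff(unique(traits[[group_col]]), env$group)
      if (length(unknown)) {
        rlang::abort(paste0("groups in trait matrix missing from env table: ",
                            paste(unknown, collapse = ", ")),
                     class = "traitnet_join_error")
      }
    }
  }

  # --- trait variability ----------------------------------------------
  tn_log(config, "computing CV tables")
  cvt <- cv_table(traits, group_col)
  emit(cvt, "cv_table.csv")
  emit(cv_group_means(cvt), "cv_group_means.csv")
  emit(cv_trait_ranking(cvt, mode = config$cv_ranking_mode,
                        data = traits, group = group_col),
       "cv_trait_ranking.csv")

  # --- networks -------------------------------------------------------
  tn_log(config, "building networks at alpha = ", config$alpha)
  nets <- networks_by_group(traits, group_col, alpha = config$alpha)
  for (g in names(nets)) {
    safe <- gsub("[^A-Za-z0-9_-]", "_", g)
    paths <- c(paths,
               write_edge_list(nets[[g]],
                               file.path(out, paste0("edges_", safe, ".csv"))),
               write_adjacency(nets[[g]],
                               file.path(out, paste0("adjacency_", safe, ".csv"))))
    if (requireNamespace("igraph", quietly = TRUE)) {
      paths <- c(paths,
                 write_graphml(nets[[g]],
                               file.path(out, paste0("network_", safe,
                                                     ".graphml"))))
    }
  }

  # --- metrics --------------------------------------------------------
  tn_log(config, "computing node and topology metrics")
  nm <- node_metrics_by_group(nets, method = config$community_method,
                              seed = config$seed)
  topo <- topology_by_group(nets, method = config$community_method,
                            seed = config$seed)
  emit(nm, "node_metrics.csv")
  emit(topo, "topology_metrics.csv")
  hubs <- dplyr::bind_rows(purrr::imap(nets, function(net, g) {
    h <- identify_hubs(node_metrics(net))
    h$group <- g
    h
  }))
  emit(hubs, "hub_traits.csv")

  # --- trait variability vs network metrics ---------------------------
  reg_cv_node <- cv_vs_node_metrics(cvt, nm)
  reg_cv_topo <- cv_vs_topology(cvt, topo)
  emit(reg_cv_node, "cv_vs_node_metrics.csv")
  emit(reg_cv_topo, "cv_vs_topology.csv")

  # --- environmental drivers ------------------------------------------
  screening <- NULL; regressions <- NULL
  if (!is.null(env)) {
    tn_log(config, "screening environmental drivers")
    screening <- screen_environment(topo, env, alpha = config$alpha)
    emit(screening, "env_screening.csv")
    joined <- dplyr::inner_join(topo, env, by = "group")
    fits <- list()
    eqs <- character(0)
    for (metric in unique(screening$metric)) {
      sel <- screening$variable[screening$metric == metric &
                                  screening$selected]
      if (length(sel) == 0L) next
      fit <- tryCatch(
        backward_regression(joined, metric, sel,
                            p_remove = config$p_remove),
        traitnet_insufficient_data = function(e) NULL)
      if (is.null(fit)) next
      fits[[metric]] <- fit
      eqs <- c(eqs, equation_text(fit))
    }
    if (length(fits)) {
      reg_tbl <- dplyr::bind_rows(purrr::imap(fits, function(f, metric) {
        g <- glance(f)
        g$eliminated <- paste(f$eliminated$predictor, collapse = ";")
        g
      }))
      emit(reg_tbl, "env_regressions.csv")
      p <- file.path(out, "env_regressions.txt")
      writeLines(eqs, p)
      paths <- c(paths, p)
      regressions <- reg_tbl
    }
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "traitnet",
    version = as.character(utils::packageVersion("traitnet")),
    seed = config$seed,
    alpha = config$alpha,
    community_method = config$community_method,
    p_remove = config$p_remove,
    n_groups = length(nets),
    n_traits = length(nets[[1]]$trait_names),
    n_topology_rows = nrow(topo),
    outputs = lapply(stats::setNames(paths, basename(paths)), function(p) {
      unname(tools::md5sum(p))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tn_log(config, "done: ", length(paths), " outputs in ", out)
  invisible(manifest)
}
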