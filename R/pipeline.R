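# End-to-end orchestration: synthetic (or file-based) features -> SOM ->
# neuron clusters -> traces -> pathway clusters -> transition graph ->
# property map -> work profiles, with plain-text artifacts and a
# machine-readable summary.

#' Default pipeline configuration
#'
#' Every method parameter is a named key defaulting to the analysis'
#' reference values: 1.0 nm contact cutoff, 8 x 8 non-periodic hexagonal
#' map, complete-linkage neuron clustering with silhouette-based selection,
#' average-linkage pathway clustering cut at 2 pathways.
#'
#' @param out_dir output directory for artifacts.
#' @param seed mandatory master seed (stochastic stages refuse to run
#'   without one).
#' @return a named list; pass to [run_pipeline()] after optionally
#'   overriding entries.
#' @export
default_config <- function(out_dir, seed) {
  list(out_dir = out_dir, seed = seed,
       simulate = TRUE,              # use the synthetic generator
       native_pdb = NULL, model = 1L, trajectories = NULL, stride = 1L,
       cutoff = 1.0,
       rows = 8L, cols = 8L, epochs = 100L,
       neuron_clusters = "auto", pathway_clusters = 2L,
       n_per_pathway = c(pathway1 = 12L, pathway2 = 38L),
       toy = list())
}

#' Run the full pathway-SOM workflow
#'
#' Executes features -> train -> cluster-neurons -> trace -> cluster-paths
#' -> graph -> map-force -> work on either synthetic data
#' (`config$simulate = TRUE`) or user trajectories, writing plain-text
#' artifacts into `config$out_dir` and returning (and writing) a summary.
#' Stages whose artifact files already exist are reloaded, so deleting a
#' downstream artifact and re-running regenerates only the downstream
#' stages.
#'
#' @param config a configuration list, see [default_config()].
#' @return invisibly, a list with the fitted objects and the `summary`
#'   (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(default_config(
    out_dir = config$out_dir %||% stop("config$out_dir is required"),
    seed = config$seed %||% stop("config$seed is required (stochastic stages)")),
    config)
  if (!is.numeric(cfg$seed)) stop("config$seed must be numeric")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- features -------------------------------------------------------
  dataset <- NULL
  if (isTRUE(cfg$simulate)) {
    dataset <- stage("simulate", {
      spec <- do.call(toy_unfolding_spec, cfg$toy)
      generate_dataset(spec, n_per_pathway = cfg$n_per_pathway,
                       seed = cfg$seed)
    })
    feats <- lapply(dataset$replicas, `[[`, "features")
    scalars <- lapply(dataset$replicas, function(r)
      data.frame(force = r$force, extension = r$extension))
    pairs <- dataset$pairs
  } else {
    fstage <- stage("features", {
      native <- load_structure(cfg$native_pdb, model = cfg$model)
      p <- select_native_pairs(native, cutoff = cfg$cutoff)
      list(pairs = p,
           feats = lapply(cfg$trajectories, extract_features, pairs = p,
                          stride = cfg$stride))
    })
    pairs <- fstage$pairs
    feats <- fstage$feats
    scalars <- vector("list", length(feats))
  }
  pairs_file <- file.path(cfg$out_dir, "native_pairs.csv")
  write.csv(as.data.frame(pairs), pairs_file, row.names = FALSE)

  # --- train ----------------------------------------------------------
  som_prefix <- file.path(cfg$out_dir, "som")
  model <- stage("train", {
    if (file.exists(paste0(som_prefix, ".json"))) read_som(som_prefix)
    else {
      m <- path_som(do.call(rbind, lapply(feats, unclass)),
                    rows = cfg$rows, cols = cfg$cols, epochs = cfg$epochs,
                    seed = cfg$seed)
      write_som(m, som_prefix)
      m
    }
  })

  # --- neuron clusters ------------------------------------------------
  nc <- stage("cluster-neurons", cluster_neurons(model, n = cfg$neuron_clusters))
  write.csv(data.frame(neuron = seq_along(nc$labels), cluster = nc$labels,
                       silhouette = nc$silhouette),
            file.path(cfg$out_dir, "neuron_clusters.csv"), row.names = FALSE)

  # --- traces ---------------------------------------------------------
  traces <- stage("trace", lapply(seq_along(feats), function(i)
    trace_path(model, feats[[i]], scalars = scalars[[i]],
               replica = paste0("replica_", i))))
  trace_dir <- file.path(cfg$out_dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    df <- data.frame(frame = seq_along(tr$bmu), bmu = tr$bmu, dist = tr$dist)
    if (!is.null(tr$scalars)) df <- cbind(df, tr$scalars)
    write.csv(df, file.path(trace_dir, sprintf("trace_%03d.csv", i)),
              row.names = FALSE)
  }

  # --- pathway clusters ----------------------------------------------
  pc <- stage("cluster-paths",
              cluster_paths(traces, model, n = cfg$pathway_clusters))
  lab_df <- data.frame(replica = pc$replicas, pathway = pc$labels)
  if (!is.null(dataset)) lab_df$true_label <- dataset$labels
  write.csv(lab_df, file.path(cfg$out_dir, "pathway_labels.csv"),
            row.names = FALSE)

  # --- transition graph ----------------------------------------------
  tg <- stage("graph", transition_matrix(traces, nrow(model$codebook)))
  write.csv(tg$counts, file.path(cfg$out_dir, "transition_counts.csv"),
            row.names = FALSE)
  write.csv(tg$prob, file.path(cfg$out_dir, "transition_probs.csv"),
            row.names = FALSE)
  g <- build_graph(tg)
  el <- igraph::as_edgelist(g)
  write.csv(data.frame(from = el[, 1], to = el[, 2],
                       weight = igraph::E(g)$weight,
                       prob = igraph::E(g)$prob),
            file.path(cfg$out_dir, "graph_edges.csv"), row.names = FALSE)

  # --- property map and work -----------------------------------------
  fmap <- NULL; work <- NULL
  if (any(vapply(scalars, function(s)
    !is.null(s) && "force" %in% names(s), logical(1)))) {
    fmap <- stage("map-force",
                  map_property(traces, nrow(model$codebook), "force"))
    write.csv(as.data.frame(fmap), file.path(cfg$out_dir, "force_map.csv"),
              row.names = FALSE)
    work <- stage("work", lapply(seq_along(traces), function(i) {
      s <- scalars[[i]]
      if (is.null(s) || !all(c("force", "extension") %in% names(s)))
        return(NULL)
      work_profile(s$force, s$extension)
    }))
    total_work <- vapply(work, function(w)
      if (is.null(w)) NA_real_ else w$work[nrow(w)], numeric(1))
    write.csv(data.frame(replica = seq_along(total_work),
                         total_work = total_work),
              file.path(cfg$out_dir, "total_work.csv"), row.names = FALSE)
  }

  summary <- list(
    n_pairs = nrow(pairs),
    n_replicas = length(traces),
    n_frames_total = model$n_frames,
    quantization_error = model$qe,
    neuron_clusters = nc$n,
    avg_silhouette = nc$avg_silhouette,
    pathway_counts = as.list(table(pc$labels)),
    pathway_labels = pc$labels,
    isolated_neurons = length(tg$isolated),
    seed = cfg$seed,
    config_hash = config_hash(cfg))
  if (!is.null(dataset)) summary$true_labels <- dataset$labels
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = model, traces = traces, neuron_clusters = nc,
                 pathway_clusters = pc, transition = tg, graph = g,
                 force_map = fmap, work = work, dataset = dataset,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(cfg) {
  # order-independent fingerprint of the configuration (paths excluded),
  # without digest deps
  cfg <- cfg[setdiff(names(cfg), c("out_dir", "native_pdb", "trajectories"))]
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)))
}
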