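# Pathway tracing on the map, the codebook-space path distance, pathway
# clustering and retracing of held-out trajectories.

#' Trace a replica's route on the map
#'
#' Assigns every frame of a feature matrix to its best matching unit, in
#' frame order, giving the replica's pathway across the map.
#'
#' @param model a `"path_som"`.
#' @param x frames x features matrix for one replica.
#' @param scalars optional data frame of per-frame scalars (e.g. `force` in
#'   kJ mol^-1 nm^-1, `extension` in nm, `time_ps`), length-matched to the
#'   frames.
#' @param replica optional replica identifier.
#' @return an object of class `"path_trace"`: list with `bmu` (neuron id per
#'   frame), `dist` (frame-to-BMU distance), `scalars`, `replica`.
#' @export
trace_path <- function(model, x, scalars = NULL, replica = NULL) {
  p <- predict(model, x)
  if (length(p$bmu) < 2L)
    warning("trace has fewer than 2 frames")
  if (!is.null(scalars)) {
    scalars <- as.data.frame(scalars)
    if (nrow(scalars) != length(p$bmu))
      stop("scalars (", nrow(scalars), " rows) do not match frames (",
           length(p$bmu), ")")
  }
  structure(list(bmu = p$bmu, dist = p$dist, scalars = scalars,
                 replica = replica), class = "path_trace")
}

#' @export
print.path_trace <- function(x, ...) {
  cat("Pathway trace", if (!is.null(x$replica)) paste0("(", x$replica, ")"),
      ":", length(x$bmu), "frames,", length(unique(x$bmu)),
      "distinct neurons\n")
  cat("  route head:", paste(utils::head(x$bmu, 10), collapse = " > "),
      if (length(x$bmu) > 10) "...", "\n")
  invisible(x)
}

#' Codebook-space distance between two neurons
#'
#' Mean square deviation of the two codebook vectors (squared feature units;
#' deliberately not square-rooted).
#'
#' @param model a `"path_som"`.
#' @param a,b neuron ids.
#' @return `mean((w_a - w_b)^2)`.
#' @export
bmu_pair_distance <- function(model, a, b) {
  m <- nrow(model$codebook)
  if (any(c(a, b) < 1L) || any(c(a, b) > m))
    stop("neuron id out of range 1 .. ", m)
  mean((model$codebook[a, ] - model$codebook[b, ])^2)
}

codebook_msd_matrix <- function(model) {
  W <- model$codebook
  # squared Euclidean distances / P
  g <- rowSums(W^2)
  d2 <- outer(g, g, "+") - 2 * tcrossprod(W)
  d2[d2 < 0] <- 0
  d2 / ncol(W)
}

#' Distance between two pathway traces
#'
#' The mean, over frames, of the codebook-space BMU distance between the two
#' replicas at each frame: `(1/n) sum_i d(A_i, B_i)` with
#' `d = bmu_pair_distance`. Traces must have equal frame counts unless
#' `resample = TRUE`, in which case the shorter trace is resampled to the
#' longer one's frame times by nearest-time (or nearest relative index when
#' no times are present).
#'
#' @param A,B `"path_trace"` objects.
#' @param model the `"path_som"` both traces live on.
#' @param resample allow unequal lengths via nearest-time resampling
#'   (default `FALSE`: unequal lengths are an error).
#' @return non-negative scalar; 0 when the BMU sequences are identical.
#' @export
path_distance <- function(A, B, model, resample = FALSE) {
  a <- A$bmu; b <- B$bmu
  if (length(a) != length(b)) {
    if (!resample)
      stop("traces differ in length (", length(a), " vs ", length(b),
           "); set resample = TRUE to resample the shorter one")
    if (length(a) < length(b)) a <- resample_bmu(A, B) else b <- resample_bmu(B, A)
  }
  D <- codebook_msd_matrix(model)
  mean(D[cbind(a, b)])
}

resample_bmu <- function(short, long) {
  ts <- trace_times(short); tl <- trace_times(long)
  idx <- vapply(tl, function(t) which.min(abs(ts - t)), integer(1))
  short$bmu[idx]
}

trace_times <- function(tr) {
  s <- tr$scalars
  if (!is.null(s) && "time_ps" %in% names(s)) return(s$time_ps)
  seq(0, 1, length.out = length(tr$bmu))
}

#' Cluster pathway traces
#'
#' Average-linkage agglomerative clustering of replicas on the pairwise
#' [path_distance()] matrix, cut at `n` pathways. The full dendrogram is
#' retained for inspection; minor branches are left to the user to merge.
#'
#' @param traces list of `"path_trace"` objects (>= 2), same length each.
#' @param model the shared `"path_som"`.
#' @param n number of pathway clusters to cut (default 2).
#' @param resample passed to [path_distance()].
#' @return an object of class `"pathway_clustering"`: list with `labels`,
#'   `n`, `hclust`, and the pairwise `dist` matrix.
#' @export
cluster_paths <- function(traces, model, n = 2L, resample = FALSE) {
  k <- length(traces)
  if (k < 2L) stop("need at least 2 traces")
  D <- codebook_msd_matrix(model)
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    a <- traces[[i]]$bmu; b <- traces[[j]]$bmu
    if (length(a) != length(b)) {
      M[i, j] <- M[j, i] <- path_distance(traces[[i]], traces[[j]], model,
                                          resample = resample)
    } else {
      M[i, j] <- M[j, i] <- mean(D[cbind(a, b)])
    }
  }
  ids <- vapply(seq_len(k), function(i) {
    r <- traces[[i]]$replica
    if (is.null(r)) paste0("replica_", i) else as.character(r)
  }, character(1))
  dimnames(M) <- list(ids, ids)
  hc <- hclust(stats::as.dist(M), method = "average")
  labels <- cutree(hc, k = n)
  structure(list(labels = unname(labels), n = as.integer(n), hclust = hc,
                 dist = M, replicas = ids),
            class = "pathway_clustering")
}

#' @export
print.pathway_clustering <- function(x, ...) {
  cat("Pathway clustering:", length(x$labels), "replicas cut into", x$n,
      "pathways (average linkage)\n")
  print(table(pathway = x$labels))
  invisible(x)
}

#' Export a pathway dendrogram in Newick format
#'
#' @param pc a `"pathway_clustering"`.
#' @param file output file path.
#' @return `file`, invisibly. Requires the ape package.
#' @export
write_dendrogram_newick <- function(pc, file) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(pc$hclust), file = file)
  invisible(file)
}

#' Retrace held-out frames on a trained map
#'
#' Assigns each frame of a new (e.g. lower pulling speed) trajectory to its
#' closest neuron, exactly as in training, and compares the frame-to-neuron
#' distance distribution with the training set's: comparable distributions
#' indicate the new frames are well represented by the map even though they
#' were not used to train it.
#'
#' @param model a `"path_som"` (carries its training distances).
#' @param x frames x features matrix in the training feature space.
#' @param scalars,replica passed to [trace_path()].
#' @return list with `trace` (a `"path_trace"`), `dist` (per-frame distances)
#'   and `comparison` (medians of both distributions and a two-sample
#'   Kolmogorov-Smirnov statistic).
#' @export
retrace <- function(model, x, scalars = NULL, replica = NULL) {
  tr <- trace_path(model, x, scalars = scalars, replica = replica)
  train_d <- model$training$dist
  ks <- suppressWarnings(stats::ks.test(tr$dist, train_d))
  list(trace = tr, dist = tr$dist,
       comparison = list(median_new = median(tr$dist),
                         median_training = median(train_d),
                         ks_statistic = unname(ks$statistic),
                         ks_p = ks$p.value))
}

#' Ordered sequence of visited clusters along a trace
#'
#' Collapses a BMU sequence to the run-length-encoded order of neuron
#' clusters it passes through; used to compare pathways recorded at
#' different pulling speeds (different frame counts) on the same map.
#'
#' @param trace a `"path_trace"`.
#' @param clustering a `"neuron_clustering"` for the same map.
#' @return integer vector of cluster labels, consecutive duplicates removed.
#' @export
cluster_visit_order <- function(trace, clustering) {
  cl <- clustering$labels[trace$bmu]
  cl[c(TRUE, diff(cl) != 0)]
}
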