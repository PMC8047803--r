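# Neuron transition matrix, -log probability graph, shortest paths,
# per-neuron property maps, and pulling work profiles.

#' Neuron-to-neuron transition matrix from pathway traces
#'
#' Counts transitions between consecutive frames pooled across all traces
#' (self-transitions included by default, since consecutive frames usually
#' stay on the same neuron) and row-normalizes the counts into an empirical
#' row-stochastic matrix. Neurons with no outgoing transitions keep a zero
#' row and are flagged isolated.
#'
#' @param traces list of `"path_trace"` objects (or a single trace).
#' @param n_neurons total number of neurons on the map.
#' @param include_self count self-transitions (default `TRUE`); when
#'   `FALSE`, frame pairs staying on one neuron are dropped before counting.
#' @return an object of class `"transition_graph"`: list with `counts`
#'   (n x n), `prob` (row-stochastic), `n_neurons`, `isolated` (ids with a
#'   zero row), `include_self` and `log_base` (`"natural"`).
#' @export
transition_matrix <- function(traces, n_neurons, include_self = TRUE) {
  if (inherits(traces, "path_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("no traces supplied")
  n_neurons <- as.integer(n_neurons)
  counts <- matrix(0, n_neurons, n_neurons)
  for (tr in traces) {
    b <- tr$bmu
    if (any(b < 1L | b > n_neurons))
      stop("trace contains neuron ids outside 1 .. ", n_neurons)
    if (length(b) < 2L) next
    from <- b[-length(b)]
    to <- b[-1]
    if (!include_self) {
      keep <- from != to
      from <- from[keep]; to <- to[keep]
    }
    for (t in seq_along(from))
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
  }
  rs <- rowSums(counts)
  prob <- counts
  nz <- rs > 0
  prob[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  structure(list(counts = counts, prob = prob, n_neurons = n_neurons,
                 isolated = which(!nz), include_self = include_self,
                 log_base = "natural"),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("Transition graph:", x$n_neurons, "neurons,", sum(x$counts),
      "counted transitions,", sum(x$counts > 0), "edges\n")
  if (length(x$isolated))
    cat("  isolated neurons (no outgoing transitions):",
        paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}

#' Build the -log-probability digraph
#'
#' Directed edge a -> b with weight `-log(p(a -> b))` for every transition
#' with positive count; self-loops are retained (their weight is
#' non-negative, so they never shorten a path).
#'
#' @param tg a `"transition_graph"`.
#' @return an igraph directed graph with edge attributes `weight`
#'   (`-log p`) and `prob`.
#' @export
build_graph <- function(tg) {
  stopifnot(inherits(tg, "transition_graph"))
  idx <- which(tg$counts > 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = tg$n_neurons, directed = TRUE)
  if (nrow(idx)) {
    p <- tg$prob[idx]
    g <- igraph::add_edges(g, as.vector(t(idx)))
    igraph::E(g)$weight <- -log(p)
    igraph::E(g)$prob <- p
  }
  g
}

#' Shortest-path distance between two neurons on the transition graph
#'
#' Minimal total `-log p` path from `a` to `b`; the returned distance equals
#' both the sum of edge weights and `-log` of the product of the transition
#' probabilities along the path (the two computations are checked against
#' each other). Unreachable targets give an infinite distance and an empty
#' path.
#'
#' @param graph an igraph graph from [build_graph()], or a
#'   `"transition_graph"` (converted on the fly).
#' @param a,b neuron ids.
#' @return list with `path` (neuron id sequence; `integer(0)` when `a == b`
#'   or unreachable), `distance`, and `prob` (the probability product,
#'   0 when unreachable, 1 when `a == b`).
#' @export
shortest_path_distance <- function(graph, a, b) {
  if (inherits(graph, "transition_graph")) graph <- build_graph(graph)
  n <- igraph::vcount(graph)
  if (any(c(a, b) < 1L) || any(c(a, b) > n))
    stop("unknown node: ids must be in 1 .. ", n)
  if (a == b)
    return(list(path = integer(0), distance = 0, prob = 1))
  sp <- suppressWarnings(
    igraph::shortest_paths(graph, from = a, to = b, mode = "out",
                           weights = igraph::E(graph)$weight,
                           output = "both"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) == 0L)
    return(list(path = integer(0), distance = Inf, prob = 0))
  w <- igraph::E(graph)$weight[as.integer(sp$epath[[1]])]
  p <- igraph::E(graph)$prob[as.integer(sp$epath[[1]])]
  d_sum <- sum(w)
  d_log <- -log(prod(p))
  if (is.finite(d_sum) && abs(d_sum - d_log) > 1e-9 * max(1, abs(d_sum)))
    warning("edge-weight sum and -log probability product disagree: ",
            d_sum, " vs ", d_log)
  list(path = vp, distance = d_sum, prob = prod(p))
}

#' Map a per-frame scalar onto the neurons
#'
#' Pools all frames carrying the named scalar across traces and computes the
#' per-neuron mean (and SD, count), e.g. the average pulling force per
#' neuron. Neurons visited by no frame are reported with `n = 0` and `NA`
#' mean -- missing, not zero.
#'
#' @param traces list of `"path_trace"` objects whose `scalars` contain the
#'   named column.
#' @param n_neurons total number of neurons.
#' @param property scalar column name (default `"force"`).
#' @return a `"property_map"`: data frame with columns `neuron`, `n`,
#'   `mean`, `sd`.
#' @export
map_property <- function(traces, n_neurons, property = "force") {
  if (inherits(traces, "path_trace")) traces <- list(traces)
  vals <- list(); neuron <- list()
  for (tr in traces) {
    s <- tr$scalars
    if (is.null(s) || !(property %in% names(s))) next
    vals[[length(vals) + 1L]] <- s[[property]]
    neuron[[length(neuron) + 1L]] <- tr$bmu
  }
  if (length(vals) == 0L)
    stop("scalar '", property, "' absent from every trace")
  v <- unlist(vals); b <- unlist(neuron)
  out <- data.frame(neuron = seq_len(n_neurons),
                    n = tabulate(b, nbins = n_neurons),
                    mean = NA_real_, sd = NA_real_)
  agg_mean <- tapply(v, factor(b, levels = seq_len(n_neurons)), mean)
  agg_sd <- tapply(v, factor(b, levels = seq_len(n_neurons)), sd)
  out$mean <- as.numeric(agg_mean)
  out$sd <- as.numeric(agg_sd)
  attr(out, "property") <- property
  class(out) <- c("property_map", "data.frame")
  out
}

#' Cumulative pulling work along the extension coordinate
#'
#' Trapezoidal integral of the pulling force over the end-to-end extension:
#' `W(x) = int F dx` from the first frame, e.g. over the 0-24 nm range both
#' pulling speeds sample.
#'
#' @param force per-frame force (kJ mol^-1 nm^-1).
#' @param extension per-frame extension (nm), non-decreasing up to `tol`.
#' @param tol tolerated backward jitter in the extension series (nm).
#' @return data frame with columns `extension` and `work` (kJ mol^-1);
#'   `work` is monotone non-decreasing whenever `force >= 0`.
#' @export
work_profile <- function(force, extension, tol = 1e-6) {
  if (length(force) != length(extension))
    stop("force and extension differ in length")
  if (any(diff(extension) < -tol))
    stop("extension series decreases by more than tol")
  w <- as.numeric(pracma::cumtrapz(extension, force))
  data.frame(extension = extension, work = w)
}
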