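# Hexagonal sheet SOM: training, BMU assignment, centrotypes, neuron QC,
# and neuron-level hierarchical clustering.

#' Hexagonal lattice positions for a sheet-shaped SOM
#'
#' Row-major neuron numbering (neuron 1 = top-left). Using 0-based row/column
#' indices r, c: x = c + 0.5 * (r %% 2), y = r * sqrt(3) / 2. Lattice
#' neighbors are neurons whose position distance is <= 1.01.
#'
#' @param rows,cols grid dimensions (each >= 2).
#' @return data frame with columns `id`, `row`, `col` (1-based) and `x`, `y`.
#' @export
som_grid <- function(rows, cols) {
  r <- rep(seq_len(rows) - 1L, each = cols)
  c <- rep(seq_len(cols) - 1L, times = rows)
  data.frame(id = seq_len(rows * cols), row = r + 1L, col = c + 1L,
             x = c + 0.5 * (r %% 2L), y = r * sqrt(3) / 2)
}

grid_dist2 <- function(grid) {
  dx <- outer(grid$x, grid$x, "-")
  dy <- outer(grid$y, grid$y, "-")
  dx * dx + dy * dy
}

#' Lattice adjacency of a SOM grid
#'
#' @param object a `"path_som"` model or a grid data frame from [som_grid()].
#' @return logical n_neurons x n_neurons matrix; `TRUE` for distinct neurons
#'   at lattice distance <= 1.01.
#' @export
som_neighbors <- function(object) {
  grid <- if (inherits(object, "path_som")) object$grid else object
  d2 <- grid_dist2(grid)
  adj <- d2 <= 1.01^2
  diag(adj) <- FALSE
  adj
}

#' Fit a self-organizing map to conformational features
#'
#' Trains a non-periodic, sheet-shaped hexagonal SOM on a frames x features
#' distance matrix by the classical online rule: each frame is assigned to
#' its best matching unit (BMU) and the BMU and its lattice neighbors are
#' pulled toward the frame, with both the learning rate and the Gaussian
#' neighborhood radius decaying linearly over the training. The codebook is
#' initialized uniformly at random within the per-feature data ranges and
#' frames are presented in a fresh random order each epoch; both draws come
#' from `seed`, so the fit is fully reproducible.
#'
#' @param x a `"feature_matrix"` or plain numeric matrix (frames x features).
#' @param rows,cols grid size (default 8 x 8).
#' @param epochs full passes over the data (default 100).
#' @param alpha learning rate, start and end of the linear decay
#'   (default `c(0.05, 0.01)`).
#' @param radius neighborhood radius (lattice units), start and end of the
#'   linear decay. Default: from 2/3 of the grid diagonal down to 1.
#' @param scale logical; standardize features before training (default
#'   `FALSE`: all features share nm units).
#' @param init `"range"` (default): codebook drawn uniformly within the
#'   per-feature data ranges; `"sample"`: codebook initialized from randomly
#'   sampled data frames (the kohonen-package convention, more robust on
#'   very small maps).
#' @param seed integer seed controlling codebook initialization and the
#'   per-epoch presentation order.
#' @return an object of class `"path_som"` with elements `codebook`
#'   (n_neurons x P, feature units), `grid`, `hyper` (all hyperparameters),
#'   `qe`/`qe_init` (mean frame-to-BMU distance after/before training),
#'   `training` (BMU id and distance per training frame), and `n_frames`.
#' @seealso [predict.path_som()], [cluster_neurons()], [trace_path()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 5), 20))
#' m <- path_som(x, rows = 2, cols = 2, epochs = 20, seed = 1)
#' m
#' @export
path_som <- function(x, rows = 8L, cols = 8L, epochs = 100L,
                     alpha = c(0.05, 0.01), radius = NULL, scale = FALSE,
                     init = c("range", "sample"), seed = 42L) {
  init <- match.arg(init)
  X <- unclass(x)
  attributes(X) <- list(dim = dim(X))
  if (nrow(X) < 1L) stop("empty feature matrix")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (rows < 2L || cols < 2L) stop("rows and cols must each be >= 2")
  m <- as.integer(rows) * as.integer(cols)
  if (nrow(X) < m)
    warning("fewer frames (", nrow(X), ") than neurons (", m, ")")
  ctr <- NULL; scl <- NULL
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  grid <- som_grid(rows, cols)
  gd2 <- grid_dist2(grid)
  if (is.null(radius))
    radius <- c(sqrt(max(gd2)) * 2 / 3, 1)
  set.seed(seed)
  if (init == "range") {
    rng <- apply(X, 2, range)
    W0 <- matrix(runif(m * ncol(X), rep(rng[1, ], each = m),
                       rep(rng[2, ], each = m)), nrow = m)
  } else {
    W0 <- X[sample.int(nrow(X), m, replace = nrow(X) < m), , drop = FALSE]
  }
  # one seeded presentation permutation per epoch
  order <- vapply(seq_len(epochs), function(e) sample.int(nrow(X)) - 1L,
                  integer(nrow(X)))
  qe_init <- mean(bmu_assign_cpp(W0, X)$dist)
  W <- som_train_cpp(X, W0, gd2, as.integer(epochs),
                     alpha[1], alpha[2], radius[1], radius[2], order)
  asg <- bmu_assign_cpp(W, X)
  structure(list(
    codebook = W, grid = grid,
    hyper = list(rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs), alpha = alpha, radius = radius,
                 scale = scale, init = init, seed = as.integer(seed)),
    center = ctr, scl = scl,
    qe = mean(asg$dist), qe_init = qe_init,
    training = list(bmu = asg$bmu, dist = asg$dist),
    n_frames = nrow(X)), class = "path_som")
}

som_prepare <- function(object, x) {
  X <- unclass(x)
  attributes(X) <- list(dim = dim(X))
  if (ncol(X) != ncol(object$codebook))
    stop("feature dimension ", ncol(X), " does not match model (",
         ncol(object$codebook), ")")
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2, object$center), 2, object$scl, "/")
  X
}

#' Assign frames to their best matching units
#'
#' @param object a `"path_som"` model.
#' @param newdata frames x features matrix (same feature space as training).
#' @param ... unused.
#' @return data frame with columns `bmu` (neuron id) and `dist` (Euclidean
#'   frame-to-codebook distance). Ties resolve to the lowest neuron id.
#' @export
predict.path_som <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  asg <- bmu_assign_cpp(object$codebook, som_prepare(object, newdata))
  data.frame(bmu = asg$bmu, dist = asg$dist)
}

#' Best matching unit of a single feature vector
#'
#' @param model a `"path_som"`.
#' @param x numeric feature vector.
#' @return list with `id` (neuron) and `dist` (Euclidean distance).
#' @export
assign_bmu <- function(model, x) {
  p <- predict(model, matrix(x, nrow = 1))
  list(id = p$bmu[1], dist = p$dist[1])
}

#' @export
print.path_som <- function(x, ...) {
  cat("Hexagonal SOM:", x$hyper$rows, "x", x$hyper$cols, "neurons,",
      ncol(x$codebook), "features\n")
  cat("  trained", x$hyper$epochs, "epochs on", x$n_frames,
      "frames (seed", paste0(x$hyper$seed, ")"), "\n")
  cat("  quantization error:", format(x$qe, digits = 4),
      "(initial", format(x$qe_init, digits = 4), ")\n")
  invisible(x)
}

#' @export
summary.path_som <- function(object, ...) {
  occ <- tabulate(object$training$bmu, nbins = nrow(object$codebook))
  cat("Hexagonal sheet SOM (non-periodic)\n")
  print(object)
  cat("  occupied neurons:", sum(occ > 0), "of", length(occ), "\n")
  cat("  frames per neuron: median", median(occ), ", max", max(occ), "\n")
  invisible(list(occupancy = occ, qe = object$qe))
}

#' @export
coef.path_som <- function(object, ...) object$codebook

#' Per-neuron centrotype frames
#'
#' For each neuron, the index of the assigned frame closest to the neuron's
#' codebook vector -- the frame used as the neuron's representative
#' conformation. Neurons with no assigned frame get `NA`.
#'
#' @param model a `"path_som"`.
#' @param x the feature matrix to scan (typically the training set).
#' @return data frame with columns `neuron`, `frame` (index into `x`, `NA`
#'   for empty neurons), `dist`, and `n_frames` assigned.
#' @export
centrotypes <- function(model, x) {
  X <- som_prepare(model, x)
  asg <- bmu_assign_cpp(model$codebook, X)
  m <- nrow(model$codebook)
  frame <- rep(NA_integer_, m)
  dst <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    members <- which(asg$bmu == j)
    if (length(members) == 0L) next
    frame[j] <- members[which.min(asg$dist[members])]
    dst[j] <- min(asg$dist[members])
  }
  data.frame(neuron = seq_len(m), frame = frame, dist = dst,
             n_frames = tabulate(asg$bmu, nbins = m))
}

#' Intra-neuron vs neighbor-neuron dRMSD distributions
#'
#' Quality check of the map's segregation: pairwise dRMSD between frames
#' assigned to the same neuron should be smaller than between frames assigned
#' to lattice-adjacent neurons. Pair sampling is capped per neuron (seeded)
#' to bound cost on large neurons.
#'
#' @param model a `"path_som"`.
#' @param x feature matrix the map was trained on.
#' @param max_pairs per neuron (and per neuron pair) sampling cap.
#' @param seed seed for the pair subsampling.
#' @return list with numeric vectors `intra` and `inter`, and a `summary`
#'   data frame of medians and counts.
#' @export
neuron_quality <- function(model, x, max_pairs = 200L, seed = 1L) {
  X <- som_prepare(model, x)
  asg <- bmu_assign_cpp(model$codebook, X)
  m <- nrow(model$codebook)
  members <- split(seq_len(nrow(X)), factor(asg$bmu, levels = seq_len(m)))
  adj <- som_neighbors(model)
  set.seed(seed)
  sample_pairs <- function(ii, jj) {
    # all cross pairs (ii x jj), subsampled to max_pairs
    np <- length(ii) * length(jj)
    if (np == 0L) return(NULL)
    take <- if (np > max_pairs) sample.int(np, max_pairs) else seq_len(np)
    a <- ii[((take - 1L) %% length(ii)) + 1L]
    b <- jj[((take - 1L) %/% length(ii)) + 1L]
    sqrt(rowMeans((X[a, , drop = FALSE] - X[b, , drop = FALSE])^2))
  }
  intra <- c()
  for (j in seq_len(m)) {
    ii <- members[[j]]
    if (length(ii) < 2L) next
    prs <- utils::combn(ii, 2L)
    np <- ncol(prs)
    take <- if (np > max_pairs) sample.int(np, max_pairs) else seq_len(np)
    a <- prs[1, take]; b <- prs[2, take]
    intra <- c(intra, sqrt(rowMeans((X[a, , drop = FALSE] -
                                     X[b, , drop = FALSE])^2)))
  }
  inter <- c()
  for (j in seq_len(m - 1L)) for (k in seq((j + 1L), m)) {
    if (!adj[j, k]) next
    inter <- c(inter, sample_pairs(members[[j]], members[[k]]))
  }
  list(intra = intra, inter = inter,
       summary = data.frame(
         set = c("intra", "inter"),
         n = c(length(intra), length(inter)),
         median = c(median(intra), median(inter))))
}

#' Group SOM neurons by hierarchical clustering
#'
#' Agglomerative clustering of the codebook vectors (Euclidean distance,
#' complete linkage), cut at `n` clusters. With `n = "auto"` the cut
#' maximizing the average silhouette width is chosen; near-ties (within 0.01)
#' are broken in favor of the cut with fewest negative-silhouette neurons.
#'
#' @param model a `"path_som"`.
#' @param n integer number of clusters in `2 .. n_neurons - 1`, or `"auto"`.
#' @param n_range candidate cluster counts scanned when `n = "auto"`.
#' @return an object of class `"neuron_clustering"`: list with `labels`
#'   (per-neuron cluster id), `n`, `hclust` (the full tree), `silhouette`
#'   (per-neuron width), `avg_silhouette`, and for auto selection the scan
#'   `profile`.
#' @export
cluster_neurons <- function(model, n = "auto",
                            n_range = 2:min(15L, nrow(model$codebook) - 1L)) {
  W <- model$codebook
  m <- nrow(W)
  d <- dist(W)
  hc <- hclust(d, method = "complete")
  sil_for <- function(k) {
    lab <- cutree(hc, k = k)
    s <- cluster::silhouette(lab, d)
    list(labels = lab, sil = s[, "sil_width"], avg = mean(s[, "sil_width"]))
  }
  profile <- NULL
  if (identical(n, "auto")) {
    cand <- lapply(n_range, sil_for)
    avg <- vapply(cand, `[[`, numeric(1), "avg")
    nneg <- vapply(cand, function(z) sum(z$sil < 0), integer(1))
    ok <- avg >= max(avg) - 0.01
    pick <- which(ok)[order(nneg[ok], -avg[ok])][1]
    n <- n_range[pick]
    best <- cand[[pick]]
    profile <- data.frame(n = n_range, avg_silhouette = avg,
                          n_negative = nneg)
  } else {
    n <- as.integer(n)
    if (n < 2L || n > m - 1L)
      stop("n must be in 2 .. ", m - 1L, " (or \"auto\")")
    best <- sil_for(n)
  }
  structure(list(labels = unname(best$labels), n = as.integer(n), hclust = hc,
                 silhouette = unname(best$sil), avg_silhouette = best$avg,
                 profile = profile, method = "complete",
                 metric = "euclidean"),
            class = "neuron_clustering")
}

#' @export
print.neuron_clustering <- function(x, ...) {
  cat("Neuron clustering: ", x$n, " clusters (complete linkage), ",
      "avg silhouette ", format(x$avg_silhouette, digits = 3), ", ",
      sum(x$silhouette < 0), " neuron(s) with negative silhouette\n",
      sep = "")
  invisible(x)
}

#' Plot a SOM as a hexagonal map
#'
#' Draws the hexagonal lattice, optionally filled by a per-neuron value
#' (e.g. cluster label or average force), and optionally overlays one or
#' more pathway traces.
#'
#' @param x a `"path_som"`.
#' @param property optional numeric or factor vector, one value per neuron,
#'   used to fill the hexagons. `NA` neurons are left white.
#' @param traces optional list of `"path_trace"` objects drawn as lines.
#' @param palette fill palette function (default [grDevices::hcl.colors()]).
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the grid data frame with fill colors.
#' @export
plot.path_som <- function(x, property = NULL, traces = NULL,
                          palette = function(n) grDevices::hcl.colors(n, "viridis"),
                          main = NULL, ...) {
  grid <- x$grid
  fill <- rep("white", nrow(grid))
  if (!is.null(property)) {
    if (is.factor(property) || is.character(property)) {
      f <- factor(property)
      cols <- palette(nlevels(f))
      fill <- cols[as.integer(f)]
    } else {
      ok <- is.finite(property)
      if (any(ok)) {
        br <- cut(property[ok], breaks = 100)
        cols <- palette(100)
        fill[ok] <- cols[as.integer(br)]
      }
    }
    fill[is.na(fill)] <- "white"
  }
  r <- 0.5 / cos(pi / 6)
  ang <- pi / 6 + (0:5) * pi / 3
  graphics::plot(grid$x, grid$y, type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main,
                 xlim = range(grid$x) + c(-1, 1) * 0.6,
                 ylim = range(grid$y) + c(-1, 1) * 0.6, ...)
  for (i in seq_len(nrow(grid)))
    graphics::polygon(grid$x[i] + r * cos(ang), grid$y[i] + r * sin(ang),
                      col = fill[i], border = "grey40")
  graphics::text(grid$x, grid$y, grid$id, cex = 0.6)
  if (!is.null(traces)) {
    cols <- grDevices::rainbow(length(traces))
    for (t in seq_along(traces)) {
      b <- traces[[t]]$bmu
      graphics::lines(grid$x[b] + stats::runif(length(b), -0.08, 0.08),
                      grid$y[b] + stats::runif(length(b), -0.08, 0.08),
                      col = cols[t], lwd = 1.5)
    }
  }
  invisible(cbind(grid, fill = fill))
}

#' Persist a trained SOM as a JSON header plus CSV codebook
#'
#' @param model a `"path_som"`.
#' @param prefix output path prefix: writes `<prefix>.json` and
#'   `<prefix>_codebook.csv`.
#' @return `prefix`, invisibly.
#' @export
write_som <- function(model, prefix) {
  header <- list(hyper = model$hyper, qe = model$qe, qe_init = model$qe_init,
                 n_frames = model$n_frames,
                 center = model$center, scl = model$scl,
                 training = model$training)
  jsonlite::write_json(header, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  write.csv(as.data.frame(model$codebook),
            paste0(prefix, "_codebook.csv"), row.names = FALSE)
  invisible(prefix)
}

#' Load a SOM persisted by [write_som()]
#'
#' @param prefix path prefix used at write time.
#' @return a `"path_som"` equivalent (up to numeric text round-trip) to the
#'   saved model.
#' @export
read_som <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  W <- as.matrix(read.csv(paste0(prefix, "_codebook.csv")))
  dimnames(W) <- NULL
  hyper <- header$hyper
  structure(list(codebook = W, grid = som_grid(hyper$rows, hyper$cols),
                 hyper = hyper,
                 center = header$center, scl = header$scl,
                 qe = header$qe, qe_init = header$qe_init,
                 training = list(bmu = as.integer(header$training$bmu),
                                 dist = as.numeric(header$training$dist)),
                 n_frames = header$n_frames), class = "path_som")
}
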