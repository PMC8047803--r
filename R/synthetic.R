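# Ground-truth-labelled synthetic unfolding data: a compact toy native
# structure, scripted block-wise contact rupture along two (or more)
# pathways, and force/extension traces with an optional intermediate peak.

#' Specification of a synthetic unfolding experiment
#'
#' Defines the study conditions of the toy system: a compact bead-chain
#' native structure whose native contact pairs are partitioned into
#' sequence-local blocks, per-pathway rupture orders over those blocks, the
#' frame count per replica, the feature noise, and a simple force model with
#' an optional intermediate force peak on one pathway.
#'
#' Defaults mirror the pulled two-pathway system the method targets: two
#' pathways that break the same four contact blocks in a different order
#' (the first pathway detaches the N-terminal block and carries a mechanical
#' intermediate, signalled by a force peak during its second rupture
#' window), 5% relative Gaussian feature noise, and a 0-24 nm extension
#' ramp.
#'
#' @param n_residues chain length of the toy native (>= 8).
#' @param n_frames frames per replica (conformations sampled at a fixed
#'   stride, as in the source trajectories).
#' @param n_blocks number of contact blocks the native pair set is
#'   partitioned into (>= 3).
#' @param cutoff native-contact cutoff in nm.
#' @param break_scale broken contacts plateau at `break_scale` x native
#'   distance.
#' @param noise_sd Gaussian noise SD (nm) added to every distance; `NULL`
#'   (default) uses 5% of the mean native contact distance.
#' @param pathways named list of rupture orders (permutations of the block
#'   names `"B1" ... "Bk"`); default two pathways differing in the order of
#'   the middle blocks.
#' @param force_baseline,force_noise_sd baseline pulling force and its noise
#'   (kJ mol^-1 nm^-1).
#' @param peak_amplitude extra force inside the peak window on the
#'   intermediate-bearing pathway.
#' @param peak_window frame range `c(first, last)` of the force peak;
#'   `NULL` = the second rupture window.
#' @param intermediate_pathway name of the pathway carrying the force peak.
#' @param max_extension final end-to-end extension (nm).
#' @param seed master seed for the native geometry.
#' @return a list of class `"toy_unfolding_spec"`.
#' @export
toy_unfolding_spec <- function(n_residues = 40L, n_frames = 60L,
                               n_blocks = 4L, cutoff = 1.0,
                               break_scale = 3, noise_sd = NULL,
                               pathways = NULL,
                               force_baseline = 300, force_noise_sd = 15,
                               peak_amplitude = 250, peak_window = NULL,
                               intermediate_pathway = "pathway1",
                               max_extension = 24, seed = 1L) {
  if (n_residues < 8L) stop("n_residues must be >= 8")
  if (n_blocks < 3L) stop("need at least 3 blocks")
  blocks <- paste0("B", seq_len(n_blocks))
  if (is.null(pathways)) {
    # pathway 1: N-terminal block first, then the C-terminal block
    # (intermediate); pathway 2 unfolds N-side blocks in sequence order first
    pathways <- list(
      pathway1 = c(blocks[1], blocks[n_blocks],
                   blocks[seq(2L, n_blocks - 1L)]),
      pathway2 = blocks)
  }
  for (p in pathways)
    if (!setequal(p, blocks) || length(p) != n_blocks)
      stop("every pathway must be a permutation of the block names")
  if (!intermediate_pathway %in% names(pathways))
    stop("intermediate_pathway not among the pathway names")
  if (is.null(peak_window)) {
    w <- window_bounds(n_frames, n_blocks)
    peak_window <- c(w$from[2], w$to[2])
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 n_blocks = as.integer(n_blocks), block_names = blocks,
                 cutoff = cutoff, break_scale = break_scale,
                 noise_sd = noise_sd, pathways = pathways,
                 force_baseline = force_baseline,
                 force_noise_sd = force_noise_sd,
                 peak_amplitude = peak_amplitude, peak_window = peak_window,
                 intermediate_pathway = intermediate_pathway,
                 max_extension = max_extension, seed = as.integer(seed)),
            class = "toy_unfolding_spec")
}

window_bounds <- function(n_frames, n_blocks) {
  edges <- round(seq(0, n_frames, length.out = n_blocks + 1L))
  data.frame(from = edges[-(n_blocks + 1L)] + 1L, to = edges[-1])
}

#' Toy native structure and its contact pairs
#'
#' Places the chain on a deterministic compact helix (0.5 nm radius, ~6.5
#' residues per turn) so that the native pair set under the cutoff rule
#' contains both sequence-local and turn-to-turn contacts, then partitions
#' the pairs into `n_blocks` named blocks by the quantiles of the pair
#' midpoint (i + j) / 2 -- sequence-local groups standing in for structural
#' regions (N-lobe, core, C-hairpin, ...).
#'
#' @param spec a `"toy_unfolding_spec"`.
#' @return list with `coords` (n x 3, nm), `pairs` (a `"contact_pairs"`
#'   with an extra `block` column) and `native_mean` (mean native contact
#'   distance, nm).
#' @export
generate_toy_native <- function(spec) {
  n <- spec$n_residues
  t <- seq_len(n)
  theta <- 2 * pi / 6.5
  coords <- cbind(0.5 * cos(theta * t), 0.5 * sin(theta * t), 0.13 * t)
  pairs <- select_native_pairs(coords, cutoff = spec$cutoff)
  if (nrow(pairs) < spec$n_blocks)
    stop("degenerate spec: fewer native pairs than blocks")
  mid <- (pairs$i + pairs$j) / 2
  qs <- stats::quantile(mid, probs = seq(0, 1, length.out = spec$n_blocks + 1))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  pairs$block <- spec$block_names[cut(mid, qs, labels = FALSE,
                                      include.lowest = TRUE)]
  list(coords = coords, pairs = pairs, native_mean = mean(pairs$native))
}

#' Generate one synthetic unfolding replica
#'
#' Each contact block ramps linearly from its native distance to
#' `break_scale` x native over that block's rupture window; windows are
#' consecutive equal slices of the trajectory taken in the labelled
#' pathway's block order. Gaussian noise is added to every distance (floored
#' at 0.05 nm to stay physical). The force trace is baseline + noise, plus
#' the peak amplitude inside the peak window when the label is the
#' intermediate-bearing pathway; the extension ramps linearly to
#' `max_extension`.
#'
#' @param spec a `"toy_unfolding_spec"`.
#' @param label pathway name from `spec$pathways`.
#' @param seed replica seed.
#' @param n_frames override of `spec$n_frames` (e.g. 10x for a low-speed
#'   analogue of the same scripted pathway).
#' @param native optional precomputed [generate_toy_native()] result.
#' @return list with `features` (a `"feature_matrix"`), `force`,
#'   `extension`, `label`, `seed`.
#' @export
generate_replica <- function(spec, label, seed = 1L,
                             n_frames = spec$n_frames, native = NULL) {
  if (!label %in% names(spec$pathways))
    stop("unknown pathway label: ", label)
  if (is.null(native)) native <- generate_toy_native(spec)
  pairs <- native$pairs
  order <- spec$pathways[[label]]
  wb <- window_bounds(n_frames, spec$n_blocks)
  P <- nrow(pairs)
  factor_mat <- matrix(1, nrow = n_frames, ncol = P)
  for (k in seq_along(order)) {
    cols <- which(pairs$block == order[k])
    f0 <- wb$from[k]; f1 <- wb$to[k]
    ramp <- c(rep(0, f0 - 1L),
              seq(0, 1, length.out = f1 - f0 + 1L),
              rep(1, n_frames - f1))
    factor_mat[, cols] <- 1 + ramp * (spec$break_scale - 1)
  }
  X <- factor_mat * matrix(pairs$native, nrow = n_frames, ncol = P,
                           byrow = TRUE)
  sigma <- if (is.null(spec$noise_sd)) 0.05 * native$native_mean else
    spec$noise_sd
  set.seed(seed)
  if (sigma > 0)
    X <- pmax(X + matrix(rnorm(length(X), sd = sigma), nrow = n_frames), 0.05)
  peak_scale <- n_frames / spec$n_frames
  pw <- round(spec$peak_window * peak_scale)
  in_peak <- seq_len(n_frames) >= pw[1] & seq_len(n_frames) <= pw[2]
  force <- spec$force_baseline +
    rnorm(n_frames, sd = spec$force_noise_sd) +
    spec$peak_amplitude * in_peak * (label == spec$intermediate_pathway)
  extension <- seq(0, spec$max_extension, length.out = n_frames)
  list(features = feature_matrix(X, pairs = pairs, replica = label),
       force = force, extension = extension, label = label,
       seed = as.integer(seed))
}

#' Generate a labelled synthetic dataset of unfolding replicas
#'
#' @param spec a `"toy_unfolding_spec"`.
#' @param n_per_pathway named integer vector of replica counts per pathway;
#'   the default 12/38 split of 50 replicas mirrors a minority/majority
#'   kinetic partitioning between two routes.
#' @param seed master seed; per-replica seeds are drawn from it
#'   deterministically.
#' @param n_frames override of frames per replica (see
#'   [generate_replica()]).
#' @return a list of class `"toy_dataset"`: `replicas` (list of
#'   [generate_replica()] results), `labels`, `pairs`, `native`, `spec`.
#' @export
generate_dataset <- function(spec,
                             n_per_pathway = c(pathway1 = 12L,
                                               pathway2 = 38L),
                             seed = 1L, n_frames = spec$n_frames) {
  stopifnot(all(names(n_per_pathway) %in% names(spec$pathways)),
            all(n_per_pathway >= 1L))
  native <- generate_toy_native(spec)
  labels <- rep(names(n_per_pathway), times = n_per_pathway)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, length(labels))
  replicas <- vector("list", length(labels))
  for (i in seq_along(labels))
    replicas[[i]] <- generate_replica(spec, labels[i], seed = rep_seeds[i],
                                      n_frames = n_frames, native = native)
  structure(list(replicas = replicas, labels = labels,
                 pairs = native$pairs, native = native, spec = spec,
                 replica_seeds = rep_seeds),
            class = "toy_dataset")
}

#' @export
print.toy_dataset <- function(x, ...) {
  cat("Synthetic unfolding dataset:", length(x$replicas), "replicas (",
      paste(names(table(x$labels)), table(x$labels), sep = ": ",
            collapse = ", "), "),",
      nrow(x$pairs), "native pairs,",
      nrow(x$replicas[[1]]$features), "frames each\n")
  invisible(x)
}

#' Stack a toy dataset into one training matrix
#'
#' @param dataset a `"toy_dataset"`.
#' @return list with `x` (all replicas row-bound) and `replica` (row ->
#'   replica index).
#' @export
stack_dataset <- function(dataset) {
  mats <- lapply(dataset$replicas, function(r) unclass(r$features))
  list(x = do.call(rbind, mats),
       replica = rep(seq_along(mats), vapply(mats, nrow, integer(1))))
}
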