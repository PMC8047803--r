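mk_trace <- function(b) structure(list(bmu = b, scalars = NULL),
                                  class = "path_trace")

test_that("transition counts enumerate consecutive frame pairs", {
  tg <- transition_matrix(mk_trace(c(1, 1, 2, 2, 3)), n_neurons = 3)
  expect_equal(tg$counts,
               matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(tg$prob[1, ], c(0.5, 0.5, 0))
  expect_equal(tg$prob[2, ], c(0, 0.5, 0.5))
  # neuron 3 has no outgoing transition: zero row, flagged isolated
  expect_equal(tg$isolated, 3)
  expect_equal(sum(tg$counts), 4)
  # constant trace: only the self transition, probability 1
  tgc <- transition_matrix(mk_trace(rep(2, 6)), n_neurons = 3)
  expect_equal(tgc$prob[2, 2], 1)
  expect_equal(sum(tgc$counts), 5)
  expect_error(transition_matrix(list(), 3), "no traces")
  expect_error(transition_matrix(mk_trace(c(1, 9)), 3), "outside")
})

test_that("row-stochastic rows sum to one and self-exclusion works", {
  fit <- small_fit()
  traces <- lapply(fit$ds$replicas, function(r)
    trace_path(fit$model, r$features))
  tg <- transition_matrix(traces, nrow(fit$model$codebook))
  rs <- rowSums(tg$prob)
  expect_true(all(abs(rs[rowSums(tg$counts) > 0] - 1) < 1e-12))
  expect_equal(sum(tg$counts),
               sum(vapply(traces, function(t) length(t$bmu) - 1L,
                          integer(1))))
  tg2 <- transition_matrix(traces, nrow(fit$model$codebook),
                           include_self = FALSE)
  expect_true(all(diag(tg2$counts) == 0))
})

test_that("counts are invariant to trace order and to splitting a trace", {
  b <- c(1, 1, 2, 3, 3, 2, 4, 4, 4)
  whole <- transition_matrix(mk_trace(b), 4)
  # overlapping split (boundary frame repeated) preserves every transition
  split <- transition_matrix(list(mk_trace(b[1:5]), mk_trace(b[5:9])), 4)
  expect_equal(sum(split$counts), sum(whole$counts))
  expect_identical(split$counts, whole$counts)
  # disjoint split loses exactly the one boundary transition
  split2 <- transition_matrix(list(mk_trace(b[1:5]), mk_trace(b[6:9])), 4)
  expect_equal(sum(split2$counts), sum(whole$counts) - 1)
  swapped <- transition_matrix(list(mk_trace(b[5:9]), mk_trace(b[1:5])), 4)
  expect_identical(split$counts, swapped$counts)
})

test_that("graph edges carry -log probabilities", {
  tg <- transition_matrix(mk_trace(c(1, 2, 1, 3)), n_neurons = 3)
  g <- build_graph(tg)
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  # p(1->2) = p(1->3) = 0.5 -> weight ln 2; p(2->1) = 1 -> weight 0
  i12 <- which(el[, 1] == 1 & el[, 2] == 2)
  expect_equal(w[i12], log(2), tolerance = 1e-12)
  i21 <- which(el[, 1] == 2 & el[, 2] == 1)
  expect_equal(w[i21], 0)
  # no edge where the count is zero
  expect_equal(nrow(el), 3)
  expect_true(all(w >= 0))
})

test_that("shortest paths prefer high-probability chains", {
  # chain a->c->b with p = 0.5, 0.5 beats direct a->b with p = 0.2
  prob <- matrix(0, 3, 3)
  prob[1, ] <- c(0.3, 0.2, 0.5)   # a: direct to b (0.2), to c (0.5)
  prob[3, ] <- c(0, 0.5, 0.5)     # c: to b (0.5)
  prob[2, 2] <- 1
  tg <- structure(list(counts = (prob > 0) * 1, prob = prob, n_neurons = 3,
                       isolated = integer(0), include_self = TRUE,
                       log_base = "natural"), class = "transition_graph")
  sp <- shortest_path_distance(tg, 1, 2)
  expect_equal(sp$path, c(1, 3, 2))
  expect_equal(sp$distance, 2 * log(2), tolerance = 1e-12)
  expect_equal(sp$prob, 0.25, tolerance = 1e-12)
  # a = b -> empty path, distance 0
  sp0 <- shortest_path_distance(tg, 2, 2)
  expect_equal(sp0$path, integer(0))
  expect_equal(sp0$distance, 0)
  # unreachable -> infinite distance signalled explicitly
  spu <- shortest_path_distance(tg, 2, 1)
  expect_equal(spu$distance, Inf)
  expect_equal(spu$path, integer(0))
  expect_error(shortest_path_distance(tg, 1, 9), "unknown node")
})

test_that("shortest-path distance matches exhaustive enumeration", {
  set.seed(13)
  for (r in 1:30) {
    n <- sample(4:7, 1)
    counts <- matrix(rpois(n * n, 0.8), n, n)
    tg <- structure(list(counts = counts,
                         prob = counts / pmax(rowSums(counts), 1),
                         n_neurons = n, isolated = integer(0),
                         include_self = TRUE, log_base = "natural"),
                    class = "transition_graph")
    tg$prob[rowSums(counts) == 0, ] <- 0
    ab <- sample(n, 2)
    sp <- shortest_path_distance(tg, ab[1], ab[2])
    ref <- sp_oracle(tg$prob, ab[1], ab[2])
    expect_equal(sp$distance, ref, tolerance = 1e-9)
    # internal consistency: sum of weights == -log prod p
    if (is.finite(sp$distance))
      expect_equal(sp$distance, -log(sp$prob), tolerance = 1e-9)
  }
})

test_that("map_property averages the scalar per neuron, missing not zero", {
  mk <- function(b, f) structure(list(bmu = b, scalars = data.frame(force = f)),
                                 class = "path_trace")
  # all forces equal F -> every visited neuron maps to F
  pm <- map_property(mk(c(1, 2, 2, 4), rep(7, 4)), n_neurons = 4)
  expect_equal(pm$mean[c(1, 2, 4)], c(7, 7, 7))
  expect_true(is.na(pm$mean[3]))   # unvisited: missing, not zero
  expect_equal(pm$n, c(1, 2, 0, 1))
  # forces 1,2,3 on one neuron -> mean 2
  pm2 <- map_property(mk(c(5, 5, 5), c(1, 2, 3)), n_neurons = 5)
  expect_equal(pm2$mean[5], 2)
  expect_equal(sum(pm2$n), 3)
  # pooled across traces, invariant to trace order
  a <- mk(c(1, 2), c(1, 2)); b <- mk(c(2, 1), c(4, 3))
  expect_equal(map_property(list(a, b), 2)$mean,
               map_property(list(b, a), 2)$mean)
  expect_error(map_property(list(structure(list(bmu = 1, scalars = NULL),
                                           class = "path_trace")), 2),
               "absent")
})

test_that("the maximum-force neuron lies in the scripted peak window", {
  fit <- small_fit()
  spec <- fit$spec
  traces <- lapply(fit$ds$replicas, function(r)
    trace_path(fit$model, r$features, scalars = data.frame(force = r$force)))
  fmap <- map_property(traces, nrow(fit$model$codebook), "force")
  peak_neuron <- fmap$neuron[which.max(fmap$mean)]
  pw <- spec$peak_window
  int_idx <- which(fit$ds$labels == spec$intermediate_pathway)
  visited <- unique(unlist(lapply(traces[int_idx], function(tr)
    tr$bmu[pw[1]:pw[2]])))
  expect_true(peak_neuron %in% visited)
})

test_that("work_profile integrates force over extension", {
  # constant F over dx -> W = F dx
  w <- work_profile(rep(10, 5), seq(0, 1, length.out = 5))
  expect_equal(w$work[5], 10)
  expect_true(all(diff(w$work) >= 0))
  # F = 0 -> W = 0
  expect_equal(work_profile(rep(0, 4), 1:4)$work, rep(0, 4))
  # linear ramp F: 0 -> 10 over x: 0 -> 1 -> triangle area 5
  x <- seq(0, 1, length.out = 101)
  expect_equal(work_profile(10 * x, x)$work[101], 5, tolerance = 1e-9)
  expect_error(work_profile(1:3, 1:4), "length")
  expect_error(work_profile(1:3, c(0, 1, 0.5)), "decreases")
})
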