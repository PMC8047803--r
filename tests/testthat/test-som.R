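test_that("training is deterministic given the seed", {
  set.seed(99)
  x <- matrix(rnorm(300), 30, 10)
  m1 <- path_som(x, rows = 2, cols = 3, epochs = 15, seed = 5)
  m2 <- path_som(x, rows = 2, cols = 3, epochs = 15, seed = 5)
  expect_identical(m1$codebook, m2$codebook)
  m3 <- path_som(x, rows = 2, cols = 3, epochs = 15, seed = 6)
  expect_false(identical(m1$codebook, m3$codebook))
})

test_that("far-separated points are each captured by a distinct BMU", {
  # exactly n_neurons distinct well-separated points, long training with a
  # vanishing neighborhood: every point ends up owning its own neuron and
  # the quantization error goes to ~0
  set.seed(2)
  x <- matrix(rnorm(4 * 6, sd = 10), 4, 6)
  m <- suppressWarnings(
    path_som(x, rows = 2, cols = 2, epochs = 2000, radius = c(1, 0.1),
             init = "sample", seed = 3))
  p <- predict(m, x)
  expect_equal(sort(unique(p$bmu)), sort(p$bmu))  # all BMUs distinct
  expect_lt(m$qe, 0.1)                            # quantization error ~ 0
})

test_that("codebook converges near the means of two Gaussian blobs", {
  set.seed(7)
  n <- 200; P <- 5
  mu1 <- rep(0, P); mu2 <- rep(4, P)
  x <- rbind(matrix(rnorm(n * P, mu1, 0.3), n, P, byrow = FALSE),
             matrix(rnorm(n * P, 4, 0.3), n, P))
  m <- path_som(x, rows = 2, cols = 2, epochs = 80, radius = c(1, 0.1),
                seed = 1)
  p <- predict(m, x)
  # each blob's dominant neuron codebook lies near the blob mean
  se3 <- 3 * 0.3 / sqrt(n)
  for (blob in 1:2) {
    rows <- ((blob - 1) * n + 1):(blob * n)
    bmu <- as.integer(names(which.max(table(p$bmu[rows]))))
    mu <- if (blob == 1) mu1 else mu2
    expect_lt(max(abs(m$codebook[bmu, ] - colMeans(x[rows, ]))), 10 * se3)
  }
})

test_that("assign_bmu equals the brute-force argmin with lowest-id ties", {
  fit <- small_fit()
  m <- fit$model
  set.seed(11)
  for (r in 1:200) {
    x <- fit$st$x[sample(nrow(fit$st$x), 1), ] + rnorm(ncol(m$codebook), sd = 0.3)
    got <- assign_bmu(m, x)
    ref <- bmu_oracle(m$codebook, x)
    expect_identical(got$id, ref$id)
    expect_equal(got$dist, ref$dist, tolerance = 1e-12)
  }
  # exact codebook vector -> that neuron at distance 0
  got <- assign_bmu(m, m$codebook[5, ])
  expect_equal(got$id, 5)
  expect_equal(got$dist, 0)
  # constructed tie between neurons 3 and 7 resolves to neuron 3
  W <- matrix(0, 8, 2)
  W[3, ] <- c(1, 0); W[7, ] <- c(-1, 0)
  W[c(1, 2, 4, 5, 6, 8), ] <- 50
  mt <- list(codebook = W, grid = som_grid(2, 4),
             hyper = list(rows = 2L, cols = 4L), center = NULL, scl = NULL)
  class(mt) <- "path_som"
  expect_equal(assign_bmu(mt, c(0, 0))$id, 3)
  expect_error(predict(m, matrix(0, 2, 3)), "dimension")
})

test_that("centrotypes select the assigned frame closest to the codebook", {
  fit <- small_fit()
  ct <- centrotypes(fit$model, fit$st$x)
  asg <- predict(fit$model, fit$st$x)
  for (j in seq_len(nrow(fit$model$codebook))) {
    members <- which(asg$bmu == j)
    if (length(members) == 0) {
      expect_true(is.na(ct$frame[j]))
    } else {
      d <- sqrt(rowSums(sweep(fit$st$x[members, , drop = FALSE], 2,
                              fit$model$codebook[j, ])^2))
      expect_equal(ct$frame[j], members[which.min(d)])
    }
  }
  expect_equal(ct$n_frames, tabulate(asg$bmu, nrow(fit$model$codebook)))
})

test_that("neuron_quality degenerates to 0 / offset on constructed input", {
  W <- rbind(rep(0, 4), rep(1, 4), rep(10, 4), rep(20, 4))
  mt <- list(codebook = W, grid = som_grid(2, 2),
             hyper = list(rows = 2L, cols = 2L), center = NULL, scl = NULL)
  class(mt) <- "path_som"
  # two copies of each of the first two codebook vectors; neurons 1 and 2
  # are lattice-adjacent and their codebooks differ by the constant 1
  x <- W[c(1, 1, 2, 2), ]
  nq <- neuron_quality(mt, x)
  expect_equal(unique(nq$intra), 0)
  expect_equal(unique(nq$inter), 1)
  # all frames identical -> both distributions degenerate at 0
  x2 <- W[c(1, 1, 1, 1), ]
  nq2 <- neuron_quality(mt, x2)
  expect_equal(unique(nq2$intra), 0)
  expect_equal(length(nq2$inter), 0)
})

test_that("map segregates conformations: intra-neuron dRMSD < neighbor", {
  fit <- small_fit()
  nq <- neuron_quality(fit$model, fit$st$x, seed = 1)
  expect_lt(median(nq$intra), median(nq$inter))
})

test_that("quantization error does not exceed its initialization value", {
  set.seed(2)
  x <- matrix(rnorm(600), 60, 10)
  for (s in 1:20) {
    m <- path_som(x, rows = 3, cols = 3, epochs = 10, seed = s)
    expect_lte(m$qe, m$qe_init)
  }
})

test_that("time-adjacent frames land on identical or adjacent neurons", {
  fit <- small_fit()
  adj <- som_neighbors(fit$model)
  frac <- mean(vapply(fit$ds$replicas, function(r) {
    b <- trace_path(fit$model, r$features)$bmu
    f <- b[-length(b)]; t <- b[-1]
    mean(f == t | adj[cbind(f, t)])
  }, numeric(1)))
  expect_gte(frac, 0.8)
})

test_that("cluster_neurons separates two codebook blobs and cuts trees", {
  set.seed(4)
  x <- rbind(matrix(rnorm(300, 0, 0.2), 30, 10),
             matrix(rnorm(300, 6, 0.2), 30, 10))
  m <- path_som(x, rows = 2, cols = 4, epochs = 60, radius = c(1, 0.3),
                seed = 2)
  nc <- cluster_neurons(m, n = 2)
  # the two clusters split the codebook by which blob each neuron tracks
  blob <- as.integer(rowMeans(m$codebook) > 3)
  expect_equal(length(unique(nc$labels[blob == 0])), 1)
  expect_equal(length(unique(nc$labels[blob == 1])), 1)
  expect_true(all(nc$silhouette > 0))
  # n = n_neurons - 1: single pair merged = closest pair under the metric
  nc2 <- cluster_neurons(m, n = nrow(m$codebook) - 1)
  paired <- which(tabulate(nc2$labels) == 2)
  members <- which(nc2$labels == paired)
  D <- as.matrix(dist(m$codebook)); diag(D) <- Inf
  expect_equal(unname(sort(members)),
               unname(sort(which(D == min(D), arr.ind = TRUE)[1, ])))
  expect_error(cluster_neurons(m, n = 1), "n must be")
})

test_that("auto cluster count maximizes silhouette with the tie rule", {
  fit <- small_fit()
  nc <- cluster_neurons(fit$model, n = "auto")
  expect_true(nc$n >= 2)
  prof <- nc$profile
  ok <- prof$avg_silhouette >= max(prof$avg_silhouette) - 0.01
  expect_true(prof$n_negative[prof$n == nc$n] == min(prof$n_negative[ok]))
})

test_that("an 8x8 map cut at 8 clusters labels every neuron in 1..8", {
  fit <- small_fit()
  ds <- fit$ds
  m <- path_som(fit$st$x, rows = 8, cols = 8, epochs = 30, seed = 1)
  nc <- cluster_neurons(m, n = 8)
  expect_equal(sort(unique(nc$labels)), 1:8)
  expect_equal(length(nc$labels), 64)
})

test_that("SOM persists losslessly through the JSON+CSV round-trip", {
  fit <- small_fit()
  prefix <- tempfile()
  write_som(fit$model, prefix)
  m2 <- read_som(prefix)
  expect_equal(m2$codebook, fit$model$codebook, tolerance = 1e-12)
  expect_identical(m2$training$bmu, fit$model$training$bmu)
  expect_equal(m2$hyper$seed, fit$model$hyper$seed)
  expect_equal(m2$qe, fit$model$qe, tolerance = 1e-12)
})

test_that("permuting frame order changes the codebook but not the
           two-pathway classification", {
  fit <- small_fit()
  set.seed(31)
  perm <- sample(nrow(fit$st$x))
  m2 <- path_som(fit$st$x[perm, ], rows = 4, cols = 4, epochs = 40, seed = 7)
  expect_false(identical(m2$codebook, fit$model$codebook))
  lab <- function(m) {
    traces <- lapply(fit$ds$replicas, function(r) trace_path(m, r$features))
    cluster_paths(traces, m, n = 2)$labels
  }
  l1 <- lab(fit$model); l2 <- lab(m2)
  # same partition up to label swap
  agree <- max(mean(l1 == l2), mean(l1 == (3 - l2)))
  expect_equal(agree, 1)
})
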