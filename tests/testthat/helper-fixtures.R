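# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 3-residue toy PDB: CB atoms at 0, 0.5, 1.2 nm along x
toy_pdb_path <- function() memo("toy_pdb", {
  p <- tempfile(fileext = ".pdb")
  write_pdb_cb(matrix(c(0, 0, 0, 0.5, 0, 0, 1.2, 0, 0),
                      ncol = 3, byrow = TRUE), p)
  p
})

# small synthetic spec: quick to generate and train on
small_spec <- function(...) toy_unfolding_spec(n_residues = 20L,
                                               n_frames = 30L, ...)

# a small trained SOM on a 12-replica dataset (shared by several files)
small_fit <- function() memo("small_fit", {
  spec <- small_spec()
  ds <- generate_dataset(spec,
                         n_per_pathway = c(pathway1 = 4L, pathway2 = 8L),
                         seed = 7)
  st <- stack_dataset(ds)
  model <- path_som(st$x, rows = 4, cols = 4, epochs = 40, seed = 7)
  list(spec = spec, ds = ds, st = st, model = model)
})

# brute-force BMU oracle: plain loop over neurons
bmu_oracle <- function(codebook, x) {
  d <- apply(codebook, 1, function(w) sqrt(sum((w - x)^2)))
  list(id = which.min(d), dist = min(d))
}

# brute-force shortest path over all simple paths (small graphs only)
sp_oracle <- function(prob, a, b) {
  n <- nrow(prob)
  if (a == b) return(0)
  best <- Inf
  rec <- function(node, visited, logp) {
    if (node == b) { best <<- min(best, -logp); return(invisible()) }
    for (k in seq_len(n)) {
      if (prob[node, k] > 0 && !(k %in% visited))
        rec(k, c(visited, k), logp + log(prob[node, k]))
    }
  }
  rec(a, a, 0)
  best
}
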