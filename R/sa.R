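# Structural-alphabet encoding of local backbone fragments and per-fragment
# divergence of neuron ensembles from the folded-state distribution.

#' Read a structural alphabet from CSV
#'
#' The file has a `letter` column followed by the numeric prototype
#' descriptor columns (one row per letter). The packaged default is a
#' synthetic 25-letter alphabet (`sa25_synthetic_alphabet.csv`) whose
#' prototypes are ideal 4-residue fragments on a 5 x 5 curvature x torsion
#' grid, described by the descriptor of [fragment_descriptor()]; any
#' user-supplied alphabet in the same layout can replace it.
#'
#' @param path CSV file; default: the packaged synthetic alphabet.
#' @return a `"structural_alphabet"`: list with `letters` (character) and
#'   `prototypes` (letters x descriptor-dimension matrix).
#' @export
read_sa_alphabet <- function(path = system.file("extdata",
                                                "sa25_synthetic_alphabet.csv",
                                                package = "pathsom")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"letter" %in% names(df)) stop("alphabet file needs a 'letter' column")
  proto <- as.matrix(df[, setdiff(names(df), "letter"), drop = FALSE])
  if (nrow(proto) < 2L) stop("alphabet needs at least 2 letters")
  if (any(!is.finite(proto))) stop("non-finite prototype descriptors")
  structure(list(letters = as.character(df$letter), prototypes = proto),
            class = "structural_alphabet")
}

#' Descriptor of a 4-residue backbone fragment
#'
#' Internal-coordinate descriptor of four consecutive reference-atom
#' positions: the three non-consecutive distances d(1,3), d(1,4), d(2,4)
#' (nm) plus the signed dihedral angle of the four points (radians), which
#' separates left- from right-handed local geometries.
#'
#' @param p 4 x 3 coordinate matrix (nm).
#' @return numeric vector `c(d13, d14, d24, dihedral)`.
#' @export
fragment_descriptor <- function(p) {
  stopifnot(nrow(p) == 4L, ncol(p) == 3L)
  d <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  dihedral <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2))
  c(d13 = d(1, 3), d14 = d(1, 4), d24 = d(2, 4), dihedral = dihedral)
}

#' Encode a conformation as a structural-alphabet string
#'
#' Every overlapping 4-residue fragment is assigned the alphabet letter
#' whose prototype descriptor is nearest in Euclidean distance (ties go to
#' the first letter in the alphabet).
#'
#' @param coords n x 3 reference-atom coordinates (nm), n >= 4.
#' @param alphabet a `"structural_alphabet"`.
#' @param descriptor function mapping a 4 x 3 fragment to a descriptor
#'   vector of the alphabet's dimension (default [fragment_descriptor()]).
#' @return character vector of letters, length `n - 3`.
#' @export
encode_fragments <- function(coords, alphabet,
                             descriptor = fragment_descriptor) {
  stopifnot(inherits(alphabet, "structural_alphabet"))
  n <- nrow(coords)
  if (is.null(n) || n < 4L) stop("need at least 4 residues to encode")
  proto <- alphabet$prototypes
  out <- character(n - 3L)
  for (f in seq_len(n - 3L)) {
    desc <- descriptor(coords[f:(f + 3L), , drop = FALSE])
    if (length(desc) != ncol(proto))
      stop("descriptor dimension ", length(desc),
           " does not match alphabet (", ncol(proto), ")")
    d2 <- rowSums(sweep(proto, 2, desc)^2)
    out[f] <- alphabet$letters[which.min(d2)]
  }
  out
}

#' Tabulate letter counts per fragment position
#'
#' @param encodings list of equal-length letter vectors (one per
#'   conformation), as returned by [encode_fragments()].
#' @param letters the alphabet's letters (column order of the result).
#' @return positions x letters count matrix.
#' @export
letter_counts <- function(encodings, letters) {
  L <- length(encodings[[1]])
  counts <- matrix(0L, nrow = L, ncol = length(letters),
                   dimnames = list(NULL, letters))
  for (e in encodings) {
    if (length(e) != L) stop("encodings differ in length")
    for (pos in seq_len(L))
      counts[pos, e[pos]] <- counts[pos, e[pos]] + 1L
  }
  counts
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Per-fragment divergence of a neuron ensemble from the folded state
#'
#' For each fragment position, the Jensen-Shannon divergence (base 2, range
#' [0, 1]) between the neuron's letter distribution and the reference
#' (folded-state) distribution. A pseudocount regularizes empty categories;
#' the default is 1 / (total sample size) per distribution.
#'
#' @param neuron_counts,ref_counts positions x letters count matrices over
#'   the same alphabet (see [letter_counts()]).
#' @param pseudocount added to every cell before normalization; `NULL`
#'   (default) uses 1 / (row sum) per matrix; use 0 for raw frequencies.
#' @return numeric vector of per-position divergences in [0, 1].
#' @export
fragment_divergence <- function(neuron_counts, ref_counts,
                                pseudocount = NULL) {
  if (!all(dim(neuron_counts) == dim(ref_counts)))
    stop("count matrices must share dimensions (same alphabet and length)")
  if (!is.null(colnames(neuron_counts)) && !is.null(colnames(ref_counts)) &&
      !identical(colnames(neuron_counts), colnames(ref_counts)))
    stop("alphabet mismatch between count matrices")
  norm <- function(cnt) {
    pc <- if (is.null(pseudocount)) 1 / pmax(rowSums(cnt), 1) else pseudocount
    x <- cnt + pc
    x / rowSums(x)
  }
  P <- norm(neuron_counts)
  Q <- norm(ref_counts)
  vapply(seq_len(nrow(P)), function(i) js_divergence(P[i, ], Q[i, ]),
         numeric(1))
}
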