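# Structure reading, native contact-pair selection, distance featurization.

#' Load a reference structure from a (multi-model) PDB file
#'
#' Reads one model of a PDB file and keeps a single reference coordinate per
#' residue: the Cbeta atom, or the Calpha atom for glycine (which has no
#' Cbeta). Coordinates are converted from Angstrom to nanometres.
#'
#' @param path path to a PDB file (single- or multi-model).
#' @param model 1-based model index to use (NMR ensembles typically deposit
#'   many models; the default uses the first).
#' @param gly_ca logical; if `TRUE` (default) glycine residues fall back to
#'   their Calpha atom, so every residue contributes one feature site. If
#'   `FALSE`, glycines are an error.
#' @return an object of class `"mdstructure"`: a list with `residues`
#'   (data frame: `resno`, `resid`, `chain`, `atom` actually used), `coords`
#'   (n x 3 matrix, nm), `model`, and `source`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_pdb_cb(matrix(c(0, 0, 0, 0.5, 0, 0, 1.2, 0, 0), ncol = 3,
#'                     byrow = TRUE), pdb)
#' s <- load_structure(pdb)
#' nrow(s$coords)
#' @export
load_structure <- function(path, model = 1L, gly_ca = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    stop("model index ", model, " out of range (file has ", n_models,
         " model(s))")
  atoms <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "_")
  res_keys <- unique(key)
  idx <- integer(length(res_keys))
  used_atom <- character(length(res_keys))
  for (r in seq_along(res_keys)) {
    rows <- which(key == res_keys[r])
    resid <- atoms$resid[rows[1]]
    cb <- rows[atoms$elety[rows] == "CB"]
    if (length(cb) >= 1L) {
      idx[r] <- cb[1]
      used_atom[r] <- "CB"
    } else if (gly_ca || resid == "GLY") {
      if (!gly_ca && resid == "GLY")
        stop("glycine residue ", atoms$resno[rows[1]],
             " has no CB and gly_ca = FALSE")
      ca <- rows[atoms$elety[rows] == "CA"]
      if (length(ca) < 1L)
        stop("residue ", resid, " ", atoms$resno[rows[1]],
             " has neither CB nor CA reference atom")
      idx[r] <- ca[1]
      used_atom[r] <- "CA"
    } else {
      stop("residue ", resid, " ", atoms$resno[rows[1]],
           " has no CB reference atom")
    }
  }
  atom_rows <- as.integer(rownames(atoms)[idx])
  xyz_cols <- as.vector(rbind(3 * atom_rows - 2, 3 * atom_rows - 1,
                              3 * atom_rows))
  coords <- matrix(pdb$xyz[model, xyz_cols], ncol = 3, byrow = TRUE) / 10
  if (any(!is.finite(coords))) stop("non-finite coordinates in model ", model)
  structure(list(
    residues = data.frame(resno = atoms$resno[idx], resid = atoms$resid[idx],
                          chain = atoms$chain[idx], atom = used_atom,
                          stringsAsFactors = FALSE),
    coords = coords, model = as.integer(model), gly_ca = gly_ca,
    source = path), class = "mdstructure")
}

#' @export
print.mdstructure <- function(x, ...) {
  cat("Reference structure:", nrow(x$coords), "residues (model", x$model,
      "of", basename(x$source), ")\n")
  cat("  reference atoms:", sum(x$residues$atom == "CB"), "CB,",
      sum(x$residues$atom == "CA"), "CA (Gly fallback)\n")
  invisible(x)
}

#' Select native contact pairs below a distance cutoff
#'
#' The feature space of the method: all residue pairs i < j whose reference
#' atoms lie strictly closer than `cutoff` in the native structure. Pairs are
#' returned in (i, j)-lexicographic order, so the feature ordering is
#' reproducible.
#'
#' @param native an `"mdstructure"` or an n x 3 coordinate matrix in nm.
#' @param cutoff distance cutoff in nm (default 1.0); strictly-closer pairs
#'   are included, boundary-equal distances are excluded.
#' @return an object of class `"contact_pairs"`: a data frame with columns
#'   `i`, `j` (1-based residue indices) and `native` (native distance, nm),
#'   with the cutoff and residue count stored as attributes.
#' @export
select_native_pairs <- function(native, cutoff = 1.0) {
  coords <- if (inherits(native, "mdstructure")) native$coords else native
  if (!is.matrix(coords) || ncol(coords) != 3)
    stop("native must be an mdstructure or an n x 3 coordinate matrix")
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 residues to form pairs")
  if (cutoff <= 0) {
    out <- data.frame(i = integer(0), j = integer(0), native = numeric(0))
  } else {
    d <- as.matrix(dist(coords))
    sel <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    ord <- order(sel[, 1], sel[, 2])
    sel <- sel[ord, , drop = FALSE]
    out <- data.frame(i = as.integer(sel[, 1]), j = as.integer(sel[, 2]),
                      native = d[sel])
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "n_residues") <- n
  class(out) <- c("contact_pairs", "data.frame")
  out
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat("Native contact pairs:", nrow(x), "pairs below",
      attr(x, "cutoff"), "nm over", attr(x, "n_residues"), "residues\n")
  invisible(x)
}

#' Extract a contact-distance feature matrix from a trajectory
#'
#' Computes, for every (strided) frame, the distance of each native contact
#' pair. Input can be a trajectory file (multi-model PDB or DCD, read with
#' bio3d; coordinates assumed Angstrom and converted to nm), a bio3d-style
#' `xyz` matrix (frames x 3n), or a frames x n x 3 array. Numeric input is
#' assumed to already be in nm.
#'
#' @param traj trajectory source (file path, xyz matrix, or 3-D array).
#' @param pairs a `"contact_pairs"` object defining the feature columns.
#' @param stride keep every `stride`-th frame, starting at the first
#'   (default 1 = all frames).
#' @param replica optional replica identifier stored in the metadata.
#' @param time_ps optional per-frame times (ps), strided along with frames.
#' @return a `"feature_matrix"`: frames x n_pairs numeric matrix (nm) with
#'   attributes `pairs`, `stride`, `replica`, `frames` (original frame
#'   indices) and optionally `time_ps`.
#' @export
extract_features <- function(traj, pairs, stride = 1L, replica = NULL,
                             time_ps = NULL) {
  stopifnot(inherits(pairs, "contact_pairs"))
  if (is.character(traj)) {
    if (!file.exists(traj)) stop("trajectory file not found: ", traj)
    if (grepl("\\.dcd$", traj, ignore.case = TRUE)) {
      xyz <- bio3d::read.dcd(traj, verbose = FALSE)
    } else {
      xyz <- bio3d::read.pdb(traj, multi = TRUE, verbose = FALSE)$xyz
    }
    xyz <- unclass(xyz) / 10  # Angstrom -> nm
  } else if (is.array(traj) && length(dim(traj)) == 3L) {
    stopifnot(dim(traj)[3] == 3L)
    xyz <- matrix(aperm(traj, c(3, 2, 1)), nrow = dim(traj)[1], byrow = TRUE)
  } else if (is.matrix(traj)) {
    xyz <- traj
  } else {
    stop("unsupported trajectory input")
  }
  n_res <- ncol(xyz) / 3
  if (n_res != round(n_res)) stop("xyz matrix width not a multiple of 3")
  if (nrow(pairs) > 0 && max(pairs$j) > n_res)
    stop("topology mismatch: pairs reference residue ", max(pairs$j),
         " but trajectory has ", n_res)
  if (nrow(xyz) == 0L) stop("empty trajectory")
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  keep <- seq(1L, nrow(xyz), by = stride)
  xyz <- xyz[keep, , drop = FALSE]
  P <- nrow(pairs)
  fm <- matrix(0, nrow = nrow(xyz), ncol = P)
  for (k in seq_len(P)) {
    ci <- 3L * (pairs$i[k] - 1L)
    cj <- 3L * (pairs$j[k] - 1L)
    dx <- xyz[, ci + 1L] - xyz[, cj + 1L]
    dy <- xyz[, ci + 2L] - xyz[, cj + 2L]
    dz <- xyz[, ci + 3L] - xyz[, cj + 3L]
    fm[, k] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  feature_matrix(fm, pairs = pairs, stride = stride, replica = replica,
                 frames = keep,
                 time_ps = if (!is.null(time_ps)) time_ps[keep] else NULL)
}

#' Construct a feature matrix object
#'
#' Low-level constructor used by [extract_features()] and the synthetic
#' generator; wraps a frames x pairs distance matrix with its metadata.
#'
#' @param x numeric matrix, frames x n_pairs, distances in nm.
#' @param pairs,stride,replica,frames,time_ps metadata; see
#'   [extract_features()].
#' @return a `"feature_matrix"` object.
#' @export
feature_matrix <- function(x, pairs = NULL, stride = 1L, replica = NULL,
                           frames = seq_len(nrow(x)), time_ps = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x))) stop("feature matrix contains non-finite entries")
  attr(x, "pairs") <- pairs
  attr(x, "stride") <- as.integer(stride)
  attr(x, "replica") <- replica
  attr(x, "frames") <- frames
  attr(x, "time_ps") <- time_ps
  class(x) <- c("feature_matrix", "matrix", "array")
  x
}

#' Distance root-mean-square deviation between two feature vectors
#'
#' Superposition-free structural dissimilarity: the RMS difference between
#' two vectors of internal distances.
#'
#' @param a,b numeric vectors of equal length (nm).
#' @return `sqrt(mean((a - b)^2))`, in nm.
#' @export
drmsd <- function(a, b) {
  if (length(a) != length(b)) stop("feature vectors differ in length")
  sqrt(mean((a - b)^2))
}

#' Write reference-atom coordinates as a (multi-model) PDB file
#'
#' Writes one pseudo-atom per residue (named CB, residue ALA) so that toy
#' structures round-trip through [load_structure()]. Coordinates are given in
#' nm and written in Angstrom.
#'
#' @param coords an n x 3 matrix (nm), or a list of such matrices for a
#'   multi-model file.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_cb <- function(coords, path) {
  models <- if (is.list(coords)) coords else list(coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    xyz <- models[[m]] * 10  # nm -> Angstrom
    if (length(models) > 1L)
      writeLines(sprintf("MODEL     %4d", m), con)
    for (i in seq_len(nrow(xyz))) {
      writeLines(sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        i, " CB ", "ALA", "A", i, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0), con)
    }
    if (length(models) > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
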