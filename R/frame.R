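#' Molecular frame and trajectory containers
#'
#' A `voa_frame` holds one snapshot: element labels, Cartesian coordinates
#' in Angstrom and a molecule id per atom.  A `voa_trajectory` holds a
#' constant-topology stack of frames with coordinates in an
#' `n_atoms x 3 x n_frames` array.  Atom indices are 1-based everywhere in
#' the user-facing API, matching the atom-numbering convention of structure
#' schemes; no 0-based indices ever leak out.
#'
#' @param labels character vector of element symbols.
#' @param xyz numeric `n x 3` matrix of coordinates (Angstrom).
#' @param mol molecule id per atom (integer or character); atoms with equal
#'   id belong to the same molecule.  Defaults to a single molecule.
#' @param index frame index (bookkeeping only).
#' @return `frame()` returns a `voa_frame`; `trajectory()` a `voa_trajectory`.
#' @examples
#' f <- frame(c("O", "H", "H"),
#'            rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' n_atoms(f)
#' @export
frame <- function(labels, xyz, mol = rep(1L, length(labels)), index = 1L) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("`xyz` must be a numeric n x 3 matrix")
  if (length(labels) != nrow(xyz))
    stop("length(labels) != nrow(xyz)")
  if (length(mol) != nrow(xyz))
    stop("molecule ids must cover every atom")
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(labels = as.character(labels), xyz = xyz,
                 mol = mol, index = as.integer(index)),
            class = "voa_frame")
}

#' @rdname frame
#' @param coords `n_atoms x 3 x n_frames` array, or a list of `n x 3`
#'   matrices with identical dimensions.
#' @export
trajectory <- function(labels, coords, mol = rep(1L, length(labels))) {
  if (is.list(coords)) {
    n <- length(coords)
    if (n == 0L) stop("empty trajectory")
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1L]]), 3L, n))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("`coords` must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1L] != length(labels))
    stop("atom count of `coords` does not match `labels`")
  if (length(mol) != length(labels))
    stop("molecule ids must cover every atom")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  structure(list(labels = as.character(labels), coords = coords, mol = mol),
            class = "voa_trajectory")
}

#' @rdname frame
#' @param x a `voa_frame` or `voa_trajectory`.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "voa_frame")) nrow(x$xyz)
  else if (inherits(x, "voa_trajectory")) dim(x$coords)[1L]
  else stop("not a voa_frame or voa_trajectory")
}

#' @rdname frame
#' @export
n_frames <- function(x) {
  if (inherits(x, "voa_trajectory")) dim(x$coords)[3L]
  else if (inherits(x, "voa_frame")) 1L
  else stop("not a voa_frame or voa_trajectory")
}

#' @rdname frame
#' @param traj a `voa_trajectory`.
#' @param i frame number (1-based).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "voa_trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  frame(traj$labels, traj$coords[, , i, drop = TRUE], traj$mol, index = i)
}

#' @rdname frame
#' @param frames list of `voa_frame`s with identical topology.
#' @export
as_trajectory <- function(frames) {
  if (inherits(frames, "voa_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1L, all(vapply(frames, inherits, TRUE, "voa_frame")))
  f1 <- frames[[1L]]
  for (f in frames) {
    if (!identical(f$labels, f1$labels))
      stop("frames differ in atom labels; cannot stack")
  }
  trajectory(f1$labels, lapply(frames, `[[`, "xyz"), f1$mol)
}

#' Subset a trajectory by frame numbers
#' @param traj a `voa_trajectory`.
#' @param idx integer vector of frame numbers to keep (order preserved).
#' @export
subset_frames <- function(traj, idx) {
  stopifnot(inherits(traj, "voa_trajectory"))
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_frames(traj))) stop("frame index out of range")
  trajectory(traj$labels, traj$coords[, , idx, drop = FALSE], traj$mol)
}

#' @export
print.voa_frame <- function(x, ...) {
  cat(sprintf("<voa_frame> %d atoms, %d molecule(s), frame %d\n",
              n_atoms(x), length(unique(x$mol)), x$index))
  invisible(x)
}

#' @export
print.voa_trajectory <- function(x, ...) {
  cat(sprintf("<voa_trajectory> %d frames x %d atoms, %d molecule(s)\n",
              n_frames(x), n_atoms(x), length(unique(x$mol))))
  invisible(x)
}

# Validate ring bond lengths: inputs are assumed whole-molecule (no PBC
# unwrapping is attempted); a broken ring almost always means a wrapped
# molecule, so fail loudly.
check_ring_bonds <- function(fr, ring, max_bond = 3.0) {
  nb <- length(ring)
  for (j in seq_len(nb)) {
    a <- ring[j]; b <- ring[j %% nb + 1L]
    d <- sqrt(sum((fr$xyz[a, ] - fr$xyz[b, ])^2))
    if (d > max_bond)
      stop(sprintf(
        "ring bond %d-%d is %.2f Angstrom (> %.1f): molecule looks broken/wrapped",
        a, b, d, max_bond))
  }
  invisible(TRUE)
}
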