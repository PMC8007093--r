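#' Read a multi-model XYZ or PDB trajectory
#'
#' The XYZ dialect is the plain multi-model one: for each model an atom-count
#' line, a comment line, then `count` lines of `element x y z`.  PDB files
#' are read through \pkg{bio3d} (`MODEL`/`ENDMDL` records define frames);
#' molecule membership is taken from the chain id (falling back to residue
#' number) for PDB, and from the `mol` argument for XYZ.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; default guessed from the extension.
#' @param stride keep every `stride`-th model, starting at the first
#'   (stride 10 on 100 models gives 10 frames).
#' @param mol optional molecule id per atom (XYZ carries no topology).
#' @param max_extent warn when any frame's bounding box exceeds this many
#'   Angstrom: analyses here assume pre-wrapped, whole-molecule clusters,
#'   and a huge extent usually means an unwrapped periodic box.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb"),
                            stride = 1L, mol = NULL, max_extent = 100) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  traj <- switch(format, xyz = read_xyz(path, mol = mol),
                 pdb = read_pdb_traj(path))
  if (stride > 1L)
    traj <- subset_frames(traj, seq(1L, n_frames(traj), by = stride))
  ext <- max(apply(traj$coords, 2L, function(m) diff(range(m))))
  if (ext > max_extent)
    warning(sprintf(
      "frame bounding box spans %.0f Angstrom (> %.0f): coordinates look unwrapped",
      ext, max_extent))
  traj
}

#' @rdname read_trajectory
#' @export
read_xyz <- function(path, mol = NULL) {
  lines <- readLines(path)
  frames <- list()
  labels <- NULL
  i <- 1L
  n_total <- length(lines)
  model <- 0L
  while (i <= n_total) {
    if (!nzchar(trimws(lines[i])) && i == n_total) break
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop(sprintf("malformed atom-count line %d (after model %d)", i, model))
    if (i + 1L + nat > n_total)
      stop(sprintf("truncated file: model %d incomplete (last good model: %d)",
                   model + 1L, model))
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, 0L) < 4L)
    if (length(bad))
      stop(sprintf("malformed atom line %d", i + 1L + bad[1L]))
    lab <- vapply(toks, `[[`, "", 1L)
    xyz <- matrix(suppressWarnings(
      as.numeric(vapply(toks, function(t) t[2:4], character(3L)))),
      ncol = 3L, byrow = TRUE)
    if (any(is.na(xyz)))
      stop(sprintf("non-numeric coordinate in model %d", model + 1L))
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop(sprintf("inconsistent atom count in model %d", model + 1L))
    model <- model + 1L
    frames[[model]] <- xyz
    i <- i + 2L + nat
    while (i <= n_total && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (model == 0L) stop("no models found in ", path)
  if (is.null(mol)) mol <- rep(1L, length(labels))
  trajectory(labels, frames, mol)
}

read_pdb_traj <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB trajectories requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # n_frames x 3*n_atoms
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  nat <- ncol(xyz) / 3L
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE))
  ch <- pdb$atom$chain
  mol <- if (all(is.na(ch)) || length(unique(ch)) == 1L)
    pdb$atom$resno else as.integer(factor(ch))
  trajectory(pdb$atom$elesy, frames, mol)
}

#' Write frames as multi-model XYZ (and optionally PDB)
#'
#' @param x a [frame()], [trajectory()], or list of frames.
#' @param path output path.
#' @param comments comment line per model (recycled).
#' @param digits coordinate precision.
#' @export
write_xyz <- function(x, path, comments = NULL, digits = 6L) {
  frames <- if (inherits(x, "voa_trajectory"))
    lapply(seq_len(n_frames(x)), get_frame, traj = x)
  else if (inherits(x, "voa_frame")) list(x)
  else x
  if (is.null(comments)) comments <- sprintf("frame %d", seq_along(frames))
  comments <- rep_len(comments, length(frames))
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6L, digits, digits + 6L, digits, digits + 6L, digits)
  out <- unlist(lapply(seq_along(frames), function(k) {
    f <- frames[[k]]
    c(as.character(n_atoms(f)), comments[k],
      sprintf(fmt, f$labels, f$xyz[, 1L], f$xyz[, 2L], f$xyz[, 3L]))
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_pdb_frame <- function(x, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("writing PDB requires the 'bio3d' package")
  stopifnot(inherits(x, "voa_frame"))
  bio3d::write.pdb(file = path, xyz = as.vector(t(x$xyz)),
                   elesy = x$labels, resno = as.integer(factor(x$mol)),
                   chain = rep("A", n_atoms(x)))
  invisible(path)
}
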