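#' Geometric hydrogen-bond criteria
#'
#' Distance/angle criteria for a geometric hydrogen bond.  The angle is the
#' deviation from linearity in the trajectory-visualization convention: the
#' angle at the donor between the D->H and D->A vectors must be at most
#' `angle` degrees.  (A literal D-H-A angle cutoff below 30 degrees is
#' geometrically impossible for a 3 Angstrom contact; set
#' `convention = "dha"` to require the literal D-H-A angle itself to be
#' below the cutoff if you really want that.)  Both cutoffs are inclusive.
#'
#' @param distance maximum donor-acceptor distance, Angstrom (default 3.0).
#' @param angle maximum angular deviation, degrees (default 30).
#' @param convention `"deviation"` (default, angle between D->A and D->H) or
#'   `"dha"` (literal D-H-A angle below the cutoff).
#' @export
hbond_criteria <- function(distance = 3.0, angle = 30,
                           convention = c("deviation", "dha")) {
  convention <- match.arg(convention)
  if (distance <= 0) stop("distance cutoff must be > 0")
  if (angle <= 0 || angle > 180) stop("angle cutoff must be in (0, 180]")
  structure(list(distance = distance, angle = angle,
                 convention = convention), class = "hbond_criteria")
}

#' Declare donors (with attached hydrogens) and acceptors
#'
#' @param heavy 1-based atom indices of donor heavy atoms.
#' @param hydrogens list (parallel to `heavy`) of integer vectors of the
#'   bonded hydrogen indices of each donor.
#' @export
donor_set <- function(heavy, hydrogens) {
  heavy <- as.integer(heavy)
  if (!is.list(hydrogens)) hydrogens <- as.list(as.integer(hydrogens))
  if (length(heavy) != length(hydrogens))
    stop("one hydrogen list per donor heavy atom required")
  if (any(vapply(hydrogens, length, 0L) == 0L))
    stop("configuration error: donor declared without a bonded hydrogen")
  structure(list(heavy = heavy, hydrogens = lapply(hydrogens, as.integer)),
            class = "donor_set")
}

hbond_angle <- function(D, H, A, convention) {
  v1 <- A - D
  if (convention == "deviation") {
    v2 <- H - D
    acos(pmin(1, pmax(-1, sum(v1 * v2) /
                        sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  } else {
    u1 <- D - H; u2 <- A - H
    acos(pmin(1, pmax(-1, sum(u1 * u2) /
                        sqrt(sum(u1^2) * sum(u2^2))))) * 180 / pi
  }
}

#' Detect geometric hydrogen bonds in one frame
#'
#' A donor-H-acceptor triple is a hydrogen bond when the donor-acceptor
#' distance and the angular criterion of `criteria` are both satisfied
#' (inclusive cutoffs).  Records are ordered by (donor, acceptor, hydrogen)
#' index.
#'
#' @param fr a [frame()].
#' @param donors a [donor_set()].
#' @param acceptors integer vector of acceptor atom indices.
#' @param criteria an [hbond_criteria()].
#' @return data frame with columns `frame`, `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (one row per bond; zero rows when none).
#' @export
detect_hbonds <- function(fr, donors, acceptors,
                          criteria = hbond_criteria()) {
  stopifnot(inherits(fr, "voa_frame"), inherits(donors, "donor_set"),
            inherits(criteria, "hbond_criteria"))
  acceptors <- as.integer(acceptors)
  rec <- list()
  for (di in seq_along(donors$heavy)) {
    d <- donors$heavy[di]
    for (a in acceptors) {
      if (a == d) next
      dist <- sqrt(sum((fr$xyz[d, ] - fr$xyz[a, ])^2))
      if (dist > criteria$distance) next
      for (h in donors$hydrogens[[di]]) {
        ang <- hbond_angle(fr$xyz[d, ], fr$xyz[h, ], fr$xyz[a, ],
                           criteria$convention)
        if (ang <= criteria$angle)
          rec[[length(rec) + 1L]] <-
            data.frame(frame = fr$index, donor = d, hydrogen = h,
                       acceptor = a, distance = dist, angle = ang)
      }
    }
  }
  if (!length(rec))
    return(data.frame(frame = integer(), donor = integer(),
                      hydrogen = integer(), acceptor = integer(),
                      distance = numeric(), angle = numeric()))
  out <- do.call(rbind, rec)
  out[order(out$donor, out$acceptor, out$hydrogen), , drop = FALSE]
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Fraction of frames with at least one hydrogen bond per contact class,
#' plus the distribution of the number of simultaneous bonds.
#'
#' @param traj a [trajectory()].
#' @param donors a [donor_set()].
#' @param acceptors acceptor atom indices.
#' @param criteria an [hbond_criteria()].
#' @param group_by contact class definition: `"all"` (one class),
#'   `"donor"`, `"acceptor"`, or `"pair"` (donor-acceptor pair).
#' @return list with `occupancy` (named fractions in `[0,1]`) and
#'   `count_distribution` (per class, named vector over simultaneous-bond
#'   counts 0,1,2,... summing to 1).
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria(),
                            group_by = c("all", "donor", "acceptor", "pair")) {
  stopifnot(inherits(traj, "voa_trajectory"))
  group_by <- match.arg(group_by)
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectory")
  per_frame <- lapply(seq_len(nf), function(i)
    detect_hbonds(get_frame(traj, i), donors, acceptors, criteria))
  classify <- function(df) switch(group_by,
    all = rep("all", nrow(df)),
    donor = as.character(df$donor),
    acceptor = as.character(df$acceptor),
    pair = paste(df$donor, df$acceptor, sep = "-"))
  all_classes <- sort(unique(unlist(lapply(per_frame, function(df)
    unique(classify(df))))))
  if (!length(all_classes)) all_classes <- "all"
  counts <- sapply(all_classes, function(cl)
    vapply(per_frame, function(df) sum(classify(df) == cl), 0L))
  counts <- matrix(counts, nrow = nf,
                   dimnames = list(NULL, all_classes))
  occupancy <- colMeans(counts >= 1L)
  count_distribution <- lapply(all_classes, function(cl) {
    tab <- tabulate(counts[, cl] + 1L)
    stats::setNames(tab / nf, seq_along(tab) - 1L)
  })
  names(count_distribution) <- all_classes
  list(occupancy = occupancy, count_distribution = count_distribution)
}

#' Monomer/dimer association state per frame
#'
#' Labels each frame `dimer` when the minimum intermolecular donor-acceptor
#' distance between molecules `molA` and `molB` is at or below `threshold`
#' (inclusive), else `monomer`.  All declared donor-acceptor pairs are
#' considered by default.
#'
#' @param traj a [trajectory()].
#' @param molA,molB molecule ids.
#' @param donors a [donor_set()] (indices into the whole frame).
#' @param acceptors acceptor atom indices (whole frame).
#' @param threshold distance threshold, Angstrom (default 4.0).
#' @return data frame `frame`, `state` (`"monomer"`/`"dimer"`),
#'   `min_distance`; attribute `dimer_fraction`.
#' @export
assign_association_state <- function(traj, molA, molB, donors, acceptors,
                                     threshold = 4.0) {
  stopifnot(inherits(traj, "voa_trajectory"), inherits(donors, "donor_set"))
  if (!molA %in% traj$mol || !molB %in% traj$mol)
    stop("molecule id not present in trajectory")
  acceptors <- as.integer(acceptors)
  molof <- traj$mol
  pairs <- expand.grid(d = donors$heavy, a = acceptors)
  inter <- (molof[pairs$d] == molA & molof[pairs$a] == molB) |
           (molof[pairs$d] == molB & molof[pairs$a] == molA)
  pairs <- pairs[inter, , drop = FALSE]
  if (!nrow(pairs))
    stop("no intermolecular donor-acceptor pair between the two molecules")
  nf <- n_frames(traj)
  mind <- vapply(seq_len(nf), function(i) {
    xyz <- traj$coords[, , i]
    min(sqrt(rowSums((xyz[pairs$d, , drop = FALSE] -
                        xyz[pairs$a, , drop = FALSE])^2)))
  }, 0)
  state <- ifelse(mind <= threshold, "dimer", "monomer")
  out <- data.frame(frame = seq_len(nf), state = state, min_distance = mind)
  attr(out, "dimer_fraction") <- mean(state == "dimer")
  out
}

#' Extract a solute plus its solvation shell
#'
#' Keeps the solute molecule(s) and every whole solvent molecule with any
#' atom within `radius` (inclusive) of any solute atom; solvent molecules
#' are kept or dropped atomically, never split.
#'
#' @param fr a [frame()].
#' @param solute molecule id(s) of the solute.
#' @param radius shell radius, Angstrom.
#' @return a [frame()] with the original atom order restricted to the kept
#'   atoms.
#' @export
extract_shell <- function(fr, solute, radius) {
  stopifnot(inherits(fr, "voa_frame"))
  if (radius <= 0) stop("radius must be > 0")
  if (any(is.na(fr$mol))) stop("unknown molecule membership")
  is_solute <- fr$mol %in% solute
  if (!any(is_solute)) stop("solute molecule id not found")
  sx <- fr$xyz[is_solute, , drop = FALSE]
  keep_mol <- unique(fr$mol[is_solute])
  for (m in setdiff(unique(fr$mol), keep_mol)) {
    mi <- which(fr$mol == m)
    mx <- fr$xyz[mi, , drop = FALSE]
    d2 <- outer(rowSums(mx^2), rowSums(sx^2), `+`) - 2 * mx %*% t(sx)
    if (min(d2) <= radius^2 + 1e-12) keep_mol <- c(keep_mol, m)
  }
  keep <- fr$mol %in% keep_mol
  frame(fr$labels[keep], fr$xyz[keep, , drop = FALSE], fr$mol[keep],
        index = fr$index)
}
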