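#' Signed dihedral angle
#'
#' Signed torsion angle defined by four points, IUPAC sign convention:
#' looking down the `p2 -> p3` bond, a clockwise rotation of the far bond
#' relative to the near bond is positive.  Returned in degrees on
#' `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 length-3 numeric positions (Angstrom).
#' @return angle in degrees on `(-180, 180]`.
#' @examples
#' dihedral(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 0, -1))  # 180
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("undefined dihedral: zero-length bond vector")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined dihedral: collinear atoms")
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, sum(n1 * n2)) * 180 / pi
  wrap_deg(ang)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Wrap angles in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees.
#' @export
wrap_deg <- function(x) {
  y <- x - 360 * round(x / 360)
  y[y <= -180] <- y[y <= -180] + 360
  y[y > 180] <- y[y > 180] - 360
  y
}

#' Circular mean of angles in degrees
#'
#' atan2 of the mean sine and cosine.  When the mean resultant length is
#' below `tol` the direction is undefined and `NA` is returned.
#' @param x angles in degrees (`NA` dropped).
#' @param tol resultant-length tolerance below which the mean is undefined.
#' @export
circ_mean_deg <- function(x, tol = 1e-9) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  s <- mean(sin(r)); co <- mean(cos(r))
  if (sqrt(s^2 + co^2) < tol) return(NA_real_)
  wrap_deg(atan2(s, co) * 180 / pi)
}

#' Ring torsions of a five-membered ring
#'
#' The five endocyclic torsions `nu0..nu4` under the fixed convention:
#' `nu_j` is the dihedral about the bond between ring atoms `j+1` and `j+2`
#' (cyclic, 1-based ring positions), i.e. `nu0 = dihedral(r5, r1, r2, r3)`,
#' `nu1 = dihedral(r1, r2, r3, r4)`, and so on.  Relabelling the ring start
#' by one atom rotates the torsion list by one place.
#'
#' @param fr a [frame()].
#' @param ring integer vector of 5 distinct 1-based atom indices, in cyclic
#'   bonding order.
#' @return numeric length-5 vector `c(nu0, ..., nu4)` in degrees.
#' @export
ring_torsions <- function(fr, ring) {
  stopifnot(inherits(fr, "voa_frame"))
  ring <- as.integer(ring)
  if (length(ring) != 5L || anyDuplicated(ring))
    stop("`ring` must be 5 distinct atom indices")
  if (any(ring < 1L | ring > n_atoms(fr)))
    stop("ring atom index out of range")
  check_ring_bonds(fr, ring)
  at <- function(j) fr$xyz[ring[(j - 1L) %% 5L + 1L], ]
  vapply(0:4, function(j)
    dihedral(at(j), at(j + 1L), at(j + 2L), at(j + 3L)), 0)
}

# Two-torsion pseudorotation coefficients (Sato/Altona chain):
# Zx = (nu1 + nu3) / (2 cos 4pi/5),  Zy = (nu1 - nu3) / (2 sin 4pi/5),
# exact for nu_j = A cos(P + 4pi (j - 2) / 5).
.pseudo_cos <- 2 * cos(4 * pi / 5)
.pseudo_sin <- 2 * sin(4 * pi / 5)

#' Pseudorotation phase and amplitude from two ring torsions
#'
#' Maps the ring torsions `nu1`, `nu3` of a five-membered ring to the polar
#' pseudorotation coordinates: phase `P_theta` on `(-180, 180]` and
#' amplitude `A_r >= 0`, both in degrees.  `Z_x = (nu1 + nu3)/(2 cos 144deg)`
#' and `Z_y = (nu1 - nu3)/(2 sin 144deg)`; `P_theta = atan2(Z_y, Z_x)`,
#' `A_r = sqrt(Z_x^2 + Z_y^2)`.  For an ideal pseudorotating ring with
#' `nu_j = A cos(P + 144deg (j - 2))` this recovers `(P, A)` exactly.
#'
#' @param nu1,nu3 ring torsions in degrees (convention of [ring_torsions()]).
#' @param tol amplitude below which the phase is undefined (degrees).
#' @return list with `P_theta` (degrees, `NA` when undefined), `A_r`
#'   (degrees), `Z_x`, `Z_y`, and `phase_defined`.
#' @export
pseudorotation <- function(nu1, nu3, tol = 0.1) {
  if (!is.finite(nu1) || !is.finite(nu3)) stop("torsions must be finite")
  zx <- (nu1 + nu3) / .pseudo_cos
  zy <- (nu1 - nu3) / .pseudo_sin
  a <- sqrt(zx^2 + zy^2)
  defined <- a > tol
  p <- if (defined) wrap_deg(atan2(zy, zx) * 180 / pi) else NA_real_
  list(P_theta = p, A_r = a, Z_x = zx, Z_y = zy, phase_defined = defined)
}

#' @rdname pseudorotation
#' @param fr a [frame()].
#' @param ring 5 ring atom indices in cyclic order (see [ring_torsions()]).
#' @export
ring_pucker <- function(fr, ring, tol = 0.1) {
  nu <- ring_torsions(fr, ring)
  out <- pseudorotation(nu[2L], nu[4L], tol = tol)
  out$nu <- nu
  out
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Mean-plane construction of Cremer and Pople: ring positions are centred
#' on their centroid, the unit normal is built from the two Fourier sums
#' `R' = sum r_j sin(2 pi j / 6)` and `R'' = sum r_j cos(2 pi j / 6)`
#' (`j = 0..5` over the ring order given), and out-of-plane displacements
#' `z_j` are projections onto that normal.  Amplitudes and phase:
#' `q2 cos(phi) = sqrt(2/6) sum z_j cos(4 pi j / 6)`,
#' `q2 sin(phi) = -sqrt(2/6) sum z_j sin(4 pi j / 6)`,
#' `q3 = sqrt(1/6) sum (-1)^j z_j`, `Q = sqrt(sum z_j^2)`.
#'
#' @param fr a [frame()].
#' @param ring integer vector of 6 distinct 1-based atom indices in cyclic
#'   order (for an intermolecular pseudo-ring, the order that follows the
#'   hydrogen-bonded bridge).
#' @param tol `q2` amplitude (Angstrom) below which `phi` is undefined.
#' @param check_bonds validate ring closure distances (disable for
#'   pseudo-rings whose "bonds" include hydrogen-bond contacts longer than
#'   covalent bonds are allowed to be; the default limit of 4 Angstrom
#'   accommodates those).
#' @return list with `phi` (degrees on `(-180, 180]`, `NA` when undefined),
#'   `q2`, `q3`, `Q` (Angstrom), `z` (displacements), `phase_defined`.
#' @export
cremer_pople <- function(fr, ring, tol = 1e-4, check_bonds = TRUE) {
  stopifnot(inherits(fr, "voa_frame"))
  ring <- as.integer(ring)
  if (length(ring) != 6L || anyDuplicated(ring))
    stop("`ring` must be 6 distinct atom indices")
  if (any(ring < 1L | ring > n_atoms(fr)))
    stop("ring atom index out of range")
  if (check_bonds) check_ring_bonds(fr, ring, max_bond = 4.0)
  r <- fr$xyz[ring, , drop = FALSE]
  r <- sweep(r, 2L, colMeans(r))
  j <- 0:5
  rp <- colSums(r * sin(2 * pi * j / 6))
  rpp <- colSums(r * cos(2 * pi * j / 6))
  nrm <- cross3(rpp, rp)  # orientation: +z for a counterclockwise ring
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) stop("degenerate ring: atoms coincident or collinear")
  nrm <- nrm / nn
  z <- as.vector(r %*% nrm)
  c2 <- sqrt(2 / 6) * sum(z * cos(4 * pi * j / 6))
  s2 <- -sqrt(2 / 6) * sum(z * sin(4 * pi * j / 6))
  q2 <- sqrt(c2^2 + s2^2)
  q3 <- sqrt(1 / 6) * sum((-1)^j * z)
  Q <- sqrt(sum(z^2))
  defined <- q2 > tol
  phi <- if (defined) wrap_deg(atan2(s2, c2) * 180 / pi) else NA_real_
  list(phi = phi, q2 = q2, q3 = q3, Q = Q, z = z, phase_defined = defined)
}

#' Collective-variable time series over a trajectory
#'
#' Evaluates a list of collective variables (CVs) on every frame.  Each CV
#' spec is a list with `name`, `type` (one of `"torsion"`, `"pucker_phase"`
#' for the five-ring pseudorotation phase, `"cp_phase"` for the
#' Cremer-Pople phase of a six-ring), and `atoms` (1-based indices: 4 for a
#' torsion, 5 or 6 for the phases).  All CVs here are periodic with period
#' 360 degrees.  Degenerate values (undefined phase, degenerate dihedral)
#' are recorded as `NA` in that cell, never dropped.
#'
#' @param traj a [trajectory()].
#' @param cv_specs list of CV specs (see details).
#' @return a `voa_cvtable`: data frame with a `frame` column and one column
#'   per CV (degrees), with attributes `periodic` (logical per CV) and
#'   `cv_specs`.
#' @export
cv_timeseries <- function(traj, cv_specs) {
  stopifnot(inherits(traj, "voa_trajectory"))
  nf <- n_frames(traj)
  nat <- n_atoms(traj)
  for (cv in cv_specs) {
    if (is.null(cv$name) || is.null(cv$type) || is.null(cv$atoms))
      stop("each CV spec needs `name`, `type`, `atoms`")
    need <- switch(cv$type, torsion = 4L, pucker_phase = 5L, cp_phase = 6L,
                   stop("unknown CV type: ", cv$type))
    if (length(cv$atoms) != need || any(cv$atoms < 1L | cv$atoms > nat))
      stop(sprintf("CV '%s': needs %d valid atom indices (trajectory has %d atoms)",
                   cv$name, need, nat))
  }
  cols <- lapply(cv_specs, function(cv) {
    a <- as.integer(cv$atoms)
    vapply(seq_len(nf), function(i) {
      fr <- get_frame(traj, i)
      tryCatch(switch(cv$type,
        torsion = dihedral(fr$xyz[a[1L], ], fr$xyz[a[2L], ],
                           fr$xyz[a[3L], ], fr$xyz[a[4L], ]),
        pucker_phase = ring_pucker(fr, a)$P_theta,
        cp_phase = cremer_pople(fr, a, check_bonds = FALSE)$phi),
        error = function(e) NA_real_)
    }, 0)
  })
  names(cols) <- vapply(cv_specs, `[[`, "", "name")
  out <- data.frame(frame = seq_len(nf), cols, check.names = FALSE)
  attr(out, "periodic") <- rep(TRUE, length(cv_specs))
  attr(out, "cv_specs") <- cv_specs
  class(out) <- c("voa_cvtable", "data.frame")
  out
}

#' Write / read a CV table as CSV
#' @param cvs a `voa_cvtable` (or compatible data frame).
#' @param path CSV path; header `frame,cv1,cv2,...`, values in degrees.
#' @export
write_cv_csv <- function(cvs, path) {
  utils::write.csv(as.data.frame(cvs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  attr(out, "periodic") <- rep(TRUE, ncol(out) - 1L)
  class(out) <- c("voa_cvtable", "data.frame")
  out
}
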