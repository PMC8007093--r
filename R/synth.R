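#' Synthetic fixture generators with planted ground truth
#'
#' These generators stand in for molecular-dynamics and quantum-chemistry
#' outputs: five-membered rings built at a planted pseudorotation state,
#' hydrogen-bonded dimer frames with a planted pseudo-ring phase, von Mises
#' mixtures of periodic collective variables, solvated frames, and stick
#' spectra.  Every generator is deterministic for a given seed, and every
#' planted truth is recoverable by the corresponding analysis operation.
#'
#' @name synth
NULL

# Save/restore the global RNG state around seeded generation so that
# generators are deterministic per seed without clobbering the caller's
# stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler.  The von Mises distribution is the
#' canonical circular analogue of the normal: for large concentration
#' `kappa` the angular standard deviation approaches `1/sqrt(kappa)`
#' radians.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (`> 0`).
#' @return angles in degrees on `(-180, 180]`.
#' @export
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_deg(mu + out * 180 / pi)
}

# NeRF-style internal-coordinate placement: position X bonded to C with
# |X - C| = bond, angle(X, C, B) = angle_deg, dihedral(A, B, C, X) =
# torsion_deg (convention of dihedral()).
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ta <- torsion_deg * pi / 180
  u <- C - B; u <- u / sqrt(sum(u^2))
  n <- cross3(B - A, u)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate reference atoms for placement")
  n <- n / nn
  m <- cross3(n, u)
  C + bond * (-cos(th) * u + sin(th) * cos(ta) * m + sin(th) * sin(ta) * n)
}

# Measure (P_theta, A_r) of the 5 ring positions directly (fast path used
# inside the iterative builder; same math as ring_pucker()).
measure_ring5 <- function(xyz) {
  at <- function(j) xyz[(j - 1L) %% 5L + 1L, ]
  nu1 <- dihedral(at(1L), at(2L), at(3L), at(4L))
  nu3 <- dihedral(at(3L), at(4L), at(5L), at(6L))
  pseudorotation(nu1, nu3, tol = 0)
}

#' Build a five-membered ring at a planted pseudorotation state
#'
#' Constructs ring coordinates whose measured pseudorotation phase and
#' amplitude match the targets: an out-of-plane displacement ansatz
#' `z_j = q cos(offset + 4 pi j / 5)` on a regular pentagon, with the
#' in-plane radius rescaled each iteration to restore the mean bond length,
#' and `(q, offset)` adjusted until the measured `(P_theta, A_r)` from
#' [ring_pucker()] hit the targets (self-consistency loop).
#'
#' With `exocyclic = TRUE` the frame mimics an alpha-hydroxy lactone
#' skeleton: ring atoms 1-5 (1 = carbonyl carbon, 2 = carbinol carbon,
#' 5 = ring oxygen), atom 6 = hydroxyl oxygen on atom 2, atom 7 = hydroxyl
#' hydrogen (torsion 7-6-2-1 set by `oh_torsion`), atom 8 = carbonyl
#' oxygen on atom 1.
#'
#' @param P target pseudorotation phase, degrees.
#' @param A target torsional amplitude `A_r`, degrees (0 gives a planar
#'   ring; realizable up to roughly 60 degrees for typical bond lengths).
#' @param bond_length ring bond length, Angstrom.
#' @param oh_torsion hydroxyl torsion (atoms 7-6-2-1), degrees.
#' @param exocyclic add the OH / carbonyl probe atoms (default `TRUE`).
#' @param tol convergence tolerance on the phase (degrees) and relative
#'   amplitude.
#' @return a [frame()]; attribute `planted` records the targets.
#' @export
make_ring_geometry <- function(P, A, bond_length = 1.53, oh_torsion = 60,
                               exocyclic = TRUE, tol = 1e-6) {
  if (A < 0) stop("amplitude must be >= 0")
  theta <- 2 * pi * (0:4) / 5
  r0 <- bond_length / (2 * sin(pi / 5))
  build <- function(q, off, r) {
    z <- q * cos(off + 4 * pi * (0:4) / 5)
    xyz <- cbind(r * cos(theta), r * sin(theta), z)
    bl <- mean(sqrt(rowSums((xyz - xyz[c(2:5, 1L), ])^2)))
    list(xyz = xyz, mean_bond = bl)
  }
  if (A == 0) {
    ring <- build(0, 0, r0)$xyz
  } else {
    # linear response calibration: torsion amplitude ~ proportional to q
    q <- 0.01; off <- 0; r <- r0
    st <- build(q, off, r)
    m <- measure_ring5(st$xyz)
    q <- q * A / m$A_r
    conv <- FALSE
    for (it in 1:200) {
      st <- build(q, off, r)
      r <- r * bond_length / st$mean_bond
      st <- build(q, off, r)
      m <- measure_ring5(st$xyz)
      if (!is.finite(m$A_r) || m$A_r <= 0)
        stop("unrealizable amplitude for this bond length")
      dP <- wrap_deg(P - m$P_theta)
      dA <- A / m$A_r
      if (abs(dP) < tol && abs(dA - 1) < tol) { conv <- TRUE; break }
      off <- off + dP * pi / 180
      q <- q * dA
      if (q > 0.45 * bond_length)
        stop("unrealizable amplitude for this bond length")
    }
    if (!conv) stop("ring builder failed to converge; amplitude unrealizable?")
    ring <- st$xyz
  }
  if (!exocyclic) {
    fr <- frame(rep("C", 5L), ring, rep(1L, 5L))
    attr(fr, "planted") <- list(P = P, A = A)
    return(fr)
  }
  r1 <- ring[1L, ]; r2 <- ring[2L, ]; r3 <- ring[3L, ]; r5 <- ring[5L, ]
  o6 <- place_atom(r5, r1, r2, 1.42, 110, -120)
  h7 <- place_atom(r1, r2, o6, 0.96, 108, oh_torsion)
  v <- dihedral(r3, r2, r1, r5)
  o8 <- place_atom(r3, r2, r1, 1.23, 125, wrap_deg(v + 180))
  xyz <- rbind(ring, o6, h7, o8)
  fr <- frame(c("C", "C", "C", "C", "O", "O", "H", "O"), xyz, rep(1L, 8L))
  attr(fr, "planted") <- list(P = P, A = A, oh_torsion = oh_torsion)
  fr
}

#' Planted von Mises mixture state
#'
#' @param means named numeric vector: circular mean per CV, degrees.
#' @param kappa von Mises concentration (scalar or per CV).
#' @param weight mixture weight.
#' @export
planted_state <- function(means, kappa = 50, weight = 1) {
  if (any(kappa <= 0)) stop("kappa must be > 0")
  list(means = means, kappa = rep_len(kappa, length(means)), weight = weight)
}

#' Default six-state conformer mixture
#'
#' Two ring-pucker basins times three hydroxyl rotamers
#' (`P_theta` in (-157, 18), OH torsion in (81, -38, 149) degrees), with the
#' population weights of the water-solution conformer table
#' (0.474, 0.221, 0.100, 0.099, 0.080, 0.026) and concentration
#' `kappa = 50` per CV.
#' @param kappa von Mises concentration for every state.
#' @export
default_states_6 <- function(kappa = 50) {
  centers <- rbind(c(-157,  81), c(-157, -38), c(18, -38),
                   c(-157, 149), c(18,  81), c(18, 149))
  w <- c(0.474, 0.221, 0.100, 0.099, 0.080, 0.026)
  lapply(seq_len(6L), function(i)
    planted_state(c(P_theta = centers[i, 1L], oh_torsion = centers[i, 2L]),
                  kappa = kappa, weight = w[i]))
}

#' Sample a CV table from a planted von Mises mixture
#'
#' Draws per-frame CV vectors from the mixture without building geometry:
#' the fast path for clustering benchmarks.  Use [make_trajectory()] when
#' actual coordinates are needed.
#'
#' @param states list of [planted_state()]s (weights sum to 1).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return a `voa_cvtable` with a `truth` attribute: data frame of the
#'   generating state per frame and the drawn values.
#' @export
make_cv_table <- function(states, n_frames, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  w <- vapply(states, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-9) stop("state weights must sum to 1")
  cvnames <- names(states[[1L]]$means)
  with_seed(seed, {
    sid <- sample.int(length(states), n_frames, replace = TRUE, prob = w)
    vals <- matrix(NA_real_, n_frames, length(cvnames),
                   dimnames = list(NULL, cvnames))
    for (s in seq_along(states)) {
      idx <- which(sid == s)
      if (!length(idx)) next
      for (j in seq_along(cvnames))
        vals[idx, j] <- rvonmises_deg(length(idx),
                                      states[[s]]$means[j],
                                      states[[s]]$kappa[j])
    }
    out <- data.frame(frame = seq_len(n_frames), vals, check.names = FALSE)
    attr(out, "periodic") <- rep(TRUE, length(cvnames))
    attr(out, "truth") <- data.frame(frame = seq_len(n_frames), state = sid,
                                     vals, check.names = FALSE)
    class(out) <- c("voa_cvtable", "data.frame")
    out
  })
}

#' Synthetic trajectory from a planted conformer mixture
#'
#' Samples `(P_theta, OH torsion)` per frame from the von Mises mixture and
#' builds each frame with [make_ring_geometry()].  The truth table records
#' the generating state and the planted CV values per frame.
#'
#' @inheritParams make_cv_table
#' @param amplitude ring puckering amplitude `A_r` (degrees) used for every
#'   frame.
#' @param bond_length ring bond length, Angstrom.
#' @return list with `trajectory` (a [trajectory()]) and `truth`.
#' @export
make_trajectory <- function(states, n_frames, seed = 1L, amplitude = 40,
                            bond_length = 1.53) {
  cvs <- make_cv_table(states, n_frames, seed)
  truth <- attr(cvs, "truth")
  frames <- lapply(seq_len(n_frames), function(i)
    make_ring_geometry(P = cvs$P_theta[i], A = amplitude,
                       oh_torsion = cvs$oh_torsion[i],
                       bond_length = bond_length, tol = 1e-4))
  list(trajectory = as_trajectory(frames), truth = truth)
}

# Kabsch superposition: rotation + translation mapping rows of Q onto P
# (both m x 3) in the least-squares sense; returns function(xyz).
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2L, cq)) %*% sweep(P, 2L, cp)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  function(xyz) sweep(sweep(xyz, 2L, cq) %*% t(R), 2L, cp, `+`)
}

rot_mat <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Rz %*% Ry %*% Rx
}

#' Build a hydrogen-bonded dimer frame with a planted pseudo-ring phase
#'
#' Two five-ring monomers (from [make_ring_geometry()]) are docked so that
#' the two intermolecular O-H...O=C bridges close a six-atom pseudo-ring
#' (hydroxyl O, carbonyl C, carbonyl O of molecule A; then of molecule B)
#' whose Cremer-Pople phase matches `phi`, and both donor-acceptor (O...O)
#' distances equal `hbond_distance`.  A target hexagon is constructed
#' first (cyclic polygon with the molecular triangle side lengths and a
#' cosine out-of-plane pattern), the monomers are Kabsch-fitted onto it,
#' and molecule B's rigid placement is refined numerically against the
#' measured phase and distances.  Hydroxyl hydrogens are re-pointed along
#' the donor-acceptor axis.  Monomer pucker phases are untouched by the
#' rigid docking.
#'
#' @param P_A,P_B pseudorotation phase of each monomer, degrees.
#' @param phi target Cremer-Pople phase of the pseudo-ring, degrees.
#' @param hbond_distance donor-acceptor O...O distance, Angstrom.
#' @param amplitude monomer puckering amplitude, degrees.
#' @param oh_torsion_A,oh_torsion_B initial hydroxyl torsions (overwritten
#'   by the H re-pointing).
#' @param pucker_amp out-of-plane amplitude of the pseudo-ring hexagon,
#'   Angstrom.
#' @return a 16-atom [frame()] (molecule ids 1 and 2; atoms 9-16 mirror
#'   1-8).  Attributes: `planted` (targets), `pseudo_ring` (the six global
#'   indices 6, 1, 8, 14, 9, 16), `measured` (achieved values).
#' @export
make_dimer_frame <- function(P_A, P_B, phi, hbond_distance = 2.8,
                             amplitude = 40, oh_torsion_A = 60,
                             oh_torsion_B = 60, pucker_amp = 0.35) {
  if (hbond_distance < 2.2 || hbond_distance > 4.5)
    stop("infeasible hbond_distance")
  molA <- make_ring_geometry(P_A, amplitude, oh_torsion = oh_torsion_A)
  molB <- make_ring_geometry(P_B, amplitude, oh_torsion = oh_torsion_B)
  triA <- molA$xyz[c(6L, 1L, 8L), ]    # hydroxyl O, carbonyl C, carbonyl O
  triB <- molB$xyz[c(6L, 1L, 8L), ]
  d61 <- sqrt(sum((triA[1L, ] - triA[2L, ])^2))
  d18 <- sqrt(sum((triA[2L, ] - triA[3L, ])^2))
  sides <- c(d61, d18, hbond_distance, d61, d18, hbond_distance)
  # cyclic hexagon with those side lengths
  fR <- function(R) sum(2 * asin(pmin(1, sides / (2 * R)))) - 2 * pi
  R <- stats::uniroot(fR, c(max(sides) / 2 + 1e-9, 50))$root
  ang <- cumsum(c(0, 2 * asin(sides / (2 * R))))[1:6]
  hex0 <- cbind(R * cos(ang), R * sin(ang), 0)
  # choose the out-of-plane offset whose measured phase is closest to phi
  best <- NULL
  for (off in seq(0, 355, by = 5)) {
    z <- pucker_amp * cos(off * pi / 180 + 4 * pi * (0:5) / 6)
    hx <- hex0; hx[, 3L] <- z
    ph <- cremer_pople(frame(rep("X", 6L), hx), 1:6,
                       check_bonds = FALSE)$phi
    err <- abs(wrap_deg(ph - phi))
    if (is.null(best) || err < best$err) best <- list(hex = hx, err = err)
  }
  hex <- best$hex
  # superpose monomers onto their hexagon slots
  fitA <- kabsch_fit(hex[1:3, ], triA)
  xyzA <- fitA(molA$xyz)
  fitB <- kabsch_fit(hex[4:6, ], triB)
  xyzB0 <- fitB(molB$xyz)
  ring_idx <- c(6L, 1L, 8L, 14L, 9L, 16L)
  measure <- function(xyzB) {
    xyz <- rbind(xyzA, xyzB)
    ph <- cremer_pople(frame(rep("X", 16L), xyz), ring_idx,
                       check_bonds = FALSE)$phi
    d1 <- sqrt(sum((xyzA[8L, ] - xyzB[6L, ])^2))   # O8(A)...O6(B)
    d2 <- sqrt(sum((xyzB[8L, ] - xyzA[6L, ])^2))   # O8(B)...O6(A)
    list(phi = ph, d1 = d1, d2 = d2, xyz = xyz)
  }
  cB <- colMeans(xyzB0)
  objective <- function(par) {
    Rm <- rot_mat(par[1L], par[2L], par[3L])
    xyzB <- sweep(sweep(xyzB0, 2L, cB) %*% t(Rm), 2L, cB + par[4:6], `+`)
    m <- tryCatch(measure(xyzB), error = function(e) NULL)
    if (is.null(m) || is.na(m$phi)) return(1e6)
    pen <- (m$d1 - hbond_distance)^2 + (m$d2 - hbond_distance)^2 +
      (wrap_deg(m$phi - phi) / 60)^2
    # steric: keep non-bridge intermolecular atom pairs apart
    dmin <- 1.8
    for (i in 1:8) for (j in 1:8) {
      dd <- sqrt(sum((xyzA[i, ] - xyzB[j, ])^2))
      if (dd < dmin) pen <- pen + (dmin - dd)^2
    }
    pen
  }
  opt <- stats::optim(rep(0, 6), objective, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  opt <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  Rm <- rot_mat(opt$par[1L], opt$par[2L], opt$par[3L])
  xyzB <- sweep(sweep(xyzB0, 2L, cB) %*% t(Rm), 2L, cB + opt$par[4:6], `+`)
  # re-point hydroxyl hydrogens along the donor-acceptor axes
  uA <- xyzB[8L, ] - xyzA[6L, ]; uA <- uA / sqrt(sum(uA^2))
  xyzA[7L, ] <- xyzA[6L, ] + 0.96 * uA
  uB <- xyzA[8L, ] - xyzB[6L, ]; uB <- uB / sqrt(sum(uB^2))
  xyzB[7L, ] <- xyzB[6L, ] + 0.96 * uB
  m <- measure(xyzB)
  if (abs(wrap_deg(m$phi - phi)) > 2 ||
      abs(m$d1 - hbond_distance) > 0.05 ||
      abs(m$d2 - hbond_distance) > 0.05)
    stop(sprintf(paste0("dimer construction did not reach targets ",
                        "(phi %.1f vs %.1f; d %.3f/%.3f vs %.3f): ",
                        "geometrically inconsistent inputs?"),
                 m$phi, phi, m$d1, m$d2, hbond_distance))
  fr <- frame(rep(c("C", "C", "C", "C", "O", "O", "H", "O"), 2L), m$xyz,
              rep(1:2, each = 8L))
  attr(fr, "planted") <- list(P_A = P_A, P_B = P_B, phi = phi,
                              hbond_distance = hbond_distance)
  attr(fr, "pseudo_ring") <- ring_idx
  attr(fr, "measured") <- list(phi = m$phi, d1 = m$d1, d2 = m$d2)
  fr
}

#' Synthetic stick spectra
#'
#' `kind = "monomer"` draws `n_modes` random modes in `region` with
#' nonnegative IR/Raman and signed VCD/ROA intensities; `"random"` is an
#' alias.  `kind = "dimer-couplet"` produces the bisignate carbonyl pair of
#' a coupled-oscillator dimer: two modes at `center +/- splitting/2` with
#' VCD intensities `+couplet_sign * vcd_intensity` (lower component) and
#' the opposite sign (upper), both carrying `ir_intensity/2` in IR.
#'
#' @param kind `"monomer"`, `"dimer-couplet"`, or `"random"`.
#' @param seed RNG seed (used by the random kinds).
#' @param n_modes number of modes for the random kinds.
#' @param region wavenumber range, cm^-1.
#' @param center couplet centre, cm^-1.
#' @param splitting couplet splitting, cm^-1 (0 gives a degenerate pair
#'   whose VCD cancels on broadening).
#' @param vcd_intensity,ir_intensity couplet intensities.
#' @param couplet_sign `+1` (default: negative lobe at the upper component)
#'   or `-1`.
#' @param structure_id,energy passed to [stick_spectrum()].
#' @return a [stick_spectrum()].
#' @export
make_stick_spectrum <- function(kind = c("monomer", "dimer-couplet", "random"),
                                seed = 1L, n_modes = 25L,
                                region = c(200, 1800), center = 1760,
                                splitting = 20, vcd_intensity = 100,
                                ir_intensity = 200, couplet_sign = 1,
                                structure_id = NULL, energy = NA_real_) {
  kind <- match.arg(kind)
  if (kind == "dimer-couplet") {
    wn <- c(center - splitting / 2, center + splitting / 2)
    if (is.null(structure_id)) structure_id <- "dimer_couplet"
    return(stick_spectrum(wavenumber = wn,
                          ir = rep(ir_intensity / 2, 2L),
                          vcd = c(couplet_sign * vcd_intensity,
                                  -couplet_sign * vcd_intensity),
                          structure_id = structure_id, energy = energy))
  }
  if (is.null(structure_id)) structure_id <- paste0(kind, "_", seed)
  with_seed(seed, {
    wn <- sort(stats::runif(n_modes, region[1L], region[2L]))
    stick_spectrum(wavenumber = wn,
                   ir = abs(stats::rnorm(n_modes, 0, 50)),
                   vcd = stats::rnorm(n_modes, 0, 30),
                   raman = abs(stats::rnorm(n_modes, 0, 50)),
                   roa = stats::rnorm(n_modes, 0, 30),
                   structure_id = structure_id, energy = energy)
  })
}

water_geometry <- function(o_pos, toward) {
  u <- toward - o_pos
  nu <- sqrt(sum(u^2))
  u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
  # arbitrary perpendicular
  p <- cross3(u, if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  p <- p / sqrt(sum(p^2))
  h1 <- o_pos + 0.9572 * u
  ang <- (104.52 - 0) * pi / 180
  h2 <- o_pos + 0.9572 * (cos(ang) * u + sin(ang) * p)
  rbind(o_pos, h1, h2)
}

#' Solvate a frame with synthetic water
#'
#' Packs rigid water molecules around the solute at a target number
#' density: candidate oxygen positions are drawn uniformly in a sphere of
#' radius `r_max` around the solute centroid and accepted when at least
#' `r_contact` from every solute atom and 2.6 Angstrom from every accepted
#' water oxygen.  At liquid-water density (0.0334 molecules per cubic
#' Angstrom) a 4 Angstrom shell around a small cyclic solute holds of the
#' order of ten waters.
#'
#' @param solute a [frame()].
#' @param r_max outer packing radius from the solute centroid, Angstrom.
#' @param density target number density, waters per cubic Angstrom.
#' @param r_contact minimum water-O to solute-atom distance, Angstrom.
#' @param seed RNG seed.
#' @return a [frame()]: solute (molecule ids preserved) plus waters with
#'   fresh molecule ids.
#' @export
make_solvated_frame <- function(solute, r_max = 8, density = 0.0334,
                                r_contact = 2.8, seed = 1L) {
  stopifnot(inherits(solute, "voa_frame"))
  cen <- colMeans(solute$xyz)
  vol <- 4 / 3 * pi * r_max^3
  with_seed(seed, {
    # One pass over bulk-density candidates; rejected candidates are not
    # retried, so the accepted set approximates uniform bulk density in
    # the sterically allowed region (as in a snapshot of a liquid box).
    n_cand <- round(density * vol)
    accepted <- matrix(numeric(0), 0L, 3L)
    for (t in seq_len(n_cand)) {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      pos <- cen + stats::runif(1)^(1 / 3) * r_max * v
      dsol <- min(sqrt(rowSums(sweep(solute$xyz, 2L, pos)^2)))
      if (dsol < r_contact) next
      if (nrow(accepted) &&
          min(sqrt(rowSums(sweep(accepted, 2L, pos)^2))) < 2.6) next
      accepted <- rbind(accepted, pos)
    }
    if (!nrow(accepted)) return(solute)
    wat <- do.call(rbind, lapply(seq_len(nrow(accepted)), function(i)
      water_geometry(accepted[i, ], accepted[i, ] + stats::rnorm(3))))
    labels <- c(solute$labels, rep(c("O", "H", "H"), nrow(accepted)))
    mol0 <- max(as.integer(factor(solute$mol)))
    mol <- c(as.integer(factor(solute$mol)),
             rep(mol0 + seq_len(nrow(accepted)), each = 3L))
    frame(labels, rbind(solute$xyz, wat), mol, index = solute$index)
  })
}

#' Trajectory with a planted solute-water contact probability
#'
#' Minimal solvated fixture for occupancy statistics: each frame carries
#' one water that sits at a perfect hydrogen-bond geometry to the given
#' acceptor atom with probability `p`, and far away otherwise.
#'
#' @param solute a [frame()].
#' @param acceptor 1-based solute atom index acting as acceptor of the
#'   water donor.
#' @param p planted contact probability.
#' @param n_frames number of frames.
#' @param distance donor-acceptor distance of the planted contact.
#' @param seed RNG seed.
#' @return list: `trajectory` (solute + one water per frame; water oxygen
#'   is atom `n_atoms(solute) + 1`), `contacts` (logical truth per frame).
#' @export
make_contact_trajectory <- function(solute, acceptor, p = 0.75,
                                    n_frames = 500L, distance = 2.8,
                                    seed = 1L) {
  stopifnot(inherits(solute, "voa_frame"))
  cen <- colMeans(solute$xyz)
  acc <- solute$xyz[acceptor, ]
  u <- acc - cen; u <- u / sqrt(sum(u^2))
  with_seed(seed, {
    contact <- stats::runif(n_frames) < p
    frames <- lapply(seq_len(n_frames), function(i) {
      o_pos <- acc + (if (contact[i]) distance else 8 + stats::runif(1, 0, 2)) * u
      # water oxygen donates toward the acceptor: H on the O->acceptor axis
      w <- water_geometry(o_pos, acc)
      frame(c(solute$labels, "O", "H", "H"), rbind(solute$xyz, w),
            c(as.integer(factor(solute$mol)),
              rep(max(as.integer(factor(solute$mol))) + 1L, 3L)), index = i)
    })
    list(trajectory = as_trajectory(frames), contacts = contact)
  })
}
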