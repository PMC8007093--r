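test_that("dihedral reproduces the textbook planar cases and sign convention", {
  expect_equal(dihedral(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 0, -1)), 180)
  ortho <- dihedral(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(abs(ortho), 90)
  # IUPAC clockwise-positive looking 2 -> 3: this rotation (up to screen
  # left) is counterclockwise, hence negative
  expect_equal(ortho, -90)
  # chain reversal leaves the angle unchanged
  expect_equal(dihedral(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), c(0, 0, 1)), ortho)
})

test_that("dihedral agrees with an independent atan2 oracle on random geometry", {
  set.seed(101)
  got <- ref <- numeric(200)
  for (i in 1:200) {
    p <- matrix(rnorm(12, sd = 2), 4)
    ref[i] <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    got[i] <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  }
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("degenerate dihedral geometry raises an explicit error", {
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "zero-length")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("ring torsions vanish on a planar pentagon and rotate under relabeling", {
  th <- 2 * pi * (0:4) / 5
  flat <- frame(rep("C", 5), cbind(1.3 * cos(th), 1.3 * sin(th), 0))
  expect_equal(ring_torsions(flat, 1:5), rep(0, 5), tolerance = 1e-10)

  f <- make_ring_geometry(P = 30, A = 40, exocyclic = FALSE)
  nu <- ring_torsions(f, 1:5)
  nu_shift <- ring_torsions(f, c(2:5, 1))
  expect_equal(nu_shift, nu[c(2:5, 1)], tolerance = 1e-9)
})

test_that("pseudorotation handles the planar ring and the enantiomer map", {
  planar <- pseudorotation(0, 0)
  expect_equal(planar$A_r, 0)
  expect_true(is.na(planar$P_theta))
  expect_false(planar$phase_defined)

  p <- pseudorotation(35, -12)
  q <- pseudorotation(-35, 12)      # all torsions negated
  expect_equal(q$A_r, p$A_r)
  expect_equal(wrap_deg(q$P_theta - p$P_theta - 180), 0, tolerance = 1e-9)
})

test_that("planted pseudorotation states are recovered across the phase circle", {
  for (P in seq(-165, 180, by = 15)) {
    for (A in c(25, 40, 50)) {
      f <- make_ring_geometry(P = P, A = A, exocyclic = FALSE)
      m <- ring_pucker(f, 1:5)
      expect_lt(abs(wrap_deg(m$P_theta - P)), 1)
      expect_lt(abs(m$A_r - A) / A, 1e-3)
    }
  }
})

test_that("pucker amplitude is invariant under rigid motion, relabeling, and mirrors", {
  set.seed(7)
  f <- make_ring_geometry(P = -64, A = 40, exocyclic = FALSE)
  m0 <- ring_pucker(f, 1:5)

  R <- random_rotation()
  g <- frame(f$labels, sweep(f$xyz %*% t(R), 2, c(3.2, -1, 8), `+`))
  m1 <- ring_pucker(g, 1:5)
  expect_equal(m1$A_r, m0$A_r, tolerance = 1e-9)
  expect_equal(wrap_deg(m1$P_theta - m0$P_theta), 0, tolerance = 1e-8)

  # cyclic relabeling at the torsion level: for an ideal cosine torsion
  # pattern nu_j = A cos(P + 144 (j - 2)) the (nu1, nu3) pair of the
  # shifted labelling is the (nu2, nu4) pair of the original, and the
  # recovered state is exactly (P + 144, A).
  A <- 40; P <- -64
  nu <- A * cos((P + 144 * ((0:4) - 2)) * pi / 180)
  s0 <- pseudorotation(nu[2], nu[4])
  nus <- nu[c(2:5, 1)]
  s1 <- pseudorotation(nus[2], nus[4])
  expect_equal(s1$A_r, s0$A_r, tolerance = 1e-12)
  expect_equal(wrap_deg(s1$P_theta - s0$P_theta - 144), 0, tolerance = 1e-9)

  # on a built (slightly non-ideal) ring the same holds to within the
  # geometric non-ideality of the torsion pattern
  m2 <- ring_pucker(frame(f$labels, f$xyz), c(2:5, 1))
  expect_equal(m2$A_r, m0$A_r, tolerance = 0.05)
  shift <- wrap_deg(m2$P_theta - m0$P_theta)
  mult <- wrap_deg(shift - 144 * round(shift / 144))
  expect_lt(abs(mult), 2)

  # mirror along one axis: amplitude invariant, phase shifted by 180
  h <- frame(f$labels, f$xyz %*% diag(c(1, 1, -1)))
  m3 <- ring_pucker(h, 1:5)
  expect_equal(m3$A_r, m0$A_r, tolerance = 1e-9)
  expect_equal(wrap_deg(m3$P_theta - m0$P_theta - 180), 0, tolerance = 1e-8)
})

test_that("Cremer-Pople coordinates classify the planar, chair and phase-planted hexagons", {
  j <- 0:5
  th <- 2 * pi * j / 6
  planar <- frame(rep("C", 6), cbind(1.45 * cos(th), 1.45 * sin(th), 0))
  mp <- cremer_pople(planar, 1:6)
  expect_equal(mp$q2, 0, tolerance = 1e-12)
  expect_equal(mp$q3, 0, tolerance = 1e-12)
  expect_true(is.na(mp$phi))

  chair <- frame(rep("C", 6),
                 cbind(1.45 * cos(th), 1.45 * sin(th), 0.25 * (-1)^j))
  mc <- cremer_pople(chair, 1:6)
  expect_equal(mc$q2, 0, tolerance = 1e-10)
  expect_gt(mc$q3, 0)
  expect_equal(mc$Q^2, mc$q2^2 + mc$q3^2, tolerance = 1e-12)

  for (phi0 in c(0, -64, 90)) {
    z <- 0.3 * cos(4 * pi * j / 6 + phi0 * pi / 180)
    hx <- frame(rep("C", 6), cbind(1.45 * cos(th), 1.45 * sin(th), z))
    m <- cremer_pople(hx, 1:6)
    expect_lt(abs(wrap_deg(m$phi - phi0)), 0.5)
  }

  degen <- frame(rep("C", 6), matrix(rep(c(0, 0, 0), 6), ncol = 3,
                                     byrow = TRUE))
  expect_error(cremer_pople(degen, 1:6, check_bonds = FALSE), "degenerate")
})

test_that("Cremer-Pople amplitudes are invariant under rigid motion", {
  set.seed(11)
  j <- 0:5; th <- 2 * pi * j / 6
  z <- 0.3 * cos(4 * pi * j / 6 + 1.1) + 0.15 * (-1)^j
  hx <- cbind(1.45 * cos(th), 1.45 * sin(th), z)
  m0 <- cremer_pople(frame(rep("C", 6), hx), 1:6)
  R <- random_rotation()
  m1 <- cremer_pople(frame(rep("C", 6),
                           sweep(hx %*% t(R), 2, c(-4, 2, 1), `+`)), 1:6)
  expect_equal(m1$q2, m0$q2, tolerance = 1e-9)
  expect_equal(m1$q3, m0$q3, tolerance = 1e-9)
  expect_equal(wrap_deg(m1$phi - m0$phi), 0, tolerance = 1e-8)
})

test_that("cv_timeseries evaluates torsion and phase CVs per frame and flags NAs", {
  tr <- make_trajectory(default_states_6(), n_frames = 60, seed = 5)
  specs <- list(
    list(name = "P_theta", type = "pucker_phase", atoms = 1:5),
    list(name = "oh_torsion", type = "torsion", atoms = c(7, 6, 2, 1)))
  cvs <- cv_timeseries(tr$trajectory, specs)
  expect_s3_class(cvs, "voa_cvtable")
  expect_equal(nrow(cvs), 60)
  expect_equal(max(abs(wrap_deg(cvs$P_theta - tr$truth$P_theta))), 0,
               tolerance = 0.01)
  expect_equal(max(abs(wrap_deg(cvs$oh_torsion - tr$truth$oh_torsion))), 0,
               tolerance = 1e-8)

  # static trajectory -> constant columns
  f <- test_ring_frame()
  st <- as_trajectory(list(f, f, f))
  cvs2 <- cv_timeseries(st, specs)
  expect_equal(length(unique(cvs2$P_theta)), 1L)

  # planar ring: pucker phase undefined -> NA flagged, not dropped
  th <- 2 * pi * (0:4) / 5
  flat <- frame(rep("C", 5), cbind(1.3 * cos(th), 1.3 * sin(th), 0))
  flat_tr <- as_trajectory(list(flat))
  cvs3 <- cv_timeseries(flat_tr, list(
    list(name = "P", type = "pucker_phase", atoms = 1:5)))
  expect_equal(nrow(cvs3), 1L)
  expect_true(is.na(cvs3$P))

  expect_error(
    cv_timeseries(st, list(list(name = "bad", type = "torsion",
                                atoms = c(1, 2, 3, 99)))),
    "bad")
})

test_that("dimer CV table carries both monomer phases and the pseudo-ring phase", {
  d <- make_dimer_frame(-157, 20, -64, 2.8)
  tr <- as_trajectory(list(d))
  ring <- attr(d, "pseudo_ring")
  cvs <- cv_timeseries(tr, list(
    list(name = "P_thetaA", type = "pucker_phase", atoms = 1:5),
    list(name = "P_thetaB", type = "pucker_phase", atoms = 9:13),
    list(name = "phi", type = "cp_phase", atoms = ring)))
  expect_named(cvs, c("frame", "P_thetaA", "P_thetaB", "phi"))
  expect_lt(abs(wrap_deg(cvs$P_thetaA + 157)), 2)
  expect_lt(abs(wrap_deg(cvs$P_thetaB - 20)), 2)
  expect_lt(abs(wrap_deg(cvs$phi + 64)), 2)
})

test_that("bio3d torsions agree with the package dihedral on a shared frame", {
  skip_if_not_installed("bio3d")
  f <- test_ring_frame()
  ref <- bio3d::torsion.xyz(as.vector(t(f$xyz[c(7, 6, 2, 1), ])), atm.inc = 4)
  expect_equal(abs(dihedral(f$xyz[7, ], f$xyz[6, ], f$xyz[2, ], f$xyz[1, ])),
               abs(as.numeric(ref)), tolerance = 1e-6)
})
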