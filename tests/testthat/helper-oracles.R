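# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Dihedral via atan2 of cross/dot products, written independently of
# voamd::dihedral (different formulation: projection onto the plane
# normal to the central bond).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Exhaustive all-triples H-bond search (brute force over every
# donor/hydrogen/acceptor combination, scalar arithmetic only).
oracle_hbonds <- function(fr, heavy, hydrogens, acceptors,
                          dmax = 3.0, amax = 30) {
  hits <- NULL
  for (di in seq_along(heavy)) {
    for (h in hydrogens[[di]]) {
      for (a in acceptors) {
        if (a == heavy[di]) next
        D <- fr$xyz[heavy[di], ]; H <- fr$xyz[h, ]; A <- fr$xyz[a, ]
        dist <- sqrt(sum((D - A)^2))
        v1 <- A - D; v2 <- H - D
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (dist <= dmax && ang <= amax)
          hits <- rbind(hits, c(heavy[di], h, a))
      }
    }
  }
  hits
}

# Random rigid rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# A small rigid test frame: solute ring with probe atoms plus one water.
test_ring_frame <- function(P = -157, A = 40, oh = 81)
  make_ring_geometry(P = P, A = A, oh_torsion = oh)
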