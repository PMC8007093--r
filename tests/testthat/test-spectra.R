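test_that("a single stick broadens to a unit-area Lorentzian of the right height", {
  s <- stick_spectrum(1000, ir = 1)
  b <- broaden(s, bandwidth = 6, grid = wavenumber_grid(400, 1600))
  expect_equal(max(b$intensities$ir), 2 / (6 * pi), tolerance = 1e-3)
  expect_equal(b$wavenumber[which.max(b$intensities$ir)], 1000)
  # numerical integral over a +/- 600 cm-1 window within 0.5% of stick sum
  expect_equal(integrate_spectrum(b, "ir"), 1, tolerance = 5e-3)
})

test_that("wavenumber scaling moves peaks, never intensities", {
  s <- stick_spectrum(1000, ir = 2)
  b <- broaden(s, bandwidth = 6, scale = 0.98,
               grid = wavenumber_grid(300, 1600))
  expect_equal(b$wavenumber[which.max(b$intensities$ir)], 980)
  expect_equal(integrate_spectrum(b, "ir"), 2, tolerance = 1e-2)
  # region-dependent factors: mid-IR vs OH-stretch regions
  regions <- data.frame(from = c(0, 2500), to = c(2500, 4000),
                        factor = c(0.985, 0.96))
  expect_equal(scale_wavenumbers(c(1000, 3600), regions),
               c(985, 3456))
})

test_that("broadening errors on clipped modes and warns on thin margins", {
  s <- stick_spectrum(c(500, 1500), ir = c(1, 1))
  expect_error(broaden(s, grid = wavenumber_grid(600, 1600)), "cover")
  expect_warning(broaden(s, grid = wavenumber_grid(450, 1600)), "margin")
  expect_error(broaden(s, bandwidth = -1), "bandwidth")
})

test_that("broadening is linear and conserves integrated intensity", {
  g <- wavenumber_grid(200, 2400)
  s1 <- make_stick_spectrum("random", seed = 4, region = c(900, 1700))
  s2 <- make_stick_spectrum("random", seed = 5, region = c(900, 1700))
  b1 <- broaden(s1, grid = g); b2 <- broaden(s2, grid = g)
  comb <- stick_spectrum(c(s1$wavenumber, s2$wavenumber),
                         ir = c(2 * s1$intensities$ir, 3 * s2$intensities$ir),
                         vcd = c(2 * s1$intensities$vcd, 3 * s2$intensities$vcd))
  bc <- broaden(comb, grid = g)
  expect_equal(bc$intensities$ir, 2 * b1$intensities$ir + 3 * b2$intensities$ir,
               tolerance = 1e-12)
  expect_equal(bc$intensities$vcd,
               2 * b1$intensities$vcd + 3 * b2$intensities$vcd,
               tolerance = 1e-12)
  expect_equal(integrate_spectrum(b1, "ir"), sum(s1$intensities$ir),
               tolerance = 5e-3)
})

test_that("Boltzmann weights reproduce the closed forms and stay stable", {
  expect_equal(boltzmann_weights(rep(3.2, 5)), rep(0.2, 5))
  # Delta E = RT ln 2 -> 2/3, 1/3
  kB <- 0.001987204259
  dE <- kB * 300 * log(2)
  expect_equal(boltzmann_weights(c(0, dE), 300), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  w <- boltzmann_weights(c(0, 50), 300)
  expect_lt(w[2], 1e-30)
  expect_equal(sum(w), 1)
  expect_error(boltzmann_weights(numeric(0)), "at least one")
  expect_error(boltzmann_weights(1, temperature = -10), "temperature")
})

test_that("weighted averaging is the identity at weight 1 and cancels opposites", {
  g <- wavenumber_grid(800, 1200)
  s <- broaden(make_stick_spectrum("dimer-couplet", center = 1000), grid = g)
  expect_equal(weighted_average(list(s), 1)$intensities$vcd,
               s$intensities$vcd)
  neg <- composite_spectrum(g, lapply(s$intensities, function(y) -y))
  avg <- weighted_average(list(s, neg), c(0.5, 0.5))
  expect_equal(max(abs(avg$intensities$vcd)), 0, tolerance = 1e-12)

  mismatch <- broaden(make_stick_spectrum("dimer-couplet", center = 1000),
                      grid = wavenumber_grid(800, 1201))
  expect_error(weighted_average(list(s, mismatch), c(0.5, 0.5)), "grid")
  expect_warning(weighted_average(list(s, s), c(0.6, 0.6)), "renormaliz")
})

test_that("population-weighted averaging matches a manual summation oracle", {
  g <- wavenumber_grid(200, 2400)
  sticks <- lapply(1:3, function(i)
    make_stick_spectrum("random", seed = i, region = c(900, 1700)))
  specs <- lapply(sticks, broaden, grid = g)
  w <- c(0.5, 0.3, 0.2)
  avg <- weighted_average(specs, w)
  manual <- w[1] * specs[[1]]$intensities$roa +
    w[2] * specs[[2]]$intensities$roa + w[3] * specs[[3]]$intensities$roa
  expect_equal(avg$intensities$roa, manual, tolerance = 1e-14)
})

test_that("equilibrium fractions: closed form, numeric root, limits and mass balance", {
  eq <- equilibrium_fractions(K = 10, c = 0.05)
  expect_equal(eq$M, (-1 + sqrt(5)) / 40, tolerance = 1e-12)
  expect_equal(eq$monomer_fraction, 0.618034, tolerance = 1e-4)
  # independent numeric root of 2K M^2 + M - c = 0
  root <- uniroot(function(M) 2 * 10 * M^2 + M - 0.05, c(0, 0.05),
                  tol = 1e-14)$root
  expect_equal(eq$M, root, tolerance = 1e-10)
  # limits
  expect_equal(equilibrium_fractions(0, 0.05)$monomer_fraction, 1)
  expect_lt(equilibrium_fractions(1e12, 0.05)$monomer_fraction, 1e-3)
  # monotone decrease with K; mass balance to 1e-12 across a (K, c) grid
  fr_prev <- 1
  for (K in c(0, 0.1, 1, 10, 100, 1e4, 1e8)) {
    for (c0 in c(1e-4, 0.005, 0.05, 0.5, 2)) {
      eqi <- equilibrium_fractions(K, c0)
      expect_equal(eqi$M + 2 * eqi$D, c0, tolerance = 1e-12)
      expect_equal(eqi$monomer_fraction + eqi$dimer_fraction, 1)
    }
    fr <- equilibrium_fractions(K, 0.05)$monomer_fraction
    expect_lte(fr, fr_prev + 1e-15)
    fr_prev <- fr
  }
  expect_error(equilibrium_fractions(-1, 0.05), "K")
  expect_error(equilibrium_fractions(1, 0), "c")
})

test_that("monomer-dimer mixing applies the declared convention", {
  g <- wavenumber_grid(1600, 1900)
  mono <- broaden(make_stick_spectrum("dimer-couplet", center = 1760,
                                      splitting = 0), grid = g)
  dime <- broaden(make_stick_spectrum("dimer-couplet", center = 1740,
                                      splitting = 20), grid = g)
  expect_error(mix_monomer_dimer(mono, dime, K = 10, c = 0.05),
               "dimer_normalization")
  # K = 0: pure monomer
  mix0 <- mix_monomer_dimer(mono, dime, K = 0, c = 0.05,
                            dimer_normalization = "per-molecule")
  expect_equal(mix0$intensities$ir, mono$intensities$ir)
  # per-molecule weights at K = 10, c = 0.05: 0.618 / 0.382
  mix <- mix_monomer_dimer(mono, dime, K = 10, c = 0.05,
                           dimer_normalization = "per-molecule")
  fm <- equilibrium_fractions(10, 0.05)$monomer_fraction
  hand <- fm * mono$intensities$ir + (1 - fm) * dime$intensities$ir
  expect_equal(mix$intensities$ir, hand, tolerance = 1e-14)
  expect_equal(mix$provenance$monomer_weight + mix$provenance$dimer_weight, 1)
  # per-dimer weights: monomer [M]/c, dimer [D]/c
  mixd <- mix_monomer_dimer(mono, dime, K = 10, c = 0.05,
                            dimer_normalization = "per-dimer")
  eq <- equilibrium_fractions(10, 0.05)
  expect_equal(mixd$provenance$dimer_weight, eq$D / 0.05)
  # 0.5 / 0.5 of opposite spectra cancels
  neg <- composite_spectrum(g, lapply(mono$intensities, function(y) -y))
  Khalf <- uniroot(function(K) equilibrium_fractions(K, 0.05)$monomer_fraction - 0.5,
                   c(1e-6, 1e6), tol = 1e-14)$root
  mixc <- mix_monomer_dimer(mono, neg, K = Khalf, c = 0.05,
                            dimer_normalization = "per-molecule")
  expect_equal(max(abs(mixc$intensities$ir)), 0, tolerance = 1e-9)
})

test_that("mode displacement scans have the right layout and symmetry", {
  f <- test_ring_frame()
  set.seed(3)
  modes <- lapply(c(18, 25, 33), function(wn)
    list(wavenumber = wn, displacement = matrix(rnorm(24), ncol = 3)))
  # step 0 returns the input geometry
  d0 <- displace_along_modes(f, modes[1], steps = 0)
  expect_equal(d0[[1]]$xyz, f$xyz)
  # symmetric steps average back to the input to 1e-12
  ds <- displace_along_modes(f, modes[1], steps = c(-0.4, 0.4))
  expect_equal((ds[[1]]$xyz + ds[[2]]$xyz) / 2, f$xyz, tolerance = 1e-12)
  # 3 modes x 4 steps = 12 structures
  d12 <- displace_along_modes(f, modes, steps = c(-1, -0.5, 0.5, 1))
  expect_length(d12, 12)
  expect_named(d12[1], "mode1_step-1")
  bad <- list(list(wavenumber = 10, displacement = matrix(0.1, 3, 3)))
  expect_error(displace_along_modes(f, bad, 1), "mismatch|atoms")
})

test_that("averaging displaced sign-alternating couplets cancels VCD but conserves IR", {
  # the undisplaced dimer couplet and 12 displaced variants whose coupling
  # (hence couplet sign/splitting) alternates along each mode
  g <- wavenumber_grid(1600, 1900)
  undisp <- broaden(make_stick_spectrum("dimer-couplet", center = 1760,
                                        splitting = 20), grid = g)
  steps <- c(-1, -0.5, 0.5, 1)
  displaced <- list()
  for (mode in 1:3) {
    for (s in steps) {
      # low-frequency intermolecular modes perturb the carbonyl wavenumber
      # only weakly (a couple of cm-1) but flip the sign of the excitonic
      # coupling with the displacement direction
      displaced[[length(displaced) + 1]] <- broaden(
        make_stick_spectrum("dimer-couplet", center = 1760 + 2 * s,
                            splitting = 20 * abs(s),
                            couplet_sign = sign(s)),
        grid = g)
    }
  }
  avg <- weighted_average(displaced, rep(1 / 12, 12))
  expect_gte(max(abs(undisp$intensities$vcd)) /
               max(abs(avg$intensities$vcd)), 2)
  ir0 <- integrate_spectrum(undisp, "ir")
  ir1 <- integrate_spectrum(avg, "ir")
  expect_lt(abs(ir1 - ir0) / ir0, 0.01)
})

test_that("stick spectra round-trip through CSV with energies", {
  sticks <- list(
    make_stick_spectrum("random", seed = 1, structure_id = "cluster_1",
                        energy = 0),
    make_stick_spectrum("random", seed = 2, structure_id = "cluster_2",
                        energy = 0.35))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sticks_csv(sticks, path)
  back <- read_sticks_csv(path)
  expect_named(back, c("cluster_1", "cluster_2"))
  expect_equal(back$cluster_1$wavenumber, sticks[[1]]$wavenumber)
  expect_equal(back$cluster_2$intensities$vcd, sticks[[2]]$intensities$vcd)
  expect_equal(back$cluster_2$energy, 0.35)
  # determinism: same seed, bitwise-identical CSV
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_sticks_csv(list(make_stick_spectrum("random", seed = 1,
                                            structure_id = "cluster_1",
                                            energy = 0),
                        make_stick_spectrum("random", seed = 2,
                                            structure_id = "cluster_2",
                                            energy = 0.35)), p2)
  expect_identical(readLines(path), readLines(p2))
})

test_that("strength conversion scales with wavenumber and the documented constant", {
  s <- sticks_from_strengths(c(1000, 1500), dipole_strength = c(10, 0),
                             rotational_strength = c(50, -50))
  expect_equal(s$intensities$ir[1], 1000 * 10 * 1e-40 / 9.184e-39)
  expect_equal(s$intensities$ir[2], 0)
  expect_equal(s$intensities$vcd[2], 4 * 1500 * (-50) * 1e-44 / 9.184e-39)
  # broadened band integrates to the converted intensity
  b <- broaden(s, grid = wavenumber_grid(300, 2200))
  expect_equal(integrate_spectrum(b, "ir"), sum(s$intensities$ir),
               tolerance = 5e-3)
})

test_that("degenerate couplet cancels and split couplet is bisignate after broadening", {
  g <- wavenumber_grid(1600, 1900)
  degen <- broaden(make_stick_spectrum("dimer-couplet", splitting = 0),
                   grid = g)
  expect_equal(max(abs(degen$intensities$vcd)), 0, tolerance = 1e-12)
  split <- broaden(make_stick_spectrum("dimer-couplet", splitting = 20),
                   grid = g)
  expect_gt(max(split$intensities$vcd), 0)
  expect_lt(min(split$intensities$vcd), 0)
  # positive lobe below the centre for couplet_sign = +1
  expect_lt(g[which.max(split$intensities$vcd)],
            g[which.min(split$intensities$vcd)])
})
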