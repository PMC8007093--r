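#' Stick spectrum container
#'
#' Discrete vibrational modes of one structure: wavenumbers (cm^-1) and one
#' intensity column per observable.  IR and Raman intensities must be
#' nonnegative; VCD (rotational strengths) and ROA intensities may be
#' negative.  Intensities are taken as already converted to plottable
#' units.
#'
#' @param wavenumber numeric vector of mode wavenumbers (cm^-1, > 0).
#' @param ... named intensity vectors among `ir`, `vcd`, `raman`, `roa`
#'   (same length as `wavenumber`).
#' @param structure_id identifier of the parent structure.
#' @param energy optional energy of the parent structure (kcal/mol), used
#'   by [boltzmann_weights()].
#' @export
stick_spectrum <- function(wavenumber, ..., structure_id = "structure",
                           energy = NA_real_) {
  ints <- list(...)
  obs <- names(ints)
  if (is.null(obs) || !all(obs %in% c("ir", "vcd", "raman", "roa")))
    stop("intensity columns must be named among ir, vcd, raman, roa")
  if (!all(is.finite(wavenumber)) || any(wavenumber <= 0))
    stop("wavenumbers must be finite and positive")
  for (o in obs) {
    if (length(ints[[o]]) != length(wavenumber))
      stop("intensity column '", o, "' length mismatch")
    if (o %in% c("ir", "raman") && any(ints[[o]] < 0))
      stop("'", o, "' intensities must be >= 0")
  }
  structure(list(structure_id = structure_id,
                 wavenumber = as.numeric(wavenumber),
                 intensities = lapply(ints, as.numeric),
                 energy = energy),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> '%s': %d modes (%.0f-%.0f cm-1), observables: %s\n",
              x$structure_id, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber), paste(names(x$intensities), collapse = ", ")))
  invisible(x)
}

#' Read / write stick spectra as CSV
#'
#' Schema: `structure_id, wavenumber_cm-1, ir, vcd, raman, roa` (missing
#' observable columns allowed; an optional `energy_kcal_mol` column carries
#' the parent-structure energy).
#'
#' @param path CSV path.
#' @return `read_sticks_csv()` returns a named list of [stick_spectrum()]s.
#' @export
read_sticks_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wncol <- intersect(c("wavenumber_cm-1", "wavenumber"), names(df))[1L]
  if (is.na(wncol)) stop("no wavenumber column in ", path)
  obs <- intersect(c("ir", "vcd", "raman", "roa"), names(df))
  ids <- unique(df$structure_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$structure_id == id, , drop = FALSE]
    en <- if ("energy_kcal_mol" %in% names(sub)) sub$energy_kcal_mol[1L]
          else NA_real_
    do.call(stick_spectrum,
            c(list(wavenumber = sub[[wncol]], structure_id = id, energy = en),
              stats::setNames(lapply(obs, function(o) sub[[o]]), obs)))
  })
  stats::setNames(out, ids)
}

#' @rdname read_sticks_csv
#' @param sticks a [stick_spectrum()] or list of them.
#' @export
write_sticks_csv <- function(sticks, path) {
  if (inherits(sticks, "stick_spectrum")) sticks <- list(sticks)
  rows <- lapply(sticks, function(s) {
    df <- data.frame(structure_id = s$structure_id,
                     `wavenumber_cm-1` = s$wavenumber, check.names = FALSE)
    for (o in names(s$intensities)) df[[o]] <- s$intensities[[o]]
    if (!is.na(s$energy)) df$energy_kcal_mol <- s$energy
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composite (broadened) spectrum container
#'
#' @param wavenumber strictly increasing uniform grid (cm^-1).
#' @param intensities named list of numeric vectors on the grid.
#' @param provenance list recording contributing structures, weights and
#'   parameters.
#' @export
composite_spectrum <- function(wavenumber, intensities, provenance = list()) {
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("grid must be strictly increasing")
  for (o in names(intensities))
    if (length(intensities[[o]]) != length(wavenumber))
      stop("intensity grid length mismatch for '", o, "'")
  structure(list(wavenumber = wavenumber, intensities = intensities,
                 provenance = provenance),
            class = "composite_spectrum")
}

#' @export
print.composite_spectrum <- function(x, ...) {
  cat(sprintf("<composite_spectrum> %d points (%.0f-%.0f cm-1), observables: %s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              paste(names(x$intensities), collapse = ", ")))
  invisible(x)
}

#' Uniform wavenumber grid
#' @param from,to grid limits (cm^-1).
#' @param by spacing (cm^-1, default 1).
#' @export
wavenumber_grid <- function(from, to, by = 1) seq(from, to, by = by)

#' Apply region-dependent wavenumber scaling
#'
#' Harmonic wavenumbers are scaled (never intensities).  `scale` is either
#' one factor for all modes or a data frame `from, to, factor` of regions
#' applied to the unscaled wavenumber (first matching region wins; modes in
#' no region keep factor 1).
#' @param wavenumber numeric wavenumbers (cm^-1).
#' @param scale scalar factor, or data frame `from, to, factor`.
#' @export
scale_wavenumbers <- function(wavenumber, scale) {
  if (is.numeric(scale) && length(scale) == 1L) {
    if (scale <= 0 || scale > 1.1) stop("scaling factor must be in (0, 1.1]")
    return(scale * wavenumber)
  }
  stopifnot(is.data.frame(scale), all(c("from", "to", "factor") %in% names(scale)))
  fac <- rep(1, length(wavenumber))
  done <- rep(FALSE, length(wavenumber))
  for (r in seq_len(nrow(scale))) {
    hit <- !done & wavenumber >= scale$from[r] & wavenumber <= scale$to[r]
    fac[hit] <- scale$factor[r]
    done <- done | hit
  }
  fac * wavenumber
}

#' Lorentzian broadening of a stick spectrum
#'
#' Each mode contributes a unit-area Lorentzian of full width at half
#' maximum `bandwidth`, centred at `scale x wavenumber` and multiplied by
#' its intensity:
#' `L(x) = (Gamma/2) / (pi ((x - x0)^2 + (Gamma/2)^2))`, peak height
#' `2 / (pi Gamma)`.
#'
#' @param stick a [stick_spectrum()].
#' @param bandwidth FWHM in cm^-1 (default 6).
#' @param scale wavenumber scaling (see [scale_wavenumbers()]); default 1.
#' @param grid wavenumber grid; default spans the scaled modes with a
#'   margin of 20 bandwidths at 1 cm^-1 spacing.
#' @return a [composite_spectrum()].
#' @export
broaden <- function(stick, bandwidth = 6, scale = 1, grid = NULL) {
  stopifnot(inherits(stick, "stick_spectrum"))
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  x0 <- scale_wavenumbers(stick$wavenumber, scale)
  if (is.null(grid)) {
    lo <- max(0, floor(min(x0) - 20 * bandwidth))
    grid <- wavenumber_grid(lo, ceiling(max(x0) + 20 * bandwidth))
  }
  out_lo <- x0 < min(grid); out_hi <- x0 > max(grid)
  if (any(out_lo | out_hi)) {
    m <- which(out_lo | out_hi)[1L]
    stop(sprintf("grid [%.1f, %.1f] does not cover scaled mode %d at %.1f cm-1",
                 min(grid), max(grid), m, x0[m]))
  }
  if (min(x0) - min(grid) < 20 * bandwidth || max(grid) - max(x0) < 20 * bandwidth)
    warning("grid margin below 20 bandwidths; integrated intensity may be clipped")
  hw <- bandwidth / 2
  # n_grid x n_modes matrix of unit-area Lorentzians
  L <- hw / pi / (outer(grid, x0, `-`)^2 + hw^2)
  ints <- lapply(stick$intensities, function(s) as.vector(L %*% s))
  composite_spectrum(grid, ints,
                     provenance = list(structures = stick$structure_id,
                                       weights = 1,
                                       bandwidth_fwhm_cm1 = bandwidth,
                                       scale = scale))
}

#' Boltzmann population weights from energies
#'
#' `w_i` proportional to `exp(-(E_i - min E) / (k_B T))` with energies in
#' kcal/mol; shifted by the minimum for overflow safety; weights sum to 1.
#'
#' @param energies numeric vector, kcal/mol.
#' @param temperature kelvin (default 300).
#' @export
boltzmann_weights <- function(energies, temperature = 300) {
  if (!length(energies)) stop("at least one energy required")
  if (temperature <= 0) stop("temperature must be > 0")
  kB <- 0.001987204259  # kcal/mol/K
  w <- exp(-(energies - min(energies)) / (kB * temperature))
  w / sum(w)
}

#' Weighted average of composite spectra
#'
#' Pointwise convex combination of spectra on an identical grid.  Weights
#' must be nonnegative and sum to 1 within 1e-9 (otherwise they are
#' renormalized with a warning).  No silent resampling: a grid mismatch is
#' an error; use [resample_spectrum()] first.
#'
#' @param spectra list of [composite_spectrum()]s on one common grid.
#' @param weights numeric weights.
#' @return a [composite_spectrum()]; provenance records the weights.
#' @export
weighted_average <- function(spectra, weights) {
  stopifnot(length(spectra) == length(weights), length(spectra) >= 1L)
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-9) {
    warning("weights do not sum to 1; renormalizing")
    weights <- weights / sum(weights)
  }
  g <- spectra[[1L]]$wavenumber
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavenumber, g, tolerance = 0)) &&
        !identical(s$wavenumber, g))
      stop("grid mismatch between spectra; resample explicitly first")
  obs <- Reduce(intersect, lapply(spectra, function(s) names(s$intensities)))
  ints <- lapply(obs, function(o) {
    Reduce(`+`, Map(function(s, w) w * s$intensities[[o]], spectra, weights))
  })
  names(ints) <- obs
  composite_spectrum(g, ints, provenance = list(
    structures = unlist(lapply(spectra, function(s) s$provenance$structures)),
    weights = weights))
}

#' Resample a composite spectrum onto a new grid (linear interpolation)
#' @param spec a [composite_spectrum()].
#' @param grid new wavenumber grid inside the old range.
#' @export
resample_spectrum <- function(spec, grid) {
  stopifnot(inherits(spec, "composite_spectrum"))
  if (min(grid) < min(spec$wavenumber) || max(grid) > max(spec$wavenumber))
    stop("new grid extends beyond the spectrum range")
  ints <- lapply(spec$intensities, function(y)
    stats::approx(spec$wavenumber, y, xout = grid)$y)
  composite_spectrum(grid, ints, provenance = spec$provenance)
}

#' Write a composite spectrum as CSV (+ JSON provenance sidecar)
#' @param spec a [composite_spectrum()].
#' @param path CSV path; a sidecar `<path>.json` records provenance.
#' @export
write_spectrum_csv <- function(spec, path) {
  df <- data.frame(wavenumber = spec$wavenumber, check.names = FALSE)
  for (o in names(spec$intensities)) df[[o]] <- spec$intensities[[o]]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(spec$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert dipole and rotational strengths to stick intensities
#'
#' Optional utility, separate from the broadening pipeline (which accepts
#' intensities already in plottable units).  Uses the standard relations
#' between integrated molar absorptivity and the mode strengths,
#' `integral(eps/nu) d nu = D / 9.184e-39` and
#' `integral(Deps/nu) d nu = 4 R / 9.184e-39`
#' (strengths in esu^2 cm^2; the constant 9.184e-39 collects
#' `3000 h c ln(10) / (8 pi^3 N_A)`), so that a unit-area Lorentzian at
#' `nu` multiplied by the returned intensity integrates to the band's
#' molar absorptivity in M^-1 cm^-2.
#'
#' @param wavenumber mode wavenumbers, cm^-1.
#' @param dipole_strength dipole strengths in 1e-40 esu^2 cm^2.
#' @param rotational_strength rotational strengths in 1e-44 esu^2 cm^2.
#' @param structure_id,energy passed to [stick_spectrum()].
#' @return a [stick_spectrum()] with `ir` (and `vcd` when rotational
#'   strengths are given) intensities.
#' @export
sticks_from_strengths <- function(wavenumber, dipole_strength,
                                  rotational_strength = NULL,
                                  structure_id = "structure",
                                  energy = NA_real_) {
  conv <- 1 / 9.184e-39            # (esu^2 cm^2)^-1 -> M^-1 cm^-2 per cm^-1
  ir <- wavenumber * dipole_strength * 1e-40 * conv
  args <- list(wavenumber = wavenumber, ir = ir,
               structure_id = structure_id, energy = energy)
  if (!is.null(rotational_strength))
    args$vcd <- 4 * wavenumber * rotational_strength * 1e-44 * conv
  do.call(stick_spectrum, args)
}

#' Integrated intensity of a composite spectrum (trapezoid rule)
#' @param spec a [composite_spectrum()].
#' @param observable which observable to integrate.
#' @export
integrate_spectrum <- function(spec, observable = names(spec$intensities)[1L]) {
  y <- spec$intensities[[observable]]
  x <- spec$wavenumber
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}
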