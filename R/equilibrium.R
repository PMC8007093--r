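#' Monomer-dimer equilibrium fractions
#'
#' For the association equilibrium `2 M <-> D` with constant
#' `K = [D]/[M]^2` (M^-1) and total monomer-equivalent concentration
#' `c = [M] + 2[D]` (M), the monomer concentration is the positive root of
#' `2K [M]^2 + [M] - c = 0`, evaluated in the cancellation-free form
#' `[M] = 2c / (1 + sqrt(1 + 8Kc))` (identical to
#' `(-1 + sqrt(1 + 8Kc)) / (4K)`, with the correct limit `[M] -> c` as
#' `K -> 0`).  Molecule fractions are `[M]/c` and `2[D]/c`; they sum to 1
#' exactly.
#'
#' @param K association constant, M^-1 (`>= 0`).
#' @param c total concentration as monomer equivalents, M (`> 0`).
#' @return list: `monomer_fraction`, `dimer_fraction` (molecule fractions),
#'   `M` and `D` (concentrations, M), `K`, `c`.
#' @examples
#' equilibrium_fractions(K = 10, c = 0.05)$monomer_fraction  # (sqrt(5)-1)/2
#' @export
equilibrium_fractions <- function(K, c) {
  if (K < 0) stop("K must be >= 0")
  if (c <= 0) stop("c must be > 0")
  M <- 2 * c / (1 + sqrt(1 + 8 * K * c))
  D <- (c - M) / 2
  fm <- M / c
  list(monomer_fraction = fm, dimer_fraction = 1 - fm, M = M, D = D,
       K = K, c = c)
}

#' Equilibrium mixing of monomer and dimer spectra
#'
#' Combines a monomer and a dimer composite spectrum with the molecule
#' fractions of [equilibrium_fractions()].  The dimer normalization
#' convention must be declared explicitly: `"per-molecule"` weights the
#' dimer spectrum by the fraction of molecules bound in dimers, `2[D]/c`
#' (use when the dimer stick intensities are per dimer molecule-pair and
#' you want intensity per solute molecule); `"per-dimer"` weights by the
#' species concentration fraction `[D]/c`.  There is no silent default.
#'
#' @param monomer,dimer [composite_spectrum()]s on an identical grid.
#' @param K,c equilibrium parameters (see [equilibrium_fractions()]).
#' @param dimer_normalization `"per-molecule"` or `"per-dimer"`.
#' @return a [composite_spectrum()]; provenance records `K`, `c`, the
#'   convention and both weights.
#' @export
mix_monomer_dimer <- function(monomer, dimer, K, c,
                              dimer_normalization = c("per-molecule",
                                                      "per-dimer")) {
  if (missing(dimer_normalization))
    stop("declare dimer_normalization: 'per-molecule' or 'per-dimer'")
  dimer_normalization <- match.arg(dimer_normalization)
  stopifnot(inherits(monomer, "composite_spectrum"),
            inherits(dimer, "composite_spectrum"))
  if (!identical(monomer$wavenumber, dimer$wavenumber))
    stop("monomer and dimer grids differ; resample explicitly first")
  eq <- equilibrium_fractions(K, c)
  wm <- eq$monomer_fraction
  wd <- switch(dimer_normalization,
               "per-molecule" = eq$dimer_fraction,    # 2[D]/c
               "per-dimer" = eq$D / c)
  obs <- intersect(names(monomer$intensities), names(dimer$intensities))
  ints <- lapply(obs, function(o)
    wm * monomer$intensities[[o]] + wd * dimer$intensities[[o]])
  names(ints) <- obs
  composite_spectrum(monomer$wavenumber, ints, provenance = list(
    K = K, c = c, dimer_normalization = dimer_normalization,
    monomer_weight = wm, dimer_weight = wd,
    monomer = monomer$provenance, dimer = dimer$provenance))
}

#' Displace a geometry along normal modes
#'
#' Generates perturbed structures `geometry + s * unit(mode)` for every
#' (mode, step) combination — the scan used to probe how large-amplitude,
#' low-wavenumber (intermolecular) modes broaden bands and cancel VCD
#' couplets in flexible dimers.  Each mode's displacement matrix is
#' normalized to unit Frobenius norm, so the step `s` is the displacement
#' amplitude in Angstrom.
#'
#' @param geometry a [frame()].
#' @param modes list of modes, each a list with `wavenumber` (cm^-1) and
#'   `displacement` (`n_atoms x 3` matrix).
#' @param steps numeric step amplitudes (e.g. `c(-1, -0.5, 0.5, 1)`; a
#'   symmetric step set has mean geometry equal to the input).
#' @return list of [frame()]s labelled `mode<k>_step<s>`, in mode-major
#'   order.
#' @export
displace_along_modes <- function(geometry, modes, steps) {
  stopifnot(inherits(geometry, "voa_frame"))
  if (!all(is.finite(steps))) stop("steps must be finite")
  out <- list()
  for (k in seq_along(modes)) {
    disp <- as.matrix(modes[[k]]$displacement)
    if (!all(dim(disp) == dim(geometry$xyz)))
      stop(sprintf("mode %d displacement is %dx%d but geometry has %d atoms",
                   k, nrow(disp), ncol(disp), n_atoms(geometry)))
    disp <- disp / sqrt(sum(disp^2))
    for (s in steps) {
      fr <- frame(geometry$labels, geometry$xyz + s * disp, geometry$mol,
                  index = geometry$index)
      out[[sprintf("mode%d_step%+g", k, s)]] <- fr
    }
  }
  out
}
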