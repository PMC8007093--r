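---
title: "From MD ensembles to vibrational optical activity band-shapes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From MD ensembles to vibrational optical activity band-shapes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voamd)
```

## The problem voamd addresses

Vibrational circular dichroism (VCD) and Raman optical activity (ROA)
band-shapes of small flexible solutes are exquisitely sensitive to
conformation and to hydrogen bonding with the solvent — and, for solutes
that self-associate, to the monomer–dimer equilibrium.  A practical
protocol for predicting them is: run molecular dynamics, reduce each frame
to a few periodic collective variables (CVs) that capture the relevant
flexibility, cluster the frames on those CVs, export one representative
structure per cluster (with its solvation shell) for quantum-chemical
frequency calculations, and finally reassemble a continuous spectrum from
the per-structure stick spectra with the appropriate statistical weights.

`voamd` implements everything in that chain except the MD and the quantum
chemistry themselves: the CVs, the hydrogen-bond and association analysis,
the periodic-aware clustering and medoid export, and the spectral
assembly.  A synthetic-data module generates trajectories, dimers,
solvated frames and stick spectra with planted ground truth, so that every
stage of the pipeline can be validated by parameter recovery.

## Collective variables

### Pseudorotation of five-membered rings

A five-membered ring interconverts between envelope and twist forms along
a pseudorotation cycle.  We use the two-torsion formulation: with the
endocyclic torsions indexed so that `nu_j` is the dihedral about the bond
between ring atoms *j*+1 and *j*+2 (cyclic, 1-based), the phase and
amplitude are

$$Z_x = \frac{\nu_1 + \nu_3}{2\cos(4\pi/5)}, \qquad
  Z_y = \frac{\nu_1 - \nu_3}{2\sin(4\pi/5)},$$
$$P_\theta = \operatorname{atan2}(Z_y, Z_x), \qquad
  A_r = \sqrt{Z_x^2 + Z_y^2}.$$

These coefficients are exact for an ideal pseudorotating ring,
`nu_j = A cos(P + 144°(j−2))`: substituting gives `Z_x = A cos P` and
`Z_y = A sin P` identically.  `A_r` carries the units of the torsions
(degrees).  Dihedrals follow the IUPAC sign convention (clockwise positive
looking from atom 2 to atom 3), all phases are reported on (−180°, 180°],
and a phase is only reported when the amplitude exceeds 0.1° — below that
the ring is planar to numerical noise and the phase direction is
meaningless.

On a *real* (built or simulated) ring the torsion pattern is not an exact
cosine, so properties that are exact for the ideal pattern — e.g.
amplitude invariance under cyclic relabelling with a 144° phase shift —
hold only to the geometric non-ideality, about a degree at typical
amplitudes.  The test suite checks both regimes: exactly at the torsion
level, approximately on built rings.

### Cremer–Pople phase of six-membered (pseudo-)rings

For six-atom rings — including the *intermolecular pseudo-ring* closed by
the two O–H···O=C bridges of a hydrogen-bonded dimer — we use the
Cremer–Pople mean-plane construction.  Ring positions are centred on the
centroid, the unit normal is taken along
$\mathbf{R}''\times\mathbf{R}'$ with
$\mathbf{R}' = \sum_j \mathbf{r}_j \sin(2\pi j/6)$ and
$\mathbf{R}'' = \sum_j \mathbf{r}_j \cos(2\pi j/6)$ (this orientation
makes a counterclockwise ring have a +z normal, so that a hexagon with
planted displacements $z_j = c\cos(4\pi j/6 + \varphi_0)$ measures
$\varphi = \varphi_0$), and

$$q_2\cos\varphi = \sqrt{2/6}\sum_j z_j\cos(4\pi j/6),\qquad
  q_2\sin\varphi = -\sqrt{2/6}\sum_j z_j\sin(4\pi j/6),$$
$$q_3 = \sqrt{1/6}\sum_j (-1)^j z_j, \qquad Q^2 = q_2^2 + q_3^2 .$$

The phase is undefined (reported `NA`) when `q2 < 1e-4` Å.  Ring-bond
validation is relaxed to 4 Å for pseudo-rings, whose "bonds" include
hydrogen-bond contacts; pass `check_bonds = FALSE` for rings assembled
from even longer contacts.

No periodic-boundary unwrapping is attempted: inputs are assumed
whole-molecule, and a ring bond longer than 3 Å (covalent rings) raises an
error rather than silently producing a junk phase.

## Hydrogen bonds and association

A geometric hydrogen bond requires a donor–acceptor distance of at most
3 Å and an angular deviation from linearity of at most 30°.  The angular
criterion follows the convention of the common trajectory-visualization
tools: the angle at the donor between the D→A and D→H vectors.  A
*literal* D–H–A angle below 30° would be geometrically impossible for a
3 Å contact (the hydrogen would have to sit almost on top of the
acceptor); the literal convention is still available behind
`convention = "dha"` for completeness.  Both cutoffs are inclusive, and
the boundary behaviour is unit-tested at 2.999/3.001 Å and 29.9°/30.1°.

Frames of a two-solute trajectory are labelled `dimer` when the minimum
intermolecular donor–acceptor distance is at most 4 Å (inclusive), else
`monomer`.  All declared donor–acceptor pairs are considered; restricting
to a subset is a matter of declaring fewer pairs.

Solvation shells keep the solute plus every *whole* solvent molecule with
any atom within the radius — molecules are never split, the criterion is
any-atom rather than centre-of-mass (the point is to capture
hydrogen-bonded partners), and shell membership is monotone in the radius.

## Periodic-aware k-medoids

All CVs here are angles, so clustering uses a wrapped metric: the distance
between two CV vectors is the Euclidean norm of their per-coordinate
differences, each periodic difference first mapped to [0°, 180°], with
optional per-CV weights.  k-medoids is preferred over k-means because the
cluster centres are then actual trajectory frames, which is exactly what
the downstream quantum-chemistry step needs.

The implementation (C++ kernel, distances computed on the fly so no
O(n²) matrix is stored) seeds with the deterministic greedy PAM BUILD
procedure and then alternates assignment and in-cluster medoid update
until the assignment is stable.  Both steps are non-increasing in the
total cost, ties always break toward the lowest frame index, and the
result is fully deterministic for a given (data, k, seed); the seed is
recorded in the model for provenance.  `k` is a user input: the number of
basins is read off the CV histograms by the analyst, and no automatic
selection is attempted.  Circular cluster means use the atan2 of the mean
sine and cosine and are reported `NA` when the resultant length is below
1e-9.

The recommended `cluster::pam` on an explicitly precomputed
wrapped-distance matrix is used in the test suite as an independent
cross-check of partitions and costs on small problems; it is never the
implementation.

## Spectral assembly

Each vibrational mode contributes a *unit-area* Lorentzian centred at the
scaled wavenumber and multiplied by its intensity,

$$L(\tilde\nu) = \frac{\Gamma/2}{\pi\left[(\tilde\nu-\tilde\nu_0)^2 +
(\Gamma/2)^2\right]},$$

so the integrated band intensity equals the stick intensity and the peak
height of an isolated band is $2/(\pi\Gamma)$.  The default bandwidth is
Γ = 6 cm⁻¹ and is interpreted as the full width at half maximum; the
interpretation is stored in the output provenance because the two
half-width conventions are easily confused.  Scaling factors apply to
wavenumbers only, never to intensities, and may be region-dependent (e.g.
0.985 in the mid-IR, 0.96 in the OH/CH stretching region) via a
`from/to/factor` table.  The default grid spacing is 1 cm⁻¹; averaging
requires *identical* grids — there is no silent resampling, only the
explicit `resample_spectrum()`.  Lorentzian tails are heavy: a grid margin
of 20 bandwidths still clips ~1.6% of the integral, so a warning is issued
below that margin and the conservation tests use ±600 cm⁻¹ windows (0.3%
tail loss).

Ensemble spectra are convex combinations: cluster-population weights from
the k-medoids model, or Boltzmann factors
$w_i \propto \exp(-(E_i - \min E)/k_BT)$ from per-structure energies in
kcal/mol (default T = 300 K, the usual simulation temperature; the shifted
exponent makes 50 kcal/mol gaps underflow-safe).

### Monomer–dimer equilibrium

For 2M ⇌ D with `K = [D]/[M]²` and total monomer-equivalent concentration
`c = [M] + 2[D]`, the monomer concentration is the positive root of
`2K[M]² + [M] − c = 0`, evaluated as `[M] = 2c/(1 + sqrt(1+8Kc))` — the
cancellation-free form with the correct `K → 0` limit.  At K = 10 M⁻¹ and
c = 50 mM this gives a monomer molecule fraction of
(−1+√5)/2 ≈ 0.618.  The dimerization constant is a required user input:
it comes from independent experiments and has no sensible default.
Mixing monomer and dimer composite spectra requires an *explicit*
normalization convention — `per-molecule` (dimer weighted by 2[D]/c,
for stick intensities per dimer pair interpreted per solute molecule) or
`per-dimer` ([D]/c) — because published spectra are not consistent about
this and a silent default would be a trap.  The convention, K, c and both
weights are recorded in the provenance.

### Displacement along low-frequency modes

`displace_along_modes()` generates `geometry + s·unit(mode)` scans.  Its
purpose is diagnostic: for a flexible hydrogen-bonded dimer, displacing
along the lowest (intermolecular) normal modes and averaging the
resulting spectra shows how large-amplitude motion broadens bands and
cancels the sharp bisignate VCD couplet that a single rigid structure
predicts — the mean IR intensity is conserved while opposite-signed
couplets annihilate.  The canonical layout is 3 modes × 4 symmetric steps
= 12 structures; the step amplitudes are user inputs (they are in units
of the normalized displacement, i.e. Ångström of total distortion).  In
the synthetic validation of this mechanism the couplet sign alternates
with the displacement direction while the band centre moves by only a
couple of cm⁻¹ — low-frequency intermolecular modes perturb the coupling
much more strongly than the carbonyl wavenumber itself.

## The synthetic-data module

The generators define the study conditions for every recovery test:

* **Rings** are built from an out-of-plane cosine ansatz
  `z_j = q cos(offset + 4πj/5)` on a regular pentagon, with the in-plane
  radius rescaled to restore the bond length and `(q, offset)` iterated
  until the *measured* `(P_θ, A_r)` (through the package's own analysis
  path) match the planted targets to 1e-6.  An amplitude that cannot be
  realized at the given bond length raises an error.  The optional
  exocyclic atoms mimic an α-hydroxy lactone: a hydroxyl O/H on the
  carbinol carbon (torsion H–O–C–C is the OH rotamer CV) and a carbonyl
  O on the adjacent ring carbon.
* **Conformer mixtures** are von Mises mixtures over the periodic CVs
  (the canonical circular noise model, one concentration parameter κ per
  CV; Best–Fisher rejection sampling, no circular-statistics dependency).
  The default six-state fixture crosses two ring-pucker basins
  (P_θ ≈ −157°, 18°) with three hydroxyl rotamers (≈ 81°, −38°, 149°) at
  κ = 50 (angular spread ≈ 8°), with populations 47.4 / 22.1 / 10.0 /
  9.9 / 8.0 / 2.6 % — the population structure of a monomeric
  α-hydroxy lactone in water.  The pucker/rotamer grid keeps every pair
  of states at least ~68° apart, which matters: a cost-minimizing
  clustering can only be expected to recover the planted partition when
  the basin separation comfortably exceeds the within-basin spread.  Two
  of the literal conformer-table rows differ by only ~28° in one CV; at
  κ = 50 that pair sits inside the regime where splitting the largest
  basin is provably cheaper for k-medoids than separating a 2.6% basin,
  so the planted partition would not even be the cost optimum.  The
  fixture therefore plants the grid centres, which represent the same
  physics without making the benchmark ill-posed.
* **Dimers** are docked from a target hexagon: a cyclic polygon with the
  intramolecular triangle sides and the requested H-bond distance, given
  a cosine out-of-plane pattern for the requested Cremer–Pople phase;
  both monomers are Kabsch-fitted onto their three slots and molecule B's
  rigid placement is refined by Nelder–Mead against the *measured* phase,
  both O···O distances, and a steric penalty.  Planted monomer phases are
  preserved exactly (the docking is rigid); phase and distance targets
  are verified to 2° / 0.05 Å, and failure to converge is an error, never
  a silent miss.
* **Solvent** is packed in a single pass of bulk-density
  (0.0334 Å⁻³) candidate positions with hard-sphere rejection
  (2.8 Å to solute, 2.6 Å water–water), which approximates a snapshot of
  a liquid box well enough that a 4 Å shell around a small cyclic solute
  holds on the order of ten waters.  A separate minimal fixture plants an
  exact per-frame contact probability for occupancy statistics.
* **Stick spectra**: seeded random spectra (nonnegative IR/Raman, signed
  VCD/ROA), and the bisignate `dimer-couplet` kind — two modes at
  `centre ± splitting/2` with opposite VCD signs and equal IR halves.

What the generators deliberately do *not* emulate: force-field energetics,
correlated CV dynamics (frames are i.i.d. draws), realistic water
structure beyond hard-sphere packing, and anharmonicity.  Passing recovery
tests therefore demonstrate the *analysis chain* is correct, not that any
particular force field or QM level is adequate for a given solute.

## Numerical choices and problem sizes

* Phases in degrees on (−180, 180] everywhere externally; radians
  internal.  Atom indices 1-based everywhere.
* Phase-undefined tolerances: amplitude < 0.1° (pseudorotation),
  q2 < 1e-4 Å (Cremer–Pople), resultant < 1e-9 (circular means).
* Threshold comparisons (H-bond, dimer, shell) are inclusive (≤).
* Clustering tie-breaks: lowest frame index; relabelling after fit is by
  descending population.
* Validation problem sizes are chosen for quick desk runs: 10 000 frames
  for population recovery (binomial error ~0.5% on the largest basin),
  2 000 frames for occupancy (±2.9% at three binomial standard errors),
  72 ring builds for the puckering round trip, 300-frame pipelines for
  the determinism checks.

## Known limitations

* The two-torsion pseudorotation uses only ν1 and ν3; the five-torsion
  least-squares phase is out of scope, and for strongly non-ideal rings
  the two conventions differ by up to a few degrees.
* No minimum-image treatment anywhere: wrapped/broken molecules must be
  made whole upstream.
* Stick intensities are taken as already in plottable units; conversion
  from dipole/rotational strengths (with its temperature and lineshape
  conventions) is the caller's responsibility.
* The k-medoids alternation converges to a local cost optimum; the
  deterministic BUILD seeding makes this reproducible, but on poorly
  separated data the optimum itself may not coincide with the generating
  partition (see the κ/separation discussion above).
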