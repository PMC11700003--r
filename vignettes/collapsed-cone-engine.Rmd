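---
title: "A successive-scattering collapsed-cone dose engine with corrected multiple-scatter transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A successive-scattering collapsed-cone dose engine with corrected multiple-scatter transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Model-based dose calculation for high-dose-rate Ir-192 brachytherapy must
account for the patient's actual media: the standard water-geometry
formalism ignores heterogeneities, while full Monte Carlo is too slow for
routine planning.  Collapsed-cone point-kernel superposition engines close
this gap by transporting released scatter energy along a discrete set of
cone axes.  They separate the total dose by photon scatter generation —
primary (`prim`), first scatter (`1sc`) and multiple scatter (`msc`,
everything scattered at least twice) — because each generation's energy
release pattern is derived from the previous generation's dose, and each
generation can be transported with its own approximations.

The known weakness of this architecture is the multiple-scatter dose in
media that differ from the kernel medium (water).  The classic transport
scales only the kernel *attenuation* by the medium-to-water ratio of
spectrum-averaged linear attenuation, `eta_msc`.  Energy absorbed per unit
path is then proportional to attenuation, not to energy absorption; in a
medium like cortical bone, where the low-energy multiple-scatter field is
absorbed (photoelectric effect) far more strongly than it is attenuated
relative to water, the engine deposits too little energy locally.
ccbrachy implements both that original transport and a corrected one that
introduces the linear energy-absorption ratio `chi_msc` and balances the
changed local absorption by a compensating change in the energy carried
forward along each transport line.

## The multiple-scatter line transport

Each transport direction `m` (solid angle `dOmega = 4*pi/M`) sweeps the
grid with parallel lines.  Per line and kernel term, an effective energy
fluence `R` of multiple-scatter radiant energy is iterated over the steps
`j`:

```
eps_j     = exp(-eta_j * c * dl)
sigma_j   = S2sc_j * rho_j * dOmega * C / c
dR_j      = sigma_j * (1 - eps_j) / (eta_j * c)
bracket_j = (1 - eps_j) * R_{j-1} + sigma_j * dl - dR_j
```

`bracket_j` collects the energy absorbed from the entering fluence, the
local self-absorption of the voxel's own released scerma `S2sc_j`, and the
self-absorption correction `dR_j` that forwards the remainder of the local
release.  The two modes differ only here:

* **original**: `dose_j = bracket_j / (dlmax * rho_j)` and
  `R_j = R_{j-1} * eps_j + dR_j` — attenuation scaling only;
* **corrected**: `dose_j = (chi_j/eta_j) * bracket_j / (dlmax * rho_j)`
  and `R_j = R_{j-1} * eps_j + dR_j + (1 - chi_j/eta_j) * bracket_j`.

The correction term re-routes exactly the extra energy absorbed locally
(or missing, for `chi/eta < 1` as in low-density gas) out of (into) the
transported fluence, so *both* modes satisfy, step by step and to
round-off,

```
R_in + released = absorbed' + R_out .
```

For all-water phantoms `chi = eta = 1`, the correction vanishes
identically, and the two modes produce bit-identical dose grids — these
two guarantees are asserted directly in the test suite
(`mscLineRecursion()` is an R reference implementation of the recursion
used to cross-check the compiled transport).  The derivation of `dR_j`
assumes uniform release along the step attenuated to the step exit; it
reduces to `sigma_j * dl` as `dl -> 0` and never produces a negative
bracket (`1 - exp(-x) <= x`).

The same recursion transports the first-scatter scerma with the 1sc
kernel; there the energy-absorption ratio (`chi_1sc/eta_1sc`) is applied
in both engine modes, matching the established first-scatter formulation.
The engine mode flag therefore changes the msc component only.

## Transport line lattice and kernel tilting

For a direction with dominant axis component `|d_a|`, the grid is swept
slab by slab: each voxel belongs to exactly one sheared voxel chain
(transverse drift accumulated and rounded per slab), and every step has
the constant length `dlmax = voxelSize / |d_a|`.  The summed step length
per voxel then equals `dlmax` exactly for every voxel — the normalization
assumed by the `1/dlmax` factor in the step dose — and each voxel releases
`S2sc * rho * V` per unit kernel integral with no overlap between lines.
Energy carried by a line that leaves the grid is booked as escaped, which
makes the global balance `released = absorbed + escaped` exact for any
media map and both modes.

Kernels are generated for a photon incident along one axis, but release
sites in a brachytherapy phantom see radiation flowing radially from the
source.  The per-step kernel parameters are therefore looked up by the
angle between the transport direction and the source-to-voxel axis
(kernel tilting) in 48 equal-solid-angle polar cones.

Directions are a deterministic zenith-uniform equal-solid-angle partition
of the sphere (rings of equal cell count with a golden-angle azimuthal
offset per ring).  The high-accuracy configuration of the field uses
1620/240 directions for 1sc/msc; the packaged desk-scale profile uses
320/72, which leaves the characteristic collapsed-cone "spikes" visible in
single-voxel release patterns but averages out over extended release
regions.

## Kernels and scatter spectra

Forced-interaction Monte Carlo in infinite water generates the kernels: a
primary photon (sampled from the Ir-192 lines with scerma-production
weights `w E (mu - muen)/rho`) is forced to interact at the origin.  For
the 1sc kernel the emerging photon's collision kerma at its next
interaction site is tallied per unit released energy in
(radius, polar-angle) bins; for the msc kernel the incident energy is
drawn from the first-scatter spectrum and the *entire* descendant cascade
(generations >= 2) is tallied, so that one kernel closes the infinite
scattering series and integrates to unity.  Deposits beyond the 30 cm
tally radius are booked per polar cone so no energy is lost from the
kernel normalization.

Each cone's radial profile is fitted as `C exp(-c r) + F exp(-f r)` under
an exact conservation constraint: the kernel's total integral per cone is
pinned to the cone's tallied-plus-escaped energy share, while the decay
constants and the split between the two terms minimize a content-weighted,
radially tapered log-space residual (taper e-folding 6 cm).  The taper
concentrates fit fidelity at the radii a phantom-scale dose grid actually
samples; the far tail of the multiple-scatter deposition profile in water
is so flat (build-up compensating attenuation) that an unweighted
exponential fit would otherwise sacrifice the near field.  The fit is a
deterministic profile search over decay-constant pairs with a Nelder-Mead
polish — immune to the degeneracy that defeats free four-parameter
nonlinear fits when the profile is close to a single exponential.

The medium scaling factors are averages over the scatter-generation
spectra.  Two choices matter here:

* **Energy-fluence weighting.**  Collision kerma is
  `integral(PsiE(E) muen/rho dE)`, so the effective coefficients of a
  radiation field are its energy-fluence-weighted averages; all scatter
  spectra in the package carry energy-fluence weights.
* **Spectra at depth, not asymptotic cascade spectra.**  The scaling
  spectra are tallied from a Monte Carlo run of the benchmark water
  phantom over the 1-10 cm radial range (`scatterSpectraAtDepth()`), the
  distances at which dose is reported.  The infinite-medium cascade
  fluence spectrum is markedly softer (it is dominated by aged photons far
  from their release) and would overstate the bone absorption correction;
  evaluating coefficients over the clinically relevant distance range
  follows the same logic as the `fitCoeffsOverDistance()` update for
  primary coefficients, which replaces single-depth spectral averages by
  effective values fitted over a 0-10 cm range (11 radii, unweighted least
  squares on the transmission).

The `chi`/`eta` factors are per-medium constants of a run: the engine
deliberately does not model spatial evolution of the scatter spectrum
(spectrum hardening inside a heterogeneity), consistent with the
one-kernel-plus-scaling architecture.  This is the main known limitation:
inside and just behind a strong absorber the true low-energy field is
depleted, so a single global `chi_msc` over-corrects slightly there, and
profiles through bone show a rounded shape with interface underestimation
relative to Monte Carlo.

## Physics data

Elemental interaction coefficients (H, C, N, O, Na, Mg, P, S, Ar, Ca;
1 keV-1.5 MeV, 160-point log grid, log-log interpolation clamped at the
grid ends) come from the package's analytic cross-section model:

* incoherent scattering: exact free-electron Klein-Nishina total and
  energy-transfer cross sections, integrated numerically over angle;
* photoelectric absorption: `1.27586e-22 Z^4 E_keV^-3.5513
  (1 + 7.31968 E/mec2)` cm^2 per atom;
* coherent scattering: `7.50275e-24 Z^2.5 E_keV^-2.11943` cm^2 per atom.

The two parametrized terms were calibrated once against published water
attenuation/absorption values (residuals 0.2% in `mu/rho`, about 3% in
`muen/rho`) and bone-to-water absorption ratios in the 50-150 keV range;
air values reproduce published numbers to better than 1%.  Radiative
losses are neglected (`muen = mutr`), appropriate below 1.5 MeV in low-Z
media with electron transport disabled.  The same tables drive the engine,
the kernel generation and the Monte Carlo reference, so engine-vs-MC
comparisons isolate transport-algorithm differences rather than
cross-section differences.  The model omits binding effects (incoherent
scattering function, Doppler broadening), atomic form factors (coherent
scattering samples the Thomson distribution) and absorption edges — all
below 5 keV for these elements and immaterial for an Ir-192 field — so
absolute doses are approximate even though the internal comparison is
consistent.

The packaged Ir-192 spectrum is a bare-point-source line spectrum
(27 lines, 65 keV-1.38 MeV, emission probabilities normalized to unit
sum).  Source encapsulation, self-absorption and the line-source geometry
of a real HDR source are not modeled; profile normalization against a
full water-geometry formalism is replaced by a homogeneous-water run of
the same engine or reference.

## Monte Carlo reference

The reference is a photon-only random walk sharing the phantom, source
and coefficient tables with the engine.  Scatter generations are tracked
with a bookkeeping number: source photons start at 0 and every photon
produced in a photon interaction gets its parent's number plus one
(`assignBkn()`; whether elastic Rayleigh scattering increments is
configurable, the default applies the rule literally).  Collision kerma —
the dose surrogate when electron transport is disabled — is scored per
voxel into the classes prim/1sc/msc by a track-length estimator.  With
forcing enabled, primary flights use expected-value scoring — the
analytically attenuated fluence is integrated over the entire flight ray,
which removes nearly all primary variance — and their collisions are
forced to occur inside the phantom by weight multiplication with
`1 - exp(-tau_max)`; scattered flights sample analog free paths with
literal track-length scoring, which touches far fewer voxels per flight.
Photoelectric absorption becomes survival weighting and photons below 10%
weight undergo Russian roulette.  The walk is
deterministic for a fixed seed (own xoshiro256** stream, independent of
R's RNG) and tallies merge associatively across seeds.

Type A uncertainties use history-by-history statistics.  Region means and
their uncertainties are exact for regions registered before the run
(per-history region sums); post-hoc masks fall back to per-voxel variances
that ignore inter-voxel correlation and are only exact for single voxels.

## Benchmark cases and the desk-scale profile

The benchmark geometry is a cubic water phantom with the point source at
the center of the central voxel and a 2.1 x 2.1 x 3.1 cm^3 box
heterogeneity on the +x axis, its long axis along z: cortical bone
centered 6 cm (Case A) or 3 cm (Case B) from the source, or dry air at
3 cm (Case C).  At the full resolution (0.1 cm voxels, 30.1 cm side)
every box face lies exactly on a voxel boundary and the box contains
21 x 21 x 31 = 13671 voxels.

The packaged desk-scale profile (`deskScaleProfile()`) uses 0.25 cm
voxels on a 30.25 cm phantom with 320/72 transport directions and a
2e6-history forced reference.  Two deliberate geometry choices follow
from the coarser grid:

* box faces are snapped to the nearest voxel boundaries
  (2.25 x 2.25 x 3.25 cm^3, 9 x 9 x 13 = 1053 voxels), preserving the
  rule that no voxel straddles a media boundary;
* the phantom side is kept at full scale rather than cut down to a
  minimal grid, because the low-energy multiple-scatter bath around the
  heterogeneity is fed by backscatter from the surrounding water.
  Shrinking the water margin beyond the box measurably hardens the local
  multiple-scatter field and suppresses the very bone-absorption effect
  the benchmark is designed to exhibit: the box-mean multiple-scatter
  kerma enhancement of the bone case over a water box, measured with the
  internal reference, falls from 1.53 at full phantom size to 1.45 when
  the side is reduced to 16 cm, and the multiple-scatter fraction of the
  total dose at the box falls from 0.34 to 0.27.

These problem sizes keep a full three-case benchmark (two engine modes
plus the reference per case) within about ten minutes on one CPU.  What a passing desk-scale comparison shows is that the corrected
transport moves the engine toward the generation-resolved reference in
heterogeneous media *within a consistent physics world*; it does not
establish absolute dosimetric accuracy against measured data or
production-grade Monte Carlo physics (binding effects, encapsulated
source, 0.1 cm resolution), and the published full-scale deviations are
reproduced only in sign and approximate magnitude.

## Comparison layer

`deltaMap()` forms the percentage dose difference ratio
`100 (D_gen^engine - D_gen^MC) / D_tot^MC` — the denominator is always the
*total* reference dose, so the component maps add exactly to the total
map.  `regionStats()` reports mean, SD, median and Fisher skewness over a
region (the box interior via `boxMask()`), `deltaHistogram()` uses
0.5-point bins normalized to integral 100, and `doseProfile()` extracts
the y = z = 0 line normalized to a homogeneous-water reference with the
source voxel masked.  `deskScaleRun()` bundles a full case and returns
the per-mode, per-generation statistics table.

## Numerical choices

* Voxel traversal is an exact incremental grid-crossing walk; optical
  depths are sums of crossing lengths times local linear attenuation.
* The source voxel's primary dose uses the finite-volume average of
  `1/(4 pi d^2)` over the voxel (midpoint quadrature of the unit-cube
  integral, cached) instead of the singular center value, and is flagged.
* `eps` and `(1 - eps)/(eta c)` are evaluated with `expm1` per
  direction/medium/cone (step lengths are constant per direction), which
  is exact for near-transparent media such as air (`eta ~ 1e-3`).
* Negative recursion brackets cannot occur analytically; a diagnostic
  clamp counter is kept regardless.
* Kernel-fit candidates are profiled over a fixed log grid of decay
  constants, so results are reproducible to the last bit for a given
  tally.
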