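# ccbrachy

A successive-scattering collapsed-cone dose engine for HDR ¹⁹²Ir
brachytherapy, with a corrected multiple-scatter transport and a built-in
generation-resolved photon Monte Carlo reference.

## Who this is for

Medical-physics researchers studying model-based dose calculation
algorithms (MBDCA) for brachytherapy: the package provides a complete,
inspectable implementation of a collapsed-cone point-kernel engine that
separates the total dose by photon scatter generation — primary, first
scatter (1sc) and multiple scatter (msc) — together with the Monte Carlo
machinery needed to verify it, on voxel phantoms with heterogeneities such
as cortical bone or air.

## The algorithm

The primary dose is computed by analytic ray tracing of the source
spectrum; the energy each generation releases into the next
(the *scerma*) is transported by collapsed-cone superposition: energy
released into a discrete cone is carried and absorbed on the cone axis.
Along each transport line, for each kernel term (the msc kernel is
bi-exponential, `C e^{-cr} + F e^{-fr}` per polar cone), an effective
energy fluence `R̂` is iterated over the steps `j`:

    ε_j   = exp(−η_j c Δl),          σ_j = S_j ρ_j ΔΩ C / c,
    ΔR̂_j = σ_j (1 − ε_j)/(η_j c),
    bracket_j = (1 − ε_j) R̂_{j−1} + σ_j Δl − ΔR̂_j

where `η_j` is the voxel medium's spectrum-averaged linear attenuation
ratio to water.  The **original** transport deposits
`bracket_j/(Δl_max ρ_j)` and forwards `R̂_j = R̂_{j−1} ε_j + ΔR̂_j`: local
absorption is tied to *attenuation*, which underdoses media (bone) whose
energy-absorption ratio to water, `χ_j`, exceeds `η_j` in the soft
multiple-scatter field.  The **corrected** transport scales the step dose
by `χ_j/η_j` and forwards the balance
`R̂_j = R̂_{j−1} ε_j + ΔR̂_j + (1 − χ_j/η_j)·bracket_j`, so extra locally
absorbed energy is removed from the energy carried downstream.  Both modes
conserve energy exactly at every step, and coincide bit-for-bit in water.

Everything needed to run and check the engine ships with the package:
embedded elemental cross-section tables (1 keV–1.5 MeV), an ¹⁹²Ir line
spectrum, forced-interaction kernel generation with constrained
bi-exponential fitting, benchmark phantom builders, a photon-only Monte
Carlo reference with scatter-generation bookkeeping (`bkn`) and collision
kerma scoring, and a comparison layer producing percentage dose difference
ratio maps `Δ_gen = 100 (D_gen^engine − D_gen^MC)/D_tot^MC` with region
statistics, histograms and profiles.  See the methods vignette
(`vignettes/collapsed-cone-engine.Rmd`) for models, assumptions and
numerical choices.

## Worked example

Build the bone-heterogeneity benchmark (Case A: a cortical-bone box
centered 6 cm from the source in a 30 cm water cube; at the desk-scale
0.25 cm grid the canonical 2.1×2.1×3.1 cm³ box snaps to
2.25×2.25×3.25 cm³), run both engine modes and the Monte Carlo reference,
and compare over the box voxels:

```r
library(ccbrachy)

run <- deskScaleRun("A", seed = 1,
                    config = deskScaleProfile(nHistories = 2e6))
subset(run$stats, gen %in% c("msc", "tot"),
       select = c(mode, gen, mean, sd, median))
```

```
      mode gen    mean    sd median
  original msc -12.766  4.38 -12.87
  original tot -10.981 14.10 -13.92
 corrected msc  -1.640  5.79  -2.17
 corrected tot   0.145 14.96  -3.31
```

Read: in the bone box the uncorrected engine underdoses the
multiple-scatter component by ≈12.8% of the local total reference dose
(mean Δ̄_msc = −12.8) and the total dose by ≈11%; the corrected transport
removes the deficit almost entirely (Δ̄_msc = −1.6, Δ̄_tot = +0.1).  The
per-voxel spread (`sd`) is dominated by the collapsed-cone discretization
spikes of the first-scatter component.  `run$engine` holds the two
`DoseComponents` objects, `run$mc` the `KermaTally`;
`deltaMap()`, `deltaHistogram()` and `doseProfile()` work from those
directly.

A command-line driver with `makecase`, `makekernels`, `run` and `compare`
subcommands is installed under `inst/scripts/ccbrachy`.

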