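---
title: "Active marrow dosimetry with marrowdose: models, assumptions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active marrow dosimetry with marrowdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowdose)
```

## The problem

Bone marrow is a dose-limiting organ in radionuclide therapy with
beta-emitters such as lutetium-177, terbium-161 and yttrium-90. The
radiosensitive target is the *active marrow* (AM) — the hematopoietically
active tissue inside the spongiosa of trabecular bone — interleaved at the
50-micrometre scale with inactive (adipocyte-rich) marrow (IM) and bone.
Electrons emitted inside these cavities do not deposit all of their energy
in AM, so the flat-organ approximation (absorbed fraction of one) fails
badly, and it fails differently for different radionuclides: terbium-161
emits roughly twelve conversion/Auger electrons below 50 keV per decay whose
ranges are microns, while yttrium-90 betas average close to one MeV and
cross many cavities.

`marrowdose` implements the full small-scale dosimetry chain:

1. per-decay electron emission spectra from decay-scheme constants,
2. specific absorbed fraction (SAF) tables per skeletal site, source
   compartment and marrow cellularity,
3. S-values (absorbed dose per decay, mGy/MBq-s) by spectrum–SAF
   convolution, with skeletal, spongiosa and cellularity averaging,
4. a condensed-history Monte Carlo electron transport simulator for
   voxel-scale energy deposition.

## Emission spectra

Continuous spectra are built per beta branch from Fermi theory,

$$N(E)\,dE \propto p\,W\,(W_0 - W)^2\, F(Z, W)\, C(W)\, dE,$$

with the relativistic point-charge Coulomb correction $F$ (Lanczos complex
gamma; nuclear radius $1.2\,A^{1/3}$ fm) and the shape factor
$C = q^2 + p^2$ for unique first-forbidden transitions (the yttrium-90
ground-state branch). Each branch is normalised so its integral equals the
branching fraction; discrete conversion/Auger lines are kept exact and are
never histogrammed onto the grid, so micron-range Auger energies are not
smeared.

The bundled decay constants (endpoints, branch fractions, principal line
energies at the known conversion edges) are calibrated so that the per-decay
summaries — mean beta energies 133/154/933 keV, total electron energies
148.0/202.5/933.1 keV per decay, and conversion/Auger counts below 50 keV —
match the ICRP-107 reference values for the three nuclides to well within
3%. Users holding the licensed ICRP-107 dataset can export its records into
the decay dialect (`read_decay_table()`) and use them directly. Photons are
deliberately excluded everywhere: all S-values and deposition fractions are
electron-only, which understates total dose for the gamma-emitting nuclides
and is the standard convention for these bone models.

The default beta grid is 1 keV bins from 0.5 keV to the largest endpoint —
finer than any SAF grid, so quadrature error is negligible against SAF
uncertainty. A toy allowed branch with the Coulomb correction switched off
(`daughter_Z = 0`) reproduces an independent $10^5$-point quadrature of
$p\,W\,(W_0-W)^2$ to 0.1%, which the test suite asserts.

## SAF tables and interpolation

SAF tables give $\Phi(E)$ in kg$^{-1}$ for the AM target per skeletal site,
source compartment (AM, IM, trabecular bone volume TBV or surface TBS) and
cellularity, on monoenergetic grids spanning 1–$10^4$ keV (male) or
10–$10^4$ keV (female). Between grid points we interpolate log-log linearly:
exact for power-law segments, positive by construction, and monotone between
nodes. Below the grid minimum the value is clamped to the edge: an electron
below 10 keV has a range under 2.5 um, far below the 50 um resolution of the
source models, so the SAF is effectively saturated there. This policy
matters for terbium-161 on the female grid (many lines below 10 keV) and is
a package choice, not something the source data dictate. Above $10^4$ keV
(never reached by these spectra) the edge value is used likewise.

Validation on assembly rejects non-monotone grids, negative SAFs, missing
(site, source) pairs, and any self-irradiation table whose implied absorbed
fraction $\Phi \times m_{AM}$ exceeds 1.05 at any energy.

Cellularity — the active fraction of the marrow volume,
$1 - V_{IM}/(V_{AM}+V_{IM})$ — is defined on volumes; we take AM and IM mass
densities equal (1.03 g/cm$^3$), so mass and volume fractions coincide and
the mass table drives everything.

## S-values and averaging

For one nuclide against one SAF table,

$$S = 10^9 \left[\sum_i y_i E_i \Phi(E_i) + \int n(E)\,E\,\Phi(E)\,dE\right]
\quad \text{(mGy/MBq-s)},$$

with energies in joules via $1.602176634\times10^{-16}$ J/keV and the
integral by the trapezoid rule on the beta grid. Skeletal averages weight
each site by the product of its target-mass and source-mass fractions
(cross-site irradiation neglected, so weights need not sum to one); the TBS
surface source carries the trabecular bone mass, since a surface has no mass
of its own — a package decision where the convention is ambiguous. The
spongiosa S-value mass-weights the skeletal-averaged AM, IM and TBS sources
by $m_{src}/m_{spongiosa}$.

The engine is continuously checked against an independent brute-force oracle
(all emissions merged onto a $10^5$-point list, summed term by term) to
0.1%, and all averaging formulas against hand-evaluated two-site and
equal-mass cases exactly.

## The synthetic skeleton

No real SAF supplement can be redistributed, so the generator builds a
structurally faithful stand-in: 13 sites with masses drawn around the adult
reference AM distribution, self-SAFs as a plateau $(1-\text{leak})/m_{AM}$
times a smooth roll-off $1/(1+(E/E_0)^p)$ with $E_0 \in [300, 500]$ keV and
$p \in [1.1, 1.4]$ (chosen so MeV electrons still deposit a realistic
fraction in mm-scale cavities), and cross-compartment SAFs as the self shape
damped by $1-e^{-E/E_{rise}}$ with amplitudes 0.65/0.45/0.30 and rise scales
40/80/150 keV for TBS/IM/TBV. Amplitudes descend and rise scales ascend, so
the physical source ordering AM > TBS > IM > TBV holds pointwise in energy
and hence for *any* emission spectrum. Cellularity-varied self tables scale
by $w(E) + (1-w(E))\,c_{ref}/c$ with $w(E) = w_{max} E/(E+E_w)$
($w_{max}=0.85$, $E_w=60$ keV): at low energy the SAF goes as $1/c$ (fewer
AM voxels absorb the same local energy), at high energy the dependence
weakens. The low-energy-emitter-most-affected cellularity pattern then
emerges from the energy mix, not from anything nuclide-specific.

What the synthetic corpus does *not* emulate: the magnitudes of any real
phantom, inter-site SAF correlations, and sex differences beyond the grid
minimum. Passing tests on it demonstrate correct bookkeeping, formulas,
orderings and scalings — not agreement with any published table, which
requires converting the published supplements via `ingest_saf_worksheet()`.

## Voxel-scale transport

The simulator is deliberately simple condensed-history CSDA transport:
electrons take steps of 5% of the residual range (capped at half a voxel
side), lose energy continuously along the step (deposited at the midpoint),
and scatter once per step by a Gaussian multiple-scattering angle from the
Rossi–Greisen scattering power $(13.6\,\text{MeV}/p\beta c)^2/X_0$. The
thin-step logarithmic correction of the Highland formula is omitted
deliberately: it is calibrated for a single slab, and applying it to every
micron-scale substep suppresses the accumulated deflection far below the
measured diffusivity of electron tracks in water. With the present form,
simulated monoenergetic point kernels put 50% of the energy within 0.42–0.45
of the CSDA range across 50–1000 keV, consistent with published scaled
kernels (~0.35–0.45); with the log term they came out near 0.6. No secondary
(delta-ray) transport is performed; the radiative share of each energy loss
is treated as escaping bremsstrahlung, so deposited energy runs 0.4–2% below
emitted. Stopping powers are a bundled 35-point log-spaced soft-tissue table
(collision + radiative, matching reference unit-density tabulations to a few
percent), density 1.03 g/cm$^3$, electrons absorbed below 1 keV.

Two source modes cover the published study designs: a point source at the
origin (radial profiles, 30/50/90% energy radii) and homogeneous activity in
a single voxel (the self-absorbed fraction of a 50 um model voxel or an
8.2 um stem-cell-sized voxel, with a delta-method standard error over
decays). With $10^5$ decays the three-nuclide self-absorbed fractions at
50 um reproduce the published 28.2/12.9/0.6% within the 15% band expected of
simplified transport, as do the terbium-161 values at 8.2 um. The published
8.2 um values for lutetium-177 (4.8%) and yttrium-90 (0.2%) are *not*
reproducible in this source geometry by any electron transport: for
yttrium-90, a mean length-biased chord of ~3.2 um at ~0.2 keV/um stops less
than 0.1% of 946 keV per decay even before delta-ray losses. We report our
honest values (~2.9% and ~0.09%) and flag the comparison; the original
tally definition at that scale is not recoverable from the description.

Default test runs use $10^4$–$10^5$ decays (the acceptance script uses
$2\times10^5$); the statistical error scales as $1/\sqrt{n}$ and is
asserted to do so.

## Numerical choices and edge cases

* keV to joules via the exact SI elementary charge; Gy/decay to mGy/MBq-s
  via $10^9$.
* Writers emit 15-significant-digit decimals; all bundled and generated
  values are short decimals, so every file round-trips byte-exactly
  (asserted for the whole corpus).
* Zero-yield branches give identically zero spectra; nuclides with no beta
  branches make `mean_beta_energy()` an error, not a NaN.
* Degenerate skeletons (single site, empty compartments) reduce to the
  obvious limits exactly; an all-zero tissue mass is an error.
* `interpolate_saf()` snaps queries landing exactly on grid points to the
  tabulated values, avoiding log round-trip error.

## Known limitations

* Electron-only: photon dose is out of scope and non-negligible for
  lutetium-177 and terbium-161 at the organ scale.
* The transport has no delta rays, no track-structure detail below 1 keV,
  and Gaussian-only scattering; its stated accuracy band is ±15% on
  voxel-scale deposition fractions.
* Decay constants are calibrated reconstructions of the reference per-decay
  summaries, not the licensed ICRP-107 records themselves; line-by-line
  energies can differ while summaries agree.
* Synthetic SAFs support verification, not clinical use; real supplements
  must be converted for quantitative skeletal S-values.
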