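---
title: "Methods: diffusion, solvation and hydration analysis in CarboDiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion, solvation and hydration analysis in CarboDiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CarboDiff)
```

CarboDiff analyzes the translational diffusion and hydration of
carbohydrates in aqueous solution. This vignette is the package's own
account of the models it implements, the parameters that matter, the
numerical choices made where the design was genuinely open, and the
limits of what the validation shows.

## Units and containers

Internally everything is in Å, ps, amu and K. Diffusion coefficients
cross the API boundary in 10⁻⁹ m²/s, the unit in which solution values
for small solutes are tabulated; the conversion 1 Å²/ps =
100 × 10⁻⁹ m²/s is exact and asserted by round-trip tests. Boltzmann's
constant is the SI-exact 1.380649 × 10⁻²³ J/K.

Trajectories (`Trajectory`) are arrays of per-frame coordinates with a
per-frame orthorhombic box; only orthorhombic cells are supported and
triclinic input is rejected at read time, since every system of interest
here is cubic. A `SystemMap` assigns atoms to solute copies and water
oxygens (1-based in R, 0-based in the on-disk grouping format, which is
stated in the format's header line). A `SolventModel` carries the
viscosity and temperature entering all hydrodynamic conversions;
built-ins are experimental water (η = 0.00089 kg m⁻¹ s⁻¹), TIP5P
(0.0007) and OPC (0.00079), all at 298 K — literature viscosities of
those water models, not quantities this package estimates.

## Diffusion from mean squared displacement

For free diffusion in three dimensions ⟨Δr²(t)⟩ = 6Dt.
`computeMSD()` averages squared center-of-mass displacements over all
solute copies and, by default, over all time origins. Multi-origin
averaging is the variance-optimal standard; a `multiOrigin = FALSE`
switch restricts to the single origin t = 0 for fidelity to the literal
single-origin displacement sum. The displacement entering the average is
the squared norm Δr²; an outer square of that quantity would have units
Å⁴ and be inconsistent with a 6D slope, so the estimator is defined as
the mean of squared displacements.

`fitDiffusion()` extracts D = slope/6 by ordinary least squares with a
free intercept. Design choices here:

- **Fit window.** Default 10–50% of the maximum lag. Short lags carry
  non-diffusive transients and intercept effects; lags beyond half the
  series have few origins and large variance. Both bounds are
  configurable, and weighted or through-origin fits are available as
  options.
- **Replicates.** MSD curves are averaged across replicates
  (`averageMSD()`) before the fit, and per-replicate fits are retained:
  the regression standard error of the pooled fit understates the
  true uncertainty because residuals at successive lags are strongly
  correlated, so the replicate-to-replicate standard deviation is the
  honest dispersion estimate. Pairwise comparisons of replicate-level
  estimates use Welch's two-tailed t test (`welchT()`), which does not
  assume equal variances.
- **Drift removal.** Subtracting the net system center-of-mass motion is
  available (`removeDrift = TRUE`) but off by default; with no external
  forces the net drift of a well-prepared system is negligible, and
  silently altering displacements is worse than documenting the switch.
- **Wrapped input.** MSD on wrapped coordinates is meaningless, so
  center-of-mass jumps exceeding half a box length raise an error
  directing the user to `unwrapTrajectory()`, which accumulates
  minimum-image inter-frame displacements. Unwrapping assumes no true
  displacement reaches half a box between saved frames — comfortably
  satisfied at 10 ps saving intervals for solutes with D of order
  10⁻⁹ m²/s.

`stokesEinstein()` converts between D and the hydrodynamic radius via
D = k_BT/(6πηR_H); the relation is its own inverse and the round trip is
exact. `finiteBoxCorrection()` adds the leading periodic-boundary
correction k_BTξ/(6πηL), ξ = 2.837297 for a cubic lattice. It is offered
as an explicit, optional operation because simulated D values at the
system sizes of interest have been reported insensitive to it; applying
it is a user decision, not a default.

## Solvation structure

`computeRDF()` histograms minimum-image distances from the solute's
*geometric* (unweighted) center to all water oxygens — the mass-weighted
center is available as an option but the geometric center is the
convention for these profiles — normalized by spherical shell volume and
by ρ = n_waters/V_box, and averaged over frames. The default bin width
is 0.05 Å; published peak statistics carry ±0.06 Å uncertainties, so
bins finer than that add noise, not information.

Because first-shell extrema read off a raw histogram jump between
adjacent bins, `firstShellStats()` locates the first interior maximum
and the following minimum on a Savitzky–Golay-smoothed copy of the curve
(cubic, default 11-bin window) and reports the raw-curve values at those
positions; profiles with no interior structure raise an error rather
than returning a fabricated shell. `integrateN1()` evaluates
N1 = 4πρ∫₀^rmin g(r)r²dr by trapezoidal quadrature on the raw curve by
default (the smoothed curve is an option); whether published
coordination numbers used raw or smoothed profiles is not stated
anywhere we could anchor to, so raw is the default as the assumption-free
choice.

`occupancyMap()` deposits, per frame and per water oxygen, a normalized
3-D Gaussian onto a voxel grid centered on the solute (default 0.25 Å
spacing, 25 Å cube, i.e. 100³ voxels). Frames are first superposed on
the solute — translation always, rotation by Kabsch least-squares when
the solute has ≥3 atoms — because the density of interest is the water
structure in the solute frame; superposition can be switched off.
The deposition width σ defaults to 1.0 Å, of the order of a water
oxygen van der Waals radius; the tool that popularized these maps does
not document its default, so σ is exposed as a parameter. Each deposit
is normalized to unit mass, so voxel sum × voxel volume equals the mean
water count inside the grid (asserted to 10⁻³ in tests). The 3.6/3.8/4.0%
display cutoffs are attached to written grids as metadata only —
rendering is not this package's concern.

## Aggregation kinetics

A contact is a minimum-image nearest-atom distance ≤ 2.85 Å between two
solute copies (the minimum O–O distance in liquid methanol, a
hydrogen-bond contact scale). All atoms participate by default
(`heavyOnly` excludes hydrogens). An aggregate is a connected component
of the per-frame contact graph.

The persistence rule — contacts must survive at least two consecutive
frames — is ambiguous as a phrase: applied to edges, to components, or
to membership sets, it yields different bookkeeping. CarboDiff defines
an **aggregate event** as a maximal run of consecutive frames over which
an *identical* membership set is a connected component; any gain or loss
of a member ends the event and starts a new one. Events shorter than
`minPersistenceFrames` (default 2) are discarded from the aggregate
statistics. This membership-run semantics makes lifetimes well-defined
and reproducible; it is a declared convention, not the only possible
reading.

Free-monomer concentrations are computed from raw per-frame singleton
counts, *not* reduced by solutes in discarded short events. This keeps
the per-frame conservation law — free monomers plus aggregate members
equal the total solute count — exact and independent of the persistence
filter, at the cost of a convention choice where the source phrasing is
silent. Lifetimes are event length × frame interval (ns); sizes are
summarized by the event-frame-weighted mean S; concentrations use
`concentrationMM()` with the mean box volume.

## The hydration model

The empirical layer treats the hydrodynamic sphere as the bare solute
sphere plus its tightly entrained waters:

- N_W = (4/3)π(R_H³ − R_g³)/V_W, with V_W = 30 Å³ per water;
- inverted, R_H = (3V_W N/(4π) + R_g³)^{1/3}, with N ≈ 1.1 waters per
  polar atom;
- composed with Stokes–Einstein in experimental water
  (η = 0.00089 kg m⁻¹ s⁻¹ — the empirical prediction targets experiment,
  so the experimental viscosity is the default, overridable per
  `SolventModel`).

The two relations are exact algebraic inverses, property-tested to
10⁻¹². Negative N_W (R_H < R_g) is reported with a warning rather than
clamped: for extended polymers such as dextran or hyaluronic acid R_g
can exceed R_H and the spherical-envelope picture simply does not apply;
a silent floor at zero would hide exactly the failure the diagnostic
should expose.

Polar atoms are oxygens, with carboxylate, amide and ester groups
contributing two each (`polarAtomCount()`). The packaged polar-atom
table carries the printed counts where a published value exists and
footnote-rule-derived counts elsewhere, each derived row flagged in its
`provenance` column. Two counting wrinkles deserve note. First, the
printed counts are internally inconsistent about glycosidic oxygens
(some disaccharides counted at 10, others at 11, though all contain 11
oxygens); the table stores the printed values verbatim and does not
"correct" them. Second, for the tetra-O-acetylated glucoside the
all-oxygen rule (4 esters × 2 + ring O + methyl-ether O = 10) is
inconsistent with the published empirical diffusion value, which is only
recovered with a count of 9; the shipped table therefore uses 9 — the
ester-plus-ring-oxygen count with the methyl ether excluded — and says
so in its provenance note. With the shipped counts, 16 of the 18
published empirical cells are reproduced exactly at 2-decimal rounding
(the two trisaccharides differ by 0.01, an artifact of recomputing from
inputs that were themselves printed rounded).

The default R_g source for prediction is the TIP5P column of the radii
table; the TIP5P and OPC columns agree to 0.01 Å throughout, so the
choice is immaterial and configurable.

## Synthetic data: what it emulates and what it does not

The generators replace molecular dynamics as the source of test inputs;
their defaults *are* the reference study conditions and are not tuned
per test:

- `simulateBrownian()`: 20 single-pseudo-atom solutes in a cubic
  664,424 Å³ box (50 mM), frames every 10 ps, 1000 frames (10 ns) per
  replicate, each solute an independent Gaussian walk with per-dimension
  step variance 2DΔt — the exact increment law of free diffusion. Steps
  with σ ≥ L/4 are refused (unwrapping would be ambiguous).
- `generateIdealSolvent()`: i.i.d. uniform water-oxygen positions, the
  null model with g(r) ≡ 1 and N1 = (4/3)πρr³ exactly.
- `generateAggregateFixture()`: rigid two-atom solutes arranged into
  chains with intra-cluster nearest-atom distances exactly equal to the
  requested contact distance and inter-cluster gaps at least the
  requested separation, with a per-cluster frame pattern controlling
  when each cluster exists. Size distributions, lifetimes and
  free-monomer counts are therefore known exactly by construction.
- `rigidBody()`: point sets carrying their analytic
  R_g = √(Σmᵢ|rᵢ−r_com|²/Σmᵢ).

All generators are pure functions of their seed. What passing tests on
these inputs show is that the *estimators* are correct: the MSD
machinery recovers a known D within 5% under the study's sampling
geometry; the RDF machinery is correctly normalized; the aggregation
bookkeeping is exact. What they cannot show is anything about force
fields or real water: there is no solute–solvent interaction, no
hydrodynamic coupling between solutes, and no real solvation structure
in the synthetic data. Reproducing published simulation observables that
depend on those physics (absolute first-shell statistics, aggregate
concentrations of real carbohydrates) is explicitly out of scope.

## Problem sizes and numerical tolerances in the test suite

The validation suite runs at the following scales, chosen to make the
statistical assertions comfortable rather than knife-edge: diffusion
recovery at the full study geometry (20 solutes × 10 replicates × 2000
frames, every second lag evaluated) for D ∈ {0.2, 0.62, 1.0} × 10⁻⁹
m²/s with a 5% acceptance band (replicate-mean standard error ≈ 2–3%);
RDF flatness from 48 reference points × 100 frames at unit number
density with 0.25 Å bins (per-bin counting error ≤ 0.4%, asserted
within 2%); N1 against the closed form from 8000 waters × 800 frames at
0.05 Å bins (counting error < 0.3%, asserted within 1%); aggregation
against brute-force all-pairs/all-images oracles on 100 random
configurations. Algebraic identities (round trips, analytic R_g) are
asserted at 10⁻⁹–10⁻¹².

## Known limitations

- Orthorhombic (in practice cubic) cells only.
- The spherical-envelope hydration model is inappropriate for large or
  extended polysaccharides, where R_H ≈ R_g or even R_g > R_H; the
  package reports the diagnostic negative N_W but offers no
  shape-anisotropy correction.
- Rotational diffusion, Green–Kubo estimators and water-model viscosity
  calculations are out of scope; viscosities are inputs.
- The persistence and free-monomer conventions above are declared
  choices among defensible readings; results are reproducible under
  them, and the alternatives are reachable through the exposed
  parameters.
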