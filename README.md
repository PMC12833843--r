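# CarboDiff

Translational diffusion and hydration analysis of carbohydrates in aqueous
solution, from multi-frame trajectories and from a fast empirical model.

Carbohydrate diffusion coefficients (*D*) are measured by DOSY NMR and
predicted by molecular simulation, but converged simulated *D* values
require microseconds of replicate sampling. CarboDiff implements the full
analysis chain a practitioner needs on the simulation side — and the
empirical shortcut that bypasses it:

- **MSD → D**: mean squared displacement of solute centers of mass
  (multi-origin or single-origin), linear regression of
  ⟨Δr²(t)⟩ = 6Dt, replicate averaging, and Welch comparisons of
  replicate estimates; an optional finite periodic-box (Yeh-type)
  correction ΔD = k_B T ξ/(6πηL), ξ = 2.837297.
- **Stokes–Einstein**: D = k_B T/(6πη R_H) conversions between diffusion
  coefficient and hydrodynamic radius for experimental water
  (η = 0.00089 kg/m·s), TIP5P (0.0007) and OPC (0.00079) at 298 K.
- **Solvation structure**: radial distribution function g(r) from the
  solute geometric center to water oxygens, first-shell statistics, the
  coordination number N1 = 4πρ∫₀^rmin g(r) r² dr, and Gaussian-weighted
  water occupancy grids (cube/OpenDX output).
- **Aggregation kinetics**: solute–solute contacts under the 2.85 Å
  minimum-image nearest-atom criterion, connected-component aggregates,
  a two-frame persistence filter, event lifetimes τ, mean size S, and
  free-monomer concentrations in mM.
- **Hydration model**: entrained-water counts
  N_W = (4/3)π(R_H³ − R_g³)/V_W with V_W = 30 Å³, the inverse predictor
  R_H = (3 V_W N/(4π) + R_g³)^{1/3} with N ≈ 1.1 waters per polar atom,
  and MAE scoring against experimental diffusion coefficients for 18
  carbohydrates (packaged reference tables).
- **Synthetic ground truth**: a Brownian-dynamics generator (20 solutes,
  50 mM in a 664,424 Å³ periodic cell by default), ideal-gas solvent
  configurations, and constructed aggregate fixtures with exactly known
  size distributions and lifetimes, so every estimator is validated
  against known answers.

## Worked example

Glucose, using the packaged reference radii (R_H = 3.93 Å by DOSY,
R_g = 2.64 Å from simulation) and its 6 polar oxygens:

```r
library(CarboDiff)
rad <- loadFixture("radii")
glc <- rad[rad$name == "Glc", ]

entrainedWaters(glc$rh_dosy, glc$rg_tip5p)  # 5.9 entrained waters
predictRH(glc$rg_tip5p, 1.1 * 6)            # 4.03 A predicted R_H
predictD(glc$rg_tip5p, 6)                   # 0.61 x 1e-9 m^2/s
```

The entrained-water count (5.9) tracks the experimental hydration number
of glucose (7.41); the predicted *D* (0.61) sits within 0.02 of the DOSY
value (0.63 × 10⁻⁹ m²/s). Reconstructing the whole 18-carbohydrate
empirical column from radii of gyration and polar-atom counts alone:

```r
rep <- reproduceTables()
rep$nMatched                    # 16 of 18 printed cells at 2 decimals
rep$diffusionMAE$empirical$mae  # 0.02 vs DOSY (TIP5P: 0.05, OPC: 0.04)
```

Estimating *D* from a trajectory with known ground truth (0.62):

```r
sim <- simulateBrownian(brownianSpec(nSolutes = 20, DTrue = 0.62,
                                     nFrames = 1000, seed = 5))
traj <- unwrapTrajectory(sim$trajectory, sim$map)
fitDiffusion(computeMSD(traj, sim$map))
#> DiffusionEstimate: D = 0.5718 +/- 0.0003 x 1e-9 m^2/s
#>   fit window: 499.0 - 2495.0 ps (3-dimensional)
```

A single 10 ns replicate lands within ~8% of truth; averaging the MSD
over 10 replicates with `averageMSD()` before fitting brings recovery
within 5% (the quoted regression standard error reflects residual
scatter about the line, not the dominant replicate-to-replicate
variance — hence the replicate machinery).

A command-line front end covering the same stages
(`synth`, `msd`, `fitd`, `rdf`, `volmap`, `aggregates`, `hydration`,
`predict`, `reproduce-tables`) is installed at
`inst/exec/carbodiff`; every output file records the seed and a config
digest in its header.

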