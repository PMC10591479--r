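# tubexciton

Exciton spectra and self-assembly kinetics of double-walled molecular
nanotubes.

Amphiphilic cyanine dyes (e.g. C8S3) self-assemble into double-walled
nanotubes: an inner wall (IW, ~6.9 nm diameter) inside an outer wall (OW,
~13.5 nm). After a solvent jump dissolves the OW, the intact IW templates
its recovery. `tubexciton` is a toolkit for studying *how* that recovery
proceeds — whether adsorbing molecules align immediately with the global
lattice orientation, or first form locally ordered, mutually misoriented
**patches** that anneal later — using the spectroscopic observables that
discriminate the two pictures.

The package implements, end to end:

* **Synthetic geometry** — 2D brickwork lattices rolled into concentric
  cylinders, patchwork outer walls, and a seeded stochastic model of
  outer-wall recovery (`build_lattice()`, `roll_to_cylinder()`,
  `generate_patchwork()`, `simulate_assembly()`).
* **Frenkel exciton spectra** — for molecules with positions r_n and unit
  transition dipoles d_n, the Hamiltonian
  `H = sum_n (nu_n - delta)|n><n| + sum_{n!=m} J_nm |n><m|` with site
  energies `nu_n ~ N(nu0 = 19,498 cm^-1, sigma = 231 cm^-1)`,
  gas-to-crystal shift `delta = 350 cm^-1`, and extended-dipole couplings
  `J_nm = alpha (mu/l)^2 sum_{ss'} ss'/r_nm^{ss'}` (charges q = 0.34 e at
  l = 7 Å, |mu| = q·l = 11.4 D). Disorder-averaged polarized absorption,
  `LD = A_par - A_perp` and reduced LD `LD_r = LD/A_iso` follow from the
  eigenstates (`full_spectrum()`, `stick_spectrum()`).
* **Patch identification** — DBSCAN (eps = 0.2, min_pts = 2) on the
  regularized 6-D position + orientation features (`identify_patches()`).
* **Kinetics** — empirical rate models: immediate ordering
  (`ld ∝ od`, monotone LD_r) versus delayed ordering (two-step sequential
  kinetics with ordering rate k_ord, non-monotone LD_r), fitted jointly to
  OD and LD by bounded least squares (`fit_kinetics()`).
* **Pipeline** — `run_pipeline()` chains
  generate → spectra → observables → patches → kinetics into one seeded,
  manifest-logged, bit-reproducible run. A thin CLI wrapper lives at
  `inst/scripts/pipeline.R`.

## Worked example

```r
library(tubexciton)
manifest <- run_pipeline(default_config(seed = 7), outdir = "run1")
round(manifest$timeseries, 3)
```

```
    t n_molecules    od    ld  ld_r
1   0         124 1.127 2.635 2.339
2   3         186 1.532 3.187 2.080
3   6         230 1.671 3.794 2.271
...
10 27         337 2.653 6.952 2.620
```

The OD (band-averaged isotropic absorbance) rises as monomers adsorb and
saturates. The reduced LD starts at the inner wall's value (2.34), **dips**
to 2.08 while the recovering outer wall is still a patchwork of randomly
oriented domains — material arrives faster than order — and then recovers
to 2.62 as patches reorient and merge. The patch summary shows the same
story structurally: 16 patches at early times annealing to 6, with the
largest domain growing from 23% to 85% of the outer wall:

```r
manifest$patch_summary   # t, n_molecules, n_patches, largest_fraction, f
manifest$fits$ordered     # sse = 0.175
manifest$fits$disordered  # sse = 0.121  <- delayed ordering fits better
```

The delayed-ordering ("disordered") rate model fits the OD/LD series
better than the immediate-ordering model — the spectroscopic fingerprint
of patchwork recovery.

All outputs (frames as 7-column text tables, per-frame spectra and the
time series as TSV, both fits, a JSON manifest with seeds and checksums)
are written to `outdir`; re-running the same configuration reproduces
them bit-for-bit.

See the vignette (`vignettes/nanotube-assembly.Rmd`) for the model
definitions, parameter meanings, design choices and limitations.

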