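# tidytraj

Tidy analysis of molecular-dynamics trajectories for comparing protein
variants — wild type versus point mutants — on identical structural and
energetic metrics.

The motivating use case is an enzyme–ligand–ion system such as
phospholipase Cζ (PLCζ) bound to the PIP₂ head group and its catalytic
Ca²⁺, where infertility-associated point mutations are assessed by how
they change ligand and ion binding. The package provides the full
analysis layer such a study needs, downstream of the MD engine:

* **Mobility** — mean-squared displacement
  MSD(τ) = ⟨|r(t+τ) − r(t)|²⟩ over particles and time origins, and the
  diffusion coefficient D = slope/(2d) from an ordinary least-squares
  fit of MSD versus lag, with superposed-frame mode for ligands bound in
  an active site.
* **Hydration** — radial distribution function
  g(r) = ⟨ρ(r)⟩/ρ_bulk of water around an ion, shell occupancies, and
  ion coordination counts (protein residues and waters within 3.5 Å).
* **Contacts** — hydrogen bonds (donor–acceptor < 3.5 Å, D–H···A within
  70° of linearity), salt bridges (anionic O to cationic N < 4.0 Å), and
  van der Waals contacts (|AB| < R_vdw(A) + R_vdw(B) + 0.5 Å between
  heavy atoms), with the total contact count defined as the sum of the
  three classes; intra-domain hydrogen bonds at 3.0 Å / 20°.
* **Geometry** — Kabsch superposition, per-domain backbone RMSD, radius
  of gyration, two-pass-fitted per-residue RMSF, and named residue–ligand
  distance series.
* **Energetics** — a simplified MM-GBSA-style endpoint estimator:
  ΔG = G(complex) − G(receptor) − G(ligand) with Coulomb + 12-6
  Lennard-Jones + pairwise generalized Born
  (f_GB = √(r² + aᵢaⱼ e^(−r²/4aᵢaⱼ))) + γ·SASA (Shrake–Rupley).
* **Statistics** — block-averaged means ± SEM for autocorrelated frame
  series, and a distribution-aware group comparison (KS normality gate,
  then one-way ANOVA or Kruskal–Wallis) with significance stars.
* **Synthetic ground truth** — seeded generators (Brownian particles,
  Ornstein–Uhlenbeck tethered ligands, ideal-gas water, exact
  hydrogen-bond scenes, discrete hydration shells, rigid-body proteins,
  group samples) so every estimator is validated against known answers.

Inputs are PDB/PQR structures and DCD or multi-model PDB trajectories
(read via bio3d). Everything user-facing returns tibbles, with
broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()` methods,
so results drop straight into dplyr/ggplot workflows.

## Worked example

```r
library(tidytraj)

# A ligand tethered in a binding site: stationary sd 1 Å per axis,
# so the long-lag MSD plateau is 6σ² = 6 Å².
ligand <- gen_ou_tethered(sigma = 1, tau_relax = 0.5, dt = 0.1,
                          n_frames = 2000, seed = 1, n_particles = 10)
prof <- compute_msd(ligand, 1:10, track_mode = "atoms", max_lag = 20)
head(prof, 3)
#>   lag_ns   msd n_pairs     sem
#> 1    0    0      20000 0
#> 2    0.1  1.08   19990 0.00685
#> 3    0.2  1.97   19980 0.0196
mean(prof$msd[prof$lag_ns > 10])
#> 6.1

# Hydration structure around an ion with two shells
shell <- gen_hydration_shell(list(c(2.55, 4), c(3.15, 9)), jitter = 0.08,
                             n_frames = 50, seed = 2)
rdf <- compute_rdf(shell, select_atoms(shell$topology, "ion"),
                   select_atoms(shell$topology, "water"), r_max = 8, dr = 0.1)
sort(rdf$r[order(rdf$g, decreasing = TRUE)][1:2])   # shell peaks
#> 2.55 3.15
shell_count(rdf, 3.5)   # waters inside the 3.5 Å coordination sphere
#> 13

# Compare a "wild-type" and a floppier "mutant" on radius of gyration
wt  <- compute_rg_series(gen_rigid_body_protein(60, n_frames = 150,
         per_residue_noise = 0.3, seed = 10), 1:60)
mut <- compute_rg_series(gen_rigid_body_protein(60, n_frames = 150,
         per_residue_noise = 0.6, seed = 11), 1:60)
glance(wt)$mean; glance(mut)$mean
#> 26.1 ; 26.1
glance(compare_groups(list(wt = wt$value, mutant = mut$value)))
#>   test_used statistic p_value stars n_groups
#> 1 anova          8.57 0.00369 **           2

# Printed-arithmetic identity: the total contact count is the sum of the
# hydrogen-bond, salt-bridge and van der Waals class means
total_contacts(c(hbond = 7.6, saltbridge = 0.6, vdw = 58.5))
#> 66.7
```

The first block says the tethered ligand's MSD rises from 0 and levels
off at ≈ 6 Å², the ensemble plateau for a σ = 1 Å tether — the signature
that distinguishes a bound ligand from free diffusion. The RDF block
recovers the two hydration-shell radii and the coordination count the
scene was built with. The comparison block shows the statistical layer:
two conditions with the same mean compactness but different flexibility
are distinguished by the variance-sensitive omnibus test.

A YAML-driven pipeline (`read_run_config()`, `run_stage()`,
`run_full_pipeline()`) runs any stage or the full multi-condition
comparison from files, writing CSV outputs with JSON metadata sidecars;
`inst/scripts/tidytraj-cli.R` is a thin command-line wrapper over it.

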