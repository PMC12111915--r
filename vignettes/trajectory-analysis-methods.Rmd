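---
title: "Methods: trajectory analysis for protein variant comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis for protein variant comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidytraj)
```

tidytraj implements the trajectory-analysis layer of a wild-type versus
point-mutant comparison study for a protein–ligand–ion system such as
PLCζ bound to the PIP₂ head group and its catalytic Ca²⁺: ligand and ion
mobility (MSD, diffusion coefficient), hydration structure around the ion
(radial distribution function, coordination counts), three-class contact
profiling between protein and ligand, per-domain structural metrics
(RMSD, radius of gyration, RMSF, named-pair distances), a simplified
endpoint binding-energy estimator, and the statistical layer that turns
per-frame series into means ± SEM and compares conditions. This vignette
records the models, the defaults and why, and the design choices that
were genuinely open.

## Units and conventions

Coordinates are in Å, time in ns, energies in kcal/mol. Residue ids keep
the numbering of the source file (PDB convention); atom indices are
1-based, the natural indexing in R. Only orthorhombic periodic boxes are
supported: every distance-based criterion uses the minimum-image
convention, and triclinic input is rejected with an explicit error rather
than silently mishandled.

All cutoff comparisons are strict (`<`). The source criteria mix strict
and non-strict bounds; on real-valued coordinates the boundary set has
measure zero, and a single convention keeps the production detectors and
their brute-force test oracles in exact integer agreement.

## Mean-squared displacement and diffusion

`compute_msd()` evaluates MSD(τ) = ⟨|r(t+τ) − r(t)|²⟩ over tracked
particles and multiple time origins (default: every frame is an origin;
`origin_stride` thins them). Uncertainties are block SEMs over 5
contiguous origin blocks, because consecutive origins are strongly
correlated. Displacements are taken on unwrapped coordinates — the
generators store wrapped and unwrapped sets side by side — or, when an
alignment selection is given, on coordinates superposed frame-by-frame
onto the first frame. The superposed mode is the right one for a *bound*
ligand: it removes global tumbling and drift so the MSD reflects motion
within the binding site. For a multi-atom ligand the tracked point is the
mass-weighted centre of mass by default (`track_mode = "atoms"` tracks
every atom); a single ion is tracked directly either way.

`fit_diffusion()` fits an ordinary least-squares line to MSD(τ) inside a
window given as fractions of the maximum lag, default 10–50%. The lower
edge discards the short-lag regime (ballistic/intra-well motion in real
data), the upper edge discards long lags where few origin pairs remain
and the estimate is noisy. D = slope/(2d) with dimensionality d = 3 by
default. The window, stride and dimensionality are recorded in the
pipeline's metadata sidecars because upstream tools do not document their
equivalents; these defaults are this package's own documented choices,
not reconstructions of any other tool's.

## Radial distribution function

`compute_rdf()` histograms minimum-image centre–target distances and
normalises each bin by the ideal-gas expectation ρ·4π/3·(r₂³−r₁³) with
ρ = N_target/V, averaged over frames and centres, so a homogeneous fluid
gives g(r) = 1. `r_max` must stay below half the smallest box edge (the
minimum-image sphere). `shell_count()` integrates the raw pair counts to
a radius, giving the mean neighbour count per centre — the quantity used
for first-shell occupancy.

## Geometry

`kabsch_superpose()` is the standard SVD solution of the weighted
least-squares superposition problem with the determinant correction, so a
proper rotation (det = +1) is always returned and mirror images keep a
positive residual RMSD. Collinear point sets are rejected: the rotation
about the line is not identifiable. Per-domain RMSD and Rg use backbone
atoms (N, CA, C, O) of the domain's residue range; the default domain map
(EF-hands 35–145, X–Y 155–465, C2 466–589) is user-overridable, and
residues outside every named range are excluded from per-domain metrics.

`compute_rmsf()` uses a two-pass mean-structure fit: align all frames to
the first, compute the mean structure, re-fit every frame to that mean,
recompute the mean, then take per-atom root-mean-square fluctuations
about it. Per-residue values are the mass-weighted mean of the residue's
atoms. A single-pass mode is kept for parity with simpler tools. Note a
small finite-size effect inherent to any fitted RMSF: the rigid-body fit
absorbs 6 degrees of freedom, so for N fitted atoms with isotropic noise
the measured RMSF runs a factor ≈ √(1 − 2/N) below √3·σ — about 2.5%
at N = 40.

Residue–ligand distances default to the minimum distance between heavy
atoms of the two selections (`mode = "com"` gives mass-weighted
centre-of-mass distances). The source figures name interactions like
"K297 … 4-OP4" without an atom convention; minimum heavy-atom distance is
this package's documented choice, and the mapping from phosphate labels
(1-OP4, 4-OP4, 5-OP4) to actual ligand atom names is a required
configuration table, referenced in selection expressions as `@4-OP4`.

## Contact detection

Three intermolecular classes, with criteria in `contact_criteria()`:

* **Hydrogen bonds** — donor–acceptor distance < 3.5 Å and D–H···A angle
  within 70° of linearity. The upstream criterion "angle of 180°–70°" is
  ambiguous; it is read here as the D–H···A angle ∈ [110°, 180°]
  (≤ 70° deviation from linearity), evaluated at the hydrogen. Both the
  angle floor and the vertex convention are config knobs, so the
  alternative reading (angle ≥ 70°) is one line away. Donor–hydrogen
  covalent bonds are inferred geometrically (H within 1.2 Å of an N/O/S
  heavy atom), since PDB inputs carry no connectivity. Topologies without
  hydrogens raise an explicit error pointing to the distance-only
  fallback mode.
* **Salt bridges** — anionic oxygen to cationic nitrogen < 4.0 Å, with
  group membership from residue tables (Asp/Glu carboxylates, Lys/Arg
  amine/guanidinium; histidine neutral by default with a per-residue
  protonation list; ligand phosphate oxygens added by name).
* **van der Waals** — non-hydrogen pairs with |AB| < R(A) + R(B) + 0.5 Å,
  Bondi radii by default (PQR-supplied radii are respected).

vdW contacts are *not* deduplicated against hydrogen-bond or salt-bridge
pairs by default, because the reported total contact count is defined as
the plain sum of the three class means (e.g. 7.6 + 0.6 + 58.5 = 66.7);
`count_contacts(dedupe = TRUE)` provides the other convention. The
class-sum identity `total = hbond + saltbridge + vdw` holds per frame by
construction and is asserted in the tests.

Intra-domain hydrogen bonds use the tighter 3.0 Å / 20°-from-linearity
defaults of the common trajectory H-bond tools. Ion coordination counts,
within a 3.5 Å sphere, protein residues (once per residue, via any heavy
atom) and water molecules (via their oxygen); counting residues rather
than atoms is the documented reading of the upstream counting script.

## Endpoint binding energy

`binding_energy_series()` is an explicitly simplified MM-GBSA-style
estimator: ΔG = G(complex) − G(receptor) − G(ligand) per snapshot
(default every 10 ns, snapping to the nearest frame with a warning),
where each species energy is internal Coulomb (k = 332.0637
kcal·Å/(mol·e²), ε_in = 1) + 12-6 Lennard-Jones (Lorentz–Berthelot
combining, no cutoff at these system sizes) + generalized-Born solvation
in the classic pairwise form f_GB = √(r² + aᵢaⱼ·exp(−r²/4aᵢaⱼ)) with
self-terms included (ε_out = 78.5) + a nonpolar term γ·SASA with
γ = 0.0072 kcal/mol/Å². SASA is Shrake–Rupley with 960 golden-spiral
points per atom and a 1.4 Å probe over non-hydrogen atoms. Born radii
are *inputs* (from PQR-like files or a constant default), not computed by
pairwise descreening; there is no entropy term; the single-trajectory
approximation is used. The estimator is therefore a defined, reproducible
model of the same shape as engine MM-GBSA pipelines — its absolute values
are not expected to match any particular engine's, whose GB variant,
dielectrics and salt treatment are unstated in the source. Internal terms
cancel in the difference, so the Coulomb component of ΔG equals the
receptor–ligand interaction energy exactly; this identity is asserted
numerically in the tests. Because SASA is numerical, ΔG is rigid-motion
invariant only to the discretization error of the point set (~0.01
kcal/mol on the test articles).

## Statistics

Frame series are autocorrelated, so `block_average()` reports the SEM of
5 contiguous block means rather than the naive SEM; the reported ± values
on per-frame series are treated as SEMs over frames (their magnitude on
10⁴–10⁵-frame series is consistent with SEM, not SD). `compare_groups()`
gates on per-group normality with a one-sample KS test against a normal
with the sample's own mean and sd — a deliberately simple gate whose
parameter estimation makes it conservative — then runs one-way ANOVA if
every group passes at α = 0.05 and Kruskal–Wallis otherwise. Groups
smaller than 8 observations cannot be meaningfully KS-tested; they bypass
the gate (normality p recorded as NA, treated as parametric), which keeps
closed-form small-sample behaviour (two identical groups give F = 0,
p = 1) well defined. Stars follow the usual thresholds, `****` for
p < 0.0001. Only omnibus tests are provided; post-hoc pairwise
corrections are out of scope.

## Synthetic trajectories: what they emulate, and what they do not

The generators produce the statistical structures the analyses assume,
with known ground truth, and every generator is a pure function of its
arguments including the seed (each family draws from its own stream
derived from the master seed, so adding one generator never perturbs
another's output):

* `gen_brownian()` — isotropic Brownian motion, per-axis step variance
  2·D·dt; ground truth for the MSD slope 6·D·t.
* `gen_ou_tethered()` — exact Ornstein–Uhlenbeck update; a bound ligand
  with stationary per-axis variance σ² and MSD plateau 6σ².
* `gen_ideal_gas()` — independent uniform water positions each frame;
  the g(r) ≡ 1 null. At bulk density 0.0334 Å⁻³ in a 30 Å box this is
  901 particles per frame.
* `gen_hbond_scene()` — three atoms placed so the donor–acceptor
  distance and D–H···A angle equal requested values exactly, for
  boundary testing of the detectors.
* `gen_hydration_shell()` — discrete shells of water oxygens around a
  central ion at fixed radii (± radial jitter), fresh directions each
  frame; counts conserved by construction.
* `gen_rigid_body_protein()` — a Cα helix under a prescribed rigid
  transform per frame plus per-residue isotropic Gaussian noise; known
  RMSD/Rg/RMSF test articles.
* `gen_group_samples()` — normal or lognormal group samples for the
  statistical layer.

These are statistical stand-ins, not physics: there are no force fields,
no solvent–solute interactions, no correlated side-chain motion, no
anomalous diffusion, and the "protein" is a bare Cα trace. Passing tests
therefore demonstrate that the *estimators* recover known ground truth
under the assumptions they make — they do not certify behaviour on real
all-atom trajectories, where convergence, anharmonicity and sampling
error dominate. Headline numbers from microsecond all-atom simulations
(ligand MSDs of a few Å², binding energies of tens of kcal/mol) are
cluster-scale, stochastic quantities and are deliberately not acceptance
surfaces for this package.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each check has enough
statistics for its stated tolerance: diffusion recovery uses 100
particles × 10⁴ frames (10⁶ samples, 5% tolerance on D); the tethered
plateau 40 × 4000 frames (10%); the RDF null 901 particles × 3 frames
(2% on mean g); RMSF 40 residues × 800 frames (5%); the contact oracle
50 random ~500-atom frames (exact agreement); the type-I calibration
2000 simulated 4-group datasets (0.05 ± 0.01). Numerical tie-breaks worth
knowing: the Kabsch collinearity guard triggers at a relative second
singular value of 1e-8; hydrogen–donor assignment takes the *nearest*
donor-element atom within 1.2 Å; RDF self-pairs (an atom that is both
centre and target) are excluded; energy snapshot times off the frame grid
snap to the nearest frame with a warning.

## Orchestration

`read_run_config()`/`run_stage()`/`run_full_pipeline()` drive everything
from YAML: one config per condition (input files or a `simulate` block,
selections, domain overrides, criteria overrides, per-stage parameters,
seed), flat CSV outputs, and a JSON metadata sidecar per stage recording
the config hash, seed, package version and the defaults that upstream
tools leave unstated (fit window, origin stride, angle convention,
coordination radius) so every run is auditable. Conditions compared
together must share dt. A thin command-line wrapper over these functions
ships in `inst/scripts/tidytraj-cli.R`; plotting beyond the `autoplot()`
methods, HPC submission and MD engine invocation are out of scope.

## Known limitations

* XTC trajectories cannot be read (no reader in this toolchain); DCD and
  multi-model PDB are supported, and trajectory writing is multi-model
  PDB only.
* Orthorhombic boxes only.
* Contact detection is all-pairs (quadratic); fine at analysis scale,
  not tuned for solvated million-atom systems.
* The GB estimator's absolute binding energies depend on the supplied
  Born radii and carry no entropy term; use it for relative comparisons
  under a fixed parameterisation.
* The KS normality gate is conservative (estimated parameters); its
  measured power against uniform alternatives at n = 500 is ≈ 92%.
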