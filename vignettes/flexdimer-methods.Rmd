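---
title: "Models and methods behind flexdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flexdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexdimer)
```

`flexdimer` analyses the dilute-solution structure of two-armed
multidomain protein dimers — the MASP-1/MASP-2 proteases of the
complement lectin pathway are the motivating case — by combining
coarse-grained SAXS curve calculation, constrained Monte-Carlo
conformational sampling, and bead-model hydrodynamics. This vignette
explains the models, the defaults, and the numerical decisions, so the
package can be audited and re-parameterized with confidence.

## Coordinate models and units

All coordinates are carried in nanometres; PDB files (Ångström) are
converted on read and write. A structure model is a tibble with one row
per atom. Rigid domains and flexible linkers are *declarations* layered
on top (`domain_map()`, `linker_set()`): the analysis never guesses where
flexibility lives, it varies exactly the residue ranges the user (or the
synthetic generator) declares, which mirrors how such searches are set up
in practice. Alternate locations resolve to the highest-occupancy
conformer; residue numbering is taken verbatim from the file.

## The sphere model

Scattering is computed from a cube-grid sphere model rather than from
atoms:

1. a cubic grid (default side 0.55 nm, the classic sphere-model
   resolution for this Q range) is laid over the heavy atoms;
2. each cube holding at least `atom_cutoff` atoms becomes one sphere at
   the cube center. The cutoff is tuned over 1–8 to bring the total
   sphere volume closest to the composition-derived dry volume (ties go
   to the smaller cutoff);
3. because an integer grid quantizes volume in steps of one cube, the
   common sphere radius is then rescaled once so the total volume matches
   the dry-volume target exactly. The scattering consequences are
   negligible (the radius enters only through the single-sphere form
   factor) and every downstream volume invariant becomes exact;
4. hydration adds spheres on empty cubes face-adjacent to the filled
   surface — nearest shell first, deterministic cube order — until the
   volume accounts for 0.3 g of bound water per gram of glycoprotein
   (water density 1.0 g/mL). This hydration constant is the standard
   value for glycoproteins in this method family.

Dry volumes come from consensus residue-volume tables
(`composition_tables()`), or from the model's own `dry_volume_nm3`
attribute (synthetic toys carry one). If the best achievable pre-rescale
volume is more than 30% off, the build errors rather than silently
producing a wrong-density model.

The one-bead-per-residue toys sit below atomic density, so the grid
spreads their mass slightly: coordinate R_g is preserved to ~3% for
atomic-density inputs across grid sides 0.3–0.6 nm, and to ~6% for the
coarse toys (tested explicitly).

## Debye curves and their accuracy

The normalized curve of `n` equal spheres is

$$ I(Q)/I(0) = g(Q)\left[\frac1n + \frac{2}{n^2}
   \sum_{i<j}\frac{\sin(Q r_{ij})}{Q r_{ij}}\right], $$

with `g(Q)` the squared sphere form factor; the bracket equals 1 at
`Q = 0` by construction. Pair distances are histogrammed at 0.01 nm, and
each bin is represented by its *mean* pair distance rather than its
midpoint, which cancels the first-order binning error; the binned sum is
tested to agree with the explicit double sum to 0.1% across the working
Q range (0.05–2 nm⁻¹).

## Guinier and cross-sectional analyses

`guinier_fit()` performs (weighted) least squares of `ln I` on `Q²`,
growing the window iteratively until `max(Q)·R_g` hits the configured
limit. The default limit of 1.3 is the common compact-particle
convention; it is a *configuration*, not a constant, because the
appropriate window depends on shape. Two facts worth knowing, both
visible in the test suite:

* for a uniform sphere, the Guinier approximation itself carries ≈2%
  upward truncation bias at `Q·R_g ≤ 1.3`; the closed-form checks in the
  tests use 0.8–1.0, inside the near-Gaussian regime;
* for thin rods the bias is downward and stronger — the rod tests use
  `Q·R_g ≤ 0.6` and place the `R_xs` window past `Q ≈ 1/L`.

`cross_section_fit()` fits `ln(I·Q)` vs `Q²` on a user-declared window
(`R_xs = sqrt(−2·slope)`). A numerically flat region returns `R_xs = 0`;
a genuinely rising one errors.

`concentration_series_check()` regresses `I(0)/c` and `R_g` on
concentration and raises a flag on either statistical significance
(default 1%) or a practical trend larger than 5% across the measured
range — the second criterion guards the short (3–5 point) dilution series
typical of beam-time experiments, where a blatant trend can still have
one residual degree of freedom.

## Distance distributions

`pr_from_model()` histograms all pair distances (bin default 0.1 nm);
`L` is the upper edge of the last occupied bin and `R_g` follows from the
second moment, `R_g² = ∫ r²P dr / (2∫P dr)`. `pr_from_curve()` solves a
Tikhonov-regularized indirect transform: P(r) on interior nodes of
`[0, dmax]` with `P(0) = P(dmax) = 0`, minimizing weighted χ² plus
`α`·(second-difference penalty), `α` scaled dimensionlessly against the
normal matrix (default 0.01). Small negative excursions are clipped to
zero before normalization, and `L` is read where P(r) falls below
10⁻³ of its maximum — "where P(r) reaches zero" needs an operational
epsilon. χ² rises monotonically with `α` (tested).

Peak calling uses a 3-bin moving average and a prominence floor of 2% of
the maximum by default. One caveat: P(r) computed from a *cube-grid
sphere model* carries lattice ripple at the grid period, so peak analysis
should use atom coordinates or the curve transform (both exposed); the
`smooth_bins`/`prominence` arguments are there for exactly this reason.

## The R factor

`r_factor()` scores `R = 100·Σ|I_e − η·I_c| / Σ|I_e|` after interpolating
the calculated curve onto the experimental grid. The scale η is found by
Brent minimization on `log10 η` in [−3, 3] (tolerance 10⁻⁶), with the
bracket centred on the least-squares scale so curves on wildly different
absolute scales still converge. R is zero for any uniform rescaling of
either curve (tested), and the scored Q range is recorded in every
result because fitted R factors are only comparable over a common range.

## Monte-Carlo linker sampling

The search is a generate-and-filter scan, not an equilibrium sampler:
there is no Metropolis criterion and no energy function beyond hard
steric exclusion.

* **Proposal.** Per proposal, one linker residue per chain is chosen
  uniformly and its φ/ψ dihedrals are redrawn from a flat distribution on
  (−180°, 180°] (a bounded-step mode exists). All atoms downstream of the
  varied bond rotate rigidly; glycan stubs ride with their attachment
  residue. Chains are sampled independently — no 2-fold symmetry is
  imposed, so symmetric and asymmetric dimers are both reachable.
* **Rigid units.** Clash checking groups rigid segments into units:
  consecutive segments merge unless a declared linker separates them, and
  the N-terminal units of all chains merge into one core unit because the
  dimer interface itself is rigid. Heavy-atom pairs from *different*
  units closer than 0.25 nm reject the proposal (near-bonded pairs within
  two residues on a chain are exempt). The predicate uses bounding-sphere
  prefilters with exact blocked distance evaluation, and is tested for
  equality against an independent all-pairs implementation on hundreds of
  sampled conformations.
* **Scoring.** Accepted trials are re-coarse-grained with the same grid
  parameters (hydrated, same dry-volume target as the start), scored with
  the R factor on the target's Q grid, and logged as an R-factor-vs-R_g
  table (`autoplot()` shows the familiar funnel with the ten best models
  in red). The ten lowest-R models form the best-fit ensemble; ties break
  toward the model whose R_g is nearest the target's Guinier R_g, then by
  trial index.
* **Determinism.** One master seed; proposal *k* draws its randomness
  from a seed derived by counter, so any trial is reproducible in
  isolation and identical (start, config, seed) gives an identical
  search. Walking from the previous accepted conformation makes a
  restart from a best-fit model ("Search 2") literally just a different
  start argument.
* **Diagnostics.** If fewer than 2% of any 5,000-proposal window are
  accepted the search aborts with counts, pointing at mis-declared
  linkers or an over-tight clash cutoff.

## Hydrodynamics

`sedimentation_coefficient()` uses the Kirkwood approximation to the
translational friction of `n` beads of radius `a` (default 0.284 nm, one
bead per heavy atom, hydration absorbed into the radius):

$$ f = \frac{n f_1}{1 + \dfrac{f_1}{6\pi\eta n}\sum_{i\ne j} r_{ij}^{-1}},
   \qquad f_1 = 6\pi\eta a, $$

then `s20,w = M(1 − ν̄ρ)/(N_A f)` with water at 20 °C (η = 1.002 mPa·s,
ρ = 0.99823 g/mL). Overlapping pairs are clamped to `r_ij = a` to prevent
divergence. Two touching beads give the closed-form `R_h = (4/3)a`
(tested to machine precision), rigid motion leaves `s` unchanged, and
stretching a dumbbell strictly decreases `s` — the qualitative lever used
to infer bending from sedimentation that outruns a straight model.
Kirkwood is a desk-scale stand-in for full shell-model programs and runs
a few percent low on absolute friction for solid bodies; comparisons in
this package therefore lean on the ±0.21 S agreement band conventional
for model-vs-experiment `s20,w` checks, and on signs/orderings rather
than third decimals.

Models above 20,000 heavy atoms are grid-merged into weighted cluster
beads: the exact intra-cluster inverse-distance sum is carried along and
the inter-cluster sum is evaluated on size-weighted centroids, which
keeps the reduced prediction within ~0.5% of the full sum (a naive
volume-scaled merge loses the short-distance structure and errs by
several percent — the reason this construction exists).

`composition_properties()` supplies mass, ν̄ (mass-weighted consensus
residue values; sugars via their own mass/volume ratio) and dry volume
from sequence, with glycan stubs adding one generic hexose unit each
(162.1 Da, 0.171 nm³) by default.

## Geometry analysis

* `superpose()`: closed-form proper rotation (SVD with determinant
  correction), then iterative trimming — drop pairs deviating by more
  than 2× the current RMSD, refit, repeat (≤10 iterations). The familiar
  "RMSD over N residues" arises from the trimming, never from manual
  selection. RMSD is reported in Å, the field convention.
* `buried_surface_area()`: Shrake–Rupley SASA with a deterministic
  golden-spiral point set (960 points/atom, probe 1.4 Å, consensus van
  der Waals radii); `BSA = SASA(A) + SASA(B) − SASA(AB)`, halved for the
  per-molecule figure, with the >800 Å²/molecule stable-dimer rule of
  thumb reported alongside. The two-sphere analytic cap and rigid-motion
  invariance are tested.
* `bend_parameters()`: `d` is the distance between the two end-domain
  Cα centroids; θ is the angle they subtend at the Cα centroid of the
  rigid core. This centroid construction is an operational choice — other
  angle definitions exist, and differences of a few degrees between
  definitions are expected, so recovered angles should be compared within
  one definition.
* `ensemble_align()` superposes an ensemble on its first member via the
  core Cα set; `ensemble_dispersion()` turns the end-domain centroid
  cloud into an RMS flexibility number.

## The synthetic-data generator

`make_toy_dimer()` builds the study systems: two antiparallel arms joined
at a rigid CUB1-EGF-like core, domains as uniform pseudo-atom balls (one
CA bead per residue, 50–200 per domain), linkers as explicit three-atom
(N/CA/C) backbones so dihedral moves are well defined. The `masp3d-like`
registry entry is sized to the MASP-3D regime — end-domain separation
≈9.9 nm, hydrated Guinier R_g ≈3.8 nm, maximum length ≈13 nm, interface
≈1,000 Å²/molecule, `s20,w` ≈4.3 S — and `fulllength-like` extends each
arm with SCR1/SCR2/SP-sized balls, giving the long two-peak P(r)
morphology and start-model R_g ≈8.6 nm. Core geometry (chain offset
0.8 nm, interface overlap 0.2 nm) was fixed once against those regime
targets and is not a tuning knob.

Requested bend angles are realized by rotating both arms at the first
linker and solving the rotation angle against the measured centroid θ
(root-finding to 10⁻⁴ degrees, so the 2° construction contract is easy);
geometrically infeasible requests (self-clashing bends) error. Toy mass
is derived from the declared dry volume via ν̄ = 0.73 mL/g so that
hydration and sedimentation bookkeeping stay self-consistent.

`simulate_saxs()` adds Gaussian noise with relative σ growing from 1% at
the lowest Q as a power law (exponent 1.5) to 20% at Q = 2 nm⁻¹ — the
typical error shape of a dilute-protein synchrotron curve — per
concentration and replicate, all seed-deterministic. What the generator
does *not* emulate: inter-particle structure factors, buffer-subtraction
artifacts, radiation damage, detector smearing, and real glycan
chemistry. Passing recovery tests therefore demonstrate that the
*inference machinery* is correct and well-calibrated on data whose
generative model is known, not that any particular real dataset is free
of those effects.

## Problem sizes and runtime

The shipped experiments run at desk scale on one CPU: the bend-recovery
experiment uses a ~730-atom dimer, 2,000 accepted trials (~1 minute); the
full-length experiment uses ~1,300 atoms and 250 trials. These sizes were
chosen so the full suite and the acceptance script each complete in a few
minutes while leaving the statistical conclusions (±15° bend recovery,
R-factor improvement, sedimentation ordering) comfortably clear of their
thresholds.

## Known limitations

* Kirkwood friction, not a calibrated shell model: absolute `s20,w` has a
  systematic offset of a few percent; use the ±0.21 S band and orderings.
* The Guinier window rule is shape-dependent; defaults suit compact
  particles and the package deliberately exposes the limit rather than
  hard-coding per-shape values.
* Sphere-model P(r) carries grid ripple (use atoms or the indirect
  transform for peak work).
* Glycan stubs are mass/volume bookkeeping in extended geometry, not
  carbohydrate conformers.
* The search ranks single conformations by R factor; it does not fit
  ensemble weights, so breadth of the best-fit set is a qualitative, not
  thermodynamic, flexibility measure.
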