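# flexdimer

Solution-structure analysis of flexible multidomain protein dimers from
small-angle X-ray scattering (SAXS) and analytical-ultracentrifugation
data, in R.

Proteases of the complement lectin pathway such as MASP-1 and MASP-2
circulate as head-to-head homodimers of six-domain monomers
(CUB1-EGF-CUB2-SCR1-SCR2-SP). Their crystal structures are near-linear,
but in solution the arms bend at flexible inter-domain linkers, which has
direct consequences for how the protease domains reach their activation
partners. `flexdimer` implements the modelling workflow used to
demonstrate and quantify that flexibility:

* **Coarse-grained scattering.** Atoms are binned onto a cubic grid
  (default side 0.55 nm); occupied cubes become equal spheres whose total
  volume is tuned (integer atom cutoff, then an exact common-radius
  rescale) to the composition-derived dry volume, with extra surface
  spheres for 0.3 g/g bound water. The curve follows the Debye equation

  `I(Q)/I(0) = g(Q) [ n⁻¹ + 2 n⁻² Σ_{i<j} sin(Q r_ij)/(Q r_ij) ]`

  with `g(Q)` the squared form factor of the common sphere.
* **Guinier analyses.** `ln I` vs `Q²` on an iteratively chosen window
  (`max(Q)·R_g` bounded, default 1.3) gives `R_g` and `I(0)`;
  `ln(I·Q)` vs `Q²` on a higher-Q window gives the cross-sectional
  `R_xs`. `P(r)` comes either directly from pair distances or from a
  regularized indirect transform of the curve, yielding the maximum
  length `L` and the peak positions (`M`, or `M1`/`M2` for long dimers).
* **Constrained Monte-Carlo search.** Backbone dihedrals of declared
  flexible linkers are redrawn at random (both chains independently — no
  2-fold symmetry is imposed), sterically clashing trials are discarded
  at creation, every survivor is scored against the target curve with the
  goodness-of-fit R factor `R = 100 Σ|I_e − η I_c| / Σ|I_e|` (scale η
  optimized), and the ten lowest-R models form the best-fit ensemble.
* **Bead-model hydrodynamics.** One bead of radius 0.284 nm per heavy
  atom and the Kirkwood inverse-distance double sum predict the
  sedimentation coefficient `s20,w = M(1 − ν̄ρ)/(N_A f)` in water at
  20 °C — an independent, shape-sensitive check on the SAXS models.
* **Geometry.** Trimmed Kabsch superposition (RMSD "over N residues"
  emerges from 2σ outlier trimming), Shrake–Rupley buried surface areas
  at the dimer interface, and the bend parameterization: the separation
  `d` between the two end-domain centroids and the angle θ they subtend
  at the rigid-core centroid.
* **Synthetic ground truth.** A seed-deterministic generator builds
  two-armed toy dimers with known bend angles and simulates noisy dilute
  SAXS series, so the entire pipeline — including full bend-angle
  recovery experiments — is testable offline.

## Worked example: recovering a bent solution structure

```r
library(flexdimer)

# ground truth: a MASP-3D-sized dimer bent to 120 deg at the EGF-CUB2 hinge
truth  <- make_toy_dimer(toy_registry("masp3d-like", bend_deg = 120))
target <- simulate_saxs(truth$model, noise_model(), seed = 7)[[1]]
guinier_fit(target)
#> Guinier fit: Rg = 3.071 +/- 0.029 nm, I(0) = 1.002 (23 pts, Q 0.050-0.411, Q.Rg 0.15-1.26)

# search from the straight (crystal-like) start
start  <- make_toy_dimer(toy_registry("masp3d-like"))
search <- run_search(start$model, start$linkers, target,
                     n_trials = 500, seed = 42, domains = start$domains)
search
#> <search_result> 500 accepted / 967 proposals; best R = 2.65%; target Rg = 3.071 nm

best <- select_best(search, 10)
bend_parameters(best$model[[1]], start$domains)
#> # A tibble: 1 x 4
#>    d_nm theta_deg end_domain core
#>   <dbl>     <dbl> <chr>      <chr>
#> 1  7.33      123. CUB2       CUB1+EGF

predict_s20w(best$model[[1]])
#> s20,w = 4.521 S (Rh = 2.572 nm, f/f0 = 1.065, 734 beads)
predict_s20w(start$model)
#> s20,w = 4.256 S (Rh = 2.733 nm, f/f0 = 1.131, 734 beads)
```

The search recovers the 120° bend to within a few degrees, drops the R
factor from ~8% (straight start) to ~2.7%, and the bent best-fit model
sediments faster than the straight start — the same three signatures used
to establish bending in the real proteins. `autoplot(search)` draws the
R-factor-vs-R_g scatter with the ten best models highlighted;
`autoplot(pr_from_curve(target, dmax = 14))` shows the distance
distribution.

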