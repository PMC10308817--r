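---
title: "Restraint models and standard-state corrections: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restraint models and standard-state corrections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfer)
```

This vignette documents the models, parameter conventions, and numerical
choices behind `abfer`. It is the reference for *why* the functions compute
what they compute; the README shows *how* to use them end to end.

## 1. The thermodynamic cycle

An absolute binding free energy by double decoupling is assembled from a
bound leg and a free (solvent) leg:

$$
\Delta G^\circ_{\mathrm{bind}} = \Delta G_{\mathrm{Bound}} - \Delta G_{\mathrm{Free}},
$$

where the bound leg turns the interacting, unrestrained complex into a
decoupled, restrained ligand and then releases the restraint to the
standard-state volume. The package uses the *table convention* throughout:
every stage contribution is entered with the sign it carries in the bound-leg
sum, so the release stage appears as $-\Delta G_{\mathrm{Release}}$ (a
positive number, since releasing a confining restraint is favourable).
`cycle_ledger()` enforces the exact label set for each of three schemes:

| scheme | stage labels |
|---|---|
| `boresch_or_naive` | Release, Bound.Vanish, Bound.Discharge, Bound.Restrain, Sym.Corr. |
| `intramol_rigid` | the five above + Rigid.Lig., Rigid.Recept., Rigid.Complex |
| `release_to_single` | the five above + To.Dist.Rest. |

Missing, duplicated, or unknown labels are errors rather than silent `NA`s:
a cycle with a hole in it is not a free energy.

Symmetry corrections are $-k_BT \ln n$ for $n$ equivalent, unsampled states
(`symmetry_correction()`); they are additive across independent symmetries.
Poses are combined by Boltzmann weighting,
$\Delta G = -k_BT \ln \sum_i e^{-\beta \Delta G_i}$, implemented with a
log-sum-exp shift so that values around $-500$ kcal/mol do not overflow
(`combine_poses()`). Replicates aggregate to a mean with a Student-*t*
95&nbsp;% confidence half-width (`aggregate_replicates()`). The
preorganization estimate is
$\Delta G_{\mathrm{Rigid.Recept.}} + \Delta G_{\mathrm{Rigid.Lig.}} -
\Delta G_{\mathrm{Rigid.Complex}}$ with uncertainties added in quadrature
(`preorg_estimate()`); a negative estimate triggers a warning, since it
usually indicates incomplete sampling of a rigidification stage.

## 2. Restraint models

### 2.1 Boresch restraints

Six harmonic terms on six anchor atoms — receptor $a, b, c$ and ligand
$A, B, C$ — restrain one distance $r = |aA|$, two angles
$\theta_A = \angle baA$, $\theta_B = \angle aAB$, and three dihedrals
$\phi_A = cbaA$, $\phi_B = baAB$, $\phi_C = aABC$:

$$
U = \tfrac12 K_r (r - r_0)^2 + \tfrac12 K_{\theta_A}(\theta_A - \theta_{A0})^2
  + \dots + \tfrac12 K_{\phi_C}\,\mathrm{wrap}(\phi_C - \phi_{C0})^2 .
$$

Dihedral deviations are wrapped to $(-\pi, \pi]$ (`wrap_angle()`), which
makes the energy exactly $2\pi$-periodic. Angles in the API are radians;
equilibrium angles are *printed* and *serialized* in degrees because that is
how simulation inputs are written. Construction rejects $K < 0$, $r_0 \le 0$
and equilibrium angles at the poles ($\theta_0 \in \{0, \pi\}$), where the
dihedrals flanking the angle become undefined.

### 2.2 Multiple distance restraints (MDR)

`distance_restraint_set()` holds $N$ receptor–ligand atom pairs, each with a
flat-bottomed harmonic well,

$$
U_i = \tfrac12 K_i \,\max(|d_i - r_{0,i}| - r_{\mathrm{fb},i},\, 0)^2 ,
$$

where $r_{\mathrm{fb}} = 0$ recovers a plain harmonic and $K = \infty$ a hard
wall. Duplicate pairs are rejected. The same functional form with
intramolecular pairs (`intramolecular_restraint_set()`) implements the
rigidification stages of the `intramol_rigid` scheme.

### 2.3 Soft-core-free scaling and schedules

`scale_restraints()` multiplies all force constants by a factor (used to
build restraining/releasing legs), and `lambda_schedule()` supplies the
standard window ladders. `release_to_single_schedule()` scales every force
constant except one (default: the stiffest) by $(1-\lambda)^5$; the
quintic power keeps $\partial U/\partial\lambda$ finite and smooth at the
endpoint where restraints vanish.

## 3. Restraint selection from trajectories

Selection works on heavy-atom distance statistics only:

1. `pair_distance_stats()` ranks receptor–ligand heavy-atom pairs within a
   contact cutoff (default 10 Å) by the standard deviation of their distance
   over frames. Low variance identifies geometrically stable contacts.
2. `select_distance_restraints()` walks the ranked list greedily, keeping a
   pair only if both atoms are unused so far, yielding disjoint anchors.
3. `enumerate_boresch_candidates()` completes a ranked pair $(a, A)$ into
   six anchors by walking the bonded graph (bonds inferred from mean
   geometry by element-dependent cutoffs, `infer_bonds()`), scoring
   completions by the summed variances of the six degrees of freedom and
   flagging candidates whose mean angles approach collinearity
   ($\theta$ within 0.3 rad of a pole by default), where the Boresch
   dihedrals become numerically unstable (`collinearity_penalty()`).
4. `fit_force_constants()` sets $K = k_BT / \mathrm{Var}$, the force constant
   whose Gaussian fluctuation matches the observed one. Distances and angles
   use linear variance; **dihedrals use circular statistics**
   (`circular_mean()`, `circular_var()`), since a linear variance of angles
   clustered across the $\pm\pi$ seam would be wildly inflated. Angles
   $\theta$ live on $(0, \pi)$ and never cross a seam, so linear statistics
   are correct there.
5. `fit_flat_bottom_radii()` sets $r_{\mathrm{fb}}$ from a percentile
   (default 99th) of the observed $|d - r_0|$, so that the restraint replays
   the trajectory with (near-)zero energy and only activates outside the
   sampled basin.

Atom indices are **1-based** everywhere, matching R convention; the JSON
serializers write 1-based indices and state so in the field names.

## 4. Standard-state release corrections

Releasing a decoupled, restrained ligand into $V^\circ = 1660\,\text{Å}^3$
(1 M) costs

$$
\Delta G_{\mathrm{Release}} = -k_BT \ln \frac{V^\circ\, 8\pi^2}{Z_{\mathrm{ext}}},
\qquad
Z_{\mathrm{ext}} = \int e^{-\beta U}\, dV_{\mathrm{ext}},
$$

where the integral runs over the six external degrees of freedom of the
rigid ligand with the appropriate Jacobian. The package computes it by four
independent routes; their mutual agreement is the core correctness argument
and is enforced by the test suite.

### 4.1 Analytic (Gaussian) Boresch formula

For stiff restraints the integrand is approximately Gaussian and

$$
\Delta G = -k_BT \ln\!\left[
\frac{8\pi^2 V^\circ\; \sqrt{K_r K_{\theta_A} K_{\theta_B} K_{\phi_A} K_{\phi_B} K_{\phi_C}}}
     {r_0^2 \sin\theta_{A0} \sin\theta_{B0}\; (2\pi k_BT)^3}
\right].
$$

`boresch_release_analytic()` requires all six $K > 0$. The approximation
error is a few hundredths of a kcal/mol in the fitted-restraint regime
($K \gtrsim 10$ kcal/mol/rad², equilibria away from the poles) and grows for
soft restraints, where the true integrand feels the Jacobian's curvature.

### 4.2 Numerical quadrature

Because the six Boresch terms are separable, $Z_{\mathrm{ext}}$ factors into
six one-dimensional integrals with Jacobians $r^2$, $\sin\theta_A$,
$\sin\theta_B$, and 1 for the dihedrals. `boresch_release_numeric()`
evaluates each by composite Simpson quadrature with interval doubling until
the value is stable; the last doubling step is reported as
`convergence_estimate`. Integration bounds are chosen where the Boltzmann
factor falls below $10^{-10}$ (clipped to the physical domain); a free
coordinate ($K = 0$) integrates its full-range Jacobian volume exactly
(2 for $\theta$, $2\pi$ for $\phi$). $K_r = 0$ is refused: the radial
integral would be unbounded.

### 4.3 Closed single-distance form

A single (flat-bottomed) distance restraint has

$$
\Delta G = -k_BT \ln \frac{V^\circ}{4\pi \int_0^\infty r^2 e^{-\beta U(r)}\,dr},
$$

with a hard wall ($K = \infty$) giving the exact shell volume
$I = (r_{\mathrm{hi}}^3 - r_{\mathrm{lo}}^3)/3$
(`single_distance_release()`). A useful exact identity, tested to $10^{-7}$:
a Boresch restraint with only $K_r > 0$ equals this form, because the free
angular volume $2 \cdot 2 \cdot (2\pi)^3 \cdot$(…) cancels the $8\pi^2$ and
leaves $4\pi$.

### 4.4 Rigid-body 6-DoF grid

For MDR sets no closed form exists in general. If the anchor atoms are rigid
(exactly true under the `intramol_rigid` scheme), the external integral can
be evaluated on a direct product grid: ligand-anchor translations on a cubic
midpoint grid × orientations on a z–y′–z″ Euler-angle midpoint grid with
Haar weight $\sin\theta$ (`rigid_body_release()`, `orientation_grid()`).
Numerical choices, each visible in the API:

- **Midpoint rules everywhere.** The midpoint $\theta$-sum of $\sin\theta$
  has the closed form $(\pi/m)/\sin(\pi/(2m))$, converging to its exact
  value quadratically; $\psi, \phi$ midpoint sums are exact for periodic
  integrands. The orientation count `orientations = n` uses $m = n/2$
  $\theta$-nodes.
- **Translation bounds** default to the restrained region plus a `buffer`;
  the integrand is checked on the grid boundary and the run errors if the
  boundary Boltzmann weight exceeds $10^{-6}$ of the maximum — a truncated
  integral is a silently wrong free energy. The buffer needed is
  $\approx \sqrt{27.6\, k_BT / K}$ for the softest force constant $K$.
- **Element size** must resolve the narrowest feature; the radial width of a
  harmonic term is $\sigma_r = \sqrt{k_BT/K}$. With `refine = TRUE` the
  element is halved and orientation count doubled until successive values
  agree within `convergence_tol`; the last step is reported as
  `convergence_estimate`.
- Grid nodes where anchors become coincident or collinear have undefined
  internal coordinates; these measure-zero configurations are assigned zero
  Boltzmann weight.

The same grid evaluates Boresch energies on rigid anchors
(`boresch_reference_geometry()`), giving a fourth, mechanism-independent
route to the same number.

### 4.5 Monte Carlo oracle

`mc_confinement_free_energy()` samples translations uniformly in a box and
orientations uniformly from $SO(3)$, estimating
$\hat Z = 8\pi^2 V_{\mathrm{box}} \langle e^{-\beta U} \rangle$ with
standard error propagated as
$k_BT \cdot \mathrm{sd}(w) / (\sqrt{n}\,\bar w)$. It is unbiased and
assumption-free (no separability, no rigidity beyond the anchors), which
makes it the arbiter when the deterministic routes are extended — at the
price of slow $1/\sqrt{n}$ convergence.

### 4.6 Scaling laws used as tests

Two exact laws pin the implementation independent of any oracle: scaling
$V^\circ$ by $c$ shifts every route by exactly $-k_BT\ln c$, and scaling all
six Boresch force constants by $c$ shifts the analytic form by exactly
$3 k_BT \ln c$. Both hold to near machine precision in the suite, alongside
monotonicity of $-\Delta G_{\mathrm{Release}}$ in each force constant.

## 5. The synthetic trajectory generator

`generate_synthetic_trajectory()` draws i.i.d. Gaussian displacements per
atom per frame about a mean structure (per-atom `sigma`, default 0.25 Å),
then optionally post-conditions selected atom pairs so that their
*distances* fluctuate with a prescribed standard deviation — this is what
lets tests engineer a known best restraint pair and verify the selection
machinery recovers it. Seeded draws are bit-reproducible via
`withr::with_seed()`, so the generator never perturbs the caller's RNG
state.

Realism and limits, stated plainly: the generator has no dynamics (no
autocorrelation between frames), no bonded structure beyond the mean
geometry, no anharmonicity, and no coupling between degrees of freedom. It
is a *statistical* stand-in adequate for testing estimators whose inputs are
per-frame geometric observables — which is exactly the scope of this
package — and inadequate for anything kinetic.

The generator's defaults (0.25 Å per-atom sigma, 298 K, 10 Å contact
cutoff) are study conditions typical of a solvated protein–ligand complex;
they are not tuned to any particular test.

## 6. Diagnostics

- `water_occupancy()` counts non-hydrogen water oxygens within a radius of a
  site center per frame; it warns when the radius exceeds twice the default,
  since large spheres stop measuring *binding-site* hydration.
- `dof_timeseries()` extracts the six Boresch coordinates (or the $N$ MDR
  distances) per frame; replaying them through the restraint energy function
  must reproduce the per-frame energies exactly, and the test suite enforces
  that identity.
- `rmsf()` superposes each frame onto the mean structure by the Kabsch
  algorithm (SVD with a determinant sign correction so reflections are never
  returned) before computing per-atom fluctuations; for isotropic Gaussian
  noise of scale $\sigma$ the expected RMSF is $\sigma\sqrt{3}$, which the
  suite checks, along with exact invariance under rigid motions of the whole
  trajectory.

## 7. Constants and conventions

| quantity | value |
|---|---|
| $k_B$ | $1.9872041 \times 10^{-3}$ kcal/mol/K |
| $T$ (default) | 298 K |
| $k_BT$ at 298 K | 0.59219 kcal/mol |
| $V^\circ$ | 1660 Å³ |
| energies | kcal/mol |
| lengths | Å |
| angles in the API | radians |
| angles printed / on disk | degrees |
| atom indices | 1-based |
| dihedral statistics | circular; angle statistics linear |

All of these are carried by `thermo_context()` objects rather than globals,
so non-default temperatures or standard volumes flow through every route
consistently.
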