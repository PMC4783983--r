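---
title: "Methods: trajectory analysis of solvent-controlled protein dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of solvent-controlled protein dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvdyn)
```

# The scientific setting

When a protein-solvent system is simulated with the solute and the solvent
coupled to *separate* thermostats (e.g. protein at 300 K with solvent at
180 K, written P300/S180), one can ask which temperature governs the
protein's internal flexibility. Answering that question from the resulting
trajectories takes a pipeline of standard but interlocking analyses:
replica joining, structural property averages, per-residue RMSF and its
dependence on burial depth, essential dynamics (ED), cosine-content
convergence diagnostics, combined ED for two-condition comparison,
static/dynamic hydrogen-bond (HB) bookkeeping, free-energy landscapes
(FELs), and solvent mean-square displacement (MSD). `solvdyn` implements
that pipeline as reusable, tested components, together with synthetic-data
generators that plant known ground truth so each stage can be verified
without running an MD engine.

The package ships the published joined-trajectory averages for proteinase
K at the four temperature combinations (`reference_tables()`); the
percent- and fold-change arithmetic of the comparison tables is recomputed
from those printed values. The absolute averages themselves are *not*
regenerated — they summarise hundreds of nanoseconds of all-atom MD, which
is out of scope for an analysis package.

# Models and procedures

## Essential dynamics

Frames are least-squares fitted (Kabsch superposition via SVD, reflection
branch corrected to determinant +1) to the starting structure on the
analysis selection — by convention the solute CA atoms — and the 3n x 3n
Cartesian covariance of the selection is accumulated with population
normalisation 1/F and no mass weighting. Its eigenvectors are collective
motion directions; eigenvalues are variances (reported in both Angstrom^2
and nm^2, 1 nm^2 = 100 Angstrom^2); the trace is the total mean square
fluctuation (TMSF). Fitting to the *starting structure* rather than the
trajectory mean keeps the ED frame consistent with the RMSD reference;
iterative fitting to the mean is a conceivable option but is not needed
for the comparisons the pipeline makes. Eigenvector signs are fixed by
making the largest-magnitude component positive, so spectra and
projections are reproducible.

Projections are `p_k(t) = v_k . (x_fit(t) - <x>)`. Projection variances
equal eigenvalues by construction (a test asserts this to 1e-6 relative),
and the fitted frames are exactly reconstructed from the full eigenvector
basis.

**Combined ED** concatenates two trajectories fitted to a common
reference and diagonalises the joint covariance. For each half we report
the projection mean and the projection mean square displacement
`msd_h(k) = mean(p_k^2)` *about the combined mean*: a common origin is
what lets the MSD capture the conformational shift between the two
simulations as well as the fluctuation within each. This convention for
the projection "MSD" is a package decision — the quantity is not defined
unambiguously in the literature — and is flagged here deliberately.

## Cosine content

For a projection series `p(t)` on `[0, T]`,
`c_k = (2/T) (int cos(k pi t / T) p(t) dt)^2 / int p(t)^2 dt`,
discretised with the trapezoid rule after mean-centring; the time scale
cancels. Values near 1 mean the mode looks like random diffusion
(unconverged sampling); near 0, converged sampling. `c_k` of an all-zero
series is undefined and raises an error rather than returning 0. By
Cauchy-Schwarz `c_k` lies in [0, 1]; a property test asserts this on
random series.

## Hydrogen bonds

A bond is a (donor, hydrogen, acceptor) triple with donor-acceptor
distance <= 3.5 Angstrom and donor-hydrogen-acceptor angle (vertex at the
hydrogen) >= 120 degrees. Both bounds are inclusive, reading "maximum
distance" and "minimum angle" literally; an epsilon of 1e-9 degrees at the
angle boundary absorbs floating-point rounding in `acos`. Donor/acceptor
roles come from a static atom-name table (N/O donors with attached
hydrogens; N/O acceptors — see `R/system.R`), not from force-field typing.
Hydrogens are attached to the nearest N/O of the same residue within 1.25
Angstrom; missing mainchain amide hydrogens are placed on the bisector
extension of the C(prev)-N and CA-N bonds at 1.0 Angstrom; side-chain
donors without hydrogens fall back to a distance-only criterion with a
warning. Pairs closer than 1.8 Angstrom are treated as covalently bonded
and excluded. Minimum-image distances are used when a box is present.

Bond identity is the full triple, so two hydrogens of one donor reaching
the same acceptor count as two dynamic bonds. The bookkeeping follows the
field's definitions: the *static* number is the per-frame count averaged
over frames, the *dynamic* number is the count of distinct triples ever
seen, and *persistency* is the percentage of frames in which a triple
exists. These definitions force the identity
`sum(persistency)/100 = static_mean` exactly, and the package implements
it exactly. Some published intra-protein rows violate this identity
beyond rounding; the shipped acceptance checks therefore test it on the
protein-solvent rows whose printed precision supports it, and the
discrepancy is left as a property of the published table, not something
to emulate. Classes follow the mainchain flags of the two partners (M-M,
M-S, S-S intra-protein; M-solv, S-solv by the protein partner against
water), with water-water bonds never counted.

## Structural properties

* **RMSD**: backbone (N, CA, C, O) after Kabsch fitting to the starting
  structure. Including the carbonyl O is a package default; a pure
  N/CA/C selection can be passed explicitly.
* **Rg**: mass-weighted by default (the common tool default), geometric
  optional.
* **Native contacts**: solute heavy-atom pairs in different residues
  closer than 6 Angstrom (strict `<`) in the reference; the same pairs
  are recounted per frame. Recounting *native* pairs (rather than
  counting all contacts per frame) is the default because that is what
  the quantity's name promises; intra-residue pairs are excluded as they
  never break.
* **SASA**: Shrake-Rupley with a deterministic golden-spiral point set
  (960 points/atom, probe 1.4 Angstrom), Bondi radii by element. The
  quadrature error on an isolated sphere is under 1%.
* **Secondary structure**: Kabsch-Sander electrostatic HB energy
  `E = 0.084 * 332 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, bond if
  `E < -0.5`. Reduced alphabet: H (alpha, two consecutive i->i+4 turns),
  G (3/10), E (parallel/antiparallel bridges), T (isolated turns), C,
  with priority H > E > G > T. Helix counts report H+G together, matching
  the convention of grouping 3/10 with alpha helices. Chains shorter than
  3 residues are all-coil with a warning.
* **Deltas**: `percent_change = 100 (b - a) / a` and
  `fold_change = (b - a) / a` (so "a 3.64-fold increase" means the value
  grew by 3.64 times the baseline). Secondary-structure changes are
  computed on the helix+sheet+turn sum. A zero baseline with a nonzero
  target is an error, not an `Inf`.

## Flexibility vs burial depth

RMSF is computed per residue from the fitted CA coordinates. For the
depth profile, surface atoms are heavy solute atoms with more than 0.5
Angstrom^2 of SASA on the *trajectory mean structure* (a single static
profile, not per-frame averaging); a residue's depth is the distance from
its CA to the nearest surface atom, zero if its own CA is at the surface.
Residues are binned into equal-width depth bins; empty bins are `NA`,
never zero. The 0.5 Angstrom^2 threshold and the nearest-surface-atom
depth are package choices — the notion of "distance from the protein core
to the surface" has no canonical definition — and both are configurable.

## Free-energy landscapes

`histogram_fel()` is Boltzmann inversion, `F_b = -kT ln(n_b / n_max)`,
with empty bins masked. `langevin_sample()` integrates overdamped
Euler-Maruyama dynamics on analytic 1D potentials,
`s <- s - U'(s)/friction dt + sqrt(2 kT dt/friction) xi`.

`wt_metadynamics()` adds a history-dependent bias: every `stride_ps` a
Gaussian hill of height `w0 exp(-V(s)/((gamma-1) kT))` and width `sigma`
is deposited at the current CV value; defaults are w0 = 0.4 kJ/mol,
sigma = 0.35 CV units, stride 2 ps, bias factor gamma = 10 — the standard
settings for eigenvector-projection CVs. The bias and its gradient live
on a grid of spacing sigma/5, so each step costs O(1). Two estimators are
returned: the instantaneous `F = -(gamma/(gamma-1)) V_bias` and a
shot-noise-reduced `fes_avg` that averages the bias shape over the second
half of the run (the growing global offset of `V_bias` cancels when the
estimate is shifted to min 0). The reconstruction used by the original
workflow (weighted-histogram analysis in an external engine) is replaced
by these standard bias-potential estimators, plus an optional
`reweighted_fel()` using `exp(V_bias/kT)` weights under the final bias.

Two numerical points deserve emphasis because both were found the hard
way and are now covered by tests:

1. **The integration step must resolve the bias.** With the per-step
   random displacement `sqrt(2 kT dt / friction)` comparable to the hill
   width, the walker cannot equilibrate in the bias it deposits and the
   reconstruction develops a growing systematic dome. The defaults
   (dt = 0.01 ps, friction = 5) keep the step near 0.1 CV units, well
   below sigma = 0.35.
2. **Boundaries are imperfect.** The walker reflects at the grid bounds,
   and the bias is systematically under-built within about three hill
   widths of a boundary (no hills are ever centred beyond it). Flatness
   and barrier checks therefore evaluate the estimate away from the
   bounds.

## Solvent MSD and hydration shell

Coordinates are unwrapped by accumulating minimum-image frame-to-frame
displacements (orthorhombic boxes), then
`MSD(tau) = <|r(t+tau) - r(t)|^2>` over molecules and all sliding time
origins, with `D = slope/6` from a linear fit over a configurable lag
window. Waters are classified per frame as hydration (oxygen within 4.5
Angstrom of any protein heavy atom — a conventional first-shell bound,
configurable) or bulk; when subset MSDs are computed, membership is taken
at each time origin. The expected signatures are linear growth for free
diffusion, `MSD = v^2 tau^2` for ballistic motion, and a plateau at
`6 kT / kappa` for harmonic (glass-like) confinement.

## Replica management

`join_equilibrated()` drops frames with `time <= discard` (default 1000
ps, i.e. the first nanosecond — the conventional fixed equilibration
discard rather than an automated plateau detector, so joined lengths are
predictable: six 15-ns replicas saved every 10 ps become one 84-ns,
8400-frame trajectory) and concatenates the rest onto a continuous time
grid, keeping a provenance table. Order-free statistics (ED spectra, HB
statistics, RMSF) are invariant to replica order; a permutation test
asserts this.

# What the synthetic generators emulate — and what they do not

* `gen_gaussian_mode_trajectory()` plants an exact low-rank covariance
  (`frames = reference + sum_k z_k v_k`, `z_k ~ N(0, lambda_k)` i.i.d.
  per frame). It emulates the *equilibrium fluctuation* structure that ED
  should recover; it has no kinetics, so it says nothing about
  convergence diagnostics on correlated data. Planted modes are drawn
  orthogonal to the six rigid-body modes of the selection, since
  superposition would otherwise silently drain their variance.
* `gen_random_walk()` supplies the diffusion-like regime that makes
  cosine contents approach 1; `gen_two_state()` is a Markov chain whose
  stationary ratio `exp(-delta_F)` is enforced through detailed balance,
  with Gaussian jitter at 5% of the state separation so histograms stay
  bimodal.
* `gen_toy_protein_solvent()` builds an ideal peptide (helix phi/psi =
  -57/-47; extended -120/120; ideal bond geometry N-CA 1.46, CA-C 1.52,
  C-N 1.33 Angstrom, omega 180) plus waters, and moves designated
  acceptor atoms so that each scheduled bond satisfies the detection
  criteria exactly on its "on" frames and misses the distance cutoff by
  exactly 0.3 Angstrom on its "off" frames (violating distance rather
  than angle avoids boundary ambiguity). Donor sites sit four residues
  apart on an extended chain, moved acceptors are always acceptor-only
  atoms, and scheduled waters point their hydrogens away from the
  protein, so the schedule is reproduced with zero false positives or
  negatives — the tests assert exact equality. The geometry is purely
  kinematic: no energetics, no water model, no thermal noise.
* `gen_beta_hairpin()` places a second extended strand, rotated 180
  degrees about z, at an offset calibrated once (by least-squares
  placement of two N-H...O=C rungs) so the Kabsch-Sander antiparallel
  bridge pattern forms between strand interiors.
* `gen_solvent_box()` gives diffusing (wrapped random walk) or arrested
  (Ornstein-Uhlenbeck about fixed cages) single-site waters in a periodic
  box.

Passing tests on these fixtures shows the *analysis* code is correct at
exact thresholds and on known covariances and rates. It does not show
that real trajectories are converged, that the donor/acceptor name table
covers exotic chemistry, or that the reduced DSSP alphabet matches full
DSSP on real proteins.

# Problem sizes and tolerances in the shipped checks

The test-suite and acceptance-script sizes were chosen so the whole suite
runs in about a minute on one CPU while keeping Monte-Carlo error well
inside each tolerance: ED recovery uses 60 residues x 10^4 frames
(eigenvalues within 10%, eigenvector overlap > 0.99); the HB detector is
compared with brute-force enumeration on 100 random clouds (exact
equality); Langevin equipartition uses 2 x 10^6 steps at dt = 0.002
(variance within 5%; the Euler-Maruyama stationary variance carries a
known O(kappa dt / friction) bias, which this dt keeps near 0.5%);
metadynamics barrier recovery averages five 2-ns runs against a 5 kT
double-well with minima at +/-2 CV units (within 10%; the +/-2 separation
keeps the barrier-top curvature small enough that Gaussian smoothing with
sigma = 0.35 biases the estimate by only a few percent); the flat-landscape
check runs 24 ns so the time-averaged estimator's residual roughness sits
below 1.5 x w0; two-state and histogram-FEL checks use 10^5 samples;
solvent MSD checks use 60-80 particles over 2000-3000 frames.

# Known limitations

* The PDB reader keeps the first alternate location and performs no
  remediation; no protonation-state prediction.
* DSSP is the reduced 5-letter variant: no pi-helix, bend, or
  beta-bridge distinction, and no ladder/sheet topology output.
* The metadynamics engine works on analytic or precomputed 1D CVs only —
  it is a sampler for validating FEL reconstruction, not an MD engine;
  biasing an eigenvector projection as a function of atomic coordinates
  is out of scope.
* `unwrap_msd()` assumes orthorhombic boxes and jump-free inter-frame
  displacements (particles must move less than half a box edge between
  frames).
* Depth profiles use the nearest-surface-atom approximation, not a
  molecular-surface mesh.
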