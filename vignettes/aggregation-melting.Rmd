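---
title: "Melting analysis of multi-chain peptide ensembles"
author: "aggremelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting analysis of multi-chain peptide ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggremelt)
```

## The problem

Short peptides in solution either stay monomeric or associate into
oligomers and, eventually, amyloid-like fibrils or gels.  Coarse-grained
replica-exchange simulations of a small number of chains (here eight) in a
cubic periodic box, run across a ladder of temperatures, give equilibrium
ensembles from which the association behaviour can be read off: the
fraction of chains in the full octamer, `f8(T)`, falls sigmoidally with
temperature, and its midpoint `T8m` is the octamer-dissociation
temperature.  Whether `T8m` lies above or below the incubation temperature
(310 K) predicts whether the peptide aggregates.

`aggremelt` implements the analysis side of that workflow:

1. **sequence descriptors** — GRAVY hydropathy, net charge, and the cubic
   box side that realises an experimental molar concentration for `n`
   chains;
2. **ensemble handling** — multi-chain Calpha-trace snapshots with energies
   and replica metadata, windowing/sub-sampling, minimum-image geometry;
3. **oligomer identification** — transitive closure of a pairwise contact
   criterion (any Calpha–Calpha distance < 7 Å);
4. **secondary structure** — beta/alpha/coil per residue from virtual-bond
   geometry plus a hydrogen-bond proxy;
5. **reweighting** — binless WHAM across the temperature ladder, melting
   profiles and heat capacity;
6. **melting statistics** — midpoints, inflections, Cv peaks, window
   convergence, and the hydropathy–melting-temperature regression;
7. **clustering** — Ward's method with WHAM-weighted ranking,
   representatives, per-residue RMSF;
8. **a synthetic generator** whose thermodynamics are exactly enumerable,
   so the whole pipeline can be validated end to end.

The simulation engine itself (the coarse-grained force field and the
replica-exchange dynamics) is out of scope: the package consumes snapshots.

## Descriptors

GRAVY is the mean Kyte–Doolittle index over the sequence; it ignores
terminal modifications and is permutation-invariant.  The net charge is a
Henderson–Hasselbalch sum over ionizable groups; the pKa set is an explicit,
injectable parameter (`defaultPka()`: D 3.65, E 4.25, C 8.3, Y 10.07, H 6.0,
K 10.53, R 12.48, N-term 9.0, C-term 3.6) because web calculators used for
reference tables do not publish theirs.  Charges that depend on fractional
terminal ionisation therefore carry a convention; only charges dominated by
fully (de)protonated groups are convention-free, and the automated checks
restrict themselves to those.

The box side for concentration `C` (mM) and `n` chains is
`(n / (C N_A))^(1/3)` with the exact SI Avogadro constant, converted to
Ångström:

```{r descriptors}
computeGravy("ARKQIV")
boxSideForConcentration(4.210, 8)
```

Printed reference tables round concentrations to three decimals; propagated
through the cube root this pins the side down only to about ±0.1 Å, which is
why the regression tests compare full-table sides within a ±0.15 Å band and
anchor rows at printed precision.

## The ensemble model and windowing

A `Frame` is one snapshot: per-chain Calpha coordinates (Å), the potential
energy, the 1-based ladder index at which it was sampled, a trajectory id
and a step count.  Coordinates are stored unwrapped per chain — a chain
never straddles the periodic boundary in stored form — so intra-chain
geometry is directly usable; all inter-chain distances go through the cubic
minimum-image convention.  Energies are carried opaquely in a declared unit
(default kcal/mol); only ratios `E/(kB T)` are consumed.

Long replica-exchange runs are analysed on their final segment:
`analysisWindow()` keeps the last `windowFrames` frames of each trajectory
and then every `stride`-th of those, so 48 trajectories with a 1000-frame
window at stride 8 yield the canonical 6000 analysis snapshots.

The on-disk dialect is deliberately plain: a multi-model PDB with CA records
(one MODEL per frame, chains A, B, ...), a metadata TSV
(`frame_index traj_id step temp_index energy`, both indices 0-based as the
header states), and a key=value config with the ladder and box.

## Oligomers

Two chains are associated when *any* Calpha of one is strictly closer than
7 Å (minimum image) to *any* Calpha of the other.  Oligomers are grown
iteratively — start from the lowest unassigned chain, repeatedly scan the
remaining chains in index order for one associated with any current member,
restart with the next unassigned chain — which is provably the connected
components of the association graph; the test suite checks that equivalence
against an independent brute-force closure on a thousand random frames.
From a partition, `f_m = m * count(m) / n` and `sum_m f_m = 1`.

The strict inequality at the cutoff and the use of minimum image (needed
for chains near box faces) are deliberate choices; all Calpha atoms
participate.

## Secondary structure from a Calpha trace

With only Calpha positions, secondary structure must be inferred from
virtual-bond geometry plus an interaction pattern.  A residue `i` carries a
virtual dihedral over Calpha `i-1..i+2`; the pseudo-peptide centers
(midpoints of consecutive Calphas) stand in for the hydrogen-bond-carrying
peptide groups.

* **alpha**: dihedral in the helical band (30°–70°; an ideal Calpha helix
  with 1.5 Å rise, 2.3 Å radius, 100°/residue sits at +50°), Calpha
  `(i, i+3)` distance < 6 Å (ideal ≈ 5.05 Å), *and* an `i, i+3`-type
  center contact below the hydrogen-bond proxy distance (5.5 Å; ideal
  ≈ 4.7 Å).
* **beta**: |dihedral| > 120° (planar zigzag = 180°) *and* a flanking
  pseudo-peptide center pairs with another strand's centers — a different
  chain, or the same chain at sequence separation ≥ 4 — within 5.5 Å in a
  ladder of at least 2 consecutive rungs (parallel or antiparallel),
  searched under minimum image so sheets forming across the periodic
  boundary are found.
* **coil** otherwise; chain ends with undefined dihedrals, and chains
  shorter than 5 residues, default to coil.

Every threshold is a named parameter of `secstructParams()`.  The bands are
calibrated so the analytic fixtures classify correctly: an ideal helix is
alpha in its interior, two in-register strands 4.8 Å apart are beta, and an
isolated extended strand is coil — extended local geometry alone is *not*
beta, mirroring the fact that optical measurements of "extended" content do
not imply hydrogen-bonded sheet.  The exact dihedral bands and the minimum
ladder length (2 vs 3) are calibration parameters of this package, not
facts inherited from any particular all-atom assignment scheme.

```{r secstruct}
box <- boxSpec(200)
sheet <- idealSheetFrame(10, 2)
sheet <- lapply(sheet, function(x) sweep(x, 2, c(100, 100, 100), "+"))
assignStates(sheet, box)$states
```

## Binless WHAM

Samples from all ladder temperatures are pooled.  With `N_k` snapshots at
inverse temperature `beta_k`, the dimensionless free energies `f_k` solve

```
exp(-f_k) = sum_i exp(-beta_k E_i) / sum_l N_l exp(f_l - beta_l E_i)
```

and the normalized weight of snapshot `i` at any target temperature `T` is
`w_i(T) ∝ exp(-beta E_i) / sum_l N_l exp(f_l - beta_l E_i)`.  The package
iterates this self-consistency with log-sum-exp stabilisation, gauge
`f_1 = 0`, converging on `max |Δf| < 1e-10` (deterministic given input
order).  Ensemble averages are then `sum_i w_i(T) v_i` for any per-snapshot
observable `v` (octamer fractions, chain-averaged state fractions), and the
heat capacity is `Cv(T) = (<E²> - <E>²) / (kB T²)` per system — reported
only for peak locations, since its absolute normalisation depends on the
implicit-solvent energy model upstream.

Numerical properties enforced by tests: weights sum to 1 to 1e-12 at every
temperature; adding a constant to all energies changes no weight;
duplicating every snapshot changes nothing; a two-level system sampled at
exact Boltzmann proportions reproduces its closed-form mean energy and
Schottky heat-capacity peak; and the self-consistent solution agrees to
1e-6 with an independent route — direct BFGS minimisation of the convex
multistate-reweighting likelihood (`whamFreeEnergiesOptim()`).

Statistical-inefficiency corrections are deliberately absent: the upstream
protocol sub-samples by stride instead, and the windowing operation
implements exactly that.

## Melting statistics

* `midpointTemperature()` fits the logistic `1/(1 + exp((T - Tm)/s))` by
  least squares and returns `Tm`; an interpolated 0.5 crossing is both the
  fallback (with a warning) and an alternative method, and the two agree
  within 1 K on clean sigmoids.  Profiles that never cross 0.5 raise
  directional errors ("above grid"/"below grid").
* `inflectionTemperature()` fits `a/(1 + exp((T - Ti)/s)) + b` — suited to
  the beta fraction, which never reaches 1 — and falls back to the maximum
  |slope| of a lightly smoothed profile; exact slope ties break to the
  middle of the tied range.  A fit whose width `s` exceeds a third of the
  grid span is not a dominant inflection and triggers the fallback.
* `cvPeaks()` returns local maxima above a topographic-prominence
  threshold (5 % of the range by default), tallest first.
* `windowConvergence()` computes, for consecutive simulation windows, the
  RMS deviation `sigma_f8` of each window's `f8(T)` from the final
  window's over the ladder temperatures; a run has converged when the
  series has stopped decreasing (final two values within 10 % relative, a
  non-decreasing tail, or an identically zero series).  RMS over the
  ladder was chosen as the norm; the tail tolerance is configurable.
* `linearCorrelation()` is ordinary least squares with Pearson `R` and the
  `n-2`-denominator residual standard deviation, for descriptor–melting
  regressions such as `T8m` against GRAVY.

## Clustering and RMSF

Frames at a chosen temperature are compared by all-chain Calpha RMSD after
optimal rigid superposition.  Because the chains are identical copies, the
default metric also minimises over chain relabelings: exhaustively for up
to five chains, otherwise by Hungarian assignment over chain centroids with
iterative refinement, symmetrised over both directions — a pseudo-metric
that vanishes on permutation-equivalent frames.  Ward's minimum-variance
linkage (`hclust`, `ward.D2`) is cut at `k = 5` clusters, which are ranked
by cumulative WHAM weight; each cluster's representative is its medoid
(the member minimising mean squared distance to the rest — the coordinate
mean is ill-defined under permutation symmetry; in fixed-labels mode a mean
structure does exist and the medoid is its natural proxy).  Ties break to
the lowest frame index.  Clustering operates on a weighted subsample
(default 600 frames drawn by `w_i(T)` under a fixed seed) to bound the
O(n²) distance matrix; whether one clusters all analysis snapshots or a
subsample is a documented choice of this package.

`rmsfPerResidue()` pools every chain of the supplied models, superposes
them onto an iteratively re-estimated mean chain, and reports the
per-residue root-mean-square deviation from that mean.

## The synthetic generator and what it does (not) emulate

Real trajectories of this kind are rarely redistributable, so validation
uses a generator whose thermodynamics are known exactly.  The model is a
Hamiltonian over set partitions `P` of `n` chains:

```
E(P) = -epsilon * sum_blocks choose(|b|, 2)
w(P, T) = nu^{|P|} * exp(-E(P) / (kB T))
```

`epsilon` (kcal/mol) is the contact energy per associated pair; `nu` is a
translational-entropy factor per independent oligomer (the available volume
per cluster in reference-volume units), which makes dissociation win at
high temperature.  For `n ≤ 10` the partition function is an explicit sum
(Bell(8) = 4140 terms), so `f_m(T)`, the mean energy, `Cv(T)` and the exact
midpoint of `f_n(T)` are all available from `enumeratePartitionModel()`.

Sampling uses Metropolis Monte Carlo over partitions — single-chain
reassignment plus merge/split block moves, each with its exact Hastings
correction (the test suite verifies the stationary distribution against the
enumeration for 3 and 4 chains) — with replica exchange between
neighbouring ladder temperatures; the entropic factor cancels in the swap
acceptance.  Each replica is initialised with an exact Boltzmann draw at
its own rung, which the enumerable model makes possible; this removes
burn-in bias (forming an octamer from monomers at low temperature is slow,
uphill nucleation) while leaving the Markov chain to generate all
subsequent correlated samples.  Snapshots are recorded at each exchange
point.  Each snapshot
is rendered into coordinates: blocks as in-register extended-strand bundles
(3.8 Å virtual bonds, 4.8 Å spacing — satisfying both the contact criterion
and the beta criteria), free chains as self-avoiding coils, blocks placed
with bounding-sphere separation beyond the cutoff plus margin.  Rendering
can be deferred (`renderCoords = FALSE` plus `renderFrames()` after
windowing) so only analysed frames pay the geometric cost.

Default parameters are fixed once: 8 chains of 6 residues, the 12-rung
260–370 K ladder, `epsilon = 0.65`, `nu = 50` — placing the exact octamer
midpoint near 311 K, mid-ladder and close to the 310 K incubation
temperature of the motivating experiments — 4 multiplexed replica sets (48
trajectories), a 100 Å box.  The generator emulates the *structure* of
replica-exchange data (ladder walks, exchange-point snapshots, energies
consistent with a temperature-independent density of states) and the
*geometry* the analysis consumes; it does not emulate force-field
energetics, kinetics, partial/disordered aggregates, or intra-chain
conformational transitions.  Passing end-to-end tests therefore shows the
analysis chain is correct and self-consistent, not that any force field is
accurate.

### Validation problem sizes

The end-to-end check runs five generator settings with `epsilon` from 0.564
to 0.731, whose exact midpoints span ≈270–350 K, each sampled at the
default study scale — 4 multiplex sets × 12 replicas (48 trajectories) ×
8000 sweeps (exchange every 10 sweeps) — then windowed to the last 512
snapshots per trajectory at stride 8 (3072 analysis frames).  The sampling
length is sized so the statistical error of the midpoint (well under 1 K at
these sizes) sits comfortably inside the ±2 K recovery requirement.  Two
bias sources were identified and removed during calibration: burn-in (cured
by the exact-draw initialisation) and estimator mis-specification — the
pure-logistic fit assumes `f8 → 1` at low temperature, which the partition
model does not satisfy at the weakly associating end, so the recovery check
compares the interpolated 0.5 crossing against the oracle's 0.5 crossing,
i.e. the same functional on both sides.  What remains is Monte Carlo noise
in `f8` near the transition.

```{r e2e, eval = FALSE}
spec <- toyModelSpec(epsilon = 0.65, multiplex = 2L, nSweeps = 8000L,
                     seed = 1L)
ens <- sampleEnsemble(spec, renderCoords = FALSE)
w   <- renderFrames(analysisWindow(ens, windowFrames = 512L, stride = 8L))
fm  <- oligomerFractionMatrix(w)
wt  <- solveWham(w)
f8  <- ensembleAverage(wt, fm[, 8], grid = seq(260, 370, by = 1),
                       label = "f8")
midpointTemperature(f8)           # ~311 K
oracleMidpoint(enumeratePartitionModel(spec))
```

## Numerical choices and degenerate inputs

* Rounding against printed tables uses round-half-away-from-zero.
* `kB = 0.0019872041` kcal/(mol K); `N_A = 6.02214076e23` (exact).
* WHAM: log-sum-exp throughout; single-temperature input degenerates to
  uniform weights with a warning; non-convergence raises an error carrying
  the residual.
* Sigmoid fits use Levenberg–Marquardt (`nlsLM`) with data-driven starts;
  every fallback path is exercised by tests.
* Ward merge order is deterministic given the distance matrix; medoid and
  cluster-ranking ties break to the lowest index.
* The coil builder rejects self-intersecting walks (non-bonded separation
  ≥ 4 Å) and retries; the block placer fails with an instructive error when
  the box cannot host all blocks at the required separation.

## Known limitations

* The secondary-structure thresholds are calibrated on ideal geometries;
  borderline real conformations (bent strands, 3-10-like turns) will land
  in coil more often than a full hydrogen-bond model would put them there.
* `Cv` is a per-system point estimate without error bars; only peak
  locations are meaningful.
* The best-permutation frame metric is exact only up to five chains;
  beyond that the assignment heuristic can overestimate distances for
  near-degenerate chain arrangements.
* No bootstrap uncertainties on `T8m`; the convergence diagnostic
  (`windowConvergence`) is the intended guard against under-sampling.
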