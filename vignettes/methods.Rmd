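---
title: "Methods: quantifying conformational selection vs induced fit from ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying conformational selection vs induced fit from ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpmech)
```

## The scientific question

Intrinsically disordered proteins (IDPs) often fold only upon binding a
partner. Two limiting mechanisms are distinguished: *conformational
selection* (CS), where binding-competent conformers already exist in the
unbound ensemble and the partner selects them, and *induced fit* (IF),
where partner contact drives the structural change. Real systems mix
both; the practical question is at which spatial scale each dominates.
`idpmech` operationalises this question for any two-chain system given
three conformational ensembles: the bound complex, and each chain
unbound (apo). The motivating system is the p53 transactivation domain
binding the CBP nuclear coactivator binding domain, where both chains
are disordered until bound.

## Contacts and kinetics

A residue pair is in (generic) contact when the minimum distance between
their side-chain heavy atoms is strictly below **6.5 Å**; glycine's Cα
substitutes for its missing side chain; intra-chain pairs must be at
least 2 positions apart in sequence ("not adjacent"), while all
inter-chain pairs are eligible. Electrostatic contacts require one
positive (Arg, Lys, His) and one negative (Asp, Glu) residue whose
side-chain charge-group centers of mass approach within **11 Å**; the
charge-group atom sets (e.g. Arg NE/CZ/NH1/NH2, Asp OD1/OD2/CG) are a
package choice, since "charge center" needs an operational definition.
Hydrogen bonds use a heavy-atom criterion of our own (donor–acceptor
< 3.5 Å, antecedent–donor–acceptor angle > 120°), the field-standard
geometry in the absence of explicit hydrogens. All cutoffs are strict
inequalities; boundary cases (exactly 6.5 Å) are non-contacts.

Native contacts are the generic contacts of the reference (bound)
structure, split into *tertiary* (intra-chain) and *binding*
(inter-chain) scopes. Per frame, `qf` and `qb` are the fractions of
native tertiary/binding contacts still satisfied; a channel with zero
native contacts is reported as undefined (`NA`), never 0/0.

Unbinding/unfolding kinetics are fitted in log space: ordinary least
squares of `ln q` on `t` gives the rate `k = −slope`, half-time
`ln 2 / k`, and the half-time standard error by propagation
(`ln 2 · se_k / k²`). We fit in log space rather than by nonlinear least
squares on `q` because the estimator is then closed-form, reproducible
to the last bit, and matches the log-scale presentation customary for
these decays. The default window is the first 80% of frames (trimming
the equilibrated tail); the fit refuses windows containing `q ≤ 0` and
instructs truncation instead of silently dropping points. Fits with
`k ≤ 0` (within 1e−12) are flagged non-decaying rather than reported as
infinite half-times. `averaged_fit()` averages replicate series on a
shared time grid before fitting, and also reports the across-replica
standard deviation of per-replica half-times, since fit standard errors
and across-trajectory spread answer different questions.

## Transition-state identification and Φ-values

The transition state of a two-state unfolding trajectory is located
from structure alone: the matrix of pairwise fitted Cα RMSDs between
strided frames is embedded in 2D by Sammon nonlinear mapping, the
embedded points are connected in time order, and segments are cut where
the consecutive-point displacement exceeds
`mean + jump_factor · SD` (default `jump_factor = 2`) of all
consecutive displacements; segments shorter than 3 points are merged
into their longer neighbour. The transition-state ensemble is the
frames within ±40 ps of the first inter-segment barrier (the barrier
time is the midpoint between the flanking frames). The ±40 ps width is
a package default: the literature localises transition states to a time
point without stating a window.

Sammon details: stress
`E = (1/Σ d*ᵢⱼ) Σ (d*ᵢⱼ − dᵢⱼ)² / d*ᵢⱼ`, initialisation by classical
metric scaling (`cmdscale`), pseudo-Newton descent with Sammon's magic
factor 0.3 and per-iteration step halving, so the stress is
non-increasing across accepted iterations by construction; stopping at
`ΔE < 1e−9` or 500 iterations. Zero distances between distinct frames
are jittered to 1e−6 Å with a warning (the stress is undefined at
`d* = 0`). The embedding is deterministic given the seed; the seed only
matters for degenerate inputs needing jitter.

Φ-values locate structure formation at the transition state: for
residue *i* and ensemble X, `Nᵢ^X` is the mean number of satisfied
native contacts involving *i*, and
`Φᵢ = (Nᵢ^TS − Nᵢ^U)/(Nᵢ^F − Nᵢ^U)`. Φ is undefined when the
denominator is below 1e−9 or the residue has no native contacts
(reported `NA`, never 0). Out-of-range raw values are kept in
`phi_raw` and clamped to [0, 1] in `phi`, so plots and summaries use
the clamped value while the raw one remains inspectable.

## CS/IF quantification

From each ensemble, frames are sampled *evenly in time* (not randomly;
determinism costs nothing here), 10 bound × 10 apo = 100 pairs by
default. Each apo frame is superposed onto each bound frame by **all Cα
atoms of the analysed chain**, and the pair RMSD grid gives each bound
frame its most-similar apo frame (ties broken by earlier apo
timestamp).

Atoms are binned by distance from the mass-weighted partner centroid in
half-open 0.5 Å bins over 0–50 Å (100 bins; atoms at ≥ 50 Å go to an
overflow group). Bins for a bound–apo pair use that bound frame's own
geometry. Per bin, the per-atom deviation sample of each pair is
compared against the pooled apo–apo baseline deviations by a two-sample
Kolmogorov–Smirnov test; the per-bin median P and the fraction of pairs
with P < 0.1 summarise where the bound ensemble differs significantly
from apo variability. We use per-atom deviation distributions within a
bin (not one scalar per bin) so the KS test has a sample to work with.
Exactness follows `stats::ks.test`'s default rule. This matters: with
equal small samples the exact two-sample KS null distribution is
discrete and conservative (we measured fraction P < 0.1 of 0.069 at
n = m = 50), while unequal sample sizes — the realistic case, since the
pooled baseline always dwarfs a single pair's bin sample — give a
fine-grained, calibrated null.

The Δ statistic weighs the two mechanisms: CS magnitudes are the
pairwise RMSDs among sampled apo conformers (the spread available for
selection); IF magnitudes are the residual RMSDs between each bound
frame and its most-similar apo frame. Δ is the frequency-weighted mean
of CS values minus that of IF values; since the frequency-weighted mean
of observed values equals the sample mean, Δ is exactly independent of
the histogram bin width (0.25 Å histograms are kept for reporting), and
swapping the inputs flips its sign exactly. Δ is computed at global
scope (all chain atoms) and local scope (atoms within 10 Å of the
partner centroid). The local set is measured on the *ensemble-mean*
bound conformation: a single noisy bound frame can admit high-mobility
atoms into the local set and flip the Δ_local sign, which we observed
in a file-round-trip test before fixing the definition. The 10 Å local
cutoff is a package choice; "local" versus "global" is qualitative in
the source literature.

The verdict is a labelling of the Δ signs: Δ_global > 0 ⇒ "global
conformational selection", Δ_local < 0 ⇒ "local induced fit", both ⇒
the combined verdict.

## What the synthetic generator emulates — and what it does not

The generators plant known statistical structure so that every analysis
stage has a recoverable ground truth:

* **Toy complex** — two chains (30 + 14 residues by default) of ideal
  helix (φ = −57°, ψ = −47°) flanked by seeded coil, built from
  canonical backbone internal coordinates, each residue carrying one
  pseudo side-chain heavy atom at an extended Cβ position with the
  residue's summed side-chain mass. Chains are packed to the tightest
  clash-free approach that yields ≥ 5 binding contacts and ≥ 5 atoms in
  the 10 Å near zone (so the local IF channel always has atoms to act
  on); rotations and axial offsets of the partner are scanned as
  fall-backs.
* **Deviation ensembles** — apo frames are the reference plus Gaussian
  per-atom displacements with distance-dependent amplitude (0.2 Å near
  / 1.5 Å far of a 10 Å crossover); `cs_dominant` makes bound frame *i*
  track apo conformer *i* up to a 0.1 Å residual, `if_dominant`
  displaces bound interface atoms by 1.5 Å against a quiet apo
  ensemble, and `mixed` does both at their respective scopes. 50 frames
  at 20 ps spacing.
* **Unfolding** — native contacts break independently with probability
  `1 − exp(−k·dt)` per frame (default k = 0.05 ps⁻¹, dt = 1 ps, 60
  frames) and broken residues interpolate toward seeded coil targets
  placed away from the complex. Exact independence of contacts is
  geometrically achievable only when contacts are residue-disjoint, so
  unfolding uses a two-strand *ladder* complex (one binding contact per
  rung, 5.6 Å facing gap, 6.7 Å diagonals) rather than the helix
  bundle; the measured Q then equals the planted contact states
  exactly and E[Q(t)] = exp(−kt) holds by construction.
* **Multi-basin trajectories** — k sequential basins (default 3),
  centers separated by ~3 Å Cα RMSD, 0.15 Å within-basin noise, 20
  frames per dwell, with the switch frames recorded.

All generators restore the caller's RNG state and are bit-identical
under a fixed seed. None of this is physics: there is no force field,
no solvent, no thermodynamic consistency, and the deviation fields are
atomwise independent Gaussians with none of the correlated, anisotropic
motion of real proteins. Passing the recovery suite therefore
demonstrates that the *estimators* are correct and calibrated on data
satisfying their assumptions — not that real trajectories satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Superposition is Kabsch via SVD with the determinant forced to +1
  (reflections forbidden); fewer than 3 selected atoms, or collinear
  selections, are errors. Pairwise RMSD matrices use the closed-form
  Kabsch identity for speed and recompute entries below 1e−4 Å with
  the explicit rotation, because the closed form cancels
  catastrophically near zero.
* PDB reading drops waters, heteroatoms and hydrogens, and keeps the
  highest-occupancy alternate conformer. Input residue numbering is
  preserved verbatim and never rewritten. Malformed ATOM records fail
  with the offending line number.
* Circular standard deviations of dihedrals use `sqrt(−2 ln R̄)` with
  exact zero returned for `R̄` within 1e−12 of 1, so constant angles
  report exactly 0°.
* Helicity counts a residue-frame as helical iff φ ∈ [−100°, −30°],
  ψ ∈ [−80°, −5°] and it sits in a run of ≥ 3 consecutive helical
  residues; the window and run length are package choices, documented
  so comparisons are like-for-like. Chain termini lacking a dihedral
  can never count as helical.
* Free-energy landscapes report `F = −ln(P/P_max)` in kT (no
  temperature is assumed for unit conversion), `ΣP = 1` over occupied
  cells, empty cells `F = +∞`, and basins as 4-connected components of
  cells with `F < 1 kT`. A single-conformation ensemble degenerates to
  one cell at `F = 0`.

## Problem sizes in the test suite

The recovery suite runs at sizes chosen to exercise the statistics
honestly while keeping a full run around two minutes: 400-frame Q
series with 100 seeds per rate for kinetics recovery (within 5% of
ln 2/k); 20 random 50-residue two-chain toys for exact brute-force
contact agreement; 100 seeded multi-basin trajectories (60 frames each)
for segmentation recovery (≥ 95/100 with boundaries within ±2 frames);
1000 null replicates for KS calibration (fraction P < 0.1 inside the
99% binomial envelope of 0.10, pooled P uniform at α = 0.01); and 100
seeded planted-mechanism runs for the Δ-sign recovery (≥ 95/100).

## Known limitations

* The CS/IF decomposition is heuristic: Δ compares deviation
  magnitudes, not kinetic fluxes. Flux-based discrimination (rate
  matrices over binding pathways) is explicitly out of scope.
* Φ-values from contact counts assume the native contact set is the
  right order parameter; residues without native contacts are
  undefined.
* The Sammon embedding is a local optimiser; different distance
  matrices with identical segment structure can embed with different
  global shapes. Segmentation depends only on consecutive-point
  displacements, which is why it tolerates this.
* The transition-state window (±40 ps) and local cutoff (10 Å) are
  defaults to be revisited per system; both are plain arguments.
* With a single high-temperature trajectory the TS ensemble is one
  sample; pooling across replicate trajectories (supported by running
  the stages per trajectory and pooling frames) is preferable when
  replicates exist.
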