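# idpmech

Does an intrinsically disordered protein (IDP) bind its partner by
**conformational selection** (binding-competent conformers pre-exist in the
unbound ensemble and are selectively stabilised) or by **induced fit** (the
bound conformation is imposed by partner contact)? `idpmech` answers this
question from conformational ensembles alone: a set of bound-complex
conformations and a set of unbound (apo) conformations of each chain, such
as frames from molecular-dynamics trajectories of a coupled
folding-and-binding pair (the motivating system is the p53 transactivation
domain bound to the CBP nuclear coactivator binding domain).

## The analysis

**Native contacts and kinetics.** Residue pairs are in contact when their
side-chain heavy atoms approach within 6.5 Å (Cα stands in for glycine);
salt bridges when oppositely charged side-chain charge centers come within
11 Å; hydrogen bonds by a 3.5 Å / 120° donor–acceptor criterion. The
fractions of native intra-chain (tertiary) contacts Qf and inter-chain
(binding) contacts Qb per frame give unfolding/unbinding kinetics: a
log-linear fit `ln q = a − k t` yields the rate k and half-time
t½ = ln 2 / k with closed-form standard errors.

**Transition state and Φ-values.** Pairwise Cα RMSD between strided frames
of a high-temperature trajectory is embedded in 2D by Sammon nonlinear
mapping (stress E = (1/Σd*ᵢⱼ) Σ (d*ᵢⱼ − dᵢⱼ)²/d*ᵢⱼ); time-contiguous
clusters are cut where consecutive-point displacements jump, and the
transition-state ensemble is the frames around the first inter-cluster
barrier. Per residue,

    Φᵢ = (Nᵢ^TS − Nᵢ^U) / (Nᵢ^F − Nᵢ^U)

with Nᵢ^X the mean count of satisfied native contacts of residue i in
ensemble X (transition state, folded, unfolded).

**CS vs IF quantification.** Bound and apo frames are sampled evenly in
time (10 × 10 = 100 pairs by default); each bound frame's most-similar apo
frame is found by all-Cα-superposed RMSD. Atoms are assigned to 0.5 Å
distance bins (0–50 Å) from the mass-weighted partner centroid, per-bin
local RMSD profiles are computed, and per bin the per-atom deviations of
each pair are tested against the pooled apo–apo baseline with a two-sample
Kolmogorov–Smirnov test (median P and fraction of pairs with P < 0.1 per
bin). The signed statistic

    Δ = Σ fᵢxᵢ / N_CS − Σ fⱼxⱼ / N_IF

weighs the conformational-selection magnitudes (RMSD spread among apo
conformers) against the induced-fit magnitudes (residual bound-to-best-apo
RMSD) at global scope (all atoms) and local scope (atoms within 10 Å of
the partner centroid). Δ_global > 0 with Δ_local < 0 reads "global
conformational selection with local induced fit".

A seeded synthetic-ensemble generator builds toy two-chain complexes and
ensembles with planted statistical structure (known decay rates, planted
cluster switches, CS/IF-dominant deviation fields), so every stage is
testable without MD data.

## Worked example

```r
library(idpmech)

spec <- synthetic_spec(seed = 1)            # planted study conditions
toy  <- build_toy_complex(spec)             # two-chain helix-bundle toy
ens  <- sample_csif_ensembles(spec, "mixed", toy)

res <- csif_analysis(ens$bound, ens$apo, chain = "A")
print(res)
#> csif_result for chain A
#>   Delta_global = +2.826 A, Delta_local = -1.542 A
#>   verdict: global conformational selection and local induced fit

unf <- sample_unfolding_trajectory(spec)    # exact Markov contact decay
qs  <- q_series(unf, attr(unf, "native"))
fit_first_order(qs, "qb", window = c(0, 45))
#> first-order kinetics fit (channel qb, 46 frames, t in [0, 45] ps)
#>   k = 0.047689 +/- 0.0013 ps^-1
#>   half-time = 14.53 +/- 0.39 ps   (R^2 = 0.9687)
```

The planted break rate is 0.05 ps⁻¹ (true half-time ln 2 / 0.05 = 13.9 ps);
the Δ signs recover the planted mixed mechanism. An end-to-end run with
TSVs and a JSON summary:

```r
run_all(run_config(seed = 1, mechanism = "mixed", out_dir = "out"))
```

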