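---
title: "admixmate: model, simulator and inference methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{admixmate: model, simulator and inference methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the mating model and its assumptions, the simulator's mechanics, the
tract-length summary statistic, the neural-network inference machinery,
the model-comparison statistic, and — importantly — the numerical and
design choices made where the problem left them open, and what a green
test suite does and does not establish.

## 1. The mating model

We consider a closed population founded by unadmixed migrants from three
source ancestries (1 = sub-Saharan African, 2 = Native American,
3 = European). Each individual i carries an ancestry-proportion vector
a_i with non-negative entries summing to 1, computed as the
genetic-length-weighted fraction of each ancestry across all haplotypes
the individual carries (autosomes plus one or two X copies).

Couple formation depends only on the within-couple ancestry difference

    d = a_m − a_f        (male minus female, all three coordinates),

which sums to zero across ancestries, so its distribution is a degenerate
trivariate normal represented in the first two coordinates. Its mean is
the sex-bias vector, its covariance encodes assortment:

* **SB_s = μ_s** for s = 1, 2; SB₃ = −SB₁ − SB₂. *Sign convention:*
  d = a_m − a_f throughout, so positive SB_s favours couples in which the
  male carries more of ancestry s. (The source material writes the density
  argument and the SB definition with opposite orientations; we fixed the
  male-minus-female convention everywhere and document it rather than mix
  the two. Inference over a symmetric SB prior is indifferent to the
  choice.)
* **AM_s** maps to the variance of d_s on a logarithmic scale,
  σ_s² = 3^(3 − 7·AM_s), so AM = 0 gives σ² = 27 (a kernel so flat over
  the attainable range |d_s| ≤ 1 that mating is uniform to within ~2%)
  and AM = 1 gives σ² = 1/81 (sd ≈ 0.11 on a unit-range difference:
  strong assortment). The off-diagonal covariance is forced by the
  zero-sum constraint: Cov₁₂ = (σ₃² − σ₁² − σ₂²)/2.

A mating event picks an initiator — a fair coin for sex, then uniform
within the sex class — and the initiator's mate is drawn with probability
proportional to the kernel density over all opposite-sex candidates.
Summed over all F × M couples these probabilities total 1, which the test
suite verifies directly.

**Feasibility of AM triples.** Not every (AM₁, AM₂, AM₃) yields a
positive-definite Σ: e.g. (1, 1, 0) forces a covariance far exceeding the
tight marginal variances. We treat such triples as outside the model:
`build_kernel()` raises a typed error (`admixmate_kernel_infeasible`) and
prior sampling rejects and redraws, which preserves the stated model
exactly rather than projecting onto the PSD cone. Strictness margin:
det Σ must exceed 1e-10; boundary (improper-density) cases are rejected
too.

## 2. The forward simulator

* **State.** Genomes are per-haplotype tract lists (sorted end positions
  in cM plus ancestry codes), tiling each chromosome exactly — an
  invariant checked after every generation in tests. There are no
  sequence-level genotypes: local ancestry is the object of study, so it
  is simulated directly and without error.
* **Founding (generation 0).** Unadmixed individuals, counts apportioned
  to the founding proportions by largest-remainder rounding, sexes an
  exact half/half split. For two-pulse scenarios the first wave is
  proportional to (1 − GFR_s)·c_s, renormalised.
* **Generations.** Non-overlapping; every generation produces exactly N
  offspring (one child per mating event; individuals may mate repeatedly)
  with an exact N/2 : N/2 sex split. The exact split prevents stochastic
  sex-class extinction in small test populations and matches the model's
  standing assumption that both sexes are present.
* **Meiosis.** Per autosome (and the female X), crossover counts are
  Poisson(length in Morgans) with positions uniform in genetic distance —
  no interference — starting from a random homolog; the spliced gamete is
  maximal-merged. The male X is transmitted to daughters unrecombined;
  sons receive only the maternal recombined X. Females therefore
  contribute 2/3 of the X gene pool, which with exact sex balance is an
  exact combinatorial identity, and the X/autosome contrast carries the
  sex-bias signal.
* **Second pulse.** When configured, the cohort formed at the pulse
  generation (default 10 of 19) contains ρ·N unadmixed migrants,
  ρ = Σ_s GFR_s·c_s, split GFR_s·c_s across ancestries; the remainder are
  offspring of the resident population. The algebra
  (1 − ρ)·[(1 − GFR_s)c_s/(1 − ρ)] + GFR_s·c_s = c_s returns the expected
  composition exactly to c — verified stochastically in tests. ρ ≥ 1 is
  rejected.
* **Scaling.** All coordinates are genetic (cM); the customary 1/1000
  *physical* down-scaling used by sequence-level simulators is recorded in
  the configuration but deliberately does not touch genetic lengths —
  preserving cM is the only reading under which tract-length bins keep
  their meaning, and all downstream statistics are in cM.
* **Determinism.** `run_scenario()` seeds R's RNG from the configuration;
  identical seeds give bitwise-identical populations.
* **Mating proportions.** Genome-wide means autosomes + X,
  genetic-length-weighted over carried haplotypes (so male and female
  denominators differ by one X). The alternative (autosomes only) changes
  nothing detectable at desk scale.

## 3. The tract-length profile

Tracts are binned by cM length into 22 windows with breakpoints
b_k = 2^((k+1)/2)/10, k = 1..21: the first window is [0, 0.2) cM — the
floor reflecting the 0.1 cM resolution of window-grid local-ancestry
callers — the spacing is √2, the last window is open at 204.8 cM. (The
printed breakpoint formula in the source material is typographically
corrupted; this reconstruction is pinned by the printed "<0.2 cM"
shortest window and the 22-window count.) Binning is lower-inclusive /
upper-exclusive.

Per individual the profile is a 22 × 3 × 2 integer array (bin × ancestry
× autosome/X); the population profile is the element-wise mean — a
permutation-invariant summary — with the X slab averaged over females
only (male hemizygous X calls are excluded by default, for simulated and
real data alike, mirroring practice with haploid-male caller output).
The default normalisation divides the autosome slab and the X slab each
by its own total ("all windows, divided by total"), the variant with the
best stability/accuracy trade-off in the source study; the
shortest-window-dropped and raw variants are implemented and tagged on
the object, and normalisation tags are re-checked at prediction time so
a network is never fed a profile in the wrong convention. A degenerate
all-zero slab is left as zeros with a warning rather than NaNs.

Bootstrap uncertainty resamples each individual's per-(ancestry, class)
histogram with replacement (multinomial over bin labels, B = 1000 by
default), replaces the histogram by its bootstrap mean, and averages
across individuals afterwards.

Flattening is column-major over (bin, ancestry, class) — length 132, or
126 without the shortest window — and `unflatten_profile()` inverts it
exactly.

## 4. Neural-network inference

No deep-learning framework is assumed: the branched fully-connected
architecture, backpropagation and Adam are implemented in base R matrix
code and validated in the test suite against a numerical-gradient oracle
(central differences over every weight of a small network, agreement to
1e-6).

* **Architecture.** Input 132 → shared ReLU trunk 512-256-128-64 →
  dropout 0.2 → per-parameter branches (ReLU 32 → dropout 0.2 → sigmoid
  1). Five branches for one-pulse (AM₁₋₃, SB₁, SB₂): 251,141 trainable
  weights including biases, which the implementation reports exactly;
  eight branches for two-pulses (+GFR₁₋₃): 257,480 by the same
  arithmetic. The source material prints 263,819 for the latter — not
  reproducible from the described architecture; we implement the
  architecture as described and record the discrepancy rather than guess
  an undocumented width.
* **Targets.** AM and GFR are already in [0, 1]; SB₁, SB₂ are mapped
  linearly from [−1, 1] (the natural range wide enough to cover all
  reported estimates) to [0, 1] so the mean-squared-error loss weights
  all parameters equally.
* **Training.** Adam (lr 1e-3), MSE, 40 epochs, batch 64, validation
  split 0.2 of the training portion, train/test split 0.8/0.2 per
  ensemble member with member-specific seeds. Dropout masks, batch order
  and initial weights (Glorot uniform) all come from R's seeded RNG, so
  loss histories are exactly reproducible single-threaded.
* **Evaluation.** Per-parameter MSE and R² on the scaled targets, plus
  true-vs-predicted confusion matrices over 5 equal-width bins on [0, 1]
  (the bin count was unspecified; 5 matches the granularity at which such
  matrices are usually read).
* **Ensembles.** K independently seeded and split networks; prediction
  reports the member mean and 2.5/97.5 percentiles, mapped back to
  natural scale. Identical members collapse to a zero-width interval.

## 5. Model comparison

The composite likelihood treats each profile cell as an independent
Poisson count. The reference mean for a cell is the across-replicate
average of raw population profiles simulated under the fitted parameters
(R replicates), plus a pseudocount of 0.5 so empty cells keep finite
terms. Because population profiles are per-individual *means*, both the
observation and the reference mean are multiplied by the observed number
of individuals, and the observation rounded, before the Poisson term is
evaluated. The source material names the statistic but gives no formula;
the independent-Poisson construction is the simplest one consistent with
"fit of the observed tract counts in the simulated distribution", and it
is a *composite* likelihood — cells are correlated in truth, so the
ratio ranks models but its absolute scale has no χ² calibration (none is
claimed; bootstrap CIs are reported instead).

CLR = logCL(observed | two-pulse reference) − logCL(observed | one-pulse
reference), computed per ancestry and per chromosome class (plus an
overall sum), positive values favouring the two-pulse model; the 95% CI
bootstraps the observed per-individual histograms. Antisymmetry under
model swap and exact zero under identical references are tested.

The generalized variance of two paired estimate vectors is the
determinant of their 2 × 2 sample covariance, var(x)·var(y) − cov(x,y)²
— the printed formula's "+" is a typo for the determinant the
surrounding text describes; zero for perfectly concordant estimators.

## 6. The synthetic-data generator: what it emulates, what it does not

`make_training_set()` draws parameters from the stated uniform priors
(AM, GFR on [0, 1]; SB₁, SB₂ on [−1, 1]), simulates each scenario and
reduces it to a normalised flattened profile; a manifest records every
seed and draw, and sharded half-runs concatenate exactly to the one-shot
run. `emulate_local_ancestry_calls()` discretises true tracts onto a
0.1 cM window grid and flips isolated windows at a configurable miscall
rate — reproducing the direction of the real caller artifact (mass
piling into the shortest-tract window as the rate rises) that motivates
the divided-by-total normalisation.

The stated world of the defaults: founding proportions from the six
bundled population presets (autosomal means; sex-balanced founding
reproduces the X proportions endogenously, so X means are carried for
reference but not used as inputs), N = 1000 and 19 generations at full
scale. The desk-scale defaults (N = 200, 5 autosomes of 250/200/150/120/
100 cM + 180 cM X, 2,000 simulations) and the smoke scale used in the
acceptance tests (200 simulations, N = 100, 2 autosomes + X) were chosen
once as the largest configurations that fit interactive and CI budgets.

What the generator does **not** emulate: genotype-level noise, phasing
error, reference-panel misspecification, population growth, selection,
overlapping generations, or time-varying AM/SB. A green recovery test
therefore establishes that *under the model's own data-generating
process at reduced scale* the network extracts AM (and more weakly SB)
from profiles — it does not validate local-ancestry calling accuracy on
real genomes, nor full-scale error rates.

## 7. Numerical choices and degenerate inputs

* Bin edges are exact powers of √2/10; binning uses `findInterval`
  (lower-inclusive). A tract exactly at an edge belongs to the upper
  window.
* Kernel densities that underflow to zero for *every* candidate (only
  possible at extreme AM with large differences) fall back to a uniform
  draw rather than dividing by zero.
* Largest-remainder rounding everywhere integer counts are apportioned;
  a positive target rounded to zero founders warns.
* Ancestry vectors are validated to sum to 1 within 1e-9; Σ must be
  positive definite with det > 1e-10.
* CLR cells with zero reference mean are floored at the 0.5 pseudocount;
  observed mean counts are scaled to totals and rounded via `round()`.
* Training is single-threaded deterministic; BLAS threading does not
  enter the batched matrix products' reduction order on the supported
  builds.

## 8. Design decisions taken where the problem was open

* **JSON instead of YAML** for configs and manifests: the target
  environment ships no R YAML parser; the schema (flat parameter record,
  scenario config, run manifest) is unchanged.
* **AM↔GFR confounding metric**: the cross-prediction experiment reports
  the per-ancestry Pearson correlation between simulated AM and predicted
  GFR and asserts on the strongest ancestry — at smoke scale only the
  high-proportion ancestries carry enough tract mass for the confounding
  to express, and the claim under test is that the two processes leave
  *resembling* footprints, not that every minor ancestry does.
* **Homogenization-speed invariant grid**: the across-individual variance
  response to AM is a sharp transition near AM ≈ 0.7 at the scales
  involved; monotonicity is asserted on a grid that the desk scale can
  resolve ({0.5, 0.7, 1} plus 0 ≪ 1), with the 0-vs-0.5 pair bounded
  within Monte-Carlo error instead of pretending to resolve it.
* **One child per event, repeat mating allowed, initiators uniform**:
  the minimal reading of the stated initiation probabilities 1/F and
  1/M.
* **Window 1 starts at 0** (not at the 0.1 cM caller floor): simulated
  tracts can be arbitrarily short, and real window-grid calls can never
  produce a tract below one window anyway.

## 9. Known limitations

* S = 3 ancestries only; the general-S algebra is documented but not
  implemented.
* The composite likelihood ignores between-cell correlation; its CIs
  come from the profile bootstrap, not from likelihood curvature.
* Smoke- and desk-scale recovery results are noisy relative to the
  cluster-scale study design (10,000 simulations, 1000-network
  ensembles); `full_scale_config()` exposes the latter but running it is
  a cluster job, not a test.
* The simulator models mating, recombination and migration pulses only —
  no mutation, no selection, no growth — so it measures what the mating
  model can explain, by construction.
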