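# admixmate

Forward-in-time simulation of recently admixed populations under
**ancestry-assortative mating** and **ancestry-related sex bias**, and
simulation-based inference of those mating parameters from the length
distribution of local-ancestry tracts.

## The problem

In three-way admixed populations of the Americas (sub-Saharan African,
Native American and European source ancestries), mating is not random:
socioeconomic stratification correlates with genome-wide ancestry
proportions, so mates resemble each other in ancestry (assortative mating,
AM) and couples can be systematically asymmetric between the sexes
(sex bias, SB). Standard admixture-dating methods assume random mating and
can misread this structure as, e.g., a more recent migration pulse.
`admixmate` targets population geneticists who have local-ancestry calls
for an admixed cohort (RFMix/Gnomix-style window grids or ancestry
segments) and want to quantify AM and SB — and, under a two-pulse
migration model, the gene flow rate (GFR) of a second wave — from those
calls alone.

## The model

For a couple with ancestry-proportion vectors a_f (female) and a_m (male),
write d = a_m − a_f. Mate choice follows a Gaussian kernel on d:

* mean **μ = (SB₁, SB₂)** — positive SB_s means couples where the *male*
  carries more of ancestry s are favoured; SB₃ = −SB₁ − SB₂;
* covariance **Σ** with diagonal σ₁², σ₂² and off-diagonal
  Cov₁₂ = (σ₃² − σ₁² − σ₂²)/2, where each variance encodes assortment on
  one ancestry through **σ_s² = 3^(3 − 7·AM_s)** — AM = 0 is random mating
  (σ² = 27), AM = 1 is very strong assortment (σ² = 1/81).

Each offspring arises by a coin-flip choice of a female or male initiator
(uniform within sex), whose mate is drawn with probability proportional to
the kernel density over all opposite-sex candidates. Genomes are tract
lists on 22 autosomes + X (cM coordinates); meiosis places
Poisson(length-in-Morgans) crossovers uniformly in genetic distance; the
male X passes to daughters unrecombined, so females contribute 2/3 of the
X gene pool and males 1/3 — the autosome/X contrast is what makes SB
identifiable.

A population is summarised by the **continuous ancestry tract-length
profile**: tract counts in 22 √2-spaced length bins (first edge 0.2 cM,
last 204.8 cM) × 3 ancestries × {autosome, X}, averaged over individuals
(X over females only). A branched fully-connected network (trunk
512-256-128-64, one 32-unit sigmoid branch per parameter; 251,141
trainable weights for the one-pulse model) regresses mating parameters
from the flattened profile; ensembles of independently trained networks
give 95% CIs. A composite (independent-Poisson) likelihood ratio compares
one-pulse vs two-pulse migration fits against simulated reference
profiles.

## Worked example

```r
library(admixmate)

# PEL-like founding proportions, desk-scale map, strong NAT assortment
cfg <- scenario_config(preset_proportions("PEL"),
                       population_size = 200, generations = 19,
                       map = toy_genetic_map(), seed = 7)
params <- mating_params(am = c(0.5, 0.45, 0.45), sb = c(0.1, -0.05))
sim <- run_scenario(cfg, params)
sim
#> Admixture simulation: 19 generations, one_pulse model, AM=(0.5,0.45,0.45) SB=(0.1,-0.05,-0.05)
#>   final mean ancestry: AFR=0.011 NAT=0.813 EUR=0.176

prof <- normalize_profile(population_profile(sim$population))
prof
#> Tract-length profile (22 bins x 3 ancestries x {autosome, X}), divided_by_total, all_windows, mean of 200 individual(s)
#>   autosome slab total: 1 | X slab total: 1
```

The final mean ancestry stays near the founding proportions (ancestry is a
martingale; the deviation is drift), and the normalised profile — each
slab summing to 1 — is the 132-length feature vector the network consumes.
Training and prediction:

```r
ts  <- make_training_set(cfg, prior_config(), n_sims = 2000, seed = 1)
ens <- train_ensemble(ts$features, ts$targets, K = 10,
                      spec = network_spec("one_pulse"), seed = 1)
predict_with_ci(ens, prof)    # mean and 95% CI per parameter, natural scale
```

The bundled CLI drives the same pipeline from the shell
(`exec/admixmate simulate|profile|fixtures|train|predict|compare`; JSON
configs, TSV/BED-style data files; see `admixmate_main()`).

## Scale

Defaults mirror the study design (N = 1000, 19 generations, 22 autosomes
+ X via `full_scale_config()`; 10,000 simulations and 1000-network
ensembles per population at cluster scale). Tests and examples use the
desk-scale map (5 autosomes + X) and smoke-scale simulation counts; see
`vignettes/admixmate-methods.Rmd` for what that does and does not
establish.
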