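# divloss

Forecasting nucleotide-diversity loss in spatially structured species after
habitat loss.

Conservation indicators document habitat and population declines for
thousands of species, but translating a decline into a *genetic diversity*
loss requires a population-genetic model: diversity responds to habitat loss
slowly, unevenly across space, and in ways that depend strongly on
population structure. `divloss` provides that translation layer for the
workhorse diversity metric, nucleotide diversity

&nbsp;&nbsp;&nbsp;&nbsp;π = (n/(n−1)) (1/L) Σᵢ 2pᵢ(1−pᵢ),

for practitioners and population geneticists who need short-, mid- and
long-term forecasts of π under explicit habitat-loss scenarios.

## What is inside

**The moment engine.** A species is modelled as a multideme Wright–Fisher
population on a grid of demes with migration between rook neighbours. The
engine tracks F[i,j], the probability that two lineages drawn from demes i
and j are identical in state; H = 1 − F is the expected heterozygosity
(the model's π between demes). One generation is the exact linear update

&nbsp;&nbsp;&nbsp;&nbsp;F′ = (1−u)² · B G Bᵀ,&nbsp;&nbsp;
G[k,k] = 1/(2Nₖ) + (1 − 1/(2Nₖ)) F[k,k],&nbsp; G[k,l] = F[k,l],

with B the backward migration matrix, Nₖ the deme sizes and u the mutation
rate. Because the recursion is linear, equilibria are solved directly
(a spectral solve, no iteration, no Monte Carlo error) and the transient
after any habitat edit — edge contraction, random fragmentation, gradual
decline, restoration — is propagated exactly. Species-wide π is the
census-weighted average of H over all deme pairs; local π is the mean of
the within-deme diagonal. A two-allele ("biallelic") mutation variant
matches SNP-frequency simulations exactly.

**The GDAR power law.** Short-term π loss follows the genetic
diversity–area relationship, π_lost = 1 − (1 − A_lost)^z, with z fitted
per species ([fit_power_law()], [predict_loss()]); the analogous MAR covers
allelic richness.

**Supporting modules.** A forward Wright–Fisher simulator over unlinked
SNPs (the stochastic oracle and the generator of structured genotype data);
empirical estimators (π, segregating sites, grid-local π, Hudson F_ST) with
VCF + coordinate-TSV input; in-silico extinction on geo-referenced genotype
matrices (random and south–north schemes); FRAGSTATS-style landscape
metrics; synthetic Red List / LPI / GBF indicator tables; and a pipeline
turning indicator records into per-species and aggregate π-loss forecasts.

## A worked example

```r
library(divloss)

# the endemic-conifer example: 80% habitat loss, fitted z = 0.02809
100 * predict_loss(0.02809, 0.8)
#> [1] 4.420241        # ~4.4% short-term pi loss

# a structured species: 10 x 10 demes, 5000 diploids, F_ST calibrated to 0.9
fc <- wf_forecast(0.5, fst = 0.9, scenario = "contraction", n_ref = 5000)
fc
#> pi-loss forecast (proportion of pre-loss diversity lost):
#>  horizon loss_species loss_local
#>    short       0.1105  0.0006123
#>      mid       0.1300  0.1032106
#>     long       0.4524  0.4524869
#>   m = 0.0003213, realized loss = 0.5
```

Read: removing half the range of this strongly structured species costs
11% of species-wide π immediately (the lost half held its own variants),
13% by the mid term (N/2 ≈ 2,500 generations of drift in the shrunken
population), and 45% at the new equilibrium. Under *fragmentation* the
species-wide number can instead inflate while every local population loses
diversity — a Wahlund effect the engine reproduces and the landscape
metrics explain:

```r
ens <- fragmentation_ensemble(n_maps = 10, loss_range = c(0.9, 0.9),
                              seed = 1, horizons = "long")
range(-100 * ens$loss_species_long)   # percent inflation of species-wide pi
#> [1] 124.0724 164.6142
```

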