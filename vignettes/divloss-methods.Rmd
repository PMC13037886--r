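---
title: "Methods: forecasting nucleotide-diversity loss under habitat loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forecasting nucleotide-diversity loss under habitat loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(divloss)
```

## The model

A species occupies a rectangular grid of demes (habitat patches), each a
randomly mating diploid population of census size $N_i$, connected to its
rook neighbours by a per-edge backward migration probability $m$: a lineage
now in deme $i$ had its parent in adjacent deme $k$ with probability $m$,
and stayed at home with probability $1 - m\,\mathrm{deg}(i)$. Habitat loss
removes demes; `grid_habitat()`, `edge_contraction()`,
`random_fragmentation()`, `gradual_schedule()` and `restore()` construct the
scenarios.

The central object is the matrix $F_{ij}$: the probability that two
distinct lineages, one from deme $i$ and one from deme $j$, are identical
in state. Its complement $H = 1 - F$ is the expected heterozygosity — the
model's per-site nucleotide diversity between demes. Nucleotide diversity
in any combination of demes is a function of these pairwise second moments
only, so tracking $F$ suffices to track $\pi$. One generation applies
migration, coalescence and mutation:

$$F' = (1-u)^2 \, B \, G \, B^\top, \qquad
G_{kk} = \tfrac{1}{2N_k} + \left(1 - \tfrac{1}{2N_k}\right) F_{kk}, \quad
G_{kl} = F_{kl}\ (k \ne l),$$

with $B$ the row-stochastic backward migration matrix. The update is
linear (affine) in $F$, which has two consequences the package exploits:

* **Equilibria solve directly.** Unrolling the recursion gives
  $F^\ast = \sum_{t \ge 1} a^t B^t D_v B^t$ with
  $D_v = \mathrm{diag}((1-v_k)/2N_k)$, $v = \mathrm{diag}(F^\ast)$ and
  $a = (1-u)^2$. In the eigenbasis of $B$ (symmetric for a scalar $m$) the
  geometric series sums in closed form, leaving a $D$-dimensional linear
  system in the diagonal $v$ alone. `wf_equilibrium()` therefore costs one
  eigendecomposition plus one small solve; the result is an exact fixed
  point (residual of one `wf_step()` below $10^{-10}$, asserted in the
  tests).
* **Transients are exact.** `wf_propagate()` iterates the update; there is
  no Monte Carlo error anywhere in the engine.

**Mutation models.** The default `"infinite_alleles"` scales identity by
$(1-u)^2$, giving the classic $H = \theta/(1+\theta)$ single-deme
equilibrium. The `"biallelic"` variant models two-allele symmetric
mutation, $F' = 2u(1-u) + (1-2u)^2 B G B^\top$, and matches the forward
SNP simulator *exactly*; the two agree to $O(\theta)$. Forecasts use the
infinite-alleles default (per-site $\theta$ of real species is small);
oracle comparisons use the biallelic variant so that model error and Monte
Carlo error are not confounded.

**Summaries.** $\pi_{species} = \sum_{ij} w_i w_j H_{ij}$ with
$w_i = N_i/\sum N$ (ordered pairs, within-deme pairs included);
$\pi_{local}$ is the unweighted mean of $H_{ii}$ over live demes; pairwise
$F_{ST}(i,j) = 1 - \tfrac{(H_{ii}+H_{jj})/2}{H_{ij}}$ (Hudson-style),
averaged over unordered pairs. `calibrate_migration()` bisects on
$\log m$ to reach a target average $F_{ST}$; the average is monotone
decreasing in $m$.

## Default study conditions

All headline forecasts use a 10 × 10 grid, $N_i = 50$ (total census
5,000), $u = 10^{-6}$ per lineage per generation, and migration calibrated
to the species' average pairwise $F_{ST}$. The topology bounds
$m < 1/4$, so the weakest achievable structure on this grid has average
$F_{ST} \approx 0.011$; calibration targets below that return the boundary
with a warning ("$F_{ST} \approx 0$" means this weakly structured limit).
Horizons: **short** = one generation after loss; **mid** =
$\lceil N_{ref}/2 \rceil$ generations (default $N_{ref}$ = pre-loss total
census, i.e. 2,500 generations — configurable, since the drift timescale
is really set by an emergent effective size); **long** = the new
equilibrium, computed by direct solve for edge contraction.

**Why fragmentation uses a 20,000-generation long horizon instead of the
equilibrium solve.** After random fragmentation at high loss the surviving
demes are mostly disconnected. Their true joint equilibrium is the
mutation–migration balance in which isolated fragments become almost
completely differentiated ($H_{between} \to 1$) — a state approached only
on the $1/u$ mutation timescale, with species-wide π inflated by orders of
magnitude. The biologically meaningful "long term" for fragmented
landscapes is the re-equilibration horizon of the connected case,
~20,000 generations (≈ $4 N_{ref}$), which is where contraction scenarios
have converged; `wf_forecast()` and `fragmentation_ensemble()` therefore
propagate fragmented systems for `long_generations = 20000` (configurable)
rather than solving the disconnected equilibrium. At this horizon the
engine reproduces the Wahlund-type inflation of species-wide π (up to
~+165% at 90% loss under weak structure) while mean local π collapses.

A note on what this model can and cannot reproduce. With a single
mutation-rate scale the engine's anchors are mutually constrained: the
weak-structure equilibrium proportionality (50% loss → 50% long-term π
loss) and the ~79%-remaining checkpoint at ~2,200 generations both hold at
$u = 10^{-6}$, but the long-term loss of a strongly structured
($F_{ST} = 0.9$) species then comes out near 45%, not the ~27% a
continuous-space simulation with emergent effective sizes yields, and a
species whose *average pairwise* Hudson $F_{ST}$ is truly ≈ 0 loses well
under 1% of π at 50% contraction in the short term (any model with
$F_{ST} \approx 0$ must: the between-deme heterozygosity excess available
to lose is pinned by $F_{ST}$ itself). Strong isolation by distance that
clustering-based $F_{ST}$ estimators report as "≈ 0" corresponds in this
engine to a calibrated $F_{ST}$ near 0.3, where the short-term loss at 50%
contraction is ~4%. These gaps are properties of the calibration
definition, documented here rather than papered over.

## The forward simulator

`wf_simulate()` tracks allele frequencies at $L$ unlinked biallelic sites:
per generation and site, migration mixing $x \leftarrow Bx$, symmetric
mutation $x \leftarrow u + (1-2u)x$, binomial resampling
$x' \sim \mathrm{Binom}(2N_k, x)/2N_k$. Diversity summaries use the
distinct-lineage convention ($2x(1-x)\cdot 2N/(2N-1)$ within demes) so
they estimate the same quantities as the engine. Unlinked sites suffice
because π and the number of segregating sites are single-site and
frequency-spectrum statistics; linkage would change neither expectation.
`wf_burn_in()` initialises frequencies from the single-population
stationary Beta and runs until the windowed mean of $\pi_{species}$
stabilises. Oracle comparisons run at a reduced scale chosen for runtime
(5 × 5 demes of 20 diploids, $u = 10^{-4}$, 1,200 burn-in generations,
200–2,000 SNPs, a 2,000-generation "long" horizon matching $2ut$ of the
default scale); they probe the engine's drift–migration dynamics, not the
genomic realism of any particular species.

## Empirical statistics and extinction simulation

`nucleotide_diversity()` implements
$\pi = \tfrac{n}{n-1}\tfrac{1}{L}\sum_i 2p_i(1-p_i)$ with $p_i$ = mean
dosage/2. The exact pairwise convention (individuals are pools of two
copies; within-individual comparisons enter the numerator; the
normaliser is the $n(n-1)$ ordered distinct pairs) is pinned down by a
brute-force copy-level oracle in the test suite. The correction is
individual-level, so with very few individuals per group the estimator
exceeds the copy-level expectation by a factor
$\approx (2n-1)/(2n) \cdot n/(n-1)$; `hudson_fst()` inherits this, which
is why the synthetic-genotype generator samples ≥ 10 individuals per deme
when its realized $F_{ST}$ is meant to hit a target. Grid-local π excludes
cells with fewer than two individuals (whether the original averages
included them is not stated; exclusion is the configurable default here).

`run_extinction()` overlays a grid on the sample map (occupied cells are
the habitat; area loss is counted in occupied cells), removes cells one at
a time — seeded random order, or north-to-south with west-to-east
tie-breaks — and recurves π and $S$ on survivors, optionally after seeded
subsampling to 10,000 SNPs. `fit_power_law()` then estimates $z$ by least
squares through the origin on the $\log(1-\cdot)$ scale (the functional
form forces zero loss at zero area), reporting $R^2$ on the untransformed
scale; a nonlinear refit is available (`method = "nls"`), since the
original fitting procedure is not specified.

## The indicator pipeline

Indicator tables map to area-loss proxies under the stated assumption that
population loss and habitat loss are proportional: Red List categories map
to the arithmetic midpoint of their A-criterion decline range (CR 80–95% →
87.5%; the full default table is configuration and user-overridable); LPI
series use the earliest-to-latest ratio $N_{present}/(N_{past}+1)$
averaged over populations — the published formula's $+1$ placement is
ambiguous, so the guard is an argument — excluding non-declining species;
GBF Indicator 2 is the fraction of populations lost. Species without
measured parameters draw $F_{ST}$ from a truncated normal
$\mathcal{N}(0.270, 0.211)$ on $[0,1)$ and $z$ by resampling a supplied
empirical table (default: exponential with mean 0.03 truncated at 0.45,
matching the reported across-species mean and range). Short-term
contraction forecasts use GDAR; all other horizon × scenario combinations
use nearest-bin lookup in a precomputed `build_lookup_table()`;
fragmentation forecasts report local π loss (species-wide π is misleading
in shattered landscapes and is attached alongside). Aggregates are
arithmetic means with 25–75% quantile ranges per source × horizon ×
scenario, fully seeded.

**Synthetic indicator tables** exist so the pipeline can be exercised and
tested without the (non-redistributable) global databases. Remaining
fractions are Beta-distributed, moment-matched to the published
across-species summaries: LPI remaining $\sim$ Beta(0.528, 0.938) (mean
loss 64%, IQR ≈ 40–93%); GBF lost fraction $\sim$ Beta(0.323, 1.416)
(mean 18.6%, upper quartile ≈ 0.29 — the stated 0–35% IQR and the mean
cannot be matched simultaneously by a Beta, and the mean takes priority).
The Beta family is a choice; the generating spec is serialized next to
every dataset. What passing tests on these tables shows is that the
pipeline's arithmetic and determinism are correct — not that any global
average is reproduced, since those depend entirely on the real databases.

## Numerical choices and limitations

* Equilibrium solves require $u > 0$; $u = 0$ has only the degenerate
  all-identical fixed point and is refused with a pointer to the transient
  mode. Calibration tolerance is $10^{-3}$ on $F_{ST}$; equilibrium
  residuals are ~$10^{-12}$.
* Destroyed demes return their migration mass to the source deme
  (reflecting boundary, the default), keeping $B$ symmetric; an `"absorb"`
  mode redistributes rows proportionally for sensitivity analysis.
* Edge contraction removes whole rows from the named edge, partial rows in
  reading order, guaranteeing a connected remainder; which edge the
  original experiments contracted is unstated, and by symmetry it does not
  matter on a uniform grid.
* Restoration founds new demes from live-neighbour averages
  (`"from_neighbors"`, falling back to translocation with a warning when a
  deme is stranded) or from the landscape-wide size-weighted average
  (`"translocation"`).
* `fit_to_trajectory()` fixes deme sizes and fits $(u, m, s)$ — mutation,
  migration, time scaling — by derivative-free least squares with a small
  multistart and a BFGS polish; the migration rate is only weakly
  identified from a species-wide π trajectory, hence the multistart.
* The engine is a discrete-deme approximation: continuous-space dispersal,
  overlapping generations, age structure and density regulation are out of
  scope, and parameters must be read as effective quantities when the
  model is fitted to data from such systems.
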