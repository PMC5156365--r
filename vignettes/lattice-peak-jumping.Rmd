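---
title: "Peak-jumping on rugged landscapes: model, design choices and limits"
author: "latticePeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-jumping on rugged landscapes: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticePeaks)
```

## The model

A haploid population lives on an $n \times n$ lattice; each cell is empty
or holds one organism with a binary genotype of $L$ loci. A fitness
landscape assigns every genotype $G$ a per-update survival probability
$s_G \in [0,1]$; rugged landscapes have several local peaks (genotypes
fitter than all $L$ one-mutant neighbors) separated by low-fitness
valleys.

Time advances in updates. Each update picks one lattice point uniformly at
random:

* **Occupied focal point.** The resident of genotype $G$ dies with
  probability $1 - s_G$, leaving the cell empty; otherwise nothing
  happens. Survival probabilities therefore act per *encounter*, not per
  generation: fitter genotypes simply persist longer and so parent more
  births.
* **Empty focal point.** A birth is attempted. The first parent is drawn
  uniformly among occupied cells of the *dispersal* neighborhood around the
  focal point; the mate is drawn uniformly among occupied cells of the
  *mating* neighborhood around the first parent (never the first parent's
  own cell). If either draw finds no candidate the birth simply fails — the
  first parent is not redrawn. The offspring genotype is formed by
  recombination and then mutation, and fills the focal cell.

Recombination uses a single-donor-switch model: one parent is chosen at
random (probability $1/2$) to contribute the allele at locus 1, and at each
of the $L-1$ boundaries between adjacent loci the contributing parent
switches with probability $r$. Thus $r = 0$ transmits an intact parental
haplotype and $r = 0.5$ gives independent assortment of parental alleles.
Mutation then flips each locus independently with probability $\mu$.

An *epoch* is $n^2$ updates — on average one event opportunity per cell.
Runs stop at the first epoch boundary where a designated genotype
(by default the global optimum) reaches a threshold frequency among
occupied cells, at population extinction, or at an epoch cap.

Two reproduction regimes bracket the role of space. Under **local**
reproduction both neighborhoods are the von Neumann neighborhood (the four
orthogonally adjacent cells); under **global** reproduction both are the
entire lattice minus the focal point. The common neighborhood radius is the
*reproductive distance*. Two mate-choice treatments probe the mechanism:

* **Rare global reproduction** — each mating independently escapes to the
  global neighborhood with a small probability (1/100 in the shipped
  preset), testing robustness of the local regime to occasional long-range
  mating.
* **Centers prohibited** — while a tracked genotype is rarer than a
  threshold fraction of the population (default 1%), any homotypic mate
  drawn for it is replaced by a random individual from the whole
  population. This removes the shelter that the interior of a monotypic
  cluster (a "center") provides to a nascent genotype, while leaving the
  spatial pattern itself untouched.

## Why sutures and centers matter

With several peaks discovered but none fixed, two expanding clusters of
distinct suboptimal peak genotypes eventually abut. Along that boundary —
the *suture* — matings are heterotypic, and recombination can assemble
offspring that lie in the attraction basin of a higher peak
(*peak-jumping*; on the shipped 4-locus landscape, $0011 \times 1100
\rightarrow 1111$). Away from sutures, inside monotypic *centers*, matings
are homotypic and recombination is effectively neutral, which protects rare
allele combinations from being torn apart. Local reproduction thus plays
both sides: it slows the spread of high-fitness genotypes (maintaining the
diversity peak-jumping needs) and it shelters nascent peak genotypes from
destructive recombination with the majority type.

## Landscape tools

`fitnessLandscape()` builds a survival map from a short table plus a
default for all non-specified genotypes. Three named landscapes ship with
the package (`buildNamedLandscape()`):

| name | L | survival table | role |
|------|---|----------------|------|
| `fig1_default` | 4 | $s_{0000}=0.6$, $s_{0011}=s_{1100}=0.85$, $s_{1111}=0.9$, rest $0.2$ | two suboptimal peaks whose recombinants reach the optimum |
| `s3_lethal` | 2 | $s_{00}=0.6$, $s_{01}=s_{10}=0.85$, $s_{11}=0$ | counting creations of a lethal recombinant at sutures |
| `s4_valley` | 2 | $s_{00}=0.8$, $s_{01}=s_{10}=0.6$, $s_{11}=0.9$ | valley-crossing and the centers treatments |

`localPeaks()` finds genotypes strictly fitter than all one-mutant
neighbors; `peakJumpAccessible()` decides whether some pair of distinct
suboptimal peaks has a recombinant inside the attraction basin of a peak
strictly higher than both. Basins are defined by a greedy adaptive walk to
the fittest one-mutant neighbor with ties broken toward the lowest genotype
index — the walk is deterministic, standard and cheap to test, which is why
it was chosen over stochastic basin definitions. A two-peak landscape whose
higher peak is the optimum (such as `s4_valley`) is classified as *not*
peak-jump accessible: the concept requires a third, higher peak reachable
from a suboptimal pair.

`convertRelativeFitness()` turns a table of relative fitnesses
$\omega_G$ into survivals via $s_G = \omega_G / (2\bar\omega)$, which pins
the landscape-mean survival at $1/2$ and preserves the fitness ranking
exactly. The divisor-of-two convention keeps the maximum survival below 1
for any table whose top fitness is at most twice the mean; tables violating
that bound are rejected rather than silently clipped. Because other
conversions are conceivable, the conversion function is a pluggable
argument.

Empirically measured multi-peak landscapes are not shipped;
`generateSyntheticRugged()` rejection-samples uniform survival tables until
a requested number of local peaks and a requested peak-jumping class are
met, giving reproducible synthetic stand-ins for either topology class.

## Parameters that matter

| parameter | meaning | default | notes |
|-----------|---------|---------|-------|
| `n` | lattice side | 70 in presets | an epoch is $n^2$ updates; both diversity and suture length grow with $n$ |
| `mu` | per-locus mutation probability per birth | 0.002 (main preset) | the supply of new peaks scales like $n^2\mu$ |
| `r` | between-locus crossover probability | factor levels 0, 0.02, 0.1, 0.5 | 0.5 = independent assortment |
| `initGenotype` | starting genotype | complement of the optimum | a mixed named-probability vector is accepted |
| `initDensity` | initial per-cell occupancy | $s_{G_0}$ | the stationary occupancy of the initial genotype |
| `stopFrequency` | establishment certificate | 0.5 of occupied cells | the stop threshold is not dictated by the model; majority is a conservative choice and it is configurable |
| `maxEpochs` | epoch cap | 2000 (main preset); 3000 for the suture runs, escalating caps in the $\mu$ sweep | censored runs are reported as censored, never imputed into means silently |
| boundary | lattice edge behavior | toroidal | wrap removes edge artifacts in cluster geometry; `bounded` is available because suture shapes near edges may be of interest |

## Observables

Runs log, at update resolution, every transition of a genotype count
between zero and positive, plus per-epoch genotype counts and (optionally)
full birth/death records. From these, `discoveryTime()` gives the epoch of
first appearance and `establishmentTime()` the epoch of the earliest
appearance never followed by extinction before run end — "discovery without
subsequent extinction". Runs ending without the genotype are censored
(`NA`), and summaries report establishment fractions alongside means so
censoring is never hidden.

Creations of a target genotype from non-target parents are classified by
origin: if the *pre-mutation* recombinant already equals the target the
creation is recombinational, otherwise mutational. Because the birth
pipeline is recombine-then-mutate and both intermediate genotypes are
recorded, the classification is exact and exhaustive — no re-simulation or
inference is involved. The engine maintains these counters in compiled code
for a tracked genotype; the R-side classifier applied to full birth records
is cross-checked against them in the tests.

## Experiments and inference

`experimentDesign()`/`runDesign()` run full factorials (crossover rate,
reproduction mode, mutation rate, lattice size, landscape, treatments) with
a per-run seed derived from the root seed and the (cell, replicate) index,
so results are independent of execution order and safely parallelizable.

Inference mirrors standard practice for simulation experiments:

* `bootstrapMeanCI()` — percentile bootstrap of a cell mean.
* `ratioOfMeans()` — ratio of mean waiting times with independent
  resampling of both groups. The package fixes the orientation
  *recombining treatment over $r=0$ baseline*, so ratios below 1 always
  read "recombination speeds establishment".
* `permutationInteractionTest()` — the F statistic of the highest-order
  interaction from a fixed-effects factorial ANOVA, with its null
  distribution obtained by unrestricted permutation of the raw outcomes
  across runs (Manly-style raw-data permutation), and
  $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$.

Waiting-time analyses must face censoring: runs that never establish by
the cap have no establishment epoch. Two resolutions are implemented
(`resolveCensoring()`): restricting analysis to cells where at least 90% of
runs establish, and substituting the cap for censored runs (a conservative
lower bound that biases against finding speedups). Analyses in the tests
and the acceptance script use the substitution form and report
establishment fractions alongside, so censored cells are visible.

## Numerical and design choices

* **Single RNG stream per run.** Every stochastic decision (focal point,
  survival, parent picks, rare-global coin, donor coin, crossovers,
  mutations) consumes R's RNG in a fixed documented order inside the
  compiled kernel, so a run is bit-reproducible from its seed and event
  logs are identical across re-runs.
* **Frequencies are relative to occupied cells**, both for the stop rule
  and for the centers threshold: "1% of the population" refers to
  organisms, not lattice area.
* **Mate draws exclude the first parent's cell** (an organism cannot mate
  with itself) but homotypic mates are always allowed except under the
  centers-prohibited treatment.
* **Failed births are final** within an update: if the mating neighborhood
  of the chosen first parent is empty, no birth occurs and the first
  parent is not resampled.
* **Degenerate inputs.** A lethal resident ($s_G = 0$) always dies when
  focal; an all-lethal landscape drives the population extinct and the run
  terminates with an extinction flag; `maxEpochs = 0` returns the initial
  state; tied global optima make `optimalGenotype()` (and anything relying
  on it) an explicit error rather than an arbitrary choice.
* **Basin ties** in the adaptive walk break toward the lowest genotype
  index, making `peakJumpAccessible()` deterministic.

## What the synthetic experiments do and do not show

The shipped experiments run at the standard lattice size $n = 70$ with the
preset mutation rates; the package's test suite and the acceptance script
scale them down **only in replicate count** (30 per cell for the main
factorial, 15 for the suture counts, 20 per cell for the centers
comparison) to keep a full re-run on one CPU within a few minutes. Lattice
size is deliberately *not* scaled down: the suture mechanism requires two
peak clusters to coexist, and the expected number of co-existing peak
establishments falls roughly like $n^2\mu \times$ (fixation time). On
small lattices (e.g. $n \approx 30$ at the preset mutation rates) the
first peak typically fixes before a second arises, sutures never form, and
the recombination effects shrink toward zero or reverse — which is itself
the size-dependence the lattice-size sweep (`sweepParameter("n", ...)`)
exhibits, with recombination helping more on larger lattices.

These are stylized dynamics: non-overlapping update events, exactly one
organism per cell, binary alleles, survival selection only (fertility is
genotype-independent), and mutation only at birth. Passing tests show the
implementation faithfully realizes *this* model and that its qualitative
phenomena (suture peak-jumping, center shelter, the
recombination-by-distance interaction) are robust at the preset scales;
they do not show that any particular natural population occupies the
parameter window where these effects dominate.

## Known limitations

* Genotype spaces are dense vectors of length $2^L$; practical for
  $L \lesssim 16$, intended for the small-$L$ landscapes studied here.
* The percentile bootstrap undercovers the mean of strongly skewed
  outcomes at small sample sizes (at $n = 30$ exponential samples its true
  coverage is near 91–92%); the coverage checks therefore use samples of
  200, and users comparing small skewed cells should prefer the
  permutation tests.
* Establishment times are right-censored by the epoch cap; the
  cap-substitution analysis bounds, but does not estimate, the censored
  waiting times. Interval-censored survival methods are out of scope.
* Animation/video export is out of scope; `writeSnapshots()` emits
  integer-coded grids plus a legend for external rendering.

## A minimal session

```{r example, eval = FALSE}
ls1 <- buildNamedLandscape("fig1_default")
peakJumpAccessible(ls1)

cfg <- simulationConfig(ls1, n = 70, mu = 0.002, r = 0.1, seed = 1)
run <- runSimulation(cfg, snapshotEvery = 50L)
establishmentTime(run, "1111")

des <- presetDesign("fig1", replicates = 30L)
res <- runDesign(des)
res$summary
```
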