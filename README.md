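# latticePeaks

Agent-based simulation of haploid, recombining populations on an *n* × *n*
lattice, for studying how **spatially restricted ("local") versus panmictic
("global") reproduction** changes what recombination does to adaptation on
**rugged, multi-peaked fitness landscapes**.

On a rugged landscape a population stuck on a suboptimal peak can reach a
higher one by *peak-jumping*: recombination between two distinct suboptimal
peak genotypes (e.g. `0011 × 1100`) producing an offspring in the
attraction basin of a higher peak (`1111`). Whether that happens depends on
space. Local reproduction slows the spread of high-fitness genotypes, so
several peak genotypes can coexist as clusters; where two clusters abut —
at a *suture* — heterotypic matings make recombination creative. Inside a
monotypic cluster — a *center* — matings are homotypic, which shields a
rare nascent peak genotype from being recombined off its peak. The package
implements the full stochastic model, the observables, and the factorial
experiment machinery with bootstrap and permutation inference.

## Model in brief

* Genotypes are binary haplotypes of *L* loci; a landscape maps every
  genotype *G* to a survival probability *s*<sub>*G*</sub> ∈ [0, 1]
  (listed genotypes plus a default for all others).
* Each update, a random lattice point is chosen. An occupant of genotype
  *G* dies with probability 1 − *s*<sub>*G*</sub>. An empty point triggers
  a birth: first parent uniform in the dispersal neighborhood of the focal
  point, mate uniform in the mating neighborhood of the first parent
  (no candidates → no birth). Local = von Neumann neighborhood; global =
  whole lattice minus the focal point.
* Offspring: one parent donates the allele at locus 1; the donor switches
  between adjacent loci with crossover probability *r* (*r* = 0.5 ⇒
  independent assortment); then each locus mutates with probability *μ*.
* One epoch = *n*² updates. Runs stop when a designated genotype reaches a
  threshold fraction of occupied cells at an epoch boundary, at an epoch
  cap, or on extinction. Every run is bit-reproducible from its seed.

Mate-choice treatments: **rare global reproduction** (each mating escapes
to the whole lattice with probability 1/100) and **centers prohibited** (a
tracked genotype below 1% frequency drawing a homotypic mate has the mate
replaced by a random individual — removing the shelter of clustering while
leaving spatial structure intact).

## Worked example

```r
library(latticePeaks)

ls1 <- buildNamedLandscape("fig1_default")
ls1
#> FitnessLandscape 'fig1_default': L = 4 (16 genotypes), default s = 0.2
#>   listed: s(0000) = 0.6, s(0011) = 0.85, s(1100) = 0.85, s(1111) = 0.9
#>   local peaks: 0000, 0011, 1100, 1111

pj <- peakJumpAccessible(ls1)
head(attr(pj, "witness"), 1)
#>   peak1 peak2 recombinant target
#> 1  0011  1100        0111   1111

cfg <- simulationConfig(ls1, n = 20, mu = 0.002, r = 0.1,
                        maxEpochs = 500, seed = 7)
run <- runSimulation(cfg)
run
#> SimulationRun: 500 epochs (max_epochs), 200000 updates
#> LatticeState: 20 x 20, 340/400 occupied
#>   counts: 1100: 338, 1110: 2
```

Here the population, initialized on the suboptimal peak `0000` (the
genotype farthest from the optimum, at its own survival 0.6 as initial
density), has climbed to the suboptimal peak `1100` but not yet jumped to
`1111` — on a 20 × 20 lattice a single peak fixes quickly and sutures are
rare. At the standard size *n* = 70 the factorial experiment shows the
full phenomenon:

```r
base <- simulationConfig(ls1, n = 70, mu = 0.002, r = 0, maxEpochs = 2000)
des <- experimentDesign(base, list(r = c(0, 0.1, 0.5),
                                   reproduction = c("local", "global")),
                        replicates = 30, rootSeed = 1)
res <- runDesign(des)
print(res$summary, digits = 3)
#>     r reproduction nRuns established meanEpoch ciLower ciUpper
#> 1 0.0        local    30       0.933       635     499     771
#> 2 0.1        local    30       0.967       204     158     256
#> 3 0.5        local    30       0.800       338     189     530
#> 4 0.0       global    30       0.967       765     567     977
#> 5 0.1       global    30       0.767       520     296     773
#> 6 0.5       global    30       0.167      1990    1978    1998
```

`meanEpoch` is the mean epoch at which the optimum `1111` established
("discovery without subsequent extinction") among establishing runs, with
a percentile-bootstrap 95% CI; `established` is the fraction establishing
by the 2000-epoch cap. Reading the table: under local reproduction
recombination *speeds* establishment (204 vs 635 epochs at *r* = 0.1), but
under global reproduction frequent recombination essentially *prevents* it
(16.7% vs 96.7% establishing) — recombination with the majority genotype
destroys the rare optimal type faster than it creates it, unless centers
shelter it. The crossover of the effect is the recombination ×
reproductive-distance interaction (`permutationInteractionTest()`,
p ≈ 0.001 on this design).

## Command line

A thin CLI over the same functions ships in `inst/scripts/latticepeaks.R`:

```sh
Rscript inst/scripts/latticepeaks.R simulate \
    --config inst/extdata/presets/fig1_local_r01.yaml --out out/ --snapshot-every 50
Rscript inst/scripts/latticepeaks.R experiment --preset fig1 --replicates 30 --out out/
Rscript inst/scripts/latticepeaks.R stats --outcomes out/outcomes.csv
```

YAML run configurations (see `inst/extdata/presets/`) mirror
`simulationConfig()` field-for-field; snapshot export writes integer-coded
grid CSVs with a genotype legend.

## Documentation

The methods vignette (`vignettes/lattice-peak-jumping.Rmd`) describes the
model and its assumptions, the design decisions (boundary conditions, stop
rules, censoring treatments, basin definitions), what the synthetic
experiments do and do not demonstrate, and known limitations.
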