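## S4 classes for the simulator.

#' FitnessLandscape class
#'
#' A mapping from every genotype of `L` binary loci to a per-update survival
#' probability. Genotypes not listed explicitly at construction take the
#' default survival, following the convention of landscapes specified as a
#' short table plus a background value for all non-specified genotypes.
#'
#' @slot L integer, locus count.
#' @slot survival numeric vector of length `2^L`, named by bitstring, every
#'   value in `[0, 1]`; the total survival map.
#' @slot listed character, the genotypes given explicitly (the rest were
#'   filled with `defaultSurvival`).
#' @slot defaultSurvival numeric scalar in `[0, 1]`.
#' @slot name character label.
#' @export
setClass("FitnessLandscape",
  representation(L = "integer", survival = "numeric", listed = "character",
                 defaultSurvival = "numeric", name = "character"))

setValidity("FitnessLandscape", function(object) {
  msg <- character(0)
  G <- 2L^object@L
  if (length(object@L) != 1L || object@L < 1L)
    msg <- c(msg, "L must be a single integer >= 1")
  if (length(object@survival) != G)
    msg <- c(msg, sprintf("survival must have length 2^L = %d", G))
  if (any(object@survival < 0 | object@survival > 1))
    msg <- c(msg, "all survival probabilities must lie in [0, 1]")
  if (length(object@defaultSurvival) != 1L ||
      object@defaultSurvival < 0 || object@defaultSurvival > 1)
    msg <- c(msg, "defaultSurvival must be a single probability")
  if (!identical(names(object@survival), allGenotypes(object@L)))
    msg <- c(msg, "survival must be named by bitstrings in index order")
  if (length(msg)) msg else TRUE
})

#' NeighborhoodSpec class
#'
#' Dispersal or mating neighborhood: `local` is the von Neumann ball of the
#' given radius (radius 1 = the four cells to the north, east, south and
#' west), `global` is the entire lattice minus the focal point.
#'
#' @slot mode `"local"` or `"global"`.
#' @slot radius positive integer (local mode only).
#' @slot boundary `"toroidal"` (wrap) or `"bounded"` (edges truncate).
#' @export
setClass("NeighborhoodSpec",
  representation(mode = "character", radius = "integer", boundary = "character"))

setValidity("NeighborhoodSpec", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("local", "global"))
    msg <- c(msg, "mode must be 'local' or 'global'")
  if (object@mode == "local" && (length(object@radius) != 1L || object@radius < 1L))
    msg <- c(msg, "local radius must be a positive integer")
  if (!object@boundary %in% c("toroidal", "bounded"))
    msg <- c(msg, "boundary must be 'toroidal' or 'bounded'")
  if (length(msg)) msg else TRUE
})

#' ReproductionPolicy class
#'
#' Dispersal and mating neighborhoods plus the two mate-choice treatments:
#' rare global reproduction (each mating independently escapes the local
#' neighborhood with a small probability) and centers prohibition (while a
#' tracked genotype is below a population-frequency threshold, a homotypic
#' mate drawn for it is replaced by a random individual from the whole
#' population).
#'
#' @slot dispersal,mating [NeighborhoodSpec-class] objects.
#' @slot rareGlobalProb probability that a single mating uses the global
#'   neighborhood regardless of `mating`.
#' @slot centersGenotype bitstring of the tracked genotype, or `NA_character_`
#'   when the treatment is off.
#' @slot centersThreshold population-frequency threshold (fraction of
#'   occupied cells) below which prohibition applies.
#' @export
setClass("ReproductionPolicy",
  representation(dispersal = "NeighborhoodSpec", mating = "NeighborhoodSpec",
                 rareGlobalProb = "numeric", centersGenotype = "character",
                 centersThreshold = "numeric"))

setValidity("ReproductionPolicy", function(object) {
  msg <- character(0)
  if (object@rareGlobalProb < 0 || object@rareGlobalProb > 1)
    msg <- c(msg, "rareGlobalProb must be a probability")
  if (object@centersThreshold < 0 || object@centersThreshold > 1)
    msg <- c(msg, "centersThreshold must be a fraction in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig class
#'
#' Complete specification of one stochastic run: landscape, lattice side,
#' mutation and crossover probabilities, reproduction policy, initialization,
#' stop rules and seed.
#'
#' @slot landscape a [FitnessLandscape-class].
#' @slot n lattice side length.
#' @slot mu per-locus mutation probability.
#' @slot r between-locus crossover probability (`0.5` = independent
#'   assortment).
#' @slot policy a [ReproductionPolicy-class].
#' @slot init named numeric vector: initial occupancy probability per
#'   genotype (names are bitstrings; values sum to at most 1, the remainder
#'   is the per-cell probability of starting empty).
#' @slot stopGenotype bitstring whose establishment ends the run, or
#'   `NA_character_` to run to `maxEpochs` always.
#' @slot stopFrequency fraction of occupied cells the stop genotype must
#'   reach at an epoch boundary.
#' @slot maxEpochs epoch cap (one epoch = `n^2` updates).
#' @slot seed integer RNG seed, or `NA_integer_` to use the current RNG
#'   state.
#' @export
setClass("SimulationConfig",
  representation(landscape = "FitnessLandscape", n = "integer", mu = "numeric",
                 r = "numeric", policy = "ReproductionPolicy",
                 init = "numeric", stopGenotype = "character",
                 stopFrequency = "numeric", maxEpochs = "integer",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@mu < 0 || object@mu > 1) msg <- c(msg, "mu must be in [0, 1]")
  if (object@r < 0 || object@r > 1) msg <- c(msg, "r must be in [0, 1]")
  if (any(object@init < 0) || sum(object@init) > 1 + 1e-12)
    msg <- c(msg, "init probabilities must be nonnegative and sum to <= 1")
  if (!all(nchar(names(object@init)) == object@landscape@L))
    msg <- c(msg, "init genotype length must equal the landscape's L")
  if (object@stopFrequency < 0 || object@stopFrequency > 1)
    msg <- c(msg, "stopFrequency must be in [0, 1]")
  if (object@maxEpochs < 0L) msg <- c(msg, "maxEpochs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' LatticeState class
#'
#' The population: an `n x n` grid, each cell empty (`NA`) or holding one
#' genotype (integer index).
#'
#' @slot n side length.
#' @slot L locus count of the resident landscape.
#' @slot cells integer matrix `n x n`; `NA` = empty, otherwise a genotype
#'   index in `[0, 2^L)`.
#' @export
setClass("LatticeState",
  representation(n = "integer", L = "integer", cells = "matrix"))

setValidity("LatticeState", function(object) {
  msg <- character(0)
  if (!identical(dim(object@cells), c(object@n, object@n)))
    msg <- c(msg, "cells must be an n x n matrix")
  v <- object@cells[!is.na(object@cells)]
  if (length(v) && (any(v < 0) || any(v >= 2^object@L)))
    msg <- c(msg, "cell genotype indices must lie in [0, 2^L)")
  if (length(msg)) msg else TRUE
})

#' SimulationRun class: the event log and outcome of one run
#'
#' Holds everything the tracking layer needs: the per-epoch genotype count
#' series, update-resolution appearance/extinction transitions of every
#' genotype, optional full birth/death records, creation-origin counters for
#' a tracked genotype, optional lattice snapshots and the final state.
#'
#' @slot config the [SimulationConfig-class] that produced the run.
#' @slot finalState a [LatticeState-class].
#' @slot epochs completed epochs.
#' @slot updates total updates executed.
#' @slot stopReason one of `"max_epochs"`, `"stop_frequency"`, `"extinction"`.
#' @slot counts integer matrix, `(epochs + 1) x 2^L`, genotype counts at
#'   each epoch boundary (row 1 = initialization).
#' @slot transitions data.frame (`update`, `epoch`, `genotype`, `type`) of
#'   every transition of a genotype count between zero and positive;
#'   `update = -1` marks presence at initialization.
#' @slot births data.frame of recorded births (`update`, `epoch`, focal/
#'   parent coordinates, parent, pre-mutation recombinant and offspring
#'   genotypes); empty under `recordBirths = "none"`.
#' @slot deaths data.frame of recorded deaths (`recordBirths = "all"` only).
#' @slot creationCounts named numeric (`recombination`, `mutation`) counting
#'   creations of the tracked genotype from non-tracked parents, split by
#'   whether the pre-mutation recombinant already equalled the target.
#' @slot trackedGenotype bitstring or `NA_character_`.
#' @slot snapshots list of [LatticeState-class] at the requested epoch
#'   cadence.
#' @slot snapshotEpochs integer vector parallel to `snapshots`.
#' @export
setClass("SimulationRun",
  representation(config = "SimulationConfig", finalState = "LatticeState",
                 epochs = "integer", updates = "numeric",
                 stopReason = "character", counts = "matrix",
                 transitions = "data.frame", births = "data.frame",
                 deaths = "data.frame", creationCounts = "numeric",
                 trackedGenotype = "character", snapshots = "list",
                 snapshotEpochs = "integer"))

## ---- show methods ----------------------------------------------------------

setMethod("show", "FitnessLandscape", function(object) {
  cat(sprintf("FitnessLandscape '%s': L = %d (%d genotypes), default s = %g\n",
              object@name, object@L, 2L^object@L, object@defaultSurvival))
  listed <- object@listed
  if (length(listed)) {
    s <- object@survival[listed]
    cat("  listed:", paste(sprintf("s(%s) = %g", listed, s), collapse = ", "),
        "\n")
  }
  pk <- tryCatch(localPeaks(object), error = function(e) character(0))
  if (length(pk)) cat("  local peaks:", paste(pk, collapse = ", "), "\n")
})

setMethod("show", "NeighborhoodSpec", function(object) {
  if (object@mode == "global") cat("NeighborhoodSpec: global (lattice minus focal)\n")
  else cat(sprintf("NeighborhoodSpec: local, radius %d, %s boundary\n",
                   object@radius, object@boundary))
})

setMethod("show", "ReproductionPolicy", function(object) {
  cat("ReproductionPolicy\n  dispersal: ")
  show(object@dispersal)
  cat("  mating:    ")
  show(object@mating)
  if (object@rareGlobalProb > 0)
    cat(sprintf("  rare global reproduction: p = %g per mating\n",
                object@rareGlobalProb))
  if (!is.na(object@centersGenotype))
    cat(sprintf("  centers prohibited for %s below frequency %g\n",
                object@centersGenotype, object@centersThreshold))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: n = %d, mu = %g, r = %g, maxEpochs = %d\n",
              object@n, object@mu, object@r, object@maxEpochs))
  cat(sprintf("  landscape: %s (L = %d)\n", object@landscape@name,
              object@landscape@L))
  cat(sprintf("  init: %s\n",
              paste(sprintf("%s @ %g", names(object@init), object@init),
                    collapse = ", ")))
  if (!is.na(object@stopGenotype))
    cat(sprintf("  stop: %s at frequency >= %g of occupied cells\n",
                object@stopGenotype, object@stopFrequency))
  cat(sprintf("  seed: %s\n",
              if (is.na(object@seed)) "current RNG state" else object@seed))
})

setMethod("show", "LatticeState", function(object) {
  occ <- sum(!is.na(object@cells))
  cat(sprintf("LatticeState: %d x %d, %d/%d occupied\n", object@n, object@n,
              occ, object@n^2))
  cts <- genotypeCounts(object)
  cts <- cts[cts > 0]
  if (length(cts))
    cat("  counts:", paste(sprintf("%s: %d", names(cts), cts), collapse = ", "),
        "\n")
})

setMethod("show", "SimulationRun", function(object) {
  cat(sprintf("SimulationRun: %d epochs (%s), %g updates\n", object@epochs,
              object@stopReason, object@updates))
  show(object@finalState)
})
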