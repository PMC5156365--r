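## Observables derived from event logs: discovery and establishment times,
## creation-origin classification, count series and mean relative fitness.

transitionsOf <- function(run, g) {
  tr <- run@transitions
  tr[tr$genotype == g, , drop = FALSE]
}

#' Discovery time of a genotype
#'
#' Epoch of the first appearance of `g` in the population (epoch 0 when
#' present at initialization); `NA` if `g` never appeared.
#'
#' @param run a [SimulationRun-class].
#' @param g bitstring; default the run's tracked genotype.
#' @return epoch (numeric); attribute `"update"` carries the sub-epoch
#'   update index (-1 = initialization).
#' @export
discoveryTime <- function(run, g = run@trackedGenotype) {
  tr <- transitionsOf(run, g)
  app <- tr$update[tr$type == "appearance"]
  if (!length(app)) return(NA_real_)
  u <- min(app)
  structure(max(0, floor(u / run@config@n^2)), update = u)
}

#' Establishment time of a genotype
#'
#' Epoch of the earliest appearance of `g` after which its count never
#' returned to zero before the end of the run ("discovery without subsequent
#' extinction"); `NA` when `g` is absent at run end (censored).
#'
#' @inheritParams discoveryTime
#' @return epoch (numeric) or `NA`; attribute `"update"` as in
#'   [discoveryTime()].
#' @export
establishmentTime <- function(run, g = run@trackedGenotype) {
  gi <- genotypeIndex(g, run@finalState@L)
  finalCount <- genotypeCounts(run@finalState)[gi + 1L]
  if (finalCount == 0L) return(NA_real_)
  tr <- transitionsOf(run, g)
  app <- tr$update[tr$type == "appearance"]
  ext <- tr$update[tr$type == "extinction"]
  u <- if (!length(ext)) min(app) else min(app[app > max(ext)])
  structure(max(0, floor(u / run@config@n^2)), update = u)
}

#' Classify creations of a target genotype by origin
#'
#' For each birth record: `"none"` if the offspring is not the target or a
#' parent already carries it (a copy, not a creation); `"recombination"` if
#' the pre-mutation recombinant already equalled the target; `"mutation"` if
#' only the post-mutation offspring does. The two-stage birth pipeline
#' (recombine, then mutate) makes the classification exhaustive and
#' exclusive for creations.
#'
#' @param births data.frame of birth records (from `run@births`) with
#'   columns `parent1`, `parent2`, `recombinant`, `offspring`.
#' @param target bitstring.
#' @return character vector (`"none"`, `"recombination"`, `"mutation"`),
#'   one per record.
#' @export
classifyCreation <- function(births, target) {
  if (!nrow(births)) return(character(0))
  out <- rep("none", nrow(births))
  isCreation <- births$offspring == target & births$parent1 != target &
    births$parent2 != target
  out[isCreation & births$recombinant == target] <- "recombination"
  out[isCreation & births$recombinant != target] <- "mutation"
  out
}

#' Creation counts of a genotype, by origin
#'
#' Counts births of `g` from non-`g` parents, split into recombination
#' origin (the pre-mutation recombinant already equalled `g`) and mutation
#' origin. Uses the run's C++-maintained counters when `g` is the tracked
#' genotype, otherwise classifies the recorded births (which requires
#' `recordBirths` `"novel"` or `"all"`).
#'
#' @param run a [SimulationRun-class].
#' @param g bitstring; default the tracked genotype.
#' @param per `"run"` (default: raw counts for the run), `"epoch"` or
#'   `"birth"` to normalize by completed epochs or recorded total births
#'   (the latter only meaningful with `recordBirths = "all"`).
#' @return named numeric vector `c(recombination = , mutation = )`.
#' @export
creationCounts <- function(run, g = run@trackedGenotype,
                           per = c("run", "epoch", "birth")) {
  per <- match.arg(per)
  cts <- if (identical(g, run@trackedGenotype)) {
    run@creationCounts
  } else {
    cl <- classifyCreation(run@births, g)
    c(recombination = sum(cl == "recombination"),
      mutation = sum(cl == "mutation"))
  }
  denom <- switch(per, run = 1, epoch = max(run@epochs, 1L),
                  birth = max(nrow(run@births), 1L))
  cts / denom
}

#' Mean relative fitness of a population
#'
#' Mean survival over occupied cells, relative to the survival of the
#' optimal genotype: `sum(s_g) / (occupancy * s_opt)`.
#'
#' @param state a [LatticeState-class].
#' @param landscape the resident [FitnessLandscape-class] (must have a
#'   unique optimum).
#' @return value in `[0, 1]`.
#' @export
meanRelativeFitness <- function(state, landscape) {
  occ <- occupancy(state)
  if (occ == 0L) stop("mean relative fitness is undefined for an empty population")
  sOpt <- survivalProb(landscape, optimalGenotype(landscape))
  cts <- genotypeCounts(state)
  sum(cts * landscape@survival) / (occ * sOpt)
}

#' Discovery and establishment curves over a collection of runs
#'
#' For each epoch, the fraction of runs whose discovery (establishment) time
#' is at most that epoch. Both curves are monotone nondecreasing
#' right-continuous step functions with establishment never exceeding
#' discovery.
#'
#' @param runs list of [SimulationRun-class] objects.
#' @param g bitstring; default the first run's tracked genotype.
#' @param epochs evaluation grid; default `0:max(run epochs)`.
#' @return data.frame (`epoch`, `discovered`, `established`).
#' @export
discoveryEstablishmentCurves <- function(runs, g = NULL, epochs = NULL) {
  if (!length(runs)) stop("need at least one run")
  if (is.null(g)) g <- runs[[1]]@trackedGenotype
  disc <- vapply(runs, function(rn) as.numeric(discoveryTime(rn, g)),
                 numeric(1))
  est <- vapply(runs, function(rn) as.numeric(establishmentTime(rn, g)),
                numeric(1))
  if (is.null(epochs))
    epochs <- 0:max(vapply(runs, function(rn) rn@epochs, integer(1)))
  data.frame(
    epoch = epochs,
    discovered = vapply(epochs, function(e)
      mean(!is.na(disc) & disc <= e), numeric(1)),
    established = vapply(epochs, function(e)
      mean(!is.na(est) & est <= e), numeric(1)))
}

#' Per-epoch genotype count series in long format
#'
#' @param run a [SimulationRun-class].
#' @param dropZero drop genotypes never observed (default TRUE).
#' @return data.frame (`epoch`, `genotype`, `count`).
#' @export
countSeries <- function(run, dropZero = TRUE) {
  cm <- run@counts
  keep <- if (dropZero) colSums(cm) > 0 else rep(TRUE, ncol(cm))
  cm <- cm[, keep, drop = FALSE]
  data.frame(
    epoch = rep(seq_len(nrow(cm)) - 1L, times = ncol(cm)),
    genotype = rep(colnames(cm), each = nrow(cm)),
    count = as.vector(cm))
}

#' Export the event log as CSV
#'
#' Writes one row per recorded birth and death (`event` column), ordered by
#' update index.
#'
#' @param run a [SimulationRun-class] produced with
#'   `recordBirths = "novel"` or `"all"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(run, path) {
  b <- run@births
  d <- run@deaths
  ev <- data.frame(
    update = c(b$update, d$update), epoch = c(b$epoch, d$epoch),
    event = c(rep("birth", nrow(b)), rep("death", nrow(d))),
    parent1 = c(b$parent1, rep(NA, nrow(d))),
    parent2 = c(b$parent2, rep(NA, nrow(d))),
    recombinant = c(b$recombinant, rep(NA, nrow(d))),
    genotype = c(b$offspring, d$genotype))
  ev <- ev[order(ev$update), ]
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
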