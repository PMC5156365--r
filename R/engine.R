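## The stochastic lattice engine: constructors for neighborhood/policy/config,
## initialization, the exported single-event operations (backed by the same
## C++ routines as the full run loop), and runSimulation().

#' Construct a neighborhood specification
#'
#' @param mode `"local"` (von Neumann ball) or `"global"` (entire lattice
#'   minus the focal point).
#' @param radius von Neumann radius for local mode; radius 1 is the four
#'   cells to the north, east, south and west.
#' @param boundary `"toroidal"` (wrap around the lattice edge) or
#'   `"bounded"` (neighborhoods truncate at the edge).
#' @return a [NeighborhoodSpec-class].
#' @export
neighborhoodSpec <- function(mode = c("local", "global"), radius = 1L,
                             boundary = c("toroidal", "bounded")) {
  new("NeighborhoodSpec", mode = match.arg(mode), radius = as.integer(radius),
      boundary = match.arg(boundary))
}

#' Construct a reproduction policy
#'
#' Dispersal (first parent around the empty focal cell) and mating (second
#' parent around the first) neighborhoods share one mode and radius — the
#' "reproductive distance" — in all shipped presets, but can be set
#' separately through the slots if needed.
#'
#' @param mode `"local"` or `"global"`, applied to both neighborhoods.
#' @param radius local von Neumann radius (default 1).
#' @param boundary lattice boundary behavior, see [neighborhoodSpec()].
#' @param rareGlobalProb probability that any single mating draws its mate
#'   from the whole population instead of the mating neighborhood (the rare
#'   global reproduction treatment; 1/100 in the shipped preset).
#' @param centersGenotype bitstring of a tracked nascent-peak genotype, or
#'   `NA` to disable the centers-prohibited treatment.
#' @param centersThreshold occupied-cell frequency below which a homotypic
#'   mate drawn for the tracked genotype is replaced by a random individual
#'   from the population (default 1%).
#' @return a [ReproductionPolicy-class].
#' @export
reproductionPolicy <- function(mode = c("local", "global"), radius = 1L,
                               boundary = c("toroidal", "bounded"),
                               rareGlobalProb = 0,
                               centersGenotype = NA_character_,
                               centersThreshold = 0.01) {
  spec <- neighborhoodSpec(match.arg(mode), radius, match.arg(boundary))
  new("ReproductionPolicy", dispersal = spec, mating = spec,
      rareGlobalProb = as.numeric(rareGlobalProb),
      centersGenotype = as.character(centersGenotype),
      centersThreshold = as.numeric(centersThreshold))
}

#' Construct a simulation configuration
#'
#' Defaults follow the standard initialization: the population starts as the
#' genotype farthest from the optimum (its bitwise complement), each cell
#' independently occupied with probability equal to that genotype's survival,
#' and the run stops at the first epoch boundary where the optimal genotype
#' reaches `stopFrequency` of occupied cells, or after `maxEpochs` epochs
#' (one epoch = `n^2` updates).
#'
#' @param landscape a [FitnessLandscape-class].
#' @param n lattice side length.
#' @param mu per-locus mutation probability.
#' @param r between-locus crossover probability (0 = no crossing over,
#'   0.5 = independent assortment).
#' @param policy a [ReproductionPolicy-class].
#' @param initGenotype single bitstring, or a named probability vector for a
#'   mixed initialization (names = genotypes, values = per-cell occupancy
#'   probabilities summing to <= 1). Default: [farthestGenotype()].
#' @param initDensity per-cell occupancy probability when `initGenotype` is
#'   a single bitstring. Default: that genotype's survival.
#' @param stopGenotype genotype whose rise ends the run; default the unique
#'   optimum; `NA` disables the frequency stop (run to `maxEpochs`).
#' @param stopFrequency fraction of occupied cells (default 0.5).
#' @param maxEpochs epoch cap (default 2000).
#' @param seed integer seed, or `NA` to consume the current RNG state.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(landscape, n, mu, r,
                             policy = reproductionPolicy("local"),
                             initGenotype = NULL, initDensity = NULL,
                             stopGenotype = NULL, stopFrequency = 0.5,
                             maxEpochs = 2000L, seed = NA) {
  if (is.null(initGenotype)) initGenotype <- farthestGenotype(landscape)
  if (is.character(initGenotype) && is.null(names(initGenotype))) {
    if (length(initGenotype) != 1L)
      stop("multiple init genotypes need a named probability vector")
    if (is.null(initDensity))
      initDensity <- survivalProb(landscape, initGenotype)
    init <- setNames(as.numeric(initDensity), initGenotype)
  } else {
    init <- initGenotype
  }
  if (is.null(stopGenotype)) {
    stopGenotype <- tryCatch(optimalGenotype(landscape),
                             error = function(e) NA_character_)
  }
  new("SimulationConfig", landscape = landscape, n = as.integer(n),
      mu = as.numeric(mu), r = as.numeric(r), policy = policy, init = init,
      stopGenotype = as.character(stopGenotype),
      stopFrequency = as.numeric(stopFrequency),
      maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
}

## ---- lattice state helpers -------------------------------------------------

#' Occupancy of a lattice state
#' @param state a [LatticeState-class].
#' @return integer count of occupied cells.
#' @export
occupancy <- function(state) sum(!is.na(state@cells))

#' Genotype counts of a lattice state
#' @param state a [LatticeState-class].
#' @return named integer vector over all `2^L` genotypes.
#' @export
genotypeCounts <- function(state) {
  G <- 2L^state@L
  tab <- tabulate(state@cells + 1L, nbins = G)
  setNames(as.integer(tab), allGenotypes(state@L))
}

#' Genotype frequencies among occupied cells
#' @param state a [LatticeState-class].
#' @return named numeric vector summing to 1 (NaN when empty).
#' @export
genotypeFrequencies <- function(state) {
  cts <- genotypeCounts(state)
  cts / sum(cts)
}

latticeState <- function(cells, L) {
  new("LatticeState", n = nrow(cells), L = as.integer(L), cells = cells)
}

#' Initialize a lattice
#'
#' Each cell independently receives genotype `g` with probability
#' `config@init[g]` and stays empty otherwise (one uniform draw per cell).
#'
#' @param config a [SimulationConfig-class]. The config's seed is *not*
#'   applied here; [runSimulation()] seeds once per run.
#' @return a [LatticeState-class].
#' @export
initializeLattice <- function(config) {
  n <- config@n
  L <- config@landscape@L
  p <- config@init
  idx <- genotypeIndex(names(p), L)
  cum <- cumsum(p)
  u <- runif(n * n)
  cells <- matrix(NA_integer_, n, n)
  pick <- findInterval(u, c(0, cum), left.open = TRUE)
  occ <- pick >= 1 & pick <= length(p) & u <= cum[length(cum)]
  cells[occ] <- idx[pick[occ]]
  latticeState(cells, L)
}

## ---- point/position helpers ------------------------------------------------

## 0-based column-major position <-> (row, col) 1-based
posToPoint <- function(pos, n) {
  cbind(row = pos %% n + 1L, col = pos %/% n + 1L)
}
pointToPos <- function(row, col, n) {
  (as.integer(col) - 1L) * n + (as.integer(row) - 1L)
}

latVector <- function(state) {
  v <- as.integer(state@cells)
  v[is.na(v)] <- -1L
  v
}

specMode <- function(spec) if (spec@mode == "global") 1L else 0L

#' Neighborhood of a lattice point
#'
#' @param spec a [NeighborhoodSpec-class].
#' @param point integer vector `c(row, col)` (1-based).
#' @param n lattice side length.
#' @return matrix with columns `row`, `col`: the neighborhood cells,
#'   excluding the focal point.
#' @examples
#' neighborhood(neighborhoodSpec("local"), c(6, 6), 70)
#' @export
neighborhood <- function(spec, point, n) {
  pos <- pointToPos(point[1], point[2], n)
  out <- cpp_neighborhood(n, pos, specMode(spec), spec@radius,
                          spec@boundary == "toroidal")
  posToPoint(out, n)
}

#' Select the first parent for a birth at an empty focal cell
#'
#' Uniform draw among occupied cells of the dispersal neighborhood about the
#' focal point; `NULL` when the neighborhood holds no organism (the birth
#' then fails).
#'
#' @param state a [LatticeState-class].
#' @param point focal `c(row, col)`.
#' @param policy a [ReproductionPolicy-class].
#' @return `NULL`, or a list with `point` (row, col) and `genotype`
#'   (bitstring).
#' @export
selectFirstParent <- function(state, point, policy) {
  spec <- policy@dispersal
  pos <- cpp_select_parent(latVector(state), state@n,
                           pointToPos(point[1], point[2], state@n),
                           specMode(spec), spec@radius,
                           spec@boundary == "toroidal", -1L, 1L)
  parentAt(state, pos)
}

parentAt <- function(state, pos) {
  if (pos < 0) return(NULL)
  pt <- posToPoint(pos, state@n)
  list(point = c(pt[1, "row"], pt[1, "col"]),
       genotype = genotypeString(state@cells[pt[1, "row"], pt[1, "col"]],
                                 state@L))
}

#' Select a mate for the first parent
#'
#' Uniform draw among occupied cells of the mating neighborhood about the
#' first parent, excluding the first parent's own cell. With probability
#' `rareGlobalProb` the mating neighborhood is overridden to global for this
#' mating. Under the centers-prohibited treatment, if the tracked genotype
#' is below its frequency threshold (of occupied cells) and both the first
#' parent and the drawn mate are the tracked genotype, the mate is redrawn
#' uniformly from all occupied cells except the first parent.
#'
#' @param state a [LatticeState-class].
#' @param firstParentPoint `c(row, col)` of the first parent.
#' @param policy a [ReproductionPolicy-class].
#' @return `NULL` (no candidate: the birth fails), or a list with `point`
#'   and `genotype`.
#' @export
selectMate <- function(state, firstParentPoint, policy) {
  spec <- policy@mating
  cg <- policy@centersGenotype
  cgIdx <- if (is.na(cg)) -1L else genotypeIndex(cg, state@L)
  pos <- cpp_select_mate(latVector(state), state@n, state@L,
                         pointToPos(firstParentPoint[1], firstParentPoint[2],
                                    state@n),
                         specMode(spec), spec@radius,
                         spec@boundary == "toroidal",
                         policy@rareGlobalProb, cgIdx,
                         policy@centersThreshold, 1L)
  parentAt(state, pos)
}

#' Recombine two parental genotypes
#'
#' One parent is chosen at random to contribute the allele at the first
#' locus; at each of the L-1 between-locus boundaries the contributing
#' parent switches with probability `r`. `r = 0` transmits a whole parental
#' genotype; `r = 0.5` yields independent assortment of parental alleles.
#'
#' @param g1,g2 parental bitstrings of equal length.
#' @param r between-locus crossover probability.
#' @param n number of independent offspring to draw.
#' @return character vector of `n` offspring bitstrings.
#' @export
recombineGenotypes <- function(g1, g2, r, n = 1L) {
  L <- nchar(g1)
  if (nchar(g2) != L) stop("genotypes must have equal length")
  genotypeString(cpp_recombine(genotypeIndex(g1), genotypeIndex(g2), L, r,
                               as.integer(n)), L)
}

#' Mutate a genotype
#'
#' Each locus flips (0 to 1 or 1 to 0) independently with probability `mu`.
#'
#' @param g bitstring.
#' @param mu per-locus mutation probability.
#' @param n number of independent draws.
#' @return character vector of `n` mutated bitstrings.
#' @export
mutateGenotype <- function(g, mu, n = 1L) {
  L <- nchar(g)
  genotypeString(cpp_mutate(genotypeIndex(g), L, mu, as.integer(n)), L)
}

## exact offspring distribution of the recombination operator, by
## enumeration of the 2 * 2^(L-1) donor/crossover paths; the independent
## oracle for the stochastic recombine kernel lives in the tests, this one
## is exported for users
#' Exact offspring distribution under recombination
#'
#' Enumerates all `2 * 2^(L-1)` equally-structured donor/crossover paths
#' (initial donor choice times the crossover indicator at each of the L-1
#' boundaries) and accumulates path probabilities per offspring genotype.
#'
#' @param g1,g2 parental bitstrings.
#' @param r between-locus crossover probability.
#' @return named numeric vector over all `2^L` genotypes, summing to 1.
#' @export
recombinationDistribution <- function(g1, g2, r) {
  L <- nchar(g1)
  G <- 2L^L
  p <- setNames(numeric(G), allGenotypes(L))
  b1 <- strsplit(g1, "")[[1]]
  b2 <- strsplit(g2, "")[[1]]
  for (donor0 in 0:1) {
    for (mask in seq_len(2L^(L - 1L)) - 1L) {
      switches <- as.integer(intToBits(mask)[seq_len(max(L - 1L, 1L))])
      if (L == 1L) switches <- integer(0)
      donor <- donor0
      alleles <- character(L)
      prob <- 0.5
      for (i in seq_len(L)) {
        alleles[i] <- if (donor == 0) b1[i] else b2[i]
        if (i < L) {
          sw <- switches[i]
          prob <- prob * (if (sw == 1) r else 1 - r)
          if (sw == 1) donor <- 1 - donor
        }
      }
      g <- paste(alleles, collapse = "")
      p[g] <- p[g] + prob
    }
  }
  p
}

## ---- single update step ----------------------------------------------------

#' Execute one update step
#'
#' A point is chosen at random. An occupied focal point's organism dies with
#' probability `1 - s_G`; an empty focal point triggers a birth attempt
#' (first parent from the dispersal neighborhood, mate from the mating
#' neighborhood about the first parent, recombination, then mutation). Used
#' for stepwise inspection; [runSimulation()] executes the same compiled
#' kernel for whole runs.
#'
#' @param state a [LatticeState-class].
#' @param config a [SimulationConfig-class] (its seed is ignored; the
#'   current RNG state is consumed).
#' @return list with `state` (the new [LatticeState-class]) and `event`, a
#'   one-row data.frame describing what happened (`type` is one of
#'   `"death"`, `"birth"`, `"none"`).
#' @export
updateStep <- function(state, config) {
  res <- engineRun(state, config, nUpdates = 1, recordMode = 2L,
                   snapshotEvery = 0L, tracked = -1L)
  newState <- latticeStateFromVector(res$lattice, state@n, state@L)
  ev <- data.frame(type = "none", update = 0)
  if (length(res$birth_update)) {
    pt <- posToPoint(res$birth_focal[1], state@n)
    p1 <- posToPoint(res$birth_p1[1], state@n)
    p2 <- posToPoint(res$birth_p2[1], state@n)
    ev <- data.frame(
      type = "birth", update = res$birth_update[1],
      row = pt[1, 1], col = pt[1, 2],
      parent1 = genotypeString(res$birth_g1[1], state@L),
      parent2 = genotypeString(res$birth_g2[1], state@L),
      parent1_row = p1[1, 1], parent1_col = p1[1, 2],
      parent2_row = p2[1, 1], parent2_col = p2[1, 2],
      recombinant = genotypeString(res$birth_rec[1], state@L),
      offspring = genotypeString(res$birth_off[1], state@L))
  } else if (length(res$death_update)) {
    pt <- posToPoint(res$death_pos[1], state@n)
    ev <- data.frame(type = "death", update = res$death_update[1],
                     row = pt[1, 1], col = pt[1, 2],
                     genotype = genotypeString(res$death_genotype[1],
                                               state@L))
  }
  list(state = newState, event = ev)
}

latticeStateFromVector <- function(v, n, L) {
  v[v < 0] <- NA_integer_
  latticeState(matrix(as.integer(v), n, n), L)
}

## shared bridge into cpp_run
engineRun <- function(state, config, nUpdates, recordMode, snapshotEvery,
                      tracked) {
  pol <- config@policy
  L <- config@landscape@L
  stopIdx <- if (is.na(config@stopGenotype)) -1L else
    genotypeIndex(config@stopGenotype, L)
  cgIdx <- if (is.na(pol@centersGenotype)) -1L else
    genotypeIndex(pol@centersGenotype, L)
  cpp_run(latVector(state), state@n, L, unname(config@landscape@survival),
          config@mu, config@r,
          specMode(pol@dispersal), pol@dispersal@radius,
          specMode(pol@mating), pol@mating@radius,
          pol@dispersal@boundary == "toroidal",
          pol@rareGlobalProb, cgIdx, pol@centersThreshold,
          stopIdx, config@stopFrequency, config@maxEpochs,
          nUpdates, recordMode, snapshotEvery, tracked)
}

#' Run a full simulation
#'
#' Seeds the RNG (when the config has a seed), initializes the lattice and
#' executes epochs of `n^2` updates until the stop genotype reaches the stop
#' frequency at an epoch boundary, the population goes extinct, or
#' `maxEpochs` epochs complete. Fully reproducible from the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param recordBirths `"novel"` (default: births whose offspring differs
#'   from at least one parent), `"none"` (count series and transitions
#'   only; cheapest) or `"all"` (every birth and death).
#' @param snapshotEvery record the lattice every this many epochs (0 = off).
#' @param trackedGenotype bitstring whose creations from non-tracked parents
#'   are counted in C++ split by origin (recombination vs mutation), or
#'   `NULL` for the config's stop genotype when defined.
#' @param initialState optionally a pre-built [LatticeState-class] to start
#'   from instead of [initializeLattice()].
#' @return a [SimulationRun-class].
#' @examples
#' cfg <- simulationConfig(buildNamedLandscape("fig1_default"), n = 20,
#'                         mu = 0.002, r = 0.1, maxEpochs = 50, seed = 1)
#' run <- runSimulation(cfg)
#' @export
runSimulation <- function(config, recordBirths = c("novel", "none", "all"),
                          snapshotEvery = 0L, trackedGenotype = NULL,
                          initialState = NULL) {
  recordBirths <- match.arg(recordBirths)
  recordMode <- match(recordBirths, c("none", "novel", "all")) - 1L
  if (!is.na(config@seed)) set.seed(config@seed)
  L <- config@landscape@L
  n <- config@n
  if (is.null(trackedGenotype)) trackedGenotype <- config@stopGenotype
  tracked <- if (is.na(trackedGenotype)) -1L else
    genotypeIndex(trackedGenotype, L)
  state <- if (is.null(initialState)) initializeLattice(config) else
    initialState
  res <- engineRun(state, config, nUpdates = -1, recordMode = recordMode,
                   snapshotEvery = as.integer(snapshotEvery),
                   tracked = tracked)
  n2 <- n * n
  gs <- function(i) genotypeString(i, L)
  counts <- res$counts
  colnames(counts) <- allGenotypes(L)
  transitions <- data.frame(
    update = res$trans_update,
    epoch = pmax(0, floor(res$trans_update / n2)),
    genotype = gs(res$trans_genotype),
    type = c("appearance", "extinction")[res$trans_type + 1L])
  births <- data.frame(
    update = res$birth_update,
    epoch = floor(res$birth_update / n2),
    focal = res$birth_focal,
    parent1 = if (length(res$birth_g1)) gs(res$birth_g1) else character(0),
    parent2 = if (length(res$birth_g2)) gs(res$birth_g2) else character(0),
    recombinant = if (length(res$birth_rec)) gs(res$birth_rec) else
      character(0),
    offspring = if (length(res$birth_off)) gs(res$birth_off) else
      character(0))
  deaths <- data.frame(
    update = res$death_update,
    epoch = floor(res$death_update / n2),
    position = res$death_pos,
    genotype = if (length(res$death_genotype)) gs(res$death_genotype) else
      character(0))
  snaps <- lapply(res$snapshots, latticeStateFromVector, n = n, L = L)
  new("SimulationRun", config = config,
      finalState = latticeStateFromVector(res$lattice, n, L),
      epochs = as.integer(res$epochs), updates = res$updates,
      stopReason = c("max_epochs", "stop_frequency",
                     "extinction")[res$stop_reason + 1L],
      counts = counts, transitions = transitions, births = births,
      deaths = deaths,
      creationCounts = c(recombination = res$rec_creations,
                         mutation = res$mut_creations),
      trackedGenotype = as.character(trackedGenotype), snapshots = snaps,
      snapshotEpochs = as.integer(res$snapshot_epochs))
}

## ---- config files and snapshot export --------------------------------------

#' Read a simulation configuration from YAML
#'
#' The file mirrors [simulationConfig()] field-for-field; the landscape is
#' given inline (`L`, `default_survival`, `survival: {bitstring: value}`),
#' by name (`landscape_name`), or by file (`landscape_file`, resolved
#' relative to the config file). The lattice side is the `lattice_size` key
#' (a bare `n` is a boolean in YAML 1.1; a quoted `'n'` is accepted).
#'
#' @param path YAML file path.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  landscape <- if (!is.null(y$landscape_name)) {
    buildNamedLandscape(y$landscape_name)
  } else if (!is.null(y$landscape_file)) {
    readLandscape(file.path(dirname(path), y$landscape_file))
  } else {
    fitnessLandscape(L = y$L, survival = unlist(y$survival),
                     defaultSurvival = y$default_survival %||% 0,
                     name = y$name %||% basename(path))
  }
  policy <- reproductionPolicy(
    mode = y$reproduction %||% "local",
    radius = y$radius %||% 1L,
    boundary = y$boundary %||% "toroidal",
    rareGlobalProb = y$rare_global_prob %||% 0,
    centersGenotype = y$centers_genotype %||% NA_character_,
    centersThreshold = y$centers_threshold %||% 0.01)
  init <- y$init_genotype %||% NULL
  if (!is.null(init) && is.list(init)) init <- unlist(init)
  n <- y[["lattice_size"]] %||% y[["n"]]
  if (is.null(n)) stop("config must give lattice_size")
  simulationConfig(
    landscape = landscape, n = n, mu = y$mu, r = y$r, policy = policy,
    initGenotype = init, initDensity = y$init_density %||% NULL,
    stopGenotype = if (isTRUE(is.na(y$stop_genotype)) ||
                       identical(y$stop_genotype, "none")) NA_character_
                   else y$stop_genotype %||% NULL,
    stopFrequency = y$stop_frequency %||% 0.5,
    maxEpochs = y$max_epochs %||% 2000L,
    seed = y$seed %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export lattice snapshots as integer-coded CSV grids
#'
#' Writes one CSV per snapshot (`snapshot_epoch<k>.csv`, an `n x n` integer
#' matrix with -1 for empty cells) plus `legend.csv` mapping integer codes
#' to genotype bitstrings.
#'
#' @param run a [SimulationRun-class] produced with `snapshotEvery > 0`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
writeSnapshots <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- run@finalState@L
  paths <- character(0)
  for (i in seq_along(run@snapshots)) {
    m <- run@snapshots[[i]]@cells
    m[is.na(m)] <- -1L
    p <- file.path(dir, sprintf("snapshot_epoch%d.csv",
                                run@snapshotEpochs[i]))
    write.table(m, p, sep = ",", row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  legend <- data.frame(code = c(-1L, seq_len(2L^L) - 1L),
                       genotype = c("empty", allGenotypes(L)))
  lp <- file.path(dir, "legend.csv")
  write.csv(legend, lp, row.names = FALSE)
  invisible(c(paths, lp))
}
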