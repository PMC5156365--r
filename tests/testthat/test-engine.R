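test_that("lattice initialization matches the occupancy model", {
  ls1 <- fig1Landscape()
  full <- simulationConfig(ls1, n = 10, mu = 0, r = 0, initDensity = 1,
                           maxEpochs = 0L)
  expect_equal(occupancy(initializeLattice(full)), 100L)
  empty <- simulationConfig(ls1, n = 10, mu = 0, r = 0, initDensity = 0,
                            maxEpochs = 0L)
  expect_equal(occupancy(initializeLattice(empty)), 0L)
  # default initialization: farthest genotype at its own survival (0.6),
  # occupancy binomial(n^2, 0.6)
  cfg <- simulationConfig(ls1, n = 70, mu = 0.002, r = 0)
  expect_equal(names(cfg@init), "0000")
  expect_equal(unname(cfg@init), 0.6)
  set.seed(42)
  st <- initializeLattice(cfg)
  expect_lt(abs(occupancy(st) - 0.6 * 4900), 4 * sqrt(4900 * 0.6 * 0.4))
  expect_setequal(genotypeString(unique(st@cells[!is.na(st@cells)]), 4),
                  "0000")
  # mixed initialization
  mix <- simulationConfig(ls1, n = 50, mu = 0, r = 0,
                          initGenotype = c("0011" = 0.3, "1100" = 0.3),
                          maxEpochs = 0L)
  set.seed(1)
  stm <- initializeLattice(mix)
  cts <- genotypeCounts(stm)
  expect_lt(abs(cts[["0011"]] - 750), 4 * sqrt(2500 * 0.3 * 0.7))
  expect_lt(abs(cts[["1100"]] - 750), 4 * sqrt(2500 * 0.3 * 0.7))
  expect_equal(sum(cts), cts[["0011"]] + cts[["1100"]])
})

test_that("neighborhoods have the right cells at interior, edge and corner", {
  loc <- neighborhoodSpec("local")
  nb <- neighborhood(loc, c(6, 6), 70)
  expect_equal(nrow(nb), 4)
  expect_setequal(paste(nb[, 1], nb[, 2]),
                  c("5 6", "7 6", "6 5", "6 7"))
  # toroidal corner wraps to 4 cells, bounded corner truncates to 2
  nbT <- neighborhood(loc, c(1, 1), 10)
  expect_equal(nrow(nbT), 4)
  expect_setequal(paste(nbT[, 1], nbT[, 2]),
                  c("10 1", "2 1", "1 10", "1 2"))
  bnd <- neighborhoodSpec("local", boundary = "bounded")
  expect_equal(nrow(neighborhood(bnd, c(1, 1), 10)), 2)
  # von Neumann ball of radius 2 has 2r(r+1) = 12 cells
  expect_equal(nrow(neighborhood(neighborhoodSpec("local", radius = 2),
                                 c(5, 5), 20)), 12)
  # global: the entire lattice minus the focal point
  glob <- neighborhood(neighborhoodSpec("global"), c(3, 3), 70)
  expect_equal(nrow(glob), 70^2 - 1)
  expect_false(any(glob[, 1] == 3 & glob[, 2] == 3))
})

test_that("first-parent selection is uniform over occupied dispersal cells", {
  pol <- reproductionPolicy("local")
  # all neighbors empty: no parent, no birth
  st <- makeLattice(5, 2, list(list(1, 1, "01")))
  expect_null(selectFirstParent(st, c(3, 3), pol))
  # exactly one occupied neighbor: chosen with probability 1
  st2 <- makeLattice(5, 2, list(list(2, 3, "10")))
  p <- selectFirstParent(st2, c(3, 3), pol)
  expect_equal(p$genotype, "10")
  expect_equal(unname(p$point), c(2, 3))
  # global mode: uniform over the k occupied cells (chi-square)
  set.seed(9)
  cells <- list(list(1, 1, "00"), list(2, 5, "01"), list(4, 2, "10"),
                list(5, 5, "11"), list(3, 4, "00"))
  st3 <- makeLattice(5, 2, cells)
  polG <- reproductionPolicy("global")
  draws <- replicate(20000, {
    p <- selectFirstParent(st3, c(3, 3), polG)
    paste(p$point, collapse = ",")
  })
  tab <- table(draws)
  expect_equal(length(tab), 5)
  chi <- sum((tab - 4000)^2 / 4000)
  expect_lt(chi, qchisq(0.999, df = 4))
})

test_that("mate selection excludes the first parent and honors treatments", {
  # local mating, first parent isolated: no mate, no birth
  st <- makeLattice(7, 2, list(list(4, 4, "01")))
  pol <- reproductionPolicy("local")
  expect_null(selectMate(st, c(4, 4), pol))
  # the mate is never the first parent's own cell
  st2 <- makeLattice(7, 2, list(list(4, 4, "01"), list(4, 5, "10")))
  set.seed(2)
  for (i in 1:20) {
    m <- selectMate(st2, c(4, 4), pol)
    expect_false(all(m$point == c(4, 4)))
  }
  # rare-global override: with rareGlobalProb = 1 a distant cell can mate
  stFar <- makeLattice(9, 2, list(list(1, 1, "01"), list(9, 9, "10")))
  polRG <- reproductionPolicy("local", rareGlobalProb = 1)
  m <- selectMate(stFar, c(1, 1), polRG)
  expect_equal(m$genotype, "10")
  # centers prohibition: tracked genotype below threshold drawing a
  # homotypic neighbor is redirected to a random individual. The only
  # occupied neighbor of (4,4) is the homotypic (4,5); rows 1-2 and 7-8
  # hold the 00 majority.
  cells <- c(list(list(4, 4, "11"), list(4, 5, "11")),
             lapply(seq_len(32), function(i) {
               rows <- c(1, 2, 7, 8)
               list(rows[(i - 1) %% 4 + 1], (i - 1) %/% 4 + 1, "00")
             }))
  stC <- makeLattice(8, 2, cells)
  polC <- reproductionPolicy("local", centersGenotype = "11",
                             centersThreshold = 0.5)
  set.seed(3)
  mates <- replicate(400, selectMate(stC, c(4, 4), polC)$genotype)
  # the only local neighbor is 11, but nearly all redraws land on 00
  expect_gt(mean(mates == "00"), 0.9)
  # above threshold the homotypic neighbor is kept
  polC2 <- reproductionPolicy("local", centersGenotype = "11",
                              centersThreshold = 0.01)
  mates2 <- replicate(50, selectMate(stC, c(4, 4), polC2)$genotype)
  expect_true(all(mates2 == "11"))
})

test_that("recombination matches exact path enumeration", {
  # r = 0: a whole parental genotype, each with probability 1/2
  set.seed(5)
  off0 <- recombineGenotypes("0011", "1100", 0, n = 4000)
  expect_setequal(unique(off0), c("0011", "1100"))
  expect_lt(abs(mean(off0 == "0011") - 0.5), 0.03)
  # identical parents: offspring equals the parent at any r
  expect_true(all(recombineGenotypes("0110", "0110", 0.5, n = 50) == "0110"))
  # empirical distribution vs brute-force enumeration at L = 3, r = 0.3
  ex <- bruteForceRecombination("010", "101", 0.3)
  expect_equal(sum(ex), 1)
  expect_equal(unname(recombinationDistribution("010", "101", 0.3)),
               unname(ex))
  draws <- recombineGenotypes("010", "101", 0.3, n = 50000)
  emp <- as.numeric(table(factor(draws, levels = allGenotypes(3)))) / 50000
  expect_lt(0.5 * sum(abs(emp - ex)), 0.01)
})

test_that("mutation flips loci independently at rate mu", {
  expect_equal(mutateGenotype("0110", 0, n = 3), rep("0110", 3))
  expect_equal(mutateGenotype("0110", 1, n = 3), rep("1001", 3))
  set.seed(6)
  m <- mutateGenotype("0000", 0.002, n = 200000)
  flips <- hammingDistance(m, "0000")
  se <- sqrt(4 * 0.002 * 0.998 / 200000)
  expect_lt(abs(mean(flips) - 0.008), 3 * se)
})

test_that("a single update step is one death, birth or no-op", {
  ls3 <- buildNamedLandscape("s3_lethal")
  # lethal genotype at the focal point dies with probability 1
  cfg <- simulationConfig(ls3, n = 1, mu = 0, r = 0, initGenotype = "11",
                          initDensity = 1, stopGenotype = NA_character_,
                          maxEpochs = 1L)
  st <- makeLattice(1, 2, list(list(1, 1, "11")))
  set.seed(1)
  res <- updateStep(st, cfg)
  expect_equal(res$event$type, "death")
  expect_equal(occupancy(res$state), 0L)
  # survival 1: the organism never dies
  lsSafe <- fitnessLandscape(L = 2, survival = setNames(rep(1, 4),
                                                        allGenotypes(2)))
  cfgS <- simulationConfig(lsSafe, n = 1, mu = 0, r = 0, initGenotype = "00",
                           initDensity = 1, stopGenotype = NA_character_,
                           maxEpochs = 1L)
  stS <- makeLattice(1, 2, list(list(1, 1, "00")))
  set.seed(2)
  for (i in 1:10) {
    res <- updateStep(stS, cfgS)
    expect_equal(res$event$type, "none")
    expect_equal(occupancy(res$state), 1L)
  }
  # empty focal point with empty dispersal neighborhood: no birth
  stE <- makeLattice(5, 2, list(list(1, 1, "00")))
  cfgE <- simulationConfig(ls3, n = 5, mu = 0, r = 0, initGenotype = "00",
                           stopGenotype = NA_character_, maxEpochs = 1L)
  set.seed(3)
  for (i in 1:20) {
    res <- updateStep(stE, cfgE)
    expect_true(res$event$type %in% c("none", "death"))
  }
})

test_that("runs are reproducible, conserve counts and respect stop rules", {
  cfg <- simulationConfig(fig1Landscape(), n = 15, mu = 0.002, r = 0.1,
                          maxEpochs = 200L, seed = 31L)
  # maxEpochs = 0 returns the initial state
  cfg0 <- cfg; cfg0@maxEpochs <- 0L
  run0 <- runSimulation(cfg0)
  expect_equal(run0@epochs, 0L)
  expect_equal(sum(run0@counts[1, ]), occupancy(run0@finalState))
  # same seed, identical logs; different seed, different trajectory
  runA <- runSimulation(cfg, recordBirths = "novel")
  runB <- runSimulation(cfg, recordBirths = "novel")
  expect_identical(runA@counts, runB@counts)
  expect_identical(runA@transitions, runB@transitions)
  expect_identical(runA@births, runB@births)
  cfgC <- cfg; cfgC@seed <- 32L
  runC <- runSimulation(cfgC)
  expect_false(identical(runA@counts, runC@counts))
  # count-series rows recount the final lattice exactly
  last <- runA@counts[nrow(runA@counts), ]
  expect_equal(unname(last), unname(genotypeCounts(runA@finalState)))
  expect_equal(sum(last), occupancy(runA@finalState))
  # per-epoch occupancy never jumps by more than n^2 (one change per update)
  occs <- rowSums(runA@counts)
  expect_true(all(abs(diff(occs)) <= 15^2))
  # stop rule: run ends at the epoch the stop genotype reached the
  # threshold among occupied cells
  if (runA@stopReason == "stop_frequency") {
    fin <- runA@counts[nrow(runA@counts), ]
    expect_gte(fin[["1111"]] / sum(fin), cfg@stopFrequency)
  }
})

test_that("extinction terminates a run with the extinction flag", {
  lethal <- fitnessLandscape(L = 2, survival = setNames(rep(0, 4),
                                                        allGenotypes(2)))
  cfg <- simulationConfig(lethal, n = 8, mu = 0, r = 0, initGenotype = "00",
                          initDensity = 1, stopGenotype = NA_character_,
                          maxEpochs = 100L, seed = 4L)
  run <- runSimulation(cfg)
  expect_equal(run@stopReason, "extinction")
  expect_equal(occupancy(run@finalState), 0L)
  expect_lt(run@epochs, 100L)
})

test_that("global reproduction is insensitive to spatial arrangement", {
  # with a global neighborhood the dynamics depend on the lattice only
  # through genotype counts: a clustered and a scattered initialization
  # with identical counts give indistinguishable fixation outcomes
  ls <- fitnessLandscape(L = 1, survival = c("0" = 0.7, "1" = 0.7))
  n <- 12
  nReps <- 60
  cluster <- matrix(NA_integer_, n, n)
  cluster[1:6, 1:12] <- 0L
  cluster[1:3, 1:12] <- 1L   # 36 of genotype 1, 36 of genotype 0, clustered
  set.seed(77)
  scatter <- matrix(NA_integer_, n, n)
  posns <- sample(n * n, 72)
  scatter[posns[1:36]] <- 1L
  scatter[posns[37:72]] <- 0L
  outcomes <- function(cellsM, seedBase) {
    vapply(seq_len(nReps), function(i) {
      cfg <- simulationConfig(ls, n = n, mu = 0, r = 0,
                              policy = reproductionPolicy("global"),
                              initGenotype = "0",
                              stopGenotype = NA_character_,
                              maxEpochs = 40L, seed = seedBase + i)
      st <- new("LatticeState", n = as.integer(n), L = 1L, cells = cellsM)
      run <- runSimulation(cfg, recordBirths = "none", initialState = st)
      genotypeCounts(run@finalState)[["1"]] /
        max(occupancy(run@finalState), 1)
    }, numeric(1))
  }
  fA <- outcomes(cluster, 1000)
  fB <- outcomes(scatter, 5000)
  # final frequency distributions should agree (rank-sum, generous alpha)
  expect_gt(suppressWarnings(wilcox.test(fA, fB)$p.value), 0.01)
})
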