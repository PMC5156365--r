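# Fixtures and independent oracles shared across test files. Oracles here
# are deliberately naive (exhaustive enumeration, direct counting) and never
# call the code paths they check.

fig1Landscape <- function() buildNamedLandscape("fig1_default")

# brute-force local peaks: for every genotype, compare survival against all
# single-bit flips using string manipulation only
bruteForcePeaks <- function(landscape) {
  L <- lociCount(landscape)
  gs <- allGenotypes(L)
  flip1 <- function(g) {
    vapply(seq_len(L), function(i) {
      v <- strsplit(g, "")[[1]]
      v[i] <- if (v[i] == "0") "1" else "0"
      paste(v, collapse = "")
    }, character(1))
  }
  gs[vapply(gs, function(g) {
    all(survivalProb(landscape, g) > survivalProb(landscape, flip1(g)))
  }, logical(1))]
}

# exact offspring distribution of the single-donor-switch recombination
# model by direct path enumeration over donor sequences (not genotype
# masks): donor0 in {1,2}, then L-1 independent switch indicators
bruteForceRecombination <- function(g1, g2, r) {
  L <- nchar(g1)
  a1 <- strsplit(g1, "")[[1]]
  a2 <- strsplit(g2, "")[[1]]
  p <- setNames(numeric(2^L), allGenotypes(L))
  nSwitchPatterns <- 2^(L - 1)
  for (d0 in 1:2) {
    for (pat in seq_len(nSwitchPatterns) - 1) {
      sw <- as.integer(intToBits(pat)[seq_len(L - 1)])
      donor <- d0
      out <- character(L)
      pr <- 0.5
      for (i in seq_len(L)) {
        out[i] <- if (donor == 1) a1[i] else a2[i]
        if (i < L) {
          pr <- pr * if (sw[i] == 1) r else 1 - r
          if (sw[i] == 1) donor <- 3 - donor
        }
      }
      key <- paste(out, collapse = "")
      p[key] <- p[key] + pr
    }
  }
  p
}

# small deterministic lattice: n x n, all empty except the named cells
# (list of list(row, col, genotype))
makeLattice <- function(n, L, cells = list()) {
  m <- matrix(NA_integer_, n, n)
  for (cl in cells) m[cl[[1]], cl[[2]]] <- genotypeIndex(cl[[3]], L)
  new("LatticeState", n = as.integer(n), L = as.integer(L), cells = m)
}

# construct a bare SimulationRun with a given transition table and final
# counts, for exercising the time-derivation logic in isolation
makeRunSkeleton <- function(n, L, transitions, finalCells) {
  cfg <- simulationConfig(
    fitnessLandscape(L = L,
                     survival = setNames(seq(0.1, 0.9,
                                             length.out = 2^L),
                                         allGenotypes(L))),
    n = n, mu = 0, r = 0, maxEpochs = 0L)
  new("SimulationRun", config = cfg,
      finalState = new("LatticeState", n = as.integer(n), L = as.integer(L),
                       cells = finalCells),
      epochs = 100L, updates = 100 * n^2, stopReason = "max_epochs",
      counts = matrix(0L, 1, 2^L,
                      dimnames = list(NULL, allGenotypes(L))),
      transitions = transitions,
      births = data.frame(), deaths = data.frame(),
      creationCounts = c(recombination = NA_real_, mutation = NA_real_),
      trackedGenotype = NA_character_, snapshots = list(),
      snapshotEpochs = integer(0))
}
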