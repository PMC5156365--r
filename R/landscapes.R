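## Fitness landscapes: construction, named landscapes, fitness -> survival
## conversion, and topology diagnostics (peaks, peak-jumping accessibility).

#' Construct a fitness landscape
#'
#' Builds the total genotype -> survival map from a short table of listed
#' genotypes plus a default survival for all non-specified genotypes.
#'
#' @param L locus count (inferred from `survival` names if omitted).
#' @param survival named numeric vector: bitstring -> survival probability in
#'   `[0, 1]`.
#' @param defaultSurvival survival of every unlisted genotype.
#' @param name label.
#' @return a [FitnessLandscape-class].
#' @examples
#' fitnessLandscape(survival = c("00" = 0.8, "01" = 0.6, "10" = 0.6,
#'                               "11" = 0.9))
#' @export
fitnessLandscape <- function(L = NULL, survival = numeric(0),
                             defaultSurvival = 0, name = "landscape") {
  if (is.null(L)) {
    if (!length(survival)) stop("need L or a named survival table")
    L <- nchar(names(survival)[1])
  }
  L <- as.integer(L)
  idx <- genotypeIndex(names(survival), L)
  if (anyDuplicated(idx)) stop("duplicated genotypes in survival table")
  full <- rep(as.numeric(defaultSurvival), 2L^L)
  full[idx + 1L] <- as.numeric(survival)
  names(full) <- allGenotypes(L)
  new("FitnessLandscape", L = L, survival = full,
      listed = genotypeString(sort(idx), L),
      defaultSurvival = as.numeric(defaultSurvival), name = name)
}

#' Survival probability of a genotype
#'
#' @param landscape a [FitnessLandscape-class].
#' @param g bitstring vector (each of length `landscape@L`).
#' @return numeric vector of survival probabilities.
#' @examples
#' survivalProb(buildNamedLandscape("fig1_default"), c("1111", "0101"))
#' @export
survivalProb <- function(landscape, g) {
  stopifnot(is(landscape, "FitnessLandscape"))
  idx <- genotypeIndex(g, landscape@L)
  unname(landscape@survival[idx + 1L])
}

#' Locus count of a landscape
#' @param landscape a [FitnessLandscape-class].
#' @return integer locus count.
#' @export
lociCount <- function(landscape) landscape@L

#' Full survival table of a landscape
#' @param landscape a [FitnessLandscape-class].
#' @return named numeric vector over all `2^L` genotypes.
#' @export
survivalTable <- function(landscape) landscape@survival

#' Globally optimal genotype
#'
#' The unique genotype with maximal survival. Ties for the maximum are an
#' error (the optimum is then undefined); the error message lists the tied
#' genotypes.
#'
#' @param landscape a [FitnessLandscape-class].
#' @return bitstring of the optimum.
#' @export
optimalGenotype <- function(landscape) {
  s <- landscape@survival
  top <- which(s == max(s))
  if (length(top) > 1L)
    stop("ambiguous optimum; tied genotypes: ",
         paste(names(s)[top], collapse = ", "))
  names(s)[top]
}

#' Genotype farthest from the optimum
#'
#' The bitwise complement of the optimal genotype, i.e. the unique genotype
#' at Hamming distance L from it; the canonical initial genotype.
#'
#' @param landscape a [FitnessLandscape-class] with a unique optimum.
#' @return bitstring.
#' @examples
#' farthestGenotype(buildNamedLandscape("fig1_default"))  # "0000"
#' @export
farthestGenotype <- function(landscape) {
  complementGenotype(optimalGenotype(landscape))
}

#' Built-in named landscapes
#'
#' * `fig1_default`: L = 4; s(0000) = 0.6, s(0011) = s(1100) = 0.85,
#'   s(1111) = 0.9, all other genotypes 0.2. Two suboptimal peaks whose
#'   recombinants reach the optimum: peak-jumping is possible.
#' * `s3_lethal`: L = 2; s(00) = 0.6, s(01) = s(10) = 0.85, s(11) = 0. The
#'   double mutant is lethal; used to count creations of 11 at sutures.
#' * `s4_valley`: L = 2; s(00) = 0.8, s(01) = s(10) = 0.6, s(11) = 0.9. A
#'   two-peak landscape separated by an adaptive valley; used for the
#'   centers experiments.
#'
#' @param name one of `"fig1_default"`, `"s3_lethal"`, `"s4_valley"`.
#' @return a [FitnessLandscape-class].
#' @export
buildNamedLandscape <- function(name) {
  switch(name,
    fig1_default = fitnessLandscape(
      L = 4L,
      survival = c("0000" = 0.6, "0011" = 0.85, "1100" = 0.85, "1111" = 0.9),
      defaultSurvival = 0.2, name = "fig1_default"),
    s3_lethal = fitnessLandscape(
      L = 2L,
      survival = c("00" = 0.6, "01" = 0.85, "10" = 0.85, "11" = 0),
      defaultSurvival = 0, name = "s3_lethal"),
    s4_valley = fitnessLandscape(
      L = 2L,
      survival = c("00" = 0.8, "01" = 0.6, "10" = 0.6, "11" = 0.9),
      defaultSurvival = 0, name = "s4_valley"),
    stop("unknown landscape name: ", name)
  )
}

#' Convert relative fitnesses to survival probabilities
#'
#' Converts a table of relative fitnesses \eqn{\omega_G} to survival
#' probabilities via \eqn{s_G = \omega_G / (2 \bar\omega)}, where
#' \eqn{\bar\omega} is the mean fitness over all listed genotypes. The
#' conversion halves the landscape-mean survival to 0.5 so that converted
#' landscapes are dynamically comparable to hand-specified ones; it preserves
#' the fitness ranking exactly. A different conversion can be supplied via
#' `convert`.
#'
#' @param fitness named numeric vector: bitstring -> relative fitness
#'   \eqn{\omega_G \ge 0}; must cover all `2^L` genotypes.
#' @param name label for the resulting landscape.
#' @param convert function mapping the fitness vector to survival
#'   probabilities; default `function(w) w / (2 * mean(w))`.
#' @return a [FitnessLandscape-class].
#' @examples
#' convertRelativeFitness(c("00" = 0, "01" = 1, "10" = 1, "11" = 2))
#' @export
convertRelativeFitness <- function(fitness, name = "converted",
                                   convert = function(w) w / (2 * mean(w))) {
  w <- as.numeric(fitness)
  if (any(w < 0)) stop("relative fitnesses must be nonnegative")
  if (mean(w) <= 0) stop("mean fitness must be positive")
  L <- nchar(names(fitness)[1])
  if (length(fitness) != 2^L)
    stop("fitness table must cover all 2^L genotypes")
  s <- convert(w)
  if (any(s > 1)) {
    bad <- names(fitness)[which(s > 1)]
    stop("conversion overflow: survival > 1 for genotype(s) ",
         paste(bad, collapse = ", "))
  }
  fitnessLandscape(L = L, survival = setNames(s, names(fitness)),
                   defaultSurvival = 0, name = name)
}

## one-mutant neighbor indices of genotype index i
oneMutantNeighbors <- function(i, L) {
  bitwXor(i, 2L^(seq_len(L) - 1L))
}

#' Local peaks of a landscape
#'
#' Genotypes whose survival strictly exceeds that of all L one-mutant
#' neighbors.
#'
#' @param landscape a [FitnessLandscape-class].
#' @return character vector of peak bitstrings (possibly empty).
#' @examples
#' localPeaks(buildNamedLandscape("fig1_default"))
#' @export
localPeaks <- function(landscape) {
  s <- landscape@survival
  L <- landscape@L
  G <- 2L^L
  isPeak <- vapply(seq_len(G) - 1L, function(i) {
    all(s[i + 1L] > s[oneMutantNeighbors(i, L) + 1L])
  }, logical(1))
  names(s)[isPeak]
}

## greedy adaptive walk: repeatedly move to the fittest one-mutant neighbor
## if it strictly improves survival; ties among improving neighbors broken by
## lowest genotype index. Returns the terminal (peak) index.
greedyBasinPeak <- function(i, landscape) {
  s <- landscape@survival
  L <- landscape@L
  repeat {
    nb <- oneMutantNeighbors(i, L)
    sv <- s[nb + 1L]
    best <- max(sv)
    if (best <= s[i + 1L]) return(i)
    i <- min(nb[sv == best])
  }
}

## all recombinants of two genotype indices: every locus taken from either
## parent, i.e. (p & q) | (x & (p ^ q)) over all submasks x of p ^ q
recombinantSet <- function(p, q) {
  d <- bitwXor(p, q)
  common <- bitwAnd(p, q)
  if (d == 0L) return(common)
  bits <- which(as.integer(intToBits(d)[1:31]) == 1L)
  subs <- 0L
  for (b in bits) subs <- c(subs, bitwOr(subs, 2L^(b - 1L)))
  unique(bitwOr(common, subs))
}

#' Is a landscape peak-jump accessible?
#'
#' A landscape permits peak-jumping when some pair of distinct suboptimal
#' local peaks has a recombinant (any genotype obtainable by taking each
#' locus from either parent) that lies in the attraction basin of a peak
#' strictly higher than both, where basins are defined by a greedy adaptive
#' walk to the fittest one-mutant neighbor (ties to the lowest genotype
#' index). Landscapes with fewer than two suboptimal peaks (e.g. a two-peak
#' landscape whose higher peak is the optimum) are not peak-jump accessible:
#' the concept requires a third, higher peak reachable from a suboptimal
#' pair.
#'
#' @param landscape a [FitnessLandscape-class].
#' @return logical; attribute `"witness"` holds a data.frame
#'   (`peak1`, `peak2`, `recombinant`, `target`) of all witnessing jumps.
#' @examples
#' peakJumpAccessible(buildNamedLandscape("fig1_default"))  # TRUE
#' @export
peakJumpAccessible <- function(landscape) {
  s <- landscape@survival
  L <- landscape@L
  peaks <- genotypeIndex(localPeaks(landscape), L)
  wit <- data.frame(peak1 = character(0), peak2 = character(0),
                    recombinant = character(0), target = character(0),
                    stringsAsFactors = FALSE)
  if (length(peaks) >= 2L) {
    topS <- max(s[peaks + 1L])
    sub <- peaks[s[peaks + 1L] < topS]
    if (length(sub) >= 2L) {
      prs <- combn(sub, 2L)
      for (k in seq_len(ncol(prs))) {
        p <- prs[1, k]; q <- prs[2, k]
        hi <- max(s[p + 1L], s[q + 1L])
        for (rc in recombinantSet(p, q)) {
          b <- greedyBasinPeak(rc, landscape)
          if (!(b %in% c(p, q)) && s[b + 1L] > hi) {
            wit <- rbind(wit, data.frame(
              peak1 = genotypeString(p, L), peak2 = genotypeString(q, L),
              recombinant = genotypeString(rc, L),
              target = genotypeString(b, L), stringsAsFactors = FALSE))
          }
        }
      }
    }
  }
  structure(nrow(wit) > 0, witness = wit)
}

#' Generate a synthetic rugged landscape
#'
#' Rejection-samples uniform random survival tables until the landscape has
#' exactly `nPeaks` local peaks and the requested peak-jumping
#' accessibility. Deterministic given `seed`; the caller's RNG state is left
#' untouched. Intended as a stand-in generator for rugged empirical
#' landscapes of either topology class (peak-jumping possible or not).
#'
#' @param L locus count (>= 2).
#' @param nPeaks required number of local peaks, in `[2, 2^(L-1)]`.
#' @param allowPeakJumping logical; required value of [peakJumpAccessible()].
#' @param seed integer seed.
#' @param maxTries rejection budget.
#' @return a [FitnessLandscape-class].
#' @export
generateSyntheticRugged <- function(L, nPeaks, allowPeakJumping, seed,
                                    maxTries = 20000L) {
  stopifnot(L >= 2, nPeaks >= 2, nPeaks <= 2^(L - 1))
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(seed)
  G <- 2L^as.integer(L)
  for (try in seq_len(maxTries)) {
    s <- runif(G)
    ls <- fitnessLandscape(
      L = L, survival = setNames(s, allGenotypes(L)), defaultSurvival = 0,
      name = sprintf("synthetic_L%d_p%d_%s", L, nPeaks,
                     if (allowPeakJumping) "PJplus" else "PJminus"))
    if (length(localPeaks(ls)) != nPeaks) next
    if (isTRUE(as.logical(peakJumpAccessible(ls))) != allowPeakJumping) next
    return(ls)
  }
  stop("rejection budget exhausted: no landscape with L = ", L, ", ", nPeaks,
       " peaks and peak-jumping ", allowPeakJumping, " in ", maxTries,
       " tries")
}

#' Read a landscape from a flat file
#'
#' The format is CSV with columns `genotype` and `survival` (or `fitness`,
#' which triggers [convertRelativeFitness()]), preceded by comment header
#' lines `# L: <int>`, `# default_survival: <float>` and optionally
#' `# name: <label>`.
#'
#' @param path file path.
#' @return a [FitnessLandscape-class].
#' @export
readLandscape <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getKey <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", m[1]))
  }
  L <- as.integer(getKey("L"))
  defS <- as.numeric(getKey("default_survival"))
  name <- getKey("name")
  if (is.na(name)) name <- basename(path)
  tab <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  colClasses = c(genotype = "character"))
  if ("fitness" %in% names(tab)) {
    return(convertRelativeFitness(setNames(tab$fitness, tab$genotype),
                                  name = name))
  }
  if (is.na(defS)) defS <- 0
  fitnessLandscape(L = L, survival = setNames(tab$survival, tab$genotype),
                   defaultSurvival = defS, name = name)
}

#' Write a landscape to a flat file
#'
#' Inverse of [readLandscape()]; only explicitly listed genotypes are
#' written, the rest are represented by the `default_survival` header.
#'
#' @param landscape a [FitnessLandscape-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeLandscape <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# L: %d", landscape@L),
               sprintf("# default_survival: %.17g", landscape@defaultSurvival),
               sprintf("# name: %s", landscape@name),
               "genotype,survival"), con)
  for (g in landscape@listed)
    writeLines(sprintf("%s,%.17g", g, unname(landscape@survival[g])), con)
  invisible(path)
}
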