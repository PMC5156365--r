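## Factorial experiment runner and statistics: replicate management,
## percentile-bootstrap CIs, ratio-of-means comparisons and Manly-style
## raw-data permutation tests for factorial interactions.

#' Derive a per-run seed from a root seed
#'
#' `seed = (root * 7919 + cell * 104729 + rep) mod (2^31 - 2) + 1`. All
#' intermediate products stay below 2^53, so the arithmetic is exact in
#' doubles; distinct (cell, replicate) pairs give distinct seeds for
#' replicate indices below 104729.
#'
#' @param rootSeed integer root seed.
#' @param cell cell index (1-based).
#' @param rep replicate index (1-based).
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(rootSeed, cell, rep) {
  as.integer((as.numeric(rootSeed) * 7919 + as.numeric(cell) * 104729 +
                as.numeric(rep)) %% (2^31 - 2) + 1)
}

#' Construct a factorial experiment design
#'
#' A full-factorial grid over the given factors, each cell simulated with
#' `replicates` independent runs seeded by [deriveSeed()] from one root
#' seed (so the outcome table is independent of execution order and
#' parallelizable by run).
#'
#' Recognized factor names and their effect on the base configuration:
#' * `r`: crossover probability.
#' * `mu`: mutation probability.
#' * `n`: lattice side.
#' * `reproduction`: `"local"`, `"global"`, `"local_rare_global"` (local
#'   with the policy's `rareGlobalProb`, default 0.01) or
#'   `"local_centers_prohibited"` / `"global_centers_prohibited"` (centers
#'   prohibition on the config's stop genotype at the 1% threshold).
#' * `landscape`: names of [buildNamedLandscape()] landscapes, or a named
#'   list of [FitnessLandscape-class] objects.
#' * `maxEpochs`: epoch cap (used by sweeps with escalating caps).
#'
#' @param base a [SimulationConfig-class]; cell-specific fields are
#'   overridden per factor level.
#' @param factors named list of factor levels.
#' @param replicates runs per cell.
#' @param rootSeed root seed for [deriveSeed()].
#' @param rareGlobalProb probability used by the `"local_rare_global"`
#'   reproduction level.
#' @return an object of class `"experimentDesign"` (list with the cell
#'   grid).
#' @export
experimentDesign <- function(base, factors, replicates = 30L, rootSeed = 1L,
                             rareGlobalProb = 0.01) {
  stopifnot(is(base, "SimulationConfig"), replicates >= 1L)
  landscapes <- NULL
  if (!is.null(factors$landscape) && is.list(factors$landscape)) {
    landscapes <- factors$landscape
    factors$landscape <- names(landscapes)
  }
  grid <- expand.grid(factors, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(base = base, grid = grid, landscapes = landscapes,
                 replicates = as.integer(replicates),
                 rootSeed = as.integer(rootSeed),
                 rareGlobalProb = rareGlobalProb),
            class = "experimentDesign")
}

cellConfig <- function(design, cellIdx) {
  cfg <- design$base
  row <- design$grid[cellIdx, , drop = FALSE]
  landscape <- cfg@landscape
  if (!is.null(row[["landscape"]])) {
    landscape <- if (!is.null(design$landscapes))
      design$landscapes[[row[["landscape"]]]] else
      buildNamedLandscape(row[["landscape"]])
  }
  n <- if (!is.null(row[["n"]])) as.integer(row[["n"]]) else cfg@n
  mu <- if (!is.null(row[["mu"]])) row[["mu"]] else cfg@mu
  r <- if (!is.null(row[["r"]])) row[["r"]] else cfg@r
  maxEpochs <- if (!is.null(row[["maxEpochs"]])) as.integer(row[["maxEpochs"]]) else
    cfg@maxEpochs
  policy <- cfg@policy
  if (!is.null(row[["reproduction"]])) {
    stopG <- cfg@stopGenotype
    policy <- switch(as.character(row[["reproduction"]]),
      local = reproductionPolicy("local"),
      global = reproductionPolicy("global"),
      local_rare_global = reproductionPolicy(
        "local", rareGlobalProb = design$rareGlobalProb),
      local_centers_prohibited = reproductionPolicy(
        "local", centersGenotype = stopG),
      global_centers_prohibited = reproductionPolicy(
        "global", centersGenotype = stopG),
      stop("unknown reproduction level: ", row[["reproduction"]]))
  }
  simulationConfig(landscape = landscape, n = n, mu = mu, r = r,
                   policy = policy,
                   initGenotype = if (identical(landscape,
                                                cfg@landscape))
                     cfg@init else NULL,
                   stopGenotype = if (identical(landscape, cfg@landscape))
                     cfg@stopGenotype else NULL,
                   stopFrequency = cfg@stopFrequency,
                   maxEpochs = maxEpochs, seed = NA)
}

#' Run a factorial experiment design
#'
#' Executes every cell x replicate with per-run derived seeds and collects
#' the outcome table. The result is independent of execution order because
#' each run is seeded by (cell, replicate), not by position in the loop.
#'
#' @param design an [experimentDesign()].
#' @param verbose print one line per cell.
#' @return list of class `"experimentResult"`: `outcomes` (one row per run:
#'   factor levels, `replicate`, `seed`, `established` flag,
#'   `establishmentEpoch` (`NA` when censored), `discoveryEpoch`, `epochs`,
#'   `recCreations`, `mutCreations`) and `summary` (per cell: mean
#'   establishment epoch over establishing runs, bootstrap 95% CI,
#'   establishment fraction).
#' @export
runDesign <- function(design, verbose = FALSE) {
  grid <- design$grid
  out <- vector("list", nrow(grid) * design$replicates)
  k <- 0L
  for (ci in seq_len(nrow(grid))) {
    cfg0 <- cellConfig(design, ci)
    if (verbose)
      message(sprintf("cell %d/%d: %s", ci, nrow(grid),
                      paste(names(grid), unlist(grid[ci, ]), sep = "=",
                            collapse = ", ")))
    for (rep in seq_len(design$replicates)) {
      cfg <- cfg0
      cfg@seed <- deriveSeed(design$rootSeed, ci, rep)
      run <- runSimulation(cfg, recordBirths = "none")
      est <- if (is.na(cfg@stopGenotype)) NA_real_ else
        as.numeric(establishmentTime(run, cfg@stopGenotype))
      disc <- if (is.na(cfg@stopGenotype)) NA_real_ else
        as.numeric(discoveryTime(run, cfg@stopGenotype))
      k <- k + 1L
      out[[k]] <- cbind(
        grid[ci, , drop = FALSE],
        data.frame(cell = ci, replicate = rep, seed = cfg@seed,
                   established = !is.na(est), establishmentEpoch = est,
                   discoveryEpoch = disc, epochs = run@epochs,
                   stopReason = run@stopReason,
                   recCreations = unname(run@creationCounts["recombination"]),
                   mutCreations = unname(run@creationCounts["mutation"])))
    }
  }
  outcomes <- do.call(rbind, out)
  rownames(outcomes) <- NULL
  res <- list(design = design, outcomes = outcomes,
              summary = summarizeOutcomes(outcomes, names(grid)))
  class(res) <- "experimentResult"
  res
}

#' @export
print.experimentResult <- function(x, ...) {
  cat("experimentResult:", nrow(x$outcomes), "runs in",
      nrow(x$design$grid), "cells\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Summarize an outcome table per design cell
#'
#' @param outcomes outcome data.frame from [runDesign()].
#' @param factorNames columns defining the cells.
#' @param B bootstrap resamples for the CI of the mean.
#' @param level CI level.
#' @return data.frame: factor levels, `nRuns`, `established` fraction, mean
#'   establishment epoch over establishing runs with bootstrap CI (`NA`
#'   when fewer than two runs establish).
#' @export
summarizeOutcomes <- function(outcomes, factorNames, B = 2000L,
                              level = 0.95) {
  cells <- unique(outcomes[, c(factorNames, "cell"), drop = FALSE])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- outcomes[outcomes$cell == cells$cell[i], ]
    est <- sub$establishmentEpoch[sub$established]
    ci <- if (length(est) >= 2L) bootstrapMeanCI(est, B = B, level = level)
      else c(mean = if (length(est)) mean(est) else NA_real_,
             lower = NA_real_, upper = NA_real_)
    cbind(cells[i, factorNames, drop = FALSE],
          data.frame(nRuns = nrow(sub), established = mean(sub$established),
                     meanEpoch = unname(ci[1]), ciLower = unname(ci[2]),
                     ciUpper = unname(ci[3])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile bootstrap CI of a mean
#'
#' @param values numeric vector (length >= 2 for a CI).
#' @param B resamples.
#' @param level confidence level.
#' @return named numeric `c(mean, lower, upper)`.
#' @export
bootstrapMeanCI <- function(values, B = 10000L, level = 0.95) {
  stopifnot(length(values) >= 2L, B >= 1L, level > 0, level < 1)
  nv <- length(values)
  means <- rowMeans(matrix(sample(values, nv * B, replace = TRUE), nrow = B))
  alpha <- (1 - level) / 2
  qs <- quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(mean = mean(values), lower = qs[1], upper = qs[2])
}

#' Ratio of group means with bootstrap CI
#'
#' `ratio = mean(groupA) / mean(groupB)`; both groups are resampled
#' independently. Convention throughout the package: group A is the
#' recombining treatment and group B the r = 0 baseline, so a ratio below 1
#' means recombination speeds establishment.
#'
#' @param groupA,groupB numeric outcome vectors.
#' @param B resamples.
#' @param level confidence level.
#' @return named numeric `c(ratio, lower, upper)`.
#' @export
ratioOfMeans <- function(groupA, groupB, B = 10000L, level = 0.95) {
  stopifnot(length(groupA) >= 1L, length(groupB) >= 1L)
  if (mean(groupB) <= 0) stop("baseline group mean must be positive")
  mA <- rowMeans(matrix(sample(groupA, length(groupA) * B, replace = TRUE),
                        nrow = B))
  mB <- rowMeans(matrix(sample(groupB, length(groupB) * B, replace = TRUE),
                        nrow = B))
  alpha <- (1 - level) / 2
  qs <- quantile(mA / mB, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ratio = mean(groupA) / mean(groupB), lower = qs[1], upper = qs[2])
}

## observed-statistic machinery for the permutation test: F statistic of the
## highest-order interaction in a fixed-effects factorial ANOVA, computed
## from QR decompositions of the full and interaction-free model matrices
## (fast enough to re-evaluate thousands of permutations)
interactionStatMaker <- function(data, factorNames) {
  for (f in factorNames) data[[f]] <- factor(data[[f]])
  fullForm <- stats::as.formula(
    paste("~", paste(factorNames, collapse = " * ")))
  intTerm <- paste(factorNames, collapse = ":")
  Xfull <- model.matrix(fullForm, data)
  trm <- attr(stats::terms(fullForm), "term.labels")
  asgn <- attr(Xfull, "assign")
  keep <- asgn == 0 | trm[pmax(asgn, 1)] != intTerm
  Xred <- Xfull[, keep, drop = FALSE]
  qrF <- qr(Xfull)
  qrR <- qr(Xred)
  QF <- qr.Q(qrF)[, seq_len(qrF$rank), drop = FALSE]
  QR <- qr.Q(qrR)[, seq_len(qrR$rank), drop = FALSE]
  dfInt <- qrF$rank - qrR$rank
  dfRes <- nrow(Xfull) - qrF$rank
  if (dfInt < 1L || dfRes < 1L)
    stop("design has no residual or interaction degrees of freedom")
  function(y) {
    tot <- sum(y^2)
    rssF <- tot - sum(crossprod(QF, y)^2)
    rssR <- tot - sum(crossprod(QR, y)^2)
    ((rssR - rssF) / dfInt) / (rssF / dfRes)
  }
}

#' Manly-style permutation test for a factorial interaction
#'
#' Observed statistic: the F statistic of the highest-order interaction
#' (two- or three-way) from a fixed-effects factorial ANOVA of the outcome
#' on the named factors. Null distribution: unrestricted permutation of the
#' raw outcomes across all runs/cells (raw-data permutation).
#' `p = (1 + #\{perm stat >= observed\}) / (1 + nPerm)`.
#'
#' @param data data.frame with the outcome and factor columns.
#' @param outcome name of the numeric outcome column.
#' @param factorNames two or three factor column names; the tested
#'   interaction is their highest-order term.
#' @param nPerm number of permutations (>= 999 recommended).
#' @return list: `p.value`, `statistic` (observed interaction F), `nPerm`.
#' @export
permutationInteractionTest <- function(data, outcome, factorNames,
                                       nPerm = 1999L) {
  stopifnot(length(factorNames) %in% c(2L, 3L))
  y <- data[[outcome]]
  if (anyNA(y)) stop("outcome contains NA; resolve censoring first")
  if (stats::sd(y) == 0)
    return(list(p.value = 1, statistic = NA_real_, nPerm = nPerm))
  stat <- interactionStatMaker(data, factorNames)
  obs <- stat(y)
  exceed <- 0L
  for (i in seq_len(nPerm))
    if (stat(sample(y)) >= obs) exceed <- exceed + 1L
  list(p.value = (1 + exceed) / (1 + nPerm), statistic = obs, nPerm = nPerm)
}

#' One-sided permutation test for a difference in group means
#'
#' Tests whether `mean(groupA) < mean(groupB)` by permuting group labels;
#' `p = (1 + #\{perm diff <= observed\}) / (1 + nPerm)` where
#' `diff = mean(A) - mean(B)`.
#'
#' @param groupA,groupB numeric vectors.
#' @param nPerm permutations.
#' @return list: `p.value`, `statistic` (observed mean difference).
#' @export
permutationMeanTest <- function(groupA, groupB, nPerm = 9999L) {
  y <- c(groupA, groupB)
  nA <- length(groupA)
  obs <- mean(groupA) - mean(groupB)
  cnt <- 0L
  for (i in seq_len(nPerm)) {
    idx <- sample.int(length(y), nA)
    if (mean(y[idx]) - mean(y[-idx]) <= obs) cnt <- cnt + 1L
  }
  list(p.value = (1 + cnt) / (1 + nPerm), statistic = obs)
}

#' Resolve censored establishment outcomes for analysis
#'
#' Manly's test on establishment times is ill-defined with censored runs.
#' Two treatments are offered: `"restrict"` (default) keeps only cells
#' where at least `minEstablished` of runs establish and drops censored
#' runs within them; `"substitute"` replaces censored times by the cell's
#' epoch cap (a conservative lower bound on the true waiting time).
#'
#' @param outcomes outcome table from [runDesign()].
#' @param method `"restrict"` or `"substitute"`.
#' @param minEstablished cell-level establishment fraction required under
#'   `"restrict"`.
#' @return the outcome table with a complete `establishmentEpoch` column
#'   (possibly fewer rows).
#' @export
resolveCensoring <- function(outcomes, method = c("restrict", "substitute"),
                             minEstablished = 0.9) {
  method <- match.arg(method)
  if (method == "substitute") {
    cap <- ifelse(is.na(outcomes$establishmentEpoch), outcomes$epochs,
                  outcomes$establishmentEpoch)
    outcomes$establishmentEpoch <- cap
    return(outcomes)
  }
  frac <- tapply(outcomes$established, outcomes$cell, mean)
  keep <- names(frac)[frac >= minEstablished]
  out <- outcomes[outcomes$cell %in% keep & outcomes$established, ]
  out
}

#' Parameter sweep of the recombination speedup ratio
#'
#' For each level of `parameter` (`"mu"` or `"n"`), runs the factorial
#' design (recombination rates x reproduction modes) and reports, per
#' reproduction mode and recombining rate, the ratio of mean establishment
#' epochs relative to the r = 0 baseline of the same mode
#' ([ratioOfMeans()]; censored runs are substituted by the epoch cap). A
#' cell is `flagged` when fewer than half of its runs establish by the cap
#' (establishment "rarely occurred").
#'
#' @param parameter `"mu"` or `"n"`.
#' @param levels numeric vector of parameter values.
#' @param base a [SimulationConfig-class] template.
#' @param rLevels recombination rates (must include 0, the baseline).
#' @param reproduction reproduction modes.
#' @param replicates runs per cell.
#' @param rootSeed root seed.
#' @param epochCaps optional numeric vector (recycled over `levels`) of
#'   per-level epoch caps; defaults to the base config's cap.
#' @param B bootstrap resamples for ratio CIs.
#' @return data.frame: `level`, `reproduction`, `r`, `ratio`, `lower`,
#'   `upper`, `establishedA`, `establishedB`, `flagged`.
#' @export
sweepParameter <- function(parameter = c("mu", "n"), levels, base,
                           rLevels = c(0, 0.1, 0.5),
                           reproduction = c("local", "global"),
                           replicates = 20L, rootSeed = 1L,
                           epochCaps = NULL, B = 2000L) {
  parameter <- match.arg(parameter)
  stopifnot(0 %in% rLevels)
  if (is.null(epochCaps)) epochCaps <- base@maxEpochs
  epochCaps <- rep_len(epochCaps, length(levels))
  rows <- list()
  for (li in seq_along(levels)) {
    factors <- list(r = rLevels, reproduction = reproduction)
    factors[[parameter]] <- levels[li]
    factors$maxEpochs <- epochCaps[li]
    des <- experimentDesign(base, factors, replicates = replicates,
                            rootSeed = rootSeed + li - 1L)
    res <- runDesign(des)
    oc <- resolveCensoring(res$outcomes, "substitute")
    for (mode in reproduction) {
      baseVals <- oc$establishmentEpoch[oc$reproduction == mode & oc$r == 0]
      baseEst <- mean(oc$established[oc$reproduction == mode & oc$r == 0])
      for (rv in setdiff(rLevels, 0)) {
        sel <- oc$reproduction == mode & oc$r == rv
        ratio <- ratioOfMeans(oc$establishmentEpoch[sel], baseVals, B = B)
        rows[[length(rows) + 1L]] <- data.frame(
          level = levels[li], reproduction = mode, r = rv,
          ratio = unname(ratio[1]), lower = unname(ratio[2]),
          upper = unname(ratio[3]),
          establishedA = mean(oc$established[sel]), establishedB = baseEst,
          flagged = mean(oc$established[sel]) < 0.5)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shipped experiment presets
#'
#' Named factorial designs mirroring the package's standard experiments at
#' their full scale; `n`, `replicates` and `maxEpochs` can be overridden to
#' run scaled-down versions.
#'
#' * `fig1`: 4 recombination rates x 2 reproduction modes on the
#'   `fig1_default` landscape (n = 70, mu = 0.002, 155 replicates, cap
#'   2000 epochs).
#' * `s3_sutures`: local vs global on `s3_lethal` (mu = 1e-5, r = 0.5,
#'   fixed-length runs) tracking creations of lethal genotype 11.
#' * `s4_centers`: r in \{0, 0.5\} x \{local, global,
#'   local_centers_prohibited, global_centers_prohibited\} on `s4_valley`
#'   (mu = 0.001, 40 replicates).
#' * `s6_rare_global`: as `fig1` with reproduction levels local,
#'   local_rare_global (p = 0.01) and global.
#'
#' @param name preset name.
#' @param n lattice side override.
#' @param replicates replicate override.
#' @param maxEpochs epoch-cap override.
#' @param rootSeed root seed.
#' @return an [experimentDesign()].
#' @export
presetDesign <- function(name = c("fig1", "s3_sutures", "s4_centers",
                                  "s6_rare_global"),
                         n = NULL, replicates = NULL, maxEpochs = NULL,
                         rootSeed = 1L) {
  name <- match.arg(name)
  pick <- function(x, d) if (is.null(x)) d else x
  switch(name,
    fig1 = {
      base <- simulationConfig(buildNamedLandscape("fig1_default"),
                               n = pick(n, 70L), mu = 0.002, r = 0,
                               maxEpochs = pick(maxEpochs, 2000L))
      experimentDesign(base, list(r = c(0, 0.02, 0.1, 0.5),
                                  reproduction = c("local", "global")),
                       replicates = pick(replicates, 155L),
                       rootSeed = rootSeed)
    },
    s3_sutures = {
      base <- simulationConfig(buildNamedLandscape("s3_lethal"),
                               n = pick(n, 70L), mu = 1e-5, r = 0.5,
                               initGenotype = "00",
                               stopGenotype = NA_character_,
                               maxEpochs = pick(maxEpochs, 3000L))
      experimentDesign(base, list(reproduction = c("local", "global")),
                       replicates = pick(replicates, 15L),
                       rootSeed = rootSeed)
    },
    s4_centers = {
      base <- simulationConfig(buildNamedLandscape("s4_valley"),
                               n = pick(n, 70L), mu = 0.001, r = 0.5,
                               initGenotype = "00", initDensity = 0.8,
                               maxEpochs = pick(maxEpochs, 2000L))
      experimentDesign(base, list(
        r = c(0, 0.5),
        reproduction = c("local", "global", "local_centers_prohibited",
                         "global_centers_prohibited")),
        replicates = pick(replicates, 40L), rootSeed = rootSeed)
    },
    s6_rare_global = {
      base <- simulationConfig(buildNamedLandscape("fig1_default"),
                               n = pick(n, 70L), mu = 0.002, r = 0,
                               maxEpochs = pick(maxEpochs, 2000L))
      experimentDesign(base, list(
        r = c(0, 0.02, 0.1, 0.5),
        reproduction = c("local", "local_rare_global", "global")),
        replicates = pick(replicates, 100L), rootSeed = rootSeed)
    })
}

#' Write an outcome table and run manifest
#'
#' Writes `outcomes.csv`, `summary.csv` and, when the jsonlite package is
#' available, `manifest.json` (root seed, factor grid, replicate count,
#' package version).
#'
#' @param result an `experimentResult` from [runDesign()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeExperimentResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  write.csv(result$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      rootSeed = result$design$rootSeed,
      replicates = result$design$replicates,
      grid = result$design$grid,
      package = as.character(utils::packageVersion("latticePeaks")))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
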