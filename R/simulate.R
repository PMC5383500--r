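#' @include traitTable.R pools.R
NULL

#' Simulation configuration for a synthetic assembly experiment
#'
#' Defaults describe a single grassland-like focal community: a regional
#' cloud of 600 species with two uniform \[0, 1\] traits; a Gaussian
#' environmental filter (sd 0.15) clustering the habitat-specific pool around
#' a trait optimum; per-trait biotic filtering by weak phenotype exclusion
#' (Gaussian retention, sd 0.08 -- tighter than the pool spread, so local
#' clustering is a real signal), limiting similarity (iterative removal of
#' the most similar pair until all nearest-neighbor gaps exceed 0.05,
#' yielding roughly 20-species communities), or neutral; 40 plots of
#' Poisson(15) species sampled from the community with geometric (p = 0.3)
#' abundances; and a seed-addition experiment adding 15 seeds of each of 25
#' colonists to every plot.
#'
#' @param seed integer seed governing every stochastic draw.
#' @param nRegional regional species richness (>= 50).
#' @param nTraits number of traits.
#' @param envOptimum trait optimum of the environmental filter.
#' @param envSd breadth of the Gaussian environmental filter.
#' @param bioticMode per-trait biotic filtering mode:
#'   "weak_phenotype_exclusion", "limiting_similarity", or "neutral".
#' @param wpeOptimum,wpeSd Gaussian retention kernel of weak phenotype
#'   exclusion.
#' @param lsMinDistance minimum within-community nearest-neighbor distance
#'   enforced by limiting similarity.
#' @param nPlots number of community samples (plots).
#' @param plotRichnessMean mean plot richness (Poisson, truncated at 1 and at
#'   the community size).
#' @param abundanceProb geometric parameter of the skewed count distribution.
#' @param nColonists number of seed-addition species.
#' @param seedsAdded seeds added per plot per colonist.
#' @return a list of class "fnSimulationConfig".
#' @export
simulationConfig <- function(seed = 1L, nRegional = 600L, nTraits = 2L,
                             envOptimum = rep(0.5, nTraits), envSd = 0.15,
                             bioticMode = rep("weak_phenotype_exclusion",
                                              nTraits),
                             wpeOptimum = 0.5, wpeSd = 0.08,
                             lsMinDistance = 0.05,
                             nPlots = 40L, plotRichnessMean = 15,
                             abundanceProb = 0.3,
                             nColonists = 25L, seedsAdded = 15L) {
  stopifnot(envSd > 0, wpeSd > 0, lsMinDistance > 0, lsMinDistance < 1,
            all(bioticMode %in% c("weak_phenotype_exclusion",
                                  "limiting_similarity", "neutral")),
            length(bioticMode) == nTraits,
            length(envOptimum) == nTraits)
  cfg <- list(seed = as.integer(seed), nRegional = as.integer(nRegional),
              nTraits = as.integer(nTraits), envOptimum = envOptimum,
              envSd = envSd, bioticMode = bioticMode,
              wpeOptimum = wpeOptimum, wpeSd = wpeSd,
              lsMinDistance = lsMinDistance, nPlots = as.integer(nPlots),
              plotRichnessMean = plotRichnessMean,
              abundanceProb = abundanceProb,
              nColonists = as.integer(nColonists),
              seedsAdded = as.integer(seedsAdded))
  class(cfg) <- "fnSimulationConfig"
  cfg
}

.speciesNames <- function(n, prefix = "sp") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' Simulate a regional trait cloud
#'
#' Trait values are i.i.d. uniform on \[0, 1\]; the table is already on the
#' standardized scale.
#'
#' @param config an [simulationConfig()] object.
#' @return a standardized [TraitTable-class] of `nRegional` species.
#' @export
simulateRegional <- function(config) {
  stopifnot(config$nRegional >= 50)
  set.seed(config$seed)
  tm <- matrix(stats::runif(config$nRegional * config$nTraits),
               config$nRegional, config$nTraits,
               dimnames = list(.speciesNames(config$nRegional),
                               paste0("trait", seq_len(config$nTraits))))
  kind <- stats::setNames(rep("continuous", config$nTraits), colnames(tm))
  lg <- stats::setNames(rep(FALSE, config$nTraits), colnames(tm))
  new("TraitTable", traits = tm, traitKind = kind, transformLog = lg,
      standardized = TRUE,
      ranges = matrix(rep(c(0, 1), config$nTraits), 2,
                      dimnames = list(c("min", "max"), colnames(tm))),
      referenceSpecies = rownames(tm))
}

# Gaussian admission kernel of the environmental filter.
.envKernel <- function(tm, optimum, sd) {
  d2 <- rowSums(sweep(tm, 2, optimum, "-")^2)
  exp(-d2 / (2 * sd^2))
}

#' Apply the environmental filter to a regional trait cloud
#'
#' Each species is admitted to the habitat-specific pool with probability
#' exp(-||t - optimum||^2 / (2 envSd^2)): species near the trait optimum are
#' near-certain members, distant species are excluded, so the pool is
#' clustered in functional space.
#'
#' @param traits a [TraitTable-class] (e.g. from [simulateRegional()]).
#' @param config an [simulationConfig()] object.
#' @return character vector of habitat-pool species ids.
#' @export
applyEnvFilter <- function(traits, config) {
  tm <- traitMatrix(traits)
  p <- .envKernel(tm, config$envOptimum, config$envSd)
  set.seed(config$seed + 1L)
  pool <- rownames(tm)[stats::runif(nrow(tm)) < p]
  if (length(pool) < 20)
    warning("habitat pool has fewer than 20 species")
  pool
}

#' Weak phenotype exclusion on one trait
#'
#' Retains pool species with probability
#' exp(-(t - wpeOptimum)^2 / (2 wpeSd^2)) on the affected trait, producing a
#' community clustered around the dominant phenotype.
#'
#' @param traits a [TraitTable-class].
#' @param pool character vector of candidate species.
#' @param trait affected trait name.
#' @param config an [simulationConfig()] object.
#' @param seedOffset offset added to the seed (so successive filter stages
#'   draw independently).
#' @return retained species ids.
#' @export
applyWeakPhenotypeExclusion <- function(traits, pool, trait, config,
                                        seedOffset = 2L) {
  x <- traitMatrix(traits)[pool, trait]
  p <- exp(-(x - config$wpeOptimum)^2 / (2 * config$wpeSd^2))
  set.seed(config$seed + seedOffset)
  keep <- pool[stats::runif(length(pool)) < p]
  if (!length(keep)) stop("weak phenotype exclusion removed every species")
  keep
}

#' Limiting similarity on one trait
#'
#' Iteratively finds the pair of species with the smallest distance on the
#' affected trait and removes one member uniformly at random, until every
#' nearest-neighbor gap is at least `lsMinDistance` (or only two species
#' remain, with a warning). The retained community is dispersed on that
#' trait.
#'
#' @inheritParams applyWeakPhenotypeExclusion
#' @return retained species ids.
#' @export
applyLimitingSimilarity <- function(traits, pool, trait, config,
                                    seedOffset = 3L) {
  x <- sort(traitMatrix(traits)[pool, trait])
  set.seed(config$seed + seedOffset)
  repeat {
    if (length(x) < 2) break
    gaps <- diff(x)
    if (min(gaps) >= config$lsMinDistance) break
    if (length(x) == 2) {
      warning("lsMinDistance unreachable; stopped at 2 species")
      break
    }
    i <- which.min(gaps)
    drop <- i + (stats::runif(1) < 0.5)
    x <- x[-drop]
  }
  names(x)
}

#' Sample plot communities with skewed abundances
#'
#' Per plot, draws a richness from a truncated Poisson, samples that many
#' community species without replacement (uniformly), and assigns each a
#' count from a geometric distribution shifted to support >= 1 (a log-series
#' like skewed abundance distribution).
#'
#' @param communitySpecies character vector of locally present species.
#' @param config an [simulationConfig()] object.
#' @param site site id for the output table.
#' @return community data.frame (plot_id, site_id, species_id, count).
#' @export
simulatePlots <- function(communitySpecies, config, site = "site1") {
  if (!length(communitySpecies)) stop("empty community")
  set.seed(config$seed + 4L)
  truncated <- FALSE
  rows <- lapply(seq_len(config$nPlots), function(i) {
    r <- stats::rpois(1, config$plotRichnessMean)
    r <- max(1L, r)
    if (r > length(communitySpecies)) {
      r <- length(communitySpecies)
      truncated <<- TRUE
    }
    sp <- sample(communitySpecies, r)
    data.frame(plot_id = sprintf("plot%03d", i), site_id = site,
               species_id = sp,
               count = stats::rgeom(r, config$abundanceProb) + 1L,
               stringsAsFactors = FALSE)
  })
  if (truncated)
    warning("plot richness truncated at the community size")
  do.call(rbind, rows)
}

# True per-trait biotic passage probability for a colonist trait vector,
# given the generative filters and the realized community.
.trueBioticP <- function(tvec, traits, communitySpecies, config) {
  p <- 1
  tm <- traitMatrix(traits)
  for (j in seq_len(config$nTraits)) {
    mode <- config$bioticMode[j]
    if (mode == "weak_phenotype_exclusion") {
      p <- p * exp(-(tvec[j] - config$wpeOptimum)^2 / (2 * config$wpeSd^2))
    } else if (mode == "limiting_similarity") {
      nn <- min(abs(tvec[j] - tm[communitySpecies, j]))
      p <- p * min(1, nn / config$lsMinDistance)
    }
  }
  p
}

#' Simulate a seed-addition experiment with known truth
#'
#' Colonist traits are drawn uniform on \[0, 1\] (or supplied). The true
#' establishment probability is the product of the generative environmental
#' kernel and the generative biotic passage probability (weak phenotype
#' exclusion: the Gaussian retention kernel; limiting similarity: the
#' nearest-neighbor gap to the community scaled by `lsMinDistance`, capped at
#' one; neutral traits contribute 1). Establishment in each plot is
#' Binomial(seedsAdded, true probability).
#'
#' @param traits the regional [TraitTable-class] (colonist rows are appended).
#' @param communitySpecies locally present species (for limiting-similarity
#'   truth).
#' @param community plot table from [simulatePlots()] (plot ids reused).
#' @param config an [simulationConfig()] object.
#' @param colonistTraits optional matrix of colonist trait values.
#' @return list with `traits` (table including colonists), `colonists`
#'   (data.frame species_id, site_id, plot_id, seeds_added, plants_year3,
#'   is_native), and `trueP` (named numeric).
#' @export
simulateSeedAddition <- function(traits, communitySpecies, community, config,
                                 colonistTraits = NULL) {
  set.seed(config$seed + 5L)
  if (is.null(colonistTraits)) {
    colonistTraits <- matrix(
      stats::runif(config$nColonists * config$nTraits),
      config$nColonists, config$nTraits,
      dimnames = list(.speciesNames(config$nColonists, "col"),
                      colnames(traitMatrix(traits))))
  }
  tm <- rbind(traitMatrix(traits), colonistTraits)
  allTraits <- new("TraitTable", traits = tm, traitKind = traitKind(traits),
                   transformLog = traits@transformLog, standardized = TRUE,
                   ranges = traits@ranges,
                   referenceSpecies = traits@referenceSpecies)
  pEnvTrue <- .envKernel(colonistTraits, config$envOptimum, config$envSd)
  trueP <- vapply(seq_len(nrow(colonistTraits)), function(i)
    pEnvTrue[i] * .trueBioticP(colonistTraits[i, ], traits,
                               communitySpecies, config), numeric(1))
  names(trueP) <- rownames(colonistTraits)
  plots <- unique(community$plot_id)
  site <- community$site_id[1]
  rows <- expand.grid(species_id = rownames(colonistTraits),
                      plot_id = plots, stringsAsFactors = FALSE)
  rows$site_id <- site
  rows$seeds_added <- config$seedsAdded
  rows$plants_year3 <- stats::rbinom(nrow(rows), config$seedsAdded,
                                     trueP[rows$species_id])
  rows$is_native <- TRUE
  list(traits = allTraits,
       colonists = rows[, c("species_id", "site_id", "plot_id",
                            "seeds_added", "plants_year3", "is_native")],
       trueP = trueP)
}

#' Simulate a complete assembly and seed-addition experiment
#'
#' Chains the generative stages: uniform regional trait cloud, Gaussian
#' environmental filter, per-trait biotic filters (weak phenotype exclusion
#' and/or limiting similarity), plot sampling, and a binomial seed-addition
#' experiment. Every stage draws from a seed derived deterministically from
#' `config$seed`, so the whole assembly is reproducible bit-for-bit.
#'
#' @param config an [simulationConfig()] object.
#' @return list of class "fnAssembly": `traits` (incl. colonists), `pool`
#'   ([PoolAssignment-class]), `community` (plot table), `colonists`,
#'   `trueP`, `poolSpecies`, `communitySpecies`.
#' @export
simulateAssembly <- function(config) {
  traits <- simulateRegional(config)
  poolSpecies <- applyEnvFilter(traits, config)
  comm <- poolSpecies
  off <- 2L
  for (j in seq_len(config$nTraits)) {
    tr <- colnames(traitMatrix(traits))[j]
    comm <- switch(config$bioticMode[j],
      weak_phenotype_exclusion =
        applyWeakPhenotypeExclusion(traits, comm, tr, config,
                                    seedOffset = off),
      limiting_similarity =
        applyLimitingSimilarity(traits, comm, tr, config, seedOffset = off),
      neutral = comm)
    off <- off + 1L
  }
  community <- simulatePlots(comm, config)
  sa <- simulateSeedAddition(traits, comm, community, config)
  level <- rep("environmentally_excluded", config$nRegional)
  names(level) <- speciesIds(traits)
  level[poolSpecies] <- "dark_diversity"
  level[unique(community$species_id)] <- "observed"
  pool <- new("PoolAssignment", species = speciesIds(traits),
              level = factor(level,
                             levels = c("environmentally_excluded",
                                        "dark_diversity", "observed")),
              inHabitatPool = speciesIds(traits) %in% poolSpecies,
              focalSite = community$site_id[1], minSites = 1L)
  out <- list(traits = sa$traits, pool = pool, community = community,
              colonists = sa$colonists, trueP = sa$trueP,
              poolSpecies = poolSpecies, communitySpecies = comm,
              config = config)
  class(out) <- "fnAssembly"
  out
}

#' @exportS3Method base::print
print.fnAssembly <- function(x, ...) {
  cat("Simulated assembly:\n")
  cat("  regional:", x$config$nRegional, "species,",
      x$config$nTraits, "traits\n")
  cat("  habitat pool:", length(x$poolSpecies),
      "| community:", length(x$communitySpecies), "\n")
  cat("  plots:", length(unique(x$community$plot_id)),
      "| colonists:", x$config$nColonists, "\n")
  invisible(x)
}

#' Write a simulated assembly as the standard CSV inputs
#'
#' Emits regional.csv, occurrences.csv, traits.csv, community.csv and
#' colonists.csv so that every downstream stage can be exercised from files.
#' The occurrence table encodes the habitat pool as species occurring in
#' `minSites` auxiliary habitat sites, with the focal community at the focal
#' site.
#'
#' @param assembly output of [simulateAssembly()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeAssemblyCsv <- function(assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(species_id = speciesIds(assembly$traits)),
                   file.path(dir, "regional.csv"), row.names = FALSE)
  focal <- assembly$pool@focalSite
  occ <- rbind(
    data.frame(site_id = focal,
               species_id = unique(assembly$community$species_id)),
    data.frame(site_id = "aux1", species_id = assembly$poolSpecies),
    data.frame(site_id = "aux2", species_id = assembly$poolSpecies))
  utils::write.csv(occ, file.path(dir, "occurrences.csv"), row.names = FALSE)
  tm <- traitMatrix(assembly$traits)
  utils::write.csv(cbind(data.frame(species_id = rownames(tm)),
                         as.data.frame(tm)),
                   file.path(dir, "traits.csv"), row.names = FALSE)
  utils::write.csv(assembly$community, file.path(dir, "community.csv"),
                   row.names = FALSE)
  utils::write.csv(assembly$colonists, file.path(dir, "colonists.csv"),
                   row.names = FALSE)
  invisible(dir)
}
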