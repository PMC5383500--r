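#' @include traitTable.R pools.R
NULL

.readCsv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read and validate the assembly input tables
#'
#' Reads the five CSV inputs (regional species list, occurrence table, trait
#' table, plot community table, colonist table), checks them against the
#' declared schemas, and returns typed tables plus a validation report
#' (duplicate rows, species unknown to the regional list, species with
#' incomplete traits). Duplicated rows are removed with a warning; unknown
#' species are retained in the report but excluded from modelling sets
#' downstream.
#'
#' @param paths named list or vector with elements `regional`, `occurrences`,
#'   `traits`, `community`, `colonists` (the last two optional).
#' @param traitKind,transformLog passed to [TraitTable()].
#' @return list with elements `regional` (character), `occurrences`
#'   (data.frame), `traits` ([TraitTable-class]), `community` (data.frame or
#'   NULL), `colonists` (data.frame or NULL), and `report` (list).
#' @export
readAssemblyTables <- function(paths, traitKind = character(0),
                               transformLog = character(0)) {
  paths <- as.list(paths)
  report <- list(duplicates = 0L, unknownSpecies = character(0),
                 incompleteTraits = character(0))

  regional <- unique(.readCsv(paths$regional, "species_id")$species_id)

  occ <- .readCsv(paths$occurrences, c("site_id", "species_id"))
  dup <- duplicated(occ[, c("site_id", "species_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (site, species) row(s) removed")
    report$duplicates <- report$duplicates + sum(dup)
    occ <- occ[!dup, , drop = FALSE]
  }

  trdf <- .readCsv(paths$traits, "species_id")
  if (anyDuplicated(trdf$species_id))
    stop("duplicate species_id in trait table")
  traits <- TraitTable(trdf, traitKind = traitKind,
                       transformLog = transformLog)
  report$incompleteTraits <- excludedSpecies(traits)

  community <- NULL
  if (!is.null(paths$community)) {
    community <- .readCsv(paths$community,
                          c("plot_id", "site_id", "species_id", "count"))
    dup <- duplicated(community[, c("plot_id", "species_id")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (plot, species) row(s) removed")
      report$duplicates <- report$duplicates + sum(dup)
      community <- community[!dup, , drop = FALSE]
    }
    if (any(community$count < 0)) stop("negative counts in community table")
  }

  colonists <- NULL
  if (!is.null(paths$colonists)) {
    colonists <- .readCsv(paths$colonists,
                          c("species_id", "site_id", "plot_id",
                            "seeds_added", "plants_year3"))
    if (any(colonists$seeds_added <= 0))
      stop("seeds_added must be positive")
  }

  known <- unique(c(regional,
                    if (!is.null(colonists)) colonists$species_id))
  occUnknown <- setdiff(occ$species_id, known)
  comUnknown <- if (is.null(community)) character(0) else
    setdiff(community$species_id, known)
  report$unknownSpecies <- unique(c(occUnknown, comUnknown))
  if (length(report$unknownSpecies))
    warning(length(report$unknownSpecies),
            " species not resolvable against the regional list")

  list(regional = regional, occurrences = occ, traits = traits,
       community = community, colonists = colonists, report = report)
}

#' Check a plot community table against a pool assignment
#'
#' Every locally observed species should be a member of the habitat-specific
#' pool; violations are reported, not dropped.
#'
#' @param community data.frame with `plot_id`, `species_id`, `count`.
#' @param pool a [PoolAssignment-class].
#' @return character vector of violating species ids (empty if none).
#' @export
checkCommunity <- function(community, pool) {
  bad <- setdiff(unique(community$species_id), habitatPool(pool))
  if (length(bad))
    warning(length(bad), " observed species outside the habitat pool: ",
            paste(utils::head(bad, 5), collapse = ", "))
  invisible(bad)
}

#' Relative abundances within each plot
#'
#' @param community data.frame with `plot_id`, `species_id`, `count`.
#' @return the table with an added `weight` column; weights sum to one within
#'   each plot.
#' @export
plotWeights <- function(community) {
  totals <- tapply(community$count, community$plot_id, sum)
  if (any(totals == 0)) stop("plot with zero total count")
  community$weight <- community$count /
    as.numeric(totals[as.character(community$plot_id)])
  community
}

#' Export a distance tensor in long format
#'
#' @param tensor a [DistanceTensor-class].
#' @param path CSV file to write (focal, reference, trait, distance).
#' @export
writeDistancesCsv <- function(tensor, path) {
  mats <- c(tensor@perTrait,
            if (length(tensor@multivariate))
              list(multivariate = tensor@multivariate))
  long <- do.call(rbind, lapply(names(mats), function(t) {
    m <- mats[[t]]
    data.frame(focal = rep(rownames(m), ncol(m)),
               reference = rep(colnames(m), each = nrow(m)),
               trait = t, distance = as.vector(m))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
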