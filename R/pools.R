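#' @include AllClasses.R AllGenerics.R
NULL

#' Build the habitat-specific species pool for one focal site
#'
#' Splits the regional species list into environmentally excluded species,
#' dark diversity, and the observed community. The habitat-specific pool
#' contains regional species occurring in at least `minSites` of the
#' habitat's surveyed sites (the occurrence-frequency rule guards against
#' misidentified or atypical records); species observed at the focal site are
#' always pool members. Occurrence records of species absent from the
#' regional list are flagged and dropped (they may have been unable to
#' disperse to the focal site).
#'
#' @param occurrences data.frame with columns `site_id`, `species_id`: species
#'   lists from the focal site and similar habitats.
#' @param regional character vector: the regional species list.
#' @param focalSite site id of the focal community (must appear in
#'   `occurrences`).
#' @param minSites minimum number of habitat sites a species must occur in to
#'   enter the pool (default 2, i.e. species found in only one site are
#'   excluded).
#' @return a [PoolAssignment-class].
#' @examples
#' occ <- data.frame(site_id = c("f", "f", "s1", "s1", "s2"),
#'                   species_id = c("a", "b", "b", "c", "c"))
#' buildHabitatPool(occ, regional = c("a", "b", "c", "d"), focalSite = "f")
#' @export
buildHabitatPool <- function(occurrences, regional, focalSite, minSites = 2L) {
  stopifnot(all(c("site_id", "species_id") %in% names(occurrences)))
  occurrences$site_id <- as.character(occurrences$site_id)
  occurrences$species_id <- as.character(occurrences$species_id)
  regional <- unique(as.character(regional))
  if (!focalSite %in% occurrences$site_id)
    stop("focal site '", focalSite, "' not present in the occurrence table")
  occurrences <- unique(occurrences[, c("site_id", "species_id")])
  unknown <- setdiff(occurrences$species_id, regional)
  if (length(unknown))
    warning(length(unknown), " occurring species not in the regional list; ",
            "excluded from the pool: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
  nSites <- table(occurrences$species_id)
  frequent <- names(nSites)[nSites >= minSites]
  observed <- intersect(
    occurrences$species_id[occurrences$site_id == focalSite], regional)
  pool <- union(intersect(frequent, regional), observed)
  if (!length(pool))
    stop("empty habitat-specific species pool")
  level <- rep("environmentally_excluded", length(regional))
  names(level) <- regional
  level[intersect(pool, regional)] <- "dark_diversity"
  level[observed] <- "observed"
  new("PoolAssignment",
      species = regional,
      level = factor(level, levels = c("environmentally_excluded",
                                       "dark_diversity", "observed")),
      inHabitatPool = regional %in% pool,
      focalSite = focalSite,
      minSites = as.integer(minSites))
}

#' @rdname accessors
#' @export
setMethod("speciesIds", "PoolAssignment", function(object, ...)
  object@species)

#' @rdname accessors
#' @export
setMethod("habitatPool", "PoolAssignment", function(object, ...)
  object@species[object@inHabitatPool])

#' @rdname accessors
#' @export
setMethod("darkDiversity", "PoolAssignment", function(object, ...)
  object@species[object@level == "dark_diversity"])

#' @rdname accessors
#' @export
setMethod("observedSpecies", "PoolAssignment", function(object, ...)
  object@species[object@level == "observed"])

#' @rdname accessors
#' @export
setMethod("poolLevels", "PoolAssignment", function(object, ...)
  stats::setNames(object@level, object@species))

setMethod("show", "PoolAssignment", function(object) {
  tab <- table(object@level)
  cat("PoolAssignment for focal site '", object@focalSite, "'\n", sep = "")
  cat("  regional list:           ", length(object@species), "species\n")
  cat("  habitat-specific pool:   ", sum(object@inHabitatPool),
      "(minSites =", object@minSites, ")\n")
  cat("  observed / dark / excluded:", tab[["observed"]], "/",
      tab[["dark_diversity"]], "/", tab[["environmentally_excluded"]], "\n")
})

#' Observed establishment proportions from a seed-addition experiment
#'
#' For each added species, the mean over its plots of
#' (plants in year three) / (seeds added).
#'
#' @param colonists data.frame with columns `species_id`, `plot_id`,
#'   `seeds_added`, `plants_year3`.
#' @return named numeric vector of establishment proportions.
#' @examples
#' actualEstablishment(data.frame(species_id = c("a", "a"),
#'   plot_id = c("p1", "p2"), seeds_added = c(15, 15),
#'   plants_year3 = c(3, 6)))  # a = 0.3
#' @export
actualEstablishment <- function(colonists) {
  stopifnot(all(c("species_id", "seeds_added", "plants_year3") %in%
                  names(colonists)))
  if (any(colonists$seeds_added <= 0))
    stop("seeds_added must be positive")
  if (any(colonists$plants_year3 > colonists$seeds_added))
    warning("plants_year3 exceeds seeds_added in some plots ",
            "(recruitment or clonal spread)")
  prop <- colonists$plants_year3 / colonists$seeds_added
  out <- tapply(prop, as.character(colonists$species_id), mean)
  stats::setNames(as.numeric(out), names(out))
}
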