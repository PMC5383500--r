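#' @import methods
NULL

#' Species-by-trait table with preprocessing metadata
#'
#' Central container for trait data. Rows are species, columns are traits.
#' Traits are either continuous (height, SLA, seed weight) or ordinal
#' (Ellenberg indicator values). Before modelling, traits are optionally
#' log-transformed and always range-standardized to \[0, 1\] over a reference
#' set of species (the regional modelling set: regional species with complete
#' traits); the same affine map is applied to any other species in the table
#' (e.g. added colonists), whose values may therefore fall outside \[0, 1\].
#'
#' @slot traits numeric matrix, species x traits; rownames are species ids;
#'   may contain NA (species with any missing modelled trait are excluded
#'   from modelling sets but kept in the table).
#' @slot traitKind named character, one of "continuous" or "ordinal" per trait.
#' @slot transformLog named logical; traits log-transformed during
#'   preprocessing.
#' @slot standardized logical flag; TRUE once range-standardized.
#' @slot ranges numeric matrix with rows "min","max" and one column per trait;
#'   the (post-log) extremes over the reference set used for standardization.
#' @slot referenceSpecies character; species defining the standardization
#'   range (empty until preprocessing).
#'
#' @seealso [TraitTable()], [preprocessTraits()]
#' @export
setClass("TraitTable",
  representation(
    traits = "matrix",
    traitKind = "character",
    transformLog = "logical",
    standardized = "logical",
    ranges = "matrix",
    referenceSpecies = "character"
  ),
  prototype(
    standardized = FALSE,
    ranges = matrix(numeric(0), nrow = 2, ncol = 0,
                    dimnames = list(c("min", "max"), NULL)),
    referenceSpecies = character(0)
  )
)

setValidity("TraitTable", function(object) {
  msg <- character(0)
  tr <- object@traits
  if (is.null(rownames(tr)) || anyDuplicated(rownames(tr)))
    msg <- c(msg, "species ids (rownames) must be present and unique")
  if (is.null(colnames(tr)))
    msg <- c(msg, "trait names (colnames) must be present")
  if (!setequal(names(object@traitKind), colnames(tr)))
    msg <- c(msg, "traitKind must be named by the trait columns")
  if (!all(object@traitKind %in% c("continuous", "ordinal")))
    msg <- c(msg, "traitKind values must be 'continuous' or 'ordinal'")
  if (!setequal(names(object@transformLog), colnames(tr)))
    msg <- c(msg, "transformLog must be named by the trait columns")
  if (length(msg)) msg else TRUE
})

#' Species-pool assignment for one focal community
#'
#' Partition of the regional species list into three membership levels:
#' \describe{
#'   \item{environmentally_excluded}{regional species outside the
#'     habitat-specific species pool;}
#'   \item{dark_diversity}{habitat-pool species absent from the focal
#'     community;}
#'   \item{observed}{species recorded at the focal site.}
#' }
#' Dark diversity and the observed community together form the
#' habitat-specific species pool.
#'
#' @slot species character, the regional species list.
#' @slot level factor with levels environmentally_excluded, dark_diversity,
#'   observed; one per species.
#' @slot inHabitatPool logical per species.
#' @slot focalSite the site the assignment refers to.
#' @slot minSites occurrence-frequency threshold used to build the pool.
#'
#' @seealso [buildHabitatPool()]
#' @export
setClass("PoolAssignment",
  representation(
    species = "character",
    level = "factor",
    inHabitatPool = "logical",
    focalSite = "character",
    minSites = "integer"
  )
)

setValidity("PoolAssignment", function(object) {
  msg <- character(0)
  n <- length(object@species)
  if (anyDuplicated(object@species))
    msg <- c(msg, "species ids must be unique")
  if (length(object@level) != n || length(object@inHabitatPool) != n)
    msg <- c(msg, "level and inHabitatPool must match species length")
  if (!identical(levels(object@level),
                 c("environmentally_excluded", "dark_diversity", "observed")))
    msg <- c(msg, "level must use the three canonical membership levels")
  pool <- object@level %in% c("dark_diversity", "observed")
  if (length(object@inHabitatPool) == n && !all(pool == object@inHabitatPool))
    msg <- c(msg, "habitat pool must equal dark_diversity + observed")
  if (length(msg)) msg else TRUE
})

#' Functional neighborhood specification
#'
#' A neighborhood is the set of k reference species most similar to a focal
#' species. k is resolved from a proportion p of the reference-set size n as
#' k = ceiling(p * n), or k = 1 for nearest-neighbor ("NN") neighborhoods.
#' p = 1 gives mean pairwise distance (all reference species).
#'
#' @slot label "NN" or a percentage label such as "30%".
#' @slot p proportion in \{0.1, ..., 1.0\}; NA for NN.
#' @slot k resolved neighbor count.
#' @slot n reference-set size used for resolution.
#'
#' @seealso [resolveNeighborhood()]
#' @export
setClass("NeighborhoodSpec",
  representation(label = "character", p = "numeric", k = "integer",
                 n = "integer")
)

setValidity("NeighborhoodSpec", function(object) {
  msg <- character(0)
  if (object@n < 1L) msg <- c(msg, "reference-set size n must be >= 1")
  if (object@k < 1L || object@k > object@n)
    msg <- c(msg, "k must satisfy 1 <= k <= n")
  if (identical(object@label, "NN") && object@k != 1L)
    msg <- c(msg, "NN neighborhoods have k = 1")
  if (length(msg)) msg else TRUE
})

#' Pairwise trait dissimilarities between two species sets
#'
#' Holds one distance matrix per trait (absolute differences of
#' range-standardized values, i.e. single-trait Gower terms) plus the
#' multivariate Gower matrix (mean over traits). All entries lie in \[0, 1\]
#' for species within the standardization reference set.
#'
#' @slot focal,reference character vectors of species ids (rows / columns).
#' @slot perTrait named list of numeric matrices, one per trait.
#' @slot multivariate numeric matrix (mean of per-trait matrices).
#'
#' @seealso [traitDistances()]
#' @export
setClass("DistanceTensor",
  representation(
    focal = "character",
    reference = "character",
    perTrait = "list",
    multivariate = "matrix"
  )
)

setValidity("DistanceTensor", function(object) {
  msg <- character(0)
  for (m in object@perTrait) {
    if (!identical(rownames(m), object@focal) ||
        !identical(colnames(m), object@reference))
      msg <- c(msg, "per-trait matrices must be labelled focal x reference")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted environmental- or biotic-filter model
#'
#' One binomial regression of filter passage on per-trait functional
#' neighborhood distances, at one neighborhood size and one interaction
#' scheme. Environmental models are plain logistic regressions over the
#' regional species list (pool membership as response); biotic models are
#' binomial mixed models over habitat-pool species x plots (local presence
#' as response, plot as random intercept). Predictors are z-scored before
#' fitting (interaction columns are formed from z-scored main effects and
#' then z-scored themselves); the constants are stored so that predictions
#' can be made from raw distances.
#'
#' @slot filter "environmental" or "biotic".
#' @slot neighborhood the [NeighborhoodSpec-class] used.
#' @slot scheme interaction scheme: "none", "all_pairwise" or "parsimonious".
#' @slot mains,interactions character vectors of model terms (trait names,
#'   "a:b" pairs).
#' @slot coefTable matrix with columns estimate, se, z, p; rows are
#'   "(Intercept)" then the terms.
#' @slot constants list of standardization constants (main/interaction
#'   centers and scales, constant-column flags).
#' @slot logLik,n,nParams,aicc fit summaries.
#' @slot reVariance random-intercept variance (NA for environmental models).
#' @slot plotIntercepts named numeric of estimated plot intercepts (biotic).
#' @slot converged,degenerate logical flags.
#' @slot degeneracyReasons character; e.g. "separation", "zero RE variance",
#'   "runaway estimate", "insufficient distance variation".
#'
#' @export
setClass("FilterModel",
  representation(
    filter = "character",
    neighborhood = "NeighborhoodSpec",
    scheme = "character",
    mains = "character",
    interactions = "character",
    coefTable = "matrix",
    constants = "list",
    logLik = "numeric",
    n = "integer",
    nParams = "integer",
    aicc = "numeric",
    reVariance = "numeric",
    plotIntercepts = "numeric",
    converged = "logical",
    degenerate = "logical",
    degeneracyReasons = "character"
  ),
  prototype(reVariance = NA_real_, plotIntercepts = numeric(0),
            degenerate = FALSE, degeneracyReasons = character(0))
)

setValidity("FilterModel", function(object) {
  msg <- character(0)
  if (!object@filter %in% c("environmental", "biotic"))
    msg <- c(msg, "filter must be 'environmental' or 'biotic'")
  if (!object@scheme %in% c("none", "all_pairwise", "parsimonious"))
    msg <- c(msg, "unknown interaction scheme")
  if (isTRUE(object@converged) && !is.finite(object@aicc))
    msg <- c(msg, "a converged model must have finite AICc")
  if (length(msg)) msg else TRUE
})

#' Neighborhood-size x interaction-scheme scan
#'
#' Fits of one filter model per (neighborhood size, interaction scheme)
#' combination, with AICc ranking, degeneracy diagnostics and the selected
#' model (minimum AICc among converged, non-degenerate candidates).
#'
#' @slot filter "environmental" or "biotic".
#' @slot table data.frame with columns size, scheme, aicc, delta_aicc,
#'   converged, degenerate, reasons.
#' @slot models named list of [FilterModel-class] objects keyed "size|scheme".
#' @slot selected key of the selected model.
#'
#' @seealso [scanNeighborhoods()]
#' @export
setClass("NeighborhoodScan",
  representation(
    filter = "character",
    table = "data.frame",
    models = "list",
    selected = "character"
  )
)
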