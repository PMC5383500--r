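#' @include AllClasses.R AllGenerics.R traitTable.R pools.R
NULL

#' Gower dissimilarity between two complete trait rows
#'
#' On \[0, 1\] range-standardized numeric traits the Gower dissimilarity is
#' the mean over traits of the per-trait absolute differences.
#'
#' @param a,b numeric vectors of standardized trait values (same traits).
#' @return a dissimilarity in \[0, 1\] for in-range inputs.
#' @examples
#' gowerDistance(c(0.2, 0.5, 0.9), c(0.2, 0.7, 0.5))  # 0.2
#' @export
gowerDistance <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no shared complete traits")
  mean(abs(a[keep] - b[keep]))
}

#' Pairwise trait dissimilarities between two species sets
#'
#' Computes one |a - b| matrix per trait and their mean (the multivariate
#' Gower matrix). Alternatively a precomputed square dissimilarity matrix
#' (e.g. a cophenetic phylogenetic distance matrix scaled to \[0, 1\]) can be
#' supplied and is treated as a single "trait".
#'
#' @param traits a standardized [TraitTable-class].
#' @param focal,reference species id vectors; default all modelling species.
#' @param precomputed optional named list of square dissimilarity matrices
#'   with species ids as dimnames, used instead of trait columns.
#' @return a [DistanceTensor-class].
#' @export
traitDistances <- function(traits, focal = NULL, reference = NULL,
                           precomputed = NULL) {
  if (!is.null(precomputed)) {
    ids <- rownames(precomputed[[1]])
    if (is.null(focal)) focal <- ids
    if (is.null(reference)) reference <- ids
    per <- lapply(precomputed, function(m) {
      stopifnot(all(focal %in% rownames(m)), all(reference %in% colnames(m)))
      m[focal, reference, drop = FALSE]
    })
  } else {
    stopifnot(is(traits, "TraitTable"))
    if (!isStandardized(traits))
      warning("trait table is not standardized; distances may exceed [0,1]")
    tm <- traitMatrix(traits)
    if (is.null(focal)) focal <- modelingSpecies(traits)
    if (is.null(reference)) reference <- modelingSpecies(traits)
    per <- lapply(stats::setNames(colnames(tm), colnames(tm)), function(t) {
      m <- abs(outer(tm[focal, t], tm[reference, t], "-"))
      dimnames(m) <- list(focal, reference)
      m
    })
  }
  per <- lapply(per, function(m) {
    dimnames(m) <- list(focal, reference)
    m
  })
  multi <- Reduce(`+`, per) / length(per)
  new("DistanceTensor", focal = focal, reference = reference,
      perTrait = per, multivariate = multi)
}

#' Resolve a neighborhood size to a neighbor count
#'
#' The neighborhood-size grid runs from nearest neighbor ("NN", k = 1) to
#' mean pairwise distance (p = 1, k = n) in 10\% increments. Proportions are
#' multiplied by the reference-set size and always rounded up.
#'
#' @param p "NN" or a proportion in \{0.1, 0.2, ..., 1.0\}.
#' @param n reference-set size (e.g. the habitat-specific pool size).
#' @return a [NeighborhoodSpec-class].
#' @examples
#' neighborhoodK(resolveNeighborhood(0.3, 87))   # 27
#' neighborhoodK(resolveNeighborhood("NN", 87))  # 1
#' @export
resolveNeighborhood <- function(p, n) {
  n <- as.integer(n)
  if (n < 1L) stop("reference-set size must be >= 1")
  if (identical(p, "NN") || (is.character(p) && toupper(p) == "NN"))
    return(new("NeighborhoodSpec", label = "NN", p = NA_real_, k = 1L, n = n))
  p <- as.numeric(p)
  tenths <- round(p * 10)
  if (!isTRUE(all.equal(p * 10, tenths)) || tenths < 1 || tenths > 10)
    stop("neighborhood proportion must be 'NN' or one of 0.1, 0.2, ..., 1.0")
  p <- tenths / 10
  k <- as.integer(ceiling(p * n - 1e-9))
  k <- max(1L, min(k, n))
  new("NeighborhoodSpec", label = sprintf("%d%%", as.integer(tenths * 10)),
      p = p, k = k, n = n)
}

#' @rdname accessors
#' @export
setMethod("neighborhoodK", "NeighborhoodSpec", function(object, ...) object@k)

setMethod("show", "NeighborhoodSpec", function(object) {
  cat("NeighborhoodSpec:", object@label, "-> k =", object@k,
      "of n =", object@n, "\n")
})

#' Functional neighborhood distance
#'
#' Mean of the k smallest dissimilarities from a focal species to a reference
#' set. k = 1 gives the nearest-neighbor distance, k = n the mean pairwise
#' distance. Ties are broken by species id, which leaves the mean unchanged
#' but makes neighborhood membership deterministic.
#'
#' @param d numeric vector of dissimilarities to the reference species
#'   (named by species id; the focal species must already be excluded).
#' @param k neighborhood size, 1 <= k <= length(d).
#' @return the neighborhood distance (scalar).
#' @examples
#' neighborhoodDistance(c(a = 0.05, b = 0.10, c = 0.30, d = 0.55), 2) # 0.075
#' @export
neighborhoodDistance <- function(d, k) {
  d <- d[!is.na(d)]
  if (!length(d)) stop("empty reference set")
  if (k < 1 || k > length(d))
    stop("k must be between 1 and the reference-set size")
  ids <- if (is.null(names(d))) as.character(seq_along(d)) else names(d)
  ord <- order(d, ids)
  mean(d[ord[seq_len(k)]])
}

# Row-wise sorted cumulative sums of a focal x reference distance matrix.
# selfCols: for each focal row, the reference column to exclude (NA if none).
# Returns cumsum matrix (rows padded with NA past nref) and nref per row.
.neighborCumsum <- function(D, selfCols = rep(NA_integer_, nrow(D))) {
  n <- ncol(D)
  idx <- cbind(seq_len(nrow(D)), selfCols)
  idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
  if (nrow(idx)) D[idx] <- Inf
  S <- matrix(NA_real_, nrow(D), n)
  for (i in seq_len(nrow(D))) S[i, ] <- sort.int(D[i, ], method = "radix")
  S[!is.finite(S)] <- NA_real_
  CS <- t(apply(S, 1, function(r) cumsum(ifelse(is.na(r), 0, r))))
  CS[is.na(S)] <- NA_real_
  nref <- rowSums(!is.na(S))
  list(cumsum = CS, nref = nref)
}

# Evaluate neighborhood distances from a cumsum cache for pool-resolved k.
.neighborValue <- function(cache, k) {
  keff <- pmin(k, cache$nref)
  cache$cumsum[cbind(seq_along(keff), keff)] / keff
}

# Build the environmental design cache: per predictor, sorted-distance
# cumulative sums from every focal species to the habitat pool (self-excluded
# for pool members). Shared by envPredictorMatrix and scans.
.envCache <- function(pool, traits, species = NULL,
                      basis = c("per-trait", "multivariate"),
                      precomputed = NULL) {
  basis <- match.arg(basis)
  model <- modelingSpecies(traits)
  if (!is.null(precomputed)) model <- rownames(precomputed[[1]])
  regional <- intersect(speciesIds(pool), model)
  poolSp <- intersect(habitatPool(pool), model)
  if (!length(poolSp)) stop("habitat pool empty after trait filtering")
  focal <- if (is.null(species)) regional else intersect(species, model)
  dropped <- if (is.null(species)) character(0) else setdiff(species, model)
  tens <- traitDistances(traits, focal = focal, reference = poolSp,
                         precomputed = precomputed)
  mats <- if (basis == "multivariate") list(multivariate = tens@multivariate)
          else tens@perTrait
  selfCols <- match(focal, poolSp)
  caches <- lapply(mats, .neighborCumsum, selfCols = selfCols)
  list(focal = focal, dropped = dropped, poolSize = length(poolSp),
       response = as.integer(focal %in% poolSp), caches = caches)
}

#' Environmental-filter design matrix
#'
#' For every regional species (or any supplied species, e.g. colonists at
#' prediction time), the per-trait functional neighborhood distance to the
#' habitat-specific species pool, with pool members excluded from their own
#' neighborhoods. The response is 1 for pool members, 0 for environmentally
#' excluded species. Neighborhood size is resolved against the pool size; for
#' pool members the effective k is capped at the self-excluded reference size.
#'
#' @param pool a [PoolAssignment-class].
#' @param traits a standardized [TraitTable-class].
#' @param size "NN" or a proportion in \{0.1, ..., 1.0\}.
#' @param species optional species ids to build rows for (default: regional
#'   modelling set); species with incomplete traits are dropped with a
#'   message.
#' @param basis "per-trait" (each trait its own neighborhood distance) or
#'   "multivariate" (a single Gower neighborhood distance).
#' @param precomputed optional list of square dissimilarity matrices (see
#'   [traitDistances()]).
#' @return data.frame with columns `species`, `response`, and one predictor
#'   column per trait (or `multivariate`). The resolved
#'   [NeighborhoodSpec-class] is attached as attribute "neighborhood".
#' @export
envPredictorMatrix <- function(pool, traits, size, species = NULL,
                               basis = c("per-trait", "multivariate"),
                               precomputed = NULL) {
  cache <- .envCache(pool, traits, species = species, basis = basis,
                     precomputed = precomputed)
  if (length(cache$dropped))
    message(length(cache$dropped),
            " species dropped for incomplete traits: ",
            paste(utils::head(cache$dropped, 5), collapse = ", "))
  spec <- resolveNeighborhood(size, cache$poolSize)
  out <- data.frame(species = cache$focal,
                    response = if (is.null(species)) cache$response
                               else rep(NA_integer_, length(cache$focal)),
                    stringsAsFactors = FALSE)
  for (t in names(cache$caches))
    out[[t]] <- .neighborValue(cache$caches[[t]], spec@k)
  attr(out, "neighborhood") <- spec
  out
}

#' Centering constants for abundance-weighted biotic distances
#'
#' The grand mean, per trait, of the dissimilarities between all
#' habitat-pool species and all species observed anywhere at the site
#' (self-pairs excluded). Centering gives weighted distances opposite signs
#' for species more versus less similar than typical, so that abundant
#' similar and abundant dissimilar residents pull predictions in opposite
#' directions.
#'
#' @param pool a [PoolAssignment-class].
#' @param traits a standardized [TraitTable-class].
#' @param community data.frame with `plot_id`, `species_id`, `count`.
#' @param basis "per-trait" or "multivariate".
#' @param precomputed optional list of square dissimilarity matrices.
#' @return named numeric vector of per-trait centers.
#' @export
computeCenter <- function(pool, traits, community,
                          basis = c("per-trait", "multivariate"),
                          precomputed = NULL) {
  basis <- match.arg(basis)
  model <- if (!is.null(precomputed)) rownames(precomputed[[1]])
           else modelingSpecies(traits)
  poolSp <- intersect(habitatPool(pool), model)
  obs <- intersect(unique(as.character(community$species_id)), model)
  if (!length(poolSp) || !length(obs))
    stop("need habitat-pool and observed species with complete traits")
  tens <- traitDistances(traits, focal = poolSp, reference = obs,
                         precomputed = precomputed)
  mats <- if (basis == "multivariate") list(multivariate = tens@multivariate)
          else tens@perTrait
  vapply(mats, function(m) {
    self <- cbind(match(intersect(poolSp, obs), poolSp),
                  match(intersect(poolSp, obs), obs))
    if (nrow(self)) m[self] <- NA
    mean(m, na.rm = TRUE)
  }, numeric(1))
}

#' Centered, abundance-weighted neighborhood distance within one plot
#'
#' For a target species and one plot community, each observed species j
#' contributes v_j = w_j (d_j - center), where w_j is j's relative abundance
#' in the plot (self-excluded weights renormalized to sum to one) and d_j the
#' trait dissimilarity between the target and j. Neighborhood membership is
#' determined on the weighted centered values: the k smallest v_j are summed
#' and divided by the sum of their weights, so that with k equal to the plot
#' richness the value reduces to the fully abundance-weighted centered mean
#' distance. Ties in v_j are broken by species id.
#'
#' @param d named numeric vector: dissimilarities from the target to the
#'   plot's observed species.
#' @param counts named numeric vector of the observed species' counts (same
#'   names as `d`).
#' @param center the trait's centering constant (see [computeCenter()]).
#' @param k neighborhood size; capped at the number of available reference
#'   species.
#' @param target optional target species id, removed from the reference if
#'   observed in the plot.
#' @return the signed neighborhood value (scalar in \[-1, 1\] for
#'   standardized traits).
#' @examples
#' centeredWeightedDistance(c(a = 0.2, b = 0.6), c(a = 3, b = 1),
#'                          center = 0.3, k = 2)  # 0
#' @export
centeredWeightedDistance <- function(d, counts, center, k, target = NULL) {
  stopifnot(length(d) == length(counts))
  if (!is.null(target) && target %in% names(d)) {
    keep <- names(d) != target
    d <- d[keep]; counts <- counts[keep]
  }
  if (!length(d)) stop("no reference species in plot")
  tot <- sum(counts)
  if (tot <= 0) stop("plot with zero total count")
  w <- counts / tot
  v <- w * (d - center)
  ord <- order(v, names(v))
  keff <- min(k, length(v))
  sel <- ord[seq_len(keff)]
  sum(v[sel]) / sum(w[sel])
}

# Biotic design cache for one site: for every (pool species, plot, trait),
# the cumulative sums of weighted centered distances (sorted ascending) and
# of the corresponding weights, so that any neighborhood size can be
# evaluated without re-sorting. The within-plot weight renormalization after
# self-exclusion cancels in the ratio cumV/cumW, so only column exclusion
# matters.
.bioticCache <- function(pool, traits, community, center,
                         basis = c("per-trait", "multivariate"),
                         precomputed = NULL, targets = NULL) {
  basis <- match.arg(basis)
  model <- if (!is.null(precomputed)) rownames(precomputed[[1]])
           else modelingSpecies(traits)
  poolSp <- intersect(if (is.null(targets)) habitatPool(pool) else targets,
                      model)
  if (!length(poolSp)) stop("no target species with complete traits")
  community <- community[as.character(community$species_id) %in% model, ,
                         drop = FALSE]
  community <- plotWeights(community)
  plots <- split(community, as.character(community$plot_id))
  obsAll <- unique(as.character(community$species_id))
  tens <- traitDistances(traits, focal = poolSp, reference = obsAll,
                         precomputed = precomputed)
  mats <- if (basis == "multivariate") list(multivariate = tens@multivariate)
          else tens@perTrait
  traitsUsed <- names(mats)
  out <- lapply(plots, function(pl) {
    obs <- as.character(pl$species_id)
    w <- pl$weight
    perTrait <- lapply(traitsUsed, function(t) {
      V <- sweep(mats[[t]][, obs, drop = FALSE] - center[[t]], 2, w, "*")
      nobs <- length(obs)
      cumV <- matrix(NA_real_, length(poolSp), nobs)
      cumW <- matrix(NA_real_, length(poolSp), nobs)
      selfCol <- match(poolSp, obs)
      for (i in seq_along(poolSp)) {
        cand <- seq_len(nobs)
        if (!is.na(selfCol[i])) cand <- cand[-selfCol[i]]
        if (!length(cand)) next
        ord <- cand[order(V[i, cand], obs[cand])]
        cumV[i, seq_along(ord)] <- cumsum(V[i, ord])
        cumW[i, seq_along(ord)] <- cumsum(w[ord])
      }
      list(cumV = cumV, cumW = cumW)
    })
    names(perTrait) <- traitsUsed
    nref <- length(obs) - !is.na(match(poolSp, obs))
    list(perTrait = perTrait, nref = nref,
         observed = poolSp %in% obs)
  })
  list(poolSp = poolSp, plots = out, traits = traitsUsed)
}

# Assemble the biotic design data.frame for one neighborhood size from a
# cache. Rows: pool species x plots (rows with no available reference are
# dropped). k is resolved per plot against the available reference size.
.bioticDesign <- function(cache, size) {
  rows <- lapply(names(cache$plots), function(pid) {
    pl <- cache$plots[[pid]]
    ok <- pl$nref >= 1L
    keff <- if (identical(size, "NN")) rep(1L, length(pl$nref)) else {
      p <- resolveNeighborhood(size, max(pl$nref, 1L))@p
      pmax(1L, pmin(as.integer(ceiling(p * pl$nref - 1e-9)), pl$nref))
    }
    df <- data.frame(species = cache$poolSp[ok], plot = pid,
                     response = as.integer(pl$observed[ok]),
                     stringsAsFactors = FALSE)
    idx <- cbind(which(ok), keff[ok])
    for (t in cache$traits)
      df[[t]] <- pl$perTrait[[t]]$cumV[idx] / pl$perTrait[[t]]$cumW[idx]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biotic-filter design matrix
#'
#' For every habitat-pool species and every plot, the per-trait centered,
#' abundance-weighted neighborhood distance to the plot's observed community
#' ([centeredWeightedDistance()]), with the response 1 if the species is
#' observed in that plot and 0 if it belongs to dark diversity there. Only
#' habitat-pool species enter as data points. Neighborhood proportions are
#' resolved per plot against the available (self-excluded) observed richness.
#'
#' @inheritParams computeCenter
#' @param size "NN" or a proportion in \{0.1, ..., 1.0\}.
#' @param center per-trait centering constants; computed via
#'   [computeCenter()] when NULL.
#' @param species optional target species ids (default: the habitat pool).
#'   Used at prediction time to build colonist rows; a colonist is treated as
#'   absent from every plot.
#' @return data.frame with columns `species`, `plot`, `response`, and one
#'   predictor column per trait; the centers used are attached as attribute
#'   "center" and the representative neighborhood spec as "neighborhood".
#' @export
bioticPredictorMatrix <- function(pool, traits, community, size,
                                  center = NULL,
                                  basis = c("per-trait", "multivariate"),
                                  precomputed = NULL, species = NULL) {
  basis <- match.arg(basis)
  if (is.null(center))
    center <- computeCenter(pool, traits, community, basis = basis,
                            precomputed = precomputed)
  cache <- .bioticCache(pool, traits, community, center, basis = basis,
                        precomputed = precomputed, targets = species)
  out <- .bioticDesign(cache, size)
  attr(out, "center") <- center
  attr(out, "neighborhood") <- resolveNeighborhood(
    size, max(vapply(cache$plots, function(p) max(p$nref), integer(1))))
  out
}
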