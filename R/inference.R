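#' @include models.R
NULL

.sizeFromLabel <- function(label) {
  if (identical(label, "NN")) "NN" else as.numeric(sub("%", "", label)) / 100
}

# Hard degeneracy flags that disqualify a model from selection. A zero
# random-intercept variance is a soft flag: the fallback logistic fit is
# still usable.
.hardFlags <- c("separation", "runaway estimate",
                "insufficient distance variation",
                "constant predictor column")

#' Scan neighborhood sizes and interaction schemes for one filter
#'
#' Fits one filter model per (neighborhood size, interaction scheme)
#' combination, ranks them by AICc, applies the degeneracy diagnostics
#' ([diagnoseModel()]), and selects the minimum-AICc model among converged,
#' non-degenerate candidates. AICc alone is not trusted: nearest-neighbor
#' fits with runaway estimates are excluded even when their AICc is lowest.
#'
#' @param pool a [PoolAssignment-class].
#' @param traits a standardized [TraitTable-class].
#' @param filter "environmental" or "biotic".
#' @param community plot community data.frame (required for biotic scans).
#' @param sizes list/vector of neighborhood sizes ("NN" and/or proportions).
#' @param schemes interaction schemes to fit.
#' @param basis "per-trait" or "multivariate".
#' @param excludeOrdinalPairs drop ordinal x ordinal interactions (default:
#'   TRUE for environmental scans, FALSE for biotic).
#' @param precomputed optional list of square dissimilarity matrices.
#' @return a [NeighborhoodScan-class].
#' @export
scanNeighborhoods <- function(pool, traits,
                              filter = c("environmental", "biotic"),
                              community = NULL,
                              sizes = c(list("NN"),
                                        as.list(seq(0.1, 1, by = 0.1))),
                              schemes = c("none", "all_pairwise",
                                          "parsimonious"),
                              basis = c("per-trait", "multivariate"),
                              excludeOrdinalPairs =
                                filter[1] == "environmental",
                              precomputed = NULL) {
  filter <- match.arg(filter)
  basis <- match.arg(basis)
  schemes <- match.arg(schemes, several.ok = TRUE)
  kind <- traitKind(traits)
  if (filter == "biotic") {
    if (is.null(community)) stop("biotic scans require a community table")
    center <- computeCenter(pool, traits, community, basis = basis,
                            precomputed = precomputed)
    cache <- .bioticCache(pool, traits, community, center, basis = basis,
                          precomputed = precomputed)
  } else {
    cache <- .envCache(pool, traits, basis = basis, precomputed = precomputed)
  }
  models <- list()
  rows <- list()
  for (size in sizes) {
    if (filter == "environmental") {
      spec <- resolveNeighborhood(size, cache$poolSize)
      design <- data.frame(species = cache$focal, response = cache$response,
                           stringsAsFactors = FALSE)
      for (t in names(cache$caches))
        design[[t]] <- .neighborValue(cache$caches[[t]], spec@k)
    } else {
      design <- .bioticDesign(cache, size)
      spec <- resolveNeighborhood(size,
                                  max(vapply(cache$plots, function(p)
                                    max(p$nref), integer(1))))
    }
    attr(design, "neighborhood") <- spec
    mains <- setdiff(names(design), c("species", "response", "plot"))
    fitOne <- function(inters, schemeLabel)
      .fitFilter(design, filter, spec, schemeLabel, mains, inters)
    full <- NULL
    for (scheme in schemes) {
      if (scheme %in% c("all_pairwise", "parsimonious") && is.null(full))
        full <- fitOne(.interactionTerms(mains, "all_pairwise", kind,
                                         excludeOrdinalPairs),
                       "all_pairwise")
      m <- switch(scheme,
        none = fitOne(character(0), "none"),
        all_pairwise = full,
        parsimonious = backwardEliminate(full, design))
      flags <- diagnoseModel(m, design)
      m@degenerate <- length(flags) > 0
      m@degeneracyReasons <- flags
      key <- paste(spec@label, scheme, sep = "|")
      models[[key]] <- m
      rows[[key]] <- data.frame(size = spec@label, scheme = scheme,
                                aicc = m@aicc,
                                converged = m@converged,
                                degenerate = m@degenerate,
                                reasons = paste(flags, collapse = "; "),
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  finite <- is.finite(tab$aicc)
  tab$delta_aicc <- tab$aicc - if (any(finite)) min(tab$aicc[finite]) else 0
  tab <- tab[, c("size", "scheme", "aicc", "delta_aicc", "converged",
                 "degenerate", "reasons")]
  ok <- vapply(models, function(m)
    isConverged(m) && !any(m@degeneracyReasons %in% .hardFlags), logical(1))
  if (!any(ok)) {
    print(tab)
    stop("all candidate models are degenerate or failed to converge")
  }
  ai <- vapply(models, aicc, numeric(1))
  ai[!ok] <- Inf
  selected <- names(models)[which.min(ai)]
  new("NeighborhoodScan", filter = filter, table = tab, models = models,
      selected = selected)
}

#' @rdname accessors
#' @export
setMethod("scanTable", "NeighborhoodScan", function(object, ...)
  object@table)

#' @rdname accessors
#' @export
setMethod("selectedModel", "NeighborhoodScan", function(object, ...)
  object@models[[object@selected]])

#' @rdname accessors
#' @export
setMethod("scanModels", "NeighborhoodScan", function(object, ...)
  object@models)

setMethod("show", "NeighborhoodScan", function(object) {
  cat("NeighborhoodScan (", object@filter, " filter): ",
      nrow(object@table), " fits\n", sep = "")
  cat("  selected:", object@selected, "\n")
  print(utils::head(object@table[order(object@table$aicc), ], 5))
})

#' Combine filter-passage probabilities
#'
#' The overall establishment probability is the product of the probability of
#' passing the environmental filters and the (plot-averaged) probability of
#' passing the biotic filters.
#'
#' @param pEnv,pBiotic probabilities in \[0, 1\].
#' @return elementwise product.
#' @examples
#' combineProbabilities(0.8, 0.5)  # 0.4
#' @export
combineProbabilities <- function(pEnv, pBiotic) {
  stopifnot(all(pEnv >= 0 & pEnv <= 1, na.rm = TRUE),
            all(pBiotic >= 0 & pBiotic <= 1, na.rm = TRUE))
  pEnv * pBiotic
}

#' Predict establishment for potential colonists
#'
#' Runs both fitted filter models for a set of colonist species: the
#' environmental probability from neighborhood distances to the habitat pool,
#' the biotic probability as the average across plots of plot-level
#' predictions ([predictBiotic()]), and their product.
#'
#' @param envModel,bioticModel fitted [FilterModel-class] objects (their own
#'   neighborhood sizes are used to build the colonist predictors).
#' @param pool a [PoolAssignment-class].
#' @param traits a standardized [TraitTable-class] containing the colonists.
#' @param community plot community data.frame.
#' @param species colonist species ids.
#' @param center biotic centering constants; recomputed when NULL.
#' @param basis "per-trait" or "multivariate".
#' @param rePrediction "plot" or "population" (see [predictBiotic()]).
#' @return data.frame with columns species, p_env, p_biotic, p_overall.
#'   Species with incomplete traits are skipped with a message.
#' @export
predictEstablishment <- function(envModel, bioticModel, pool, traits,
                                 community, species, center = NULL,
                                 basis = c("per-trait", "multivariate"),
                                 rePrediction = c("plot", "population")) {
  basis <- match.arg(basis)
  rePrediction <- match.arg(rePrediction)
  keep <- intersect(species, modelingSpecies(traits))
  if (length(skip <- setdiff(species, keep)))
    message("skipping colonists with incomplete traits: ",
            paste(skip, collapse = ", "))
  envDesign <- envPredictorMatrix(
    pool, traits, .sizeFromLabel(envModel@neighborhood@label),
    species = keep, basis = basis)
  pEnv <- predictEnv(envModel, envDesign)
  bioDesign <- bioticPredictorMatrix(
    pool, traits, community, .sizeFromLabel(bioticModel@neighborhood@label),
    center = center, basis = basis, species = keep)
  pBio <- predictBiotic(bioticModel, bioDesign,
                        rePrediction = rePrediction)$average
  data.frame(species = keep,
             p_env = as.numeric(pEnv[keep]),
             p_biotic = as.numeric(pBio[keep]),
             p_overall = combineProbabilities(as.numeric(pEnv[keep]),
                                              as.numeric(pBio[keep])),
             stringsAsFactors = FALSE)
}

#' Validate predicted establishment against observed establishment
#'
#' Ordinary least squares of the observed establishment proportion on the
#' predicted overall probability, with site included as a factor when more
#' than one site is present (dropped with a note otherwise). A binomial GLM
#' alternative is available but plain OLS on proportions is the default.
#'
#' @param predicted named numeric of predicted establishment per species.
#' @param actual named numeric of observed establishment proportions.
#' @param sites optional named character of site ids per species.
#' @param method "ols" (default) or "binomial".
#' @return list of class "fnValidation": slope, t, p for predicted
#'   establishment; site coefficient table; r2; adjR2; n; note.
#' @export
validateEstablishment <- function(predicted, actual, sites = NULL,
                                  method = c("ols", "binomial")) {
  method <- match.arg(method)
  sp <- intersect(names(predicted), names(actual))
  if (length(sp) < 3) stop("need at least 3 species with both values")
  df <- data.frame(actual = as.numeric(actual[sp]),
                   predicted = as.numeric(predicted[sp]))
  note <- character(0)
  useSite <- FALSE
  if (!is.null(sites)) {
    df$site <- factor(as.character(sites[sp]))
    useSite <- nlevels(df$site) > 1
    if (!useSite) note <- c(note, "single site: site factor dropped")
  }
  form <- if (useSite) actual ~ predicted + site else actual ~ predicted
  if (method == "ols") {
    fit <- stats::lm(form, data = df)
    sm <- summary(fit)
    co <- sm$coefficients
    out <- list(slope = co["predicted", "Estimate"],
                t = co["predicted", "t value"],
                p = co["predicted", "Pr(>|t|)"],
                siteCoefs = co[grep("^site", rownames(co)), , drop = FALSE],
                r2 = sm$r.squared, adjR2 = sm$adj.r.squared,
                n = nrow(df), method = method, note = note)
  } else {
    fit <- stats::glm(form, data = df, family = stats::quasibinomial())
    sm <- summary(fit)
    co <- sm$coefficients
    out <- list(slope = co["predicted", "Estimate"],
                t = co["predicted", "t value"],
                p = co["predicted", "Pr(>|t|)"],
                siteCoefs = co[grep("^site", rownames(co)), , drop = FALSE],
                r2 = NA_real_, adjR2 = NA_real_,
                n = nrow(df), method = method, note = note)
  }
  class(out) <- "fnValidation"
  out
}

#' @exportS3Method base::print
print.fnValidation <- function(x, ...) {
  cat(sprintf("Establishment validation (%s, n = %d species)\n",
              x$method, x$n))
  cat(sprintf("  predicted establishment: slope = %.3f, t = %.2f, p = %.4g\n",
              x$slope, x$t, x$p))
  if (!is.na(x$adjR2))
    cat(sprintf("  adjusted R^2 = %.3f (R^2 = %.3f)\n", x$adjR2, x$r2))
  if (length(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Validation grid over all neighborhood-size combinations
#'
#' For every combination of environmental and biotic neighborhood sizes (at
#' one interaction scheme), predicts colonist establishment from the two
#' fitted models, validates against observed establishment, and records the
#' adjusted R-squared. Cells whose models are degenerate or missing are NA,
#' not zero.
#'
#' @param envScan,bioticScan [NeighborhoodScan-class] objects.
#' @param pool,traits,community,center,basis,rePrediction see
#'   [predictEstablishment()].
#' @param colonists colonist data.frame (species_id, site_id, plot_id,
#'   seeds_added, plants_year3, optional is_native).
#' @param scheme interaction scheme whose models populate the grid.
#' @param subset "all" or "native_only" (requires an `is_native` column).
#' @return matrix of adjusted R-squared (rows: environmental sizes, columns:
#'   biotic sizes), with the per-cell validation objects in attribute
#'   "validations".
#' @export
predictionGrid <- function(envScan, bioticScan, pool, traits, community,
                           colonists, scheme = "all_pairwise",
                           subset = c("all", "native_only"),
                           center = NULL,
                           basis = c("per-trait", "multivariate"),
                           rePrediction = c("plot", "population")) {
  subset <- match.arg(subset)
  basis <- match.arg(basis)
  rePrediction <- match.arg(rePrediction)
  actual <- actualEstablishment(colonists)
  sites <- tapply(as.character(colonists$site_id),
                  as.character(colonists$species_id),
                  function(s) s[1])
  species <- unique(as.character(colonists$species_id))
  if (subset == "native_only") {
    if (!"is_native" %in% names(colonists))
      stop("native_only subset requires an is_native column")
    native <- unique(colonists$species_id[as.logical(colonists$is_native)])
    species <- intersect(species, native)
  }
  pick <- function(scan) {
    keys <- names(scanModels(scan))
    keys[endsWith(keys, paste0("|", scheme))]
  }
  envKeys <- pick(envScan)
  bioKeys <- pick(bioticScan)
  out <- matrix(NA_real_, length(envKeys), length(bioKeys),
                dimnames = list(sub("\\|.*", "", envKeys),
                                sub("\\|.*", "", bioKeys)))
  vals <- list()
  if (is.null(center))
    center <- computeCenter(pool, traits, community, basis = basis)
  keep <- intersect(species, modelingSpecies(traits))
  # colonist distance caches are shared across all grid cells
  envCache <- .envCache(pool, traits, species = keep, basis = basis)
  bioCache <- .bioticCache(pool, traits, community, center, basis = basis,
                           targets = keep)
  usable <- function(m) isConverged(m) &&
    !any(m@degeneracyReasons %in% .hardFlags)
  pEnvBy <- lapply(envKeys, function(key) {
    em <- scanModels(envScan)[[key]]
    if (!usable(em)) return(NULL)
    spec <- resolveNeighborhood(.sizeFromLabel(em@neighborhood@label),
                                envCache$poolSize)
    d <- data.frame(species = envCache$focal, stringsAsFactors = FALSE)
    for (t in names(envCache$caches))
      d[[t]] <- .neighborValue(envCache$caches[[t]], spec@k)
    predictEnv(em, d)
  })
  pBioBy <- lapply(bioKeys, function(key) {
    bm <- scanModels(bioticScan)[[key]]
    if (!usable(bm)) return(NULL)
    d <- .bioticDesign(bioCache, .sizeFromLabel(bm@neighborhood@label))
    predictBiotic(bm, d, rePrediction = rePrediction)$average
  })
  for (i in seq_along(envKeys)) {
    if (is.null(pEnvBy[[i]])) next
    for (j in seq_along(bioKeys)) {
      if (is.null(pBioBy[[j]])) next
      sp <- intersect(names(pEnvBy[[i]]), names(pBioBy[[j]]))
      pAll <- combineProbabilities(pEnvBy[[i]][sp], pBioBy[[j]][sp])
      v <- validateEstablishment(pAll, actual,
        sites = stats::setNames(as.character(sites), names(sites)))
      out[i, j] <- v$adjR2
      vals[[paste(envKeys[i], bioKeys[j], sep = " x ")]] <- v
    }
  }
  attr(out, "validations") <- vals
  attr(out, "scheme") <- scheme
  attr(out, "subset") <- subset
  out
}

#' Write a neighborhood scan as CSV
#' @param scan a [NeighborhoodScan-class].
#' @param path output file.
#' @export
writeScanCsv <- function(scan, path) {
  tab <- scanTable(scan)
  tab <- cbind(filter = scan@filter, tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write establishment predictions as CSV
#' @param predictions data.frame from [predictEstablishment()].
#' @param path output file.
#' @param site optional site id column value.
#' @export
writePredictionsCsv <- function(predictions, path, site = NA) {
  predictions$site_id <- site
  utils::write.csv(
    predictions[, c("species", "site_id", "p_env", "p_biotic", "p_overall")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write a validation grid as CSV
#' @param grid matrix from [predictionGrid()].
#' @param path output file.
#' @export
writeGridCsv <- function(grid, path) {
  long <- data.frame(env_size = rep(rownames(grid), ncol(grid)),
                     biotic_size = rep(colnames(grid), each = nrow(grid)),
                     scheme = attr(grid, "scheme"),
                     subset = attr(grid, "subset"),
                     adj_r2 = as.vector(grid))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
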