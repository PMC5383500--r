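#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TraitTable
#'
#' @param traits a numeric matrix or data.frame of trait values with species
#'   ids as rownames, or a data.frame with a `species_id` column.
#' @param traitKind named character vector giving "continuous" or "ordinal"
#'   per trait; unnamed traits default to "continuous".
#' @param transformLog character vector of trait names to log-transform during
#'   preprocessing (natural log), or a named logical vector.
#' @return a [TraitTable-class] object (not yet standardized).
#' @examples
#' tt <- TraitTable(
#'   data.frame(species_id = c("a", "b", "c"),
#'              height = c(10, 40, 90), F = c(3, 5, 7)),
#'   traitKind = c(F = "ordinal"), transformLog = "height")
#' @export
TraitTable <- function(traits, traitKind = character(0),
                       transformLog = character(0)) {
  if (is.data.frame(traits)) {
    if ("species_id" %in% names(traits)) {
      ids <- as.character(traits$species_id)
      traits <- traits[, setdiff(names(traits), "species_id"), drop = FALSE]
      rownames(traits) <- ids
    }
    traits <- as.matrix(traits)
  }
  storage.mode(traits) <- "double"
  tn <- colnames(traits)
  kind <- rep("continuous", length(tn))
  names(kind) <- tn
  if (length(traitKind)) {
    bad <- setdiff(names(traitKind), tn)
    if (length(bad))
      stop("traitKind names not in trait table: ", paste(bad, collapse = ", "))
    kind[names(traitKind)] <- traitKind
  }
  lg <- rep(FALSE, length(tn))
  names(lg) <- tn
  if (is.logical(transformLog) && !is.null(names(transformLog))) {
    lg[names(transformLog)] <- transformLog
  } else if (length(transformLog)) {
    bad <- setdiff(transformLog, tn)
    if (length(bad))
      stop("transformLog names not in trait table: ",
           paste(bad, collapse = ", "))
    lg[transformLog] <- TRUE
  }
  new("TraitTable", traits = traits, traitKind = kind, transformLog = lg)
}

#' @rdname accessors
#' @export
setMethod("speciesIds", "TraitTable", function(object, ...)
  rownames(object@traits))

#' @rdname accessors
#' @export
setMethod("traitNames", "TraitTable", function(object, ...)
  colnames(object@traits))

#' @rdname accessors
#' @export
setMethod("traitMatrix", "TraitTable", function(object, ...) object@traits)

#' @rdname accessors
#' @export
setMethod("traitKind", "TraitTable", function(object, ...) object@traitKind)

#' @rdname accessors
#' @export
setMethod("isStandardized", "TraitTable", function(object, ...)
  object@standardized)

#' @rdname accessors
#' @export
setMethod("modelingSpecies", "TraitTable", function(object, ...)
  rownames(object@traits)[stats::complete.cases(object@traits)])

#' @rdname accessors
#' @export
setMethod("excludedSpecies", "TraitTable", function(object, ...)
  rownames(object@traits)[!stats::complete.cases(object@traits)])

setMethod("show", "TraitTable", function(object) {
  cat("TraitTable:", nrow(object@traits), "species x",
      ncol(object@traits), "traits\n")
  cat("  kinds:", paste(sprintf("%s (%s)", traitNames(object),
                                substr(object@traitKind, 1, 4)),
                        collapse = ", "), "\n")
  cat("  standardized:", object@standardized, "\n")
  ex <- excludedSpecies(object)
  if (length(ex))
    cat("  species with incomplete traits:", length(ex), "\n")
})

#' Log-transform and range-standardize traits
#'
#' Traits flagged for log transformation are mapped x -> ln(x) (they must be
#' strictly positive). Every trait is then standardized to \[0, 1\] by
#' (x - min) / (max - min), with min and max computed over the reference set
#' (regional species with complete traits). Ordinal traits are rescaled the
#' same way. The identical affine map is applied to species outside the
#' reference set (e.g. colonists), whose standardized values may fall outside
#' \[0, 1\]; such species are reported via a message.
#'
#' @param x a [TraitTable-class].
#' @param logTraits optional character vector overriding the table's
#'   `transformLog` flags.
#' @param referenceSpecies species ids defining the standardization range;
#'   defaults to all species with complete traits.
#' @return a standardized [TraitTable-class].
#' @examples
#' tt <- TraitTable(matrix(c(1, exp(1), exp(2)), 3, 1,
#'                  dimnames = list(c("a", "b", "c"), "height")),
#'                  transformLog = "height")
#' traitMatrix(preprocessTraits(tt))  # 0, 0.5, 1
#' @export
preprocessTraits <- function(x, logTraits = NULL, referenceSpecies = NULL) {
  stopifnot(is(x, "TraitTable"))
  tr <- x@traits
  lg <- x@transformLog
  if (!is.null(logTraits)) {
    lg[] <- FALSE
    bad <- setdiff(logTraits, colnames(tr))
    if (length(bad))
      stop("unknown log traits: ", paste(bad, collapse = ", "))
    lg[logTraits] <- TRUE
  }
  for (t in names(lg)[lg]) {
    v <- tr[, t]
    if (any(v <= 0, na.rm = TRUE))
      stop("trait '", t, "' has non-positive values; cannot log-transform")
    tr[, t] <- log(v)
  }
  if (is.null(referenceSpecies))
    referenceSpecies <- rownames(tr)[stats::complete.cases(tr)]
  ref <- intersect(referenceSpecies, rownames(tr))
  ref <- ref[stats::complete.cases(tr[ref, , drop = FALSE])]
  if (!length(ref))
    stop("no reference species with complete traits")
  rng <- apply(tr[ref, , drop = FALSE], 2, range)
  rownames(rng) <- c("min", "max")
  span <- rng["max", ] - rng["min", ]
  if (any(span == 0))
    stop("zero range for trait(s): ",
         paste(colnames(tr)[span == 0], collapse = ", "))
  tr <- sweep(sweep(tr, 2, rng["min", ], "-"), 2, span, "/")
  out <- tr[setdiff(rownames(tr), ref), , drop = FALSE]
  oob <- rownames(out)[apply(out, 1, function(v)
    any(!is.na(v) & (v < 0 | v > 1)))]
  if (length(oob))
    message("standardized values outside [0,1] for species outside the ",
            "reference set: ", paste(oob, collapse = ", "))
  new("TraitTable", traits = tr, traitKind = x@traitKind,
      transformLog = lg, standardized = TRUE, ranges = rng,
      referenceSpecies = ref)
}
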