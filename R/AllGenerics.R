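#' @include AllClasses.R
NULL

#' Accessors for funneigh classes
#'
#' Small generic accessors used throughout the package instead of direct
#' slot access.
#'
#' @param object a funneigh S4 object.
#' @param ... unused.
#' @return The requested component; see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(object, ...) standardGeneric("speciesIds"))

#' @rdname accessors
#' @export
setGeneric("traitNames", function(object, ...) standardGeneric("traitNames"))

#' @rdname accessors
#' @export
setGeneric("traitMatrix", function(object, ...) standardGeneric("traitMatrix"))

#' @rdname accessors
#' @export
setGeneric("traitKind", function(object, ...) standardGeneric("traitKind"))

#' @rdname accessors
#' @export
setGeneric("isStandardized",
           function(object, ...) standardGeneric("isStandardized"))

#' @rdname accessors
#' @export
setGeneric("modelingSpecies",
           function(object, ...) standardGeneric("modelingSpecies"))

#' @rdname accessors
#' @export
setGeneric("excludedSpecies",
           function(object, ...) standardGeneric("excludedSpecies"))

#' @rdname accessors
#' @export
setGeneric("habitatPool", function(object, ...) standardGeneric("habitatPool"))

#' @rdname accessors
#' @export
setGeneric("darkDiversity",
           function(object, ...) standardGeneric("darkDiversity"))

#' @rdname accessors
#' @export
setGeneric("observedSpecies",
           function(object, ...) standardGeneric("observedSpecies"))

#' @rdname accessors
#' @export
setGeneric("poolLevels", function(object, ...) standardGeneric("poolLevels"))

#' @rdname accessors
#' @export
setGeneric("neighborhoodK",
           function(object, ...) standardGeneric("neighborhoodK"))

#' @rdname accessors
#' @export
setGeneric("coefTable", function(object, ...) standardGeneric("coefTable"))

#' @rdname accessors
#' @export
setGeneric("aicc", function(object, ...) standardGeneric("aicc"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate",
           function(object, ...) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("modelTerms", function(object, ...) standardGeneric("modelTerms"))

#' @rdname accessors
#' @export
setGeneric("scanTable", function(object, ...) standardGeneric("scanTable"))

#' @rdname accessors
#' @export
setGeneric("selectedModel",
           function(object, ...) standardGeneric("selectedModel"))

#' @rdname accessors
#' @export
setGeneric("scanModels", function(object, ...) standardGeneric("scanModels"))
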