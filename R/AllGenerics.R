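#' Accessor generics
#'
#' @param object an smcca S4 object.
#' @param ... passed to methods.
#' @name smcca-generics
NULL

#' @rdname smcca-generics
#' @export
setGeneric("blocks", function(object, ...) standardGeneric("blocks"))

#' @rdname smcca-generics
#' @export
setGeneric("blockNames", function(object, ...) standardGeneric("blockNames"))

#' @rdname smcca-generics
#' @export
setGeneric("subjectIds", function(object, ...) standardGeneric("subjectIds"))

#' @rdname smcca-generics
#' @export
setGeneric("blockDims", function(object, ...) standardGeneric("blockDims"))

#' @rdname smcca-generics
#' @export
setGeneric("nSubjects", function(object, ...) standardGeneric("nSubjects"))

#' @rdname smcca-generics
#' @export
setGeneric("weightMatrix", function(object, ...) standardGeneric("weightMatrix"))

#' @rdname smcca-generics
#' @export
setGeneric("canonicalCorrelations",
           function(object, ...) standardGeneric("canonicalCorrelations"))

#' @rdname smcca-generics
#' @export
setGeneric("penalties", function(object, ...) standardGeneric("penalties"))

#' @rdname smcca-generics
#' @export
setGeneric("nDims", function(object, ...) standardGeneric("nDims"))

#' @rdname smcca-generics
#' @export
setGeneric("selectedPenalties",
           function(object, ...) standardGeneric("selectedPenalties"))

#' @rdname smcca-generics
#' @export
setGeneric("stabilityTable",
           function(object, ...) standardGeneric("stabilityTable"))

#' @rdname smcca-generics
#' @export
setGeneric("meanLoadingCorrelation",
           function(object, ...) standardGeneric("meanLoadingCorrelation"))
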