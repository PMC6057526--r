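#' @include AllClasses.R
NULL

#' Accessors for svforge classes
#'
#' \code{variantTable}, \code{metaTable} and \code{libraryTable} return the
#' underlying data.frames; \code{variantIds} and \code{fractions} extract
#' and \code{fractions<-} replaces per-variant fields; \code{blocks} and
#' \code{ligationRegions} expose a \linkS4class{BlockGrid}'s ranges;
#' \code{taskTable} returns a \linkS4class{TaskPlan}'s rows.
#'
#' @param x an svforge object.
#' @param value replacement value.
#' @return The extracted component (see details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("fractions<-", function(x, value) standardGeneric("fractions<-"))

#' @rdname accessors
#' @export
setGeneric("metaTable", function(x) standardGeneric("metaTable"))

#' @rdname accessors
#' @export
setGeneric("libraryTable", function(x) standardGeneric("libraryTable"))

#' @rdname accessors
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname accessors
#' @export
setGeneric("ligationRegions", function(x) standardGeneric("ligationRegions"))

#' @rdname accessors
#' @export
setGeneric("taskTable", function(x) standardGeneric("taskTable"))

#' @rdname accessors
#' @export
setGeneric("alteredContigs", function(x) standardGeneric("alteredContigs"))

#' @rdname accessors
#' @export
setGeneric("originalContig", function(x) standardGeneric("originalContig"))
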