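#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor family for the package's S4 objects: release-probability
#' estimates (\code{prHat}, \code{standardError}, \code{confInt},
#' \code{nTrials}, \code{nSuccess}), traces (\code{dff}, \code{scanTimes},
#' \code{noiseSE}, \code{fBaseline}, \code{fBackground}, \code{roiLabel}) and
#' records (\code{scanMatrix}, \code{stimTimes}, \code{trialId}).
#'
#' @param x an epscat S4 object.
#' @return the stored component; see each class for units.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("prHat", function(x) standardGeneric("prHat"))

#' @rdname accessors
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nSuccess", function(x) standardGeneric("nSuccess"))

#' @rdname accessors
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))

#' @rdname accessors
#' @export
setGeneric("noiseSE", function(x) standardGeneric("noiseSE"))

#' @rdname accessors
#' @export
setGeneric("fBaseline", function(x) standardGeneric("fBaseline"))

#' @rdname accessors
#' @export
setGeneric("fBackground", function(x) standardGeneric("fBackground"))

#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname accessors
#' @export
setGeneric("scanMatrix", function(x) standardGeneric("scanMatrix"))

#' @rdname accessors
#' @export
setGeneric("stimTimes", function(x) standardGeneric("stimTimes"))

#' @rdname accessors
#' @export
setGeneric("trialId", function(x) standardGeneric("trialId"))

#' @rdname accessors
#' @export
setGeneric("ppr", function(x) standardGeneric("ppr"))
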