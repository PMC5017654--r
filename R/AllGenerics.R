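# Generics for accessors shared across classes.

#' @rdname ImageSlice-class
#' @param x an object.
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname PhantomSet-class
#' @param x an object.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname PhantomSet-class
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname PhantomSet-class
#' @export
setGeneric("phantomSpecOf", function(x) standardGeneric("phantomSpecOf"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("labelFields", function(x) standardGeneric("labelFields"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("atomMeans", function(x) standardGeneric("atomMeans"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("logJointTrace", function(x) standardGeneric("logJointTrace"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("retainedSamples", function(x) standardGeneric("retainedSamples"))

#' @rdname NeighborhoodGraph-class
#' @param i 1-based column-major linear pixel index.
#' @export
setGeneric("neighborsOf", function(x, i) standardGeneric("neighborsOf"))

#' @rdname NeighborhoodGraph-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname AtomStats-class
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname MatchResult-class
#' @export
setGeneric("labelMapping", function(x) standardGeneric("labelMapping"))

#' @rdname MatchResult-class
#' @export
setGeneric("objectJaccard", function(x) standardGeneric("objectJaccard"))
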