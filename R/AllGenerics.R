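#' @rdname PoaGraph-class
#' @param x,object a [PoaGraph-class] object.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname PoaGraph-class
#' @export
setGeneric("numSequences", function(x) standardGeneric("numSequences"))

#' @rdname PoaGraph-class
#' @export
setGeneric("nodeBases", function(x) standardGeneric("nodeBases"))

#' @rdname PoaGraph-class
#' @export
setGeneric("nodeRanks", function(x) standardGeneric("nodeRanks"))

#' @rdname PoaGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname PoaGraph-class
#' @export
setGeneric("backbone", function(x) standardGeneric("backbone"))

#' @rdname ParallelBases-class
#' @param x a [ParallelBases-class] object.
#' @export
setGeneric("parallelCounts", function(x) standardGeneric("parallelCounts"))

#' @rdname PolishedRead-class
#' @param x the object to extract from.
#' @export
setGeneric("polishedSequence", function(x) standardGeneric("polishedSequence"))

#' @rdname PolishedRead-class
#' @export
setGeneric("correctionCounts", function(x) standardGeneric("correctionCounts"))
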