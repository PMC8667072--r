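#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @export
setGeneric("confidence", function(x, from, to) standardGeneric("confidence"))

#' @export
setGeneric("neighborhood", function(x, gene) standardGeneric("neighborhood"))

#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' @export
setGeneric("termSize", function(x) standardGeneric("termSize"))

#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @export
setGeneric("termNamespace", function(x) standardGeneric("termNamespace"))

#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))

#' @export
setGeneric("latentTargets", function(x) standardGeneric("latentTargets"))

#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @export
setGeneric("putativeGenes", function(x) standardGeneric("putativeGenes"))

#' @export
setGeneric("candidateRecords", function(x) standardGeneric("candidateRecords"))

#' @export
setGeneric("enrichedTerms", function(x) standardGeneric("enrichedTerms"))
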