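#' Node names of a network
#'
#' @param x an [Interactome] or [ExpandedNetwork].
#' @return Character vector of gene symbols.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Number of nodes
#' @param x a network object.
#' @return Integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x a network object.
#' @return Integer count.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge list of a network
#' @param x a network object.
#' @return A two-column `data.frame` (`from`, `to`) of gene symbols.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Underlying igraph object
#' @param x a network object.
#' @return An `igraph` graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Genes of a target set
#' @param x a [TargetSet].
#' @return Character vector of gene symbols.
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' Per-gene support of a target set
#'
#' Lists, for every gene, the sources (ingredients or study ids) that
#' nominated it.
#'
#' @param x a [TargetSet].
#' @return Named list of character vectors.
#' @export
setGeneric("targetSupport", function(x) standardGeneric("targetSupport"))

#' Core targets surviving the centrality cascade
#' @param x a [ScreenReport] or [RunReport].
#' @return Character vector of gene symbols.
#' @export
setGeneric("coreTargets", function(x) standardGeneric("coreTargets"))

#' Node centralities of a connected network
#'
#' Degree (raw degree count), betweenness (Brandes, normalised by
#' \eqn{(n-1)(n-2)/2}) and closeness (\eqn{(n-1)/\sum_v d(u,v)}) for every
#' node, together with the table's medians (average-of-middle-two convention
#' for even n).
#'
#' @param g a connected [Interactome] (or igraph graph).
#' @return A [CentralityTable].
#' @export
setGeneric("centralities", function(g) standardGeneric("centralities"))
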