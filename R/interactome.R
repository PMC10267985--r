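#' Expand a seed set to its first neighbours in a background interactome
#'
#' Emulates seed-based PPI network construction: the result is the subgraph
#' of the background induced on the seeds found in it plus every node within
#' `depth` steps of a seed (default 1, i.e. direct interactors). Seeds absent
#' from the background are recorded in the result, not fatal; an empty
#' effective seed set is an error.
#'
#' @param background an [Interactome].
#' @param seeds a [TargetSet] or character vector of gene symbols.
#' @param label `"drug"` or `"disease"` (metadata only).
#' @param depth expansion depth in edges (>= 0; default 1).
#' @return An [ExpandedNetwork].
#' @examples
#' bg <- Interactome(cbind(c("A", "B", "C"), c("B", "C", "D")))
#' expandSeeds(bg, c("A", "C"))
#' @export
expandSeeds <- function(background, seeds, label = "drug", depth = 1L) {
    stopifnot(is(background, "Interactome"))
    if (is(seeds, "TargetSet")) {
        if (seeds@provenance %in% c("drug", "disease")) label <- seeds@provenance
        seeds <- targetGenes(seeds)
    }
    seeds <- unique(as.character(seeds))
    if (numNodes(background) == 0) stop("background interactome is empty")
    present <- intersect(seeds, nodeNames(background))
    missing <- setdiff(seeds, present)
    if (!length(present))
        stop("empty result: none of the ", length(seeds),
             " seeds occur in the background interactome")
    if (length(missing))
        message("expandSeeds: ", length(missing),
                " seed(s) not in background, ignored")
    g <- asIgraph(background)
    keep <- unique(names(unlist(igraph::ego(
        g, order = depth, nodes = present, mode = "all"))))
    sub <- igraph::induced_subgraph(g, keep)
    new("ExpandedNetwork", graph = new("Interactome", graph = sub),
        seeds = present, missing = missing, label = label)
}

#' Merge two expanded networks by node intersection
#'
#' Node set = the intersection of the two node sets; edge set = the union of
#' both edge sets induced on those nodes. Intersection semantics make the
#' merged network the part of the interactome relevant to both the drug and
#' the disease side, and guarantee the merged network is no larger than
#' either input.
#'
#' @param a,b [ExpandedNetwork] or [Interactome] objects.
#' @return An [Interactome].
#' @export
mergeNetworks <- function(a, b) {
    ga <- if (is(a, "ExpandedNetwork")) a@graph else a
    gb <- if (is(b, "ExpandedNetwork")) b@graph else b
    stopifnot(is(ga, "Interactome"), is(gb, "Interactome"))
    if (numNodes(ga) == 0 || numNodes(gb) == 0)
        stop("both networks must be non-empty")
    common <- intersect(nodeNames(ga), nodeNames(gb))
    if (!length(common))
        stop("empty result: the two networks share no nodes")
    ea <- edgeTable(ga); eb <- edgeTable(gb)
    edges <- rbind(ea, eb)
    keep <- edges$from %in% common & edges$to %in% common
    suppressMessages(Interactome(edges[keep, , drop = FALSE], nodes = common))
}
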