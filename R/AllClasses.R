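#' @include AllGenerics.R
NULL

#' netscreen: network-pharmacology core-target screening
#'
#' S4 containers for the screening pipeline: background interactomes,
#' drug/disease target sets, expression studies, centrality tables and
#' screening reports.
#'
#' @import methods
#' @importFrom stats median p.adjust pchisq phyper pt rexp rnorm runif setNames var
#' @importFrom utils read.delim write.table
#' @name netscreen-package
"_PACKAGE"

setOldClass("igraph")

#' Interactome: an undirected simple protein-protein interaction graph
#'
#' Nodes are gene symbols; edges are unordered symbol pairs. Self-loops and
#' parallel edges are dropped at construction (with a message giving the
#' count), so the degree sum always equals twice the edge count.
#'
#' @slot graph an undirected simple `igraph` with named vertices.
#' @export
setClass("Interactome", representation(graph = "igraph"))

setValidity("Interactome", function(object) {
    g <- object@graph
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
    if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
        return("vertices must be named with gene symbols")
    TRUE
})

#' Construct an Interactome from an edge list
#'
#' @param edges two-column matrix or data.frame of gene-symbol pairs.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to include.
#' @return An [Interactome].
#' @examples
#' g <- Interactome(data.frame(from = c("A", "B"), to = c("B", "C")))
#' numNodes(g)
#' @export
Interactome <- function(edges, nodes = NULL) {
    if (inherits(edges, "igraph")) {
        g <- igraph::as_undirected(edges, mode = "collapse")
        g <- igraph::simplify(g)
        return(new("Interactome", graph = g))
    }
    em <- as.matrix(edges)
    if (length(em) && ncol(em) < 2)
        stop("edge input must have two columns")
    em <- matrix(as.character(em[, 1:2]), ncol = 2)
    keep <- em[, 1] != em[, 2]
    n_loops <- sum(!keep)
    em <- em[keep, , drop = FALSE]
    key <- paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]), sep = "\r")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    em <- em[!dup, , drop = FALSE]
    if (n_loops + n_dup > 0)
        message("Interactome: dropped ", n_loops, " self-loop(s) and ",
                n_dup, " duplicate edge(s)")
    vs <- unique(c(as.character(em), nodes))
    g <- igraph::graph_from_data_frame(as.data.frame(em), directed = FALSE,
                                       vertices = vs)
    new("Interactome", graph = g)
}

#' @describeIn Interactome node symbols
#' @param x,object an `Interactome`
#' @export
setMethod("nodeNames", "Interactome", function(x) {
    as.character(igraph::V(x@graph)$name)
})

#' @describeIn Interactome node count
#' @export
setMethod("numNodes", "Interactome", function(x) igraph::vcount(x@graph))

#' @describeIn Interactome edge count
#' @export
setMethod("numEdges", "Interactome", function(x) igraph::ecount(x@graph))

#' @describeIn Interactome two-column edge data.frame
#' @export
setMethod("edgeTable", "Interactome", function(x) {
    el <- igraph::as_edgelist(x@graph, names = TRUE)
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
})

#' @describeIn Interactome underlying igraph
#' @export
setMethod("asIgraph", "Interactome", function(x) x@graph)

setMethod("show", "Interactome", function(object) {
    cat("Interactome with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
})

#' TargetSet: a named, deduplicated set of gene symbols with provenance
#'
#' @slot name label for the set (e.g. prescription or disease name).
#' @slot genes character vector of unique, uppercased gene symbols.
#' @slot provenance one of `"drug"`, `"disease"`, `"other"`.
#' @slot support named list: gene -> character vector of supporting sources
#'   (ingredients for drug sets, study ids for disease sets).
#' @export
setClass("TargetSet",
         representation(name = "character", genes = "character",
                        provenance = "character", support = "list"))

setValidity("TargetSet", function(object) {
    if (anyDuplicated(object@genes)) return("genes must be unique")
    if (!object@provenance %in% c("drug", "disease", "other"))
        return("provenance must be 'drug', 'disease' or 'other'")
    if (length(object@support) &&
        !all(names(object@support) %in% object@genes))
        return("support names must be a subset of genes")
    TRUE
})

#' Construct a TargetSet
#'
#' @param genes character vector of gene symbols (deduplicated, uppercased).
#' @param name label.
#' @param provenance `"drug"`, `"disease"` or `"other"`.
#' @param support optional named list gene -> sources.
#' @return A [TargetSet].
#' @export
TargetSet <- function(genes, name = "targets", provenance = "other",
                      support = list()) {
    genes <- unique(toupper(as.character(genes)))
    new("TargetSet", name = name, genes = genes,
        provenance = provenance, support = support)
}

#' @describeIn TargetSet member genes
#' @param x,object a `TargetSet`
#' @export
setMethod("targetGenes", "TargetSet", function(x) x@genes)

#' @describeIn TargetSet supporting sources per gene
#' @export
setMethod("targetSupport", "TargetSet", function(x) x@support)

#' @describeIn TargetSet number of genes
#' @export
setMethod("length", "TargetSet", function(x) length(x@genes))

setMethod("show", "TargetSet", function(object) {
    cat("TargetSet '", object@name, "' (", object@provenance, "): ",
        length(object@genes), " genes\n", sep = "")
    if (length(object@support)) {
        multi <- sum(vapply(object@support, length, 1L) >= 2)
        cat("  genes supported by >=2 sources:", multi, "\n")
    }
})

#' ExpandedNetwork: a seed set plus its first neighbours in a background graph
#'
#' The induced subgraph of the background interactome on the seeds present in
#' it and all their direct interactors (expansion depth 1 by default).
#'
#' @slot graph the induced [Interactome].
#' @slot seeds seed genes actually present in the background.
#' @slot missing seed genes absent from the background (reported, not fatal).
#' @slot label `"drug"` or `"disease"`.
#' @export
setClass("ExpandedNetwork",
         representation(graph = "Interactome", seeds = "character",
                        missing = "character", label = "character"))

#' @describeIn ExpandedNetwork node symbols
#' @param x,object an `ExpandedNetwork`
#' @export
setMethod("nodeNames", "ExpandedNetwork", function(x) nodeNames(x@graph))

#' @describeIn ExpandedNetwork node count
#' @export
setMethod("numNodes", "ExpandedNetwork", function(x) numNodes(x@graph))

#' @describeIn ExpandedNetwork edge count
#' @export
setMethod("numEdges", "ExpandedNetwork", function(x) numEdges(x@graph))

#' @describeIn ExpandedNetwork underlying igraph
#' @export
setMethod("asIgraph", "ExpandedNetwork", function(x) asIgraph(x@graph))

#' @describeIn ExpandedNetwork edge data.frame
#' @export
setMethod("edgeTable", "ExpandedNetwork", function(x) edgeTable(x@graph))

setMethod("show", "ExpandedNetwork", function(object) {
    cat("ExpandedNetwork (", object@label, "): ", numNodes(object),
        " nodes, ", numEdges(object), " edges from ", length(object@seeds),
        " seeds (", length(object@missing), " seeds not in background)\n",
        sep = "")
})

#' ExpressionStudy: a log2 expression matrix with tumour/normal labels
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' single assay `"log2"` holds genes x samples values and whose `colData`
#' carries a `group` factor with levels `tumor`/`normal` (>= 2 samples each).
#' Duplicate gene symbols (e.g. multiple probes) are collapsed at
#' construction by keeping, per symbol, the row with the largest absolute
#' tumour - normal mean difference.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        return("assay 'log2' required")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) return("colData must contain 'group'")
    grp <- as.character(cd$group)
    if (!all(grp %in% c("tumor", "normal")))
        return("groups must be 'tumor' or 'normal'")
    if (sum(grp == "tumor") < 2 || sum(grp == "normal") < 2)
        return("need >= 2 samples per group")
    if (anyDuplicated(rownames(object)))
        return("duplicate gene symbols after collapse")
    if (!all(is.finite(SummarizedExperiment::assay(object, "log2"))))
        return("values must be finite")
    TRUE
})

#' Construct an ExpressionStudy
#'
#' @param values numeric genes x samples matrix on the log2 scale, with gene
#'   symbols as rownames and sample ids as colnames.
#' @param groups character/factor mapping each sample (column) to `"tumor"`
#'   or `"normal"`; either a vector in column order or named by sample id.
#' @param study_id identifier (e.g. an emulated GEO accession).
#' @return An [ExpressionStudy].
#' @export
ExpressionStudy <- function(values, groups, study_id = "study") {
    values <- as.matrix(values)
    if (is.null(rownames(values))) stop("values must have gene rownames")
    if (!is.null(names(groups)) && !is.null(colnames(values)))
        groups <- groups[colnames(values)]
    groups <- as.character(groups)
    if (length(groups) != ncol(values))
        stop("one group label per sample required")
    if (anyDuplicated(rownames(values))) {
        tum <- groups == "tumor"
        d <- abs(rowMeans(values[, tum, drop = FALSE]) -
                 rowMeans(values[, !tum, drop = FALSE]))
        ord <- order(rownames(values), -d)
        values <- values[ord, , drop = FALSE]
        values <- values[!duplicated(rownames(values)), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = values),
        colData = S4Vectors::DataFrame(group = groups,
                                       row.names = colnames(values)))
    S4Vectors::metadata(se)$study_id <- study_id
    new("ExpressionStudy", se)
}

#' Study identifier of an ExpressionStudy
#' @param x an [ExpressionStudy].
#' @return Character id.
#' @export
studyId <- function(x) S4Vectors::metadata(x)$study_id

#' CentralityTable: per-node DC/BC/CC with the table's medians
#'
#' @slot table data.frame with columns `node`, `dc`, `bc`, `cc`.
#' @slot medians named numeric of length 3 (`dc`, `bc`, `cc`).
#' @export
setClass("CentralityTable",
         representation(table = "data.frame", medians = "numeric"))

setValidity("CentralityTable", function(object) {
    if (!all(c("node", "dc", "bc", "cc") %in% colnames(object@table)))
        return("table needs node/dc/bc/cc columns")
    if (!all(c("dc", "bc", "cc") %in% names(object@medians)))
        return("medians need dc/bc/cc entries")
    if (any(object@table$dc < 0)) return("dc must be nonnegative")
    if (any(object@table$bc < -1e-12 | object@table$bc > 1 + 1e-12))
        return("bc must lie in [0,1]")
    TRUE
})

#' @describeIn CentralityTable data.frame of per-node values
#' @param x,object a `CentralityTable`
#' @export
centralityTable <- function(x) x@table

#' Median DC/BC/CC of a centrality table
#' @param x a [CentralityTable].
#' @return Named numeric vector (`dc`, `bc`, `cc`).
#' @export
centralityMedians <- function(x) x@medians

setMethod("show", "CentralityTable", function(object) {
    cat("CentralityTable:", nrow(object@table), "nodes; medians dc =",
        object@medians[["dc"]], "bc =", signif(object@medians[["bc"]], 4),
        "cc =", signif(object@medians[["cc"]], 4), "\n")
})

#' ScreenReport: result of the two-stage median-adaptive centrality cascade
#'
#' @slot input the screened network (largest connected component of the
#'   supplied graph).
#' @slot stage1 network after the DC > 2 x median(DC) cut.
#' @slot stage2 core network after the joint DC/BC/CC median cut.
#' @slot thresholds list with elements `stage1` (named numeric, `dc`) and
#'   `stage2` (named numeric, `dc`/`bc`/`cc`).
#' @slot fallback named logical (`stage1`, `stage2`): TRUE where a strict cut
#'   would have emptied the network and the stage input was returned instead.
#' @export
setClass("ScreenReport",
         representation(input = "Interactome", stage1 = "Interactome",
                        stage2 = "Interactome", thresholds = "list",
                        fallback = "logical"))

setValidity("ScreenReport", function(object) {
    s2 <- nodeNames(object@stage2); s1 <- nodeNames(object@stage1)
    if (!all(s2 %in% s1)) return("stage2 nodes must be a subset of stage1")
    if (!all(s1 %in% nodeNames(object@input)))
        return("stage1 nodes must be a subset of the input")
    TRUE
})

#' @describeIn ScreenReport genes of the stage-2 core network
#' @param x,object a `ScreenReport`
#' @export
setMethod("coreTargets", "ScreenReport", function(x) nodeNames(x@stage2))

#' Stage networks of a screen report
#' @param x a [ScreenReport].
#' @param stage `"input"`, `"stage1"` or `"stage2"`.
#' @return The requested [Interactome].
#' @export
screenStageNetwork <- function(x, stage = c("stage2", "stage1", "input")) {
    slot(x, match.arg(stage))
}

#' Thresholds applied by the cascade
#' @param x a [ScreenReport].
#' @return List with `stage1` and `stage2` named numeric thresholds.
#' @export
screenThresholds <- function(x) x@thresholds

#' Fallback flags of the cascade
#' @param x a [ScreenReport].
#' @return Named logical (`stage1`, `stage2`).
#' @export
screenFallback <- function(x) x@fallback

setMethod("show", "ScreenReport", function(object) {
    cat("ScreenReport\n")
    cat("  input :", numNodes(object@input), "nodes /",
        numEdges(object@input), "edges\n")
    cat("  stage1:", numNodes(object@stage1), "nodes /",
        numEdges(object@stage1), "edges (DC >",
        signif(object@thresholds$stage1[["dc"]], 4),
        if (object@fallback[["stage1"]]) "; FALLBACK" else "", ")\n")
    t2 <- object@thresholds$stage2
    cat("  stage2:", numNodes(object@stage2), "nodes /",
        numEdges(object@stage2), "edges (DC >", signif(t2[["dc"]], 4),
        ", BC >", signif(t2[["bc"]], 4), ", CC >", signif(t2[["cc"]], 4),
        if (object@fallback[["stage2"]]) "; FALLBACK" else "", ")\n")
})

#' GeneSetCollection: named gene sets over a background universe
#'
#' @slot sets named list term_id -> character vector of member genes.
#' @slot descriptions named character, one per term.
#' @slot universe background gene symbols; every member gene belongs to it.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character",
                        universe = "character"))

setValidity("GeneSetCollection", function(object) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        return("sets must have unique names")
    if (any(vapply(object@sets, length, 1L) == 0))
        return("term sets must be non-empty")
    if (!all(unlist(object@sets) %in% object@universe))
        return("every term's genes must lie in the universe")
    TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (term -> genes).
#' @param descriptions optional named character descriptions.
#' @param universe background genes; defaults to the union of all sets
#'   (a DAVID-like default when no explicit background is supplied).
#' @return A [GeneSetCollection].
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, universe = NULL) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(universe)) universe <- unique(unlist(sets))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("GeneSetCollection", sets = sets,
        descriptions = descriptions, universe = unique(universe))
}

#' Gene sets of a collection
#' @param x a [GeneSetCollection].
#' @return Named list of character vectors.
#' @export
geneSets <- function(x) x@sets

#' Background universe of a collection
#' @param x a [GeneSetCollection].
#' @return Character vector of genes.
#' @export
setUniverse <- function(x) x@universe

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "terms over a universe of",
        length(object@universe), "genes\n")
})

#' @describeIn GeneSetCollection number of terms
#' @param x,object a `GeneSetCollection`
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' RunReport: machine-readable record of a full pipeline run
#'
#' @slot drugTargets pooled drug [TargetSet].
#' @slot diseaseTargets intersected disease [TargetSet].
#' @slot drugNet,diseaseNet the two [ExpandedNetwork]s.
#' @slot merged the intersection-merged [Interactome].
#' @slot screen the [ScreenReport] of the centrality cascade.
#' @slot enrichment data.frame of enrichment results.
#' @slot counts list mirroring the stagewise count chain.
#' @slot config the simulation / analysis configuration used.
#' @export
setClass("RunReport",
         representation(drugTargets = "TargetSet",
                        diseaseTargets = "TargetSet",
                        drugNet = "ExpandedNetwork",
                        diseaseNet = "ExpandedNetwork",
                        merged = "Interactome",
                        screen = "ScreenReport",
                        enrichment = "data.frame",
                        counts = "list", config = "list"))

#' @describeIn RunReport genes of the final core network
#' @param x,object a `RunReport`
#' @export
setMethod("coreTargets", "RunReport", function(x) coreTargets(x@screen))

#' Stagewise counts of a pipeline run
#' @param x a [RunReport].
#' @return Named list of node/edge/target counts per stage.
#' @export
runCounts <- function(x) x@counts

#' Enrichment table of a pipeline run
#' @param x a [RunReport].
#' @return data.frame of enrichment rows (see [enrichTargets()]).
#' @export
runEnrichment <- function(x) x@enrichment

setMethod("show", "RunReport", function(object) {
    ct <- object@counts
    cat("RunReport (seed ", object@config$seed, ")\n", sep = "")
    cat("  drug targets      :", ct$drug_targets, "\n")
    cat("  disease targets   :", ct$disease_targets, "\n")
    cat("  drug network      :", ct$drug_net_nodes, "nodes /",
        ct$drug_net_edges, "edges\n")
    cat("  disease network   :", ct$disease_net_nodes, "nodes /",
        ct$disease_net_edges, "edges\n")
    cat("  merged network    :", ct$merged_nodes, "nodes /",
        ct$merged_edges, "edges\n")
    cat("  key network       :", ct$key_nodes, "nodes /",
        ct$key_edges, "edges\n")
    cat("  core network      :", ct$core_nodes, "nodes /",
        ct$core_edges, "edges\n")
    cat("  significant terms :", ct$significant_terms, "\n")
})
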