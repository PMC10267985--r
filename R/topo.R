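#' @describeIn centralities method for Interactome
#' @export
setMethod("centralities", "Interactome", function(g) {
    .centralities_igraph(asIgraph(g))
})

#' @describeIn centralities method for igraph graphs
#' @export
setMethod("centralities", "igraph", function(g) .centralities_igraph(g))

.centralities_igraph <- function(g) {
    n <- igraph::vcount(g)
    if (n == 0) stop("empty graph")
    if (!igraph::is_connected(g))
        stop("graph is disconnected; restrict to a connected component first",
             " (screenCore() does this automatically)")
    nodes <- igraph::V(g)$name
    if (is.null(nodes)) nodes <- as.character(seq_len(n))
    dc <- as.integer(igraph::degree(g))
    if (n == 1) {
        tab <- data.frame(node = nodes, dc = 0L, bc = 0, cc = 1)
    } else {
        denom <- (n - 1) * (n - 2) / 2
        bc_raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
        bc <- if (denom > 0) bc_raw / denom else rep(0, n)
        cc <- igraph::closeness(g, normalized = TRUE)
        tab <- data.frame(node = nodes, dc = dc, bc = as.numeric(bc),
                          cc = as.numeric(cc))
    }
    rownames(tab) <- NULL
    new("CentralityTable", table = tab,
        medians = c(dc = median(tab$dc), bc = median(tab$bc),
                    cc = median(tab$cc)))
}

#' Screen a network on explicit centrality thresholds
#'
#' Induced subgraph on the nodes whose centralities exceed every supplied
#' threshold (strictly by default, matching "higher than"). If the cut would
#' empty the network, the input is returned unchanged with the `fallback`
#' flag set, so degenerate inputs never yield an empty network silently.
#'
#' @param g a connected [Interactome].
#' @param thresholds named numeric; names from `dc`, `bc`, `cc`.
#' @param strict use `>` (TRUE, default) or `>=`.
#' @return List with `network` ([Interactome]), `fallback` (logical),
#'   `thresholds` and `n_retained`.
#' @export
screenStage <- function(g, thresholds, strict = TRUE) {
    stopifnot(is(g, "Interactome"))
    if (is.null(names(thresholds)) ||
        !all(names(thresholds) %in% c("dc", "bc", "cc")))
        stop("configuration error: threshold names must be dc/bc/cc")
    ct <- centralityTable(centralities(g))
    keep <- rep(TRUE, nrow(ct))
    for (m in names(thresholds)) {
        keep <- keep & if (strict) ct[[m]] > thresholds[[m]]
                       else ct[[m]] >= thresholds[[m]]
    }
    if (!any(keep))
        return(list(network = g, fallback = TRUE, thresholds = thresholds,
                    n_retained = 0L))
    sub <- igraph::induced_subgraph(asIgraph(g), ct$node[keep])
    list(network = new("Interactome", graph = sub), fallback = FALSE,
         thresholds = thresholds, n_retained = sum(keep))
}

.largest_component <- function(g) {
    ig <- asIgraph(g)
    comp <- igraph::components(ig)
    if (comp$no > 1) {
        message("restricting to largest connected component (",
                max(comp$csize), " of ", igraph::vcount(ig), " nodes)")
        keep <- which(comp$membership == which.max(comp$csize))
        ig <- igraph::induced_subgraph(ig, keep)
    }
    new("Interactome", graph = ig)
}

#' Two-stage median-adaptive centrality cascade
#'
#' Extracts the core target network of a merged interactome:
#'
#' 1. Restrict to the largest connected component.
#' 2. Stage 1 ("key network"): keep nodes with degree strictly above twice
#'    the median degree; re-induce and re-restrict to the largest component.
#' 3. Stage 2 ("core network"): recompute degree, betweenness and closeness
#'    on the stage-1 network and keep nodes strictly above all three medians.
#'
#' Thresholds are always derived from the medians of the network at hand,
#' never fixed constants, so the cascade adapts to the input's scale. If a
#' stage's strict cut would empty the network, that stage returns its input
#' unchanged and flags the fallback.
#'
#' @param g a non-empty [Interactome].
#' @return A [ScreenReport].
#' @examples
#' star <- Interactome(cbind("HUB", paste0("L", 1:4)))
#' rep <- screenCore(star)
#' coreTargets(rep)  # the hub
#' @export
screenCore <- function(g) {
    stopifnot(is(g, "Interactome"))
    if (numNodes(g) == 0) stop("empty graph")
    g0 <- .largest_component(g)
    ct1 <- centralities(g0)
    thr1 <- c(dc = 2 * centralityMedians(ct1)[["dc"]])
    s1 <- screenStage(g0, thr1, strict = TRUE)
    g1 <- if (s1$fallback) g0 else .largest_component(s1$network)
    ct2 <- centralities(g1)
    med2 <- centralityMedians(ct2)
    s2 <- screenStage(g1, med2, strict = TRUE)
    g2 <- if (s2$fallback) g1 else s2$network
    new("ScreenReport", input = g0, stage1 = g1, stage2 = g2,
        thresholds = list(stage1 = thr1, stage2 = med2),
        fallback = c(stage1 = s1$fallback, stage2 = s2$fallback))
}
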