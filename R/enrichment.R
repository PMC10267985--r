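#' Hypergeometric over-representation analysis
#'
#' For each term with K members in a universe of N genes and a query of n
#' genes (after restriction to the universe) overlapping the term in k
#' genes, computes the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} — the one-sided over-representation test — plus a
#' Benjamini-Hochberg FDR across all terms tested. Rows are sorted by raw p
#' ascending; `significant` uses the raw p-value (the convention of common
#' annotation servers), with the FDR always reported alongside.
#'
#' @param query a [TargetSet] or character vector of genes.
#' @param coll a [GeneSetCollection].
#' @param alpha significance level on the raw p (default 0.05).
#' @param universe optional explicit background; defaults to the
#'   collection's universe.
#' @return data.frame with columns `term`, `description`, `k`, `K`, `n`,
#'   `N`, `p`, `fdr`, `significant` and list-column `overlap`.
#' @examples
#' coll <- GeneSetCollection(list(A = c("G1", "G2", "G3")),
#'                           universe = paste0("G", 1:20))
#' enrichTargets(c("G1", "G2", "G3", "G4", "G5"), coll)
#' @export
enrichTargets <- function(query, coll, alpha = 0.05, universe = NULL) {
    stopifnot(is(coll, "GeneSetCollection"))
    if (is(query, "TargetSet")) query <- targetGenes(query)
    if (is.null(universe)) universe <- setUniverse(coll)
    universe <- unique(universe)
    q <- intersect(unique(query), universe)
    if (!length(q))
        stop("empty effective query: no query gene occurs in the universe")
    N <- length(universe); n <- length(q)
    sets <- lapply(geneSets(coll), intersect, universe)
    K <- vapply(sets, length, 1L)
    ov <- lapply(sets, intersect, q)
    k <- vapply(ov, length, 1L)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    res <- data.frame(term = names(sets),
                      description = unname(coll@descriptions[names(sets)]),
                      k = k, K = K, n = n, N = N, p = p,
                      fdr = p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE, row.names = NULL)
    res$significant <- res$p < alpha
    res$overlap <- unname(ov)
    res[order(res$p, res$term), , drop = FALSE]
}
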