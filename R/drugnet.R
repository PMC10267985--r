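#' Pool and deduplicate a herb-ingredient-target table into a drug TargetSet
#'
#' The union of targets over all rows, with per-target support listing every
#' distinct ingredient that nominates it. Targets hit by two or more
#' ingredients are the prescription's overlap; their count is reported as
#' attribute `n_multi_ingredient` (and by `show()`).
#'
#' @param table data.frame with columns `herb`, `ingredient`, `target`
#'   (no blank fields; duplicates allowed on input).
#' @param name label for the set.
#' @return A [TargetSet] with provenance `"drug"`.
#' @examples
#' tbl <- data.frame(herb = c("H1", "H1", "H2"),
#'                   ingredient = c("I1", "I2", "I3"),
#'                   target = c("T1", "T1", "T2"))
#' poolTargets(tbl)
#' @export
poolTargets <- function(table, name = "drug") {
    table <- .check_drug_table(table)
    if (!nrow(table)) stop("empty herb-ingredient-target table")
    support <- lapply(split(table$ingredient, table$target),
                      function(x) sort(unique(x)))
    ts <- TargetSet(names(support), name = name, provenance = "drug",
                    support = support)
    attr(ts, "n_multi_ingredient") <-
        sum(vapply(support, length, 1L) >= 2)
    ts
}

.check_drug_table <- function(table) {
    need <- c("herb", "ingredient", "target")
    if (!all(need %in% colnames(table)))
        stop("table must have herb/ingredient/target columns")
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    for (nm in need) {
        table[[nm]] <- as.character(table[[nm]])
        if (any(is.na(table[[nm]]) | !nzchar(trimws(table[[nm]]))))
            stop("blank fields in column '", nm, "'")
    }
    table$target <- toupper(table$target)
    table
}

#' Build the ingredient-target bipartite network
#'
#' One edge per distinct (ingredient, target) pair; duplicated rows collapse.
#' Node class is carried in the igraph `type` attribute (FALSE = ingredient,
#' TRUE = target), so the graph is bipartite by construction.
#'
#' @param table data.frame with columns `herb`, `ingredient`, `target`.
#' @return A bipartite `igraph` graph.
#' @export
buildBipartite <- function(table) {
    table <- .check_drug_table(table)
    if (!nrow(table)) stop("empty herb-ingredient-target table")
    pairs <- unique(table[, c("ingredient", "target")])
    verts <- data.frame(
        name = c(unique(pairs$ingredient), unique(pairs$target)),
        type = c(rep(FALSE, length(unique(pairs$ingredient))),
                 rep(TRUE, length(unique(pairs$target)))))
    igraph::graph_from_data_frame(pairs, directed = FALSE, vertices = verts)
}
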