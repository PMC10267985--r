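#' Read an undirected edge list
#'
#' Two tab-separated columns of gene symbols; lines starting with `#` are
#' comments. A header line is detected when the first line equals
#' `from<TAB>to`.
#'
#' @param path file path.
#' @return An [Interactome].
#' @export
readEdgeList <- function(path) {
    first <- readLines(path, n = 1)
    header <- identical(tolower(trimws(first)), "from\tto")
    df <- read.delim(path, header = header, comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("edge list must have two columns")
    Interactome(df[, 1:2])
}

#' Write an undirected edge list
#' @param x an [Interactome] or [ExpandedNetwork].
#' @param path output path (tab-separated, header `from`/`to`).
#' @return Invisibly, `path`.
#' @export
writeEdgeList <- function(x, path) {
    write.table(edgeTable(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read an expression study from TSV
#'
#' @param expr_path genes x samples matrix, first column gene symbols,
#'   header row of sample ids.
#' @param groups_path two-column TSV (sample, group) mapping each sample to
#'   `tumor` or `normal`.
#' @param study_id identifier; defaults to the expression file name.
#' @return An [ExpressionStudy].
#' @export
readExpressionStudy <- function(expr_path, groups_path,
                                study_id = basename(expr_path)) {
    m <- read.delim(expr_path, stringsAsFactors = FALSE, check.names = FALSE)
    vals <- as.matrix(m[, -1, drop = FALSE])
    rownames(vals) <- as.character(m[[1]])
    grp <- read.delim(groups_path, stringsAsFactors = FALSE)
    groups <- setNames(as.character(grp[[2]]), as.character(grp[[1]]))
    ExpressionStudy(vals, groups, study_id = study_id)
}

#' Write an expression study (matrix + group sidecar)
#' @param study an [ExpressionStudy].
#' @param expr_path,groups_path output paths.
#' @return Invisibly, `expr_path`.
#' @export
writeExpressionStudy <- function(study, expr_path, groups_path) {
    vals <- SummarizedExperiment::assay(study, "log2")
    df <- data.frame(gene = rownames(vals), vals, check.names = FALSE)
    write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
    grp <- data.frame(sample = colnames(vals),
                      group = as.character(
                          SummarizedExperiment::colData(study)$group))
    write.table(grp, groups_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(expr_path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param path GMT file.
#' @param universe optional explicit background; defaults to the union of
#'   all member genes.
#' @return A [GeneSetCollection].
#' @export
readGmt <- function(path, universe = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 1L) < 3
    if (any(bad)) stop("malformed GMT line(s): ", sum(bad))
    sets <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(sets) <- vapply(parts, `[`, "", 1L)
    desc <- setNames(vapply(parts, `[`, "", 2L), names(sets))
    GeneSetCollection(sets, descriptions = desc, universe = universe)
}

#' Write a gene-set collection in GMT format
#' @param coll a [GeneSetCollection].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeGmt <- function(coll, path) {
    lines <- vapply(names(geneSets(coll)), function(nm) {
        paste(c(nm, coll@descriptions[[nm]], geneSets(coll)[[nm]]),
              collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a herb-ingredient-target table (TSV with header)
#' @param path TSV with columns `herb`, `ingredient`, `target`.
#' @return data.frame.
#' @export
readDrugTable <- function(path) {
    .check_drug_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a patient-level survival table
#' @param path TSV with columns `id`, `time_days`, `event`, `arm`.
#' @return data.frame.
#' @export
readSurvivalTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "time_days", "event", "arm")
    if (!all(need %in% colnames(df)))
        stop("survival table must have columns ", paste(need, collapse = ", "))
    df
}
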