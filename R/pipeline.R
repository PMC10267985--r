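.with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
        stop(simpleError(paste0("stage '", stage, "': ", conditionMessage(e))))
    })
}

#' Run the full screening pipeline on synthetic (or supplied) inputs
#'
#' Executes, in order: drug-target pooling, per-study differential
#' expression with multi-study intersection, first-neighbour expansion of
#' both target sets on the background interactome, intersection-merge of the
#' two expanded networks, the two-stage median-adaptive centrality cascade,
#' and gene-set enrichment of the resulting core. Any stage that produces an
#' empty result aborts with a stage-named error.
#'
#' Inputs default to the synthetic generators driven by `cfg`; any element
#' of `inputs` (`interactome`, `studies`, `drug_table`, `collection`)
#' overrides the corresponding generator, so the same orchestration runs on
#' real data. When no collection is supplied one is simulated *after*
#' screening, planting its enriched terms around the discovered core (the
#' collection is an input emulation, not a result).
#'
#' @param cfg a [simConfig()]; its `seed` makes the whole run deterministic.
#' @param de a [deConfig()] for the differential-expression stage.
#' @param alpha_enrich raw-p significance level for enrichment.
#' @param depth seed-expansion depth (default 1, direct interactors).
#' @param inputs optional named list of pre-built inputs (see above).
#' @param outdir if non-NULL, write all artifacts (edge lists, tables, GMT,
#'   `report.json`) into this directory.
#' @return A [RunReport].
#' @examples
#' \donttest{
#' rep <- runPipeline(simConfig(seed = 1))
#' runCounts(rep)$core_nodes
#' }
#' @export
runPipeline <- function(cfg = simConfig(), de = deConfig(),
                        alpha_enrich = 0.05, depth = 1L,
                        inputs = list(), outdir = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    background <- .with_stage("interactome",
        if (!is.null(inputs$interactome)) inputs$interactome
        else simInteractome(cfg))

    drug_in <- .with_stage("drug_table",
        if (!is.null(inputs$drug_table))
            list(table = inputs$drug_table, truth = NULL)
        else simDrugTable(cfg, background))
    drug_ts <- .with_stage("pool_targets", poolTargets(drug_in$table))

    studies <- .with_stage("expression",
        if (!is.null(inputs$studies)) lapply(inputs$studies,
                                             function(s) list(study = s))
        else lapply(seq_len(cfg$n_studies),
                    function(i) simExpression(cfg, i)))
    de_res <- .with_stage("de_test",
        lapply(studies, function(s) deTest(s$study, de)))
    disease_ts <- .with_stage("intersect_targets", {
        ts <- intersectTargets(de_res)
        if (!length(ts)) stop("empty result: no gene passed in all studies")
        ts
    })

    drug_net <- .with_stage("expand_drug",
        expandSeeds(background, drug_ts, depth = depth))
    disease_net <- .with_stage("expand_disease",
        expandSeeds(background, disease_ts, depth = depth))
    merged <- .with_stage("merge", mergeNetworks(drug_net, disease_net))
    screen <- .with_stage("screen", screenCore(merged))

    coll <- .with_stage("genesets",
        if (!is.null(inputs$collection))
            list(collection = inputs$collection, truth = NULL)
        else simGeneSets(cfg, coreTargets(screen)))
    enr <- .with_stage("enrich",
        enrichTargets(coreTargets(screen), coll$collection,
                      alpha = alpha_enrich))

    counts <- list(
        drug_targets = length(drug_ts),
        disease_targets = length(disease_ts),
        background_nodes = numNodes(background),
        background_edges = numEdges(background),
        drug_net_nodes = numNodes(drug_net),
        drug_net_edges = numEdges(drug_net),
        disease_net_nodes = numNodes(disease_net),
        disease_net_edges = numEdges(disease_net),
        merged_nodes = numNodes(merged),
        merged_edges = numEdges(merged),
        key_nodes = numNodes(screen@stage1),
        key_edges = numEdges(screen@stage1),
        core_nodes = numNodes(screen@stage2),
        core_edges = numEdges(screen@stage2),
        significant_terms = sum(enr$significant),
        fallback = as.list(screenFallback(screen)))

    report <- new("RunReport", drugTargets = drug_ts,
                  diseaseTargets = disease_ts, drugNet = drug_net,
                  diseaseNet = disease_net, merged = merged, screen = screen,
                  enrichment = enr, counts = counts,
                  config = unclass(cfg))
    truth <- list(de_genes = studies[[1]]$truth$de_genes,
                  hub_targets = drug_in$truth$hub_targets,
                  planted_enriched_terms = coll$truth$planted_enriched_terms)
    attr(report, "truth") <- truth
    if (!is.null(outdir)) .write_run(report, studies, coll, truth, outdir)
    report
}

.write_run <- function(report, studies, coll, truth, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeEdgeList(Interactome(edgeTable(report@merged)),
                  file.path(outdir, "merged.tsv"))
    writeEdgeList(report@screen@stage2, file.path(outdir, "core.tsv"))
    for (i in seq_along(studies)) {
        if (is.null(studies[[i]]$study)) next
        writeExpressionStudy(studies[[i]]$study,
                             file.path(outdir, sprintf("expr%d.tsv", i)),
                             file.path(outdir,
                                       sprintf("expr%d.groups.tsv", i)))
    }
    writeGmt(coll$collection, file.path(outdir, "genesets.gmt"))
    wt <- function(df, nm) write.table(df, file.path(outdir, nm), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
    wt(data.frame(gene = targetGenes(report@drugTargets)),
       "drug_targets_pooled.tsv")
    wt(data.frame(gene = targetGenes(report@diseaseTargets)),
       "disease_targets.tsv")
    enr <- report@enrichment
    enr$overlap <- vapply(enr$overlap, paste, "", collapse = ",")
    wt(enr, "enrichment.tsv")
    jsonlite::write_json(
        list(counts = report@counts,
             thresholds = lapply(screenThresholds(report@screen), as.list),
             config = report@config),
        file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
    if (length(truth))
        jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                             auto_unbox = FALSE)
    invisible(outdir)
}
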