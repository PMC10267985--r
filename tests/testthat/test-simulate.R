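test_that("preferential-attachment growth with m = 1 yields a connected tree", {
    cfg <- simConfig(seed = 7, n_genes = 50, n_interactome_nodes = 10,
                     attachment_edges = 1)
    g <- simInteractome(cfg)
    expect_equal(numNodes(g), 10)
    expect_equal(numEdges(g), 9)
    expect_true(igraph::is_connected(asIgraph(g)))
})

test_that("generators are byte-identical under the same configuration", {
    cfg <- simConfig(seed = 11, n_genes = 300, n_interactome_nodes = 120)
    expect_identical(edgeTable(simInteractome(cfg)),
                     edgeTable(simInteractome(cfg)))
    e1 <- simExpression(cfg, 2); e2 <- simExpression(cfg, 2)
    expect_identical(SummarizedExperiment::assay(e1$study, "log2"),
                     SummarizedExperiment::assay(e2$study, "log2"))
    g <- simInteractome(cfg)
    expect_identical(simDrugTable(cfg, g)$table, simDrugTable(cfg, g)$table)
    expect_identical(simSurvival(cfg), simSurvival(cfg))
    expect_identical(geneSets(simGeneSets(cfg, c("G000001"))$collection),
                     geneSets(simGeneSets(cfg, c("G000001"))$collection))
})

test_that("scale-free interactome has a heavy-tailed degree distribution", {
    g <- simInteractome(simConfig(seed = 1, n_genes = 600,
                                  n_interactome_nodes = 500,
                                  attachment_edges = 3))
    deg <- igraph::degree(asIgraph(g))
    expect_gte(max(deg), 5 * median(deg))
})

test_that("generated tables reference only symbols from the gene universe", {
    cfg <- simConfig(seed = 3, n_genes = 200, n_interactome_nodes = 80)
    universe <- simGeneUniverse(cfg)
    g <- simInteractome(cfg)
    expect_true(all(nodeNames(g) %in% universe))
    dt <- simDrugTable(cfg, g)
    expect_true(all(dt$table$target %in% universe))
    expect_true(all(dt$truth$hub_targets %in% nodeNames(g)))
    gs <- simGeneSets(cfg, nodeNames(g)[1:10])
    expect_true(all(unlist(geneSets(gs$collection)) %in% universe))
    es <- simExpression(cfg, 1)
    expect_true(all(rownames(es$study) %in% universe))
    expect_true(all(es$truth$de_genes %in% universe))
})

test_that("de_fraction = 0 plants no differential expression", {
    sim <- simExpression(simConfig(seed = 5, n_genes = 100,
                                   n_interactome_nodes = 50,
                                   de_fraction = 0))
    expect_length(sim$truth$de_genes, 0)
})

test_that("planted DE signs are shared across studies", {
    cfg <- simConfig(seed = 9, n_genes = 400, n_interactome_nodes = 100)
    s1 <- simExpression(cfg, 1); s2 <- simExpression(cfg, 2)
    expect_identical(s1$truth$de_genes, s2$truth$de_genes)
    expect_identical(s1$truth$sign, s2$truth$sign)
})

test_that("drug table has the configured shape and hub_bias extremes behave", {
    cfg <- simConfig(seed = 2, n_genes = 300, n_interactome_nodes = 200,
                     n_herbs = 6, ingredients_per_herb = 4,
                     targets_per_ingredient = 5)
    g <- simInteractome(cfg)
    dt <- simDrugTable(cfg, g)
    expect_equal(nrow(dt$table), 6 * 4 * 5)
    expect_gte(length(unique(dt$table$ingredient)), 24)
    dt0 <- simDrugTable(simConfig(seed = 2, n_genes = 300,
                                  n_interactome_nodes = 200, hub_bias = 0), g)
    expect_length(dt0$truth$hub_targets, 0)
    dt1 <- simDrugTable(simConfig(seed = 2, n_genes = 300,
                                  n_interactome_nodes = 200, hub_bias = 1,
                                  targets_per_ingredient = 5), g)
    deg <- igraph::degree(asIgraph(g))
    decile <- nodeNames(g)[order(-deg)][seq_len(ceiling(numNodes(g) / 10))]
    expect_true(all(dt1$table$target %in% decile))
})

test_that("gene-set generation rejects sets larger than the universe", {
    cfg <- simConfig(seed = 1, n_genes = 10, n_interactome_nodes = 5,
                     geneset_size = 11)
    expect_error(simGeneSets(cfg, "G000001"), "geneset_size")
})

test_that("planted gene sets over-sample the core-like set, others do not", {
    cfg <- simConfig(seed = 4, n_genes = 500, n_interactome_nodes = 100,
                     n_genesets = 20, geneset_size = 20,
                     n_planted_enriched = 3)
    core <- sprintf("G%06d", 1:40)
    gs <- simGeneSets(cfg, core)
    planted <- gs$truth$planted_enriched_terms
    frac <- vapply(geneSets(gs$collection),
                   function(s) mean(s %in% core), 1)
    expect_true(all(frac[planted] >= 0.5))
    expect_lt(mean(frac[setdiff(names(frac), planted)]), 0.3)
})

test_that("survival generator honours arm sizes and censoring", {
    cfg <- simConfig(seed = 6, surv_n_per_arm = 30)
    d <- simSurvival(cfg)
    expect_equal(unname(table(d$arm)[c("exposure", "nonexposure")]),
                 c(30L, 30L), ignore_attr = TRUE)
    expect_true(all(d$event == 1))
    dc <- simSurvival(simConfig(seed = 6, surv_n_per_arm = 30,
                                surv_censor_max = 100))
    expect_true(any(dc$event == 0))
    expect_true(all(dc$time_days <= pmax(100, dc$time_days * (dc$event == 1))))
})

test_that("all-censored input is handled and flags the undefined median", {
    km <- kmCurve(c(10, 20, 30), event = c(0, 0, 0))
    expect_false(km$median_defined)
    expect_true(is.na(km$median))
})

test_that("degenerate configurations are rejected", {
    expect_error(simConfig(n_interactome_nodes = 3, attachment_edges = 3),
                 "configuration error")
    expect_error(simConfig(noise_sd = 0), "configuration error")
    expect_error(simConfig(de_fraction = 1.2), "configuration error")
    expect_error(simConfig(surv_hazard_ratio = -1), "configuration error")
    expect_error(simConfig(n_tumor = 1), "configuration error")
})
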