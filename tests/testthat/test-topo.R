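test_that("path-graph centralities match hand values", {
    ct <- centralities(path_graph(c("A", "B", "C")))
    tab <- centralityTable(ct)
    expect_equal(tab$dc, c(1, 2, 1))
    expect_equal(tab$bc, c(0, 1, 0))     # denominator (3-1)(3-2)/2 = 1
    expect_equal(tab$cc, c(2/3, 1, 2/3), tolerance = 1e-12)
    expect_equal(unname(centralityMedians(ct)["dc"]), 1)
})

test_that("complete-graph symmetry: K4 has bc 0, cc 1, dc 3 everywhere", {
    k4 <- Interactome(t(utils::combn(c("A", "B", "C", "D"), 2)))
    tab <- centralityTable(centralities(k4))
    expect_equal(tab$dc, rep(3, 4))
    expect_equal(tab$bc, rep(0, 4))
    expect_equal(tab$cc, rep(1, 4))
})

test_that("centralities match the exhaustive path-enumeration oracle", {
    set.seed(71)
    for (i in 1:25) {
        n <- sample(4:8, 1)
        a <- random_connected_adj(n)
        labels <- sprintf("N%d", seq_len(n))
        dimnames(a) <- list(labels, labels)
        g <- Interactome(t(apply(which(upper.tri(a) & a > 0, arr.ind = TRUE),
                                 1, function(ij) labels[ij])))
        tab <- centralityTable(centralities(g))
        tab <- tab[match(labels, tab$node), ]
        o <- oracle_centralities(a)
        expect_equal(tab$dc, unname(o$dc), tolerance = 1e-10)
        expect_equal(tab$bc, unname(o$bc), tolerance = 1e-10)
        expect_equal(tab$cc, unname(o$cc), tolerance = 1e-10)
    }
})

test_that("degree sum, leaf betweenness and value ranges hold on random graphs", {
    cfg <- simConfig(seed = 72, n_genes = 300, n_interactome_nodes = 250)
    g <- simInteractome(cfg)
    tab <- centralityTable(centralities(g))
    expect_equal(sum(tab$dc), 2 * numEdges(g))
    expect_true(all(tab$bc[tab$dc == 1] == 0))
    expect_true(all(tab$bc >= 0 & tab$bc <= 1))
    expect_true(all(tab$cc > 0 & tab$cc <= 1))
})

test_that("disconnected graphs are rejected with guidance", {
    g <- Interactome(rbind(c("A", "B"), c("X", "Y")))
    expect_error(centralities(g), "disconnected")
})

test_that("star screening keeps the hub; trivial thresholds keep everything", {
    star <- Interactome(cbind("HUB", paste0("L", 1:4)))
    s <- screenStage(star, c(dc = 2))  # 2 x median degree (median 1)
    expect_equal(nodeNames(s$network), "HUB")
    expect_false(s$fallback)
    id <- screenStage(star, c(dc = -Inf, bc = -Inf, cc = -Inf))
    expect_setequal(nodeNames(id$network), nodeNames(star))
    expect_error(screenStage(star, c(eigen = 1)), "configuration error")
})

test_that("retained sets shrink monotonically as thresholds rise", {
    g <- simInteractome(simConfig(seed = 73, n_genes = 250,
                                  n_interactome_nodes = 200))
    prev <- nodeNames(g)
    for (t in c(2, 4, 8, 16)) {
        s <- screenStage(g, c(dc = t))
        if (!s$fallback) {
            expect_true(all(nodeNames(s$network) %in% prev))
            prev <- nodeNames(s$network)
        }
    }
})

test_that("two-stage cascade on a star falls back to the hub at stage 2", {
    star <- Interactome(cbind("HUB", paste0("L", 1:4)))
    rep <- screenCore(star)
    expect_equal(nodeNames(screenStageNetwork(rep, "stage1")), "HUB")
    expect_equal(coreTargets(rep), "HUB")
    expect_false(screenFallback(rep)[["stage1"]])
    expect_true(screenFallback(rep)[["stage2"]])
})

test_that("a regular graph falls back at stage 1 unchanged", {
    c6 <- Interactome(cbind(paste0("V", 1:6), paste0("V", c(2:6, 1))))
    rep <- screenCore(c6)
    expect_true(screenFallback(rep)[["stage1"]])
    expect_setequal(nodeNames(screenStageNetwork(rep, "stage1")),
                    paste0("V", 1:6))
})

test_that("cascade output nests: stage2 within stage1 within input", {
    g <- simInteractome(simConfig(seed = 74, n_genes = 500,
                                  n_interactome_nodes = 400))
    rep <- screenCore(g)
    s1 <- nodeNames(screenStageNetwork(rep, "stage1"))
    s2 <- coreTargets(rep)
    expect_true(all(s2 %in% s1))
    expect_true(all(s1 %in% nodeNames(screenStageNetwork(rep, "input"))))
    thr <- screenThresholds(rep)
    expect_named(thr$stage2, c("dc", "bc", "cc"))
    # stage-1 threshold really is twice the input median degree
    ct <- centralities(screenStageNetwork(rep, "input"))
    expect_equal(unname(thr$stage1[["dc"]]),
                 2 * unname(centralityMedians(ct)[["dc"]]))
})

test_that("the screened core is strongly hub-enriched on scale-free graphs", {
    cfg <- simConfig(seed = 75, hub_bias = 1)
    rep <- suppressMessages(runPipeline(cfg))
    truth <- attr(rep, "truth")
    core <- coreTargets(rep)
    # nearly every core node is a planted hub target (high precision) ...
    expect_gte(mean(core %in% truth$hub_targets), 0.8)
    # ... and recovery beats the uniform-draw baseline many-fold
    baseline <- length(core) / runCounts(rep)$background_nodes
    expect_gte(mean(truth$hub_targets %in% core), 5 * baseline)
})
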