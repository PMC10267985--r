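make_study <- function(tumor, normal, genes = NULL) {
    m <- rbind(cbind(tumor, normal))
    if (is.null(dim(tumor))) m <- matrix(c(tumor, normal), nrow = 1)
    if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
    rownames(m) <- genes
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    ExpressionStudy(m, c(rep("tumor", if (is.null(dim(tumor))) length(tumor)
                                      else ncol(tumor)),
                         rep("normal", if (is.null(dim(normal))) length(normal)
                                       else ncol(normal))))
}

test_that("a three-fold shifted gene is called with the expected log2FC", {
    st <- make_study(matrix(rep(c(5.0, 5.1, 4.9), 2), 2, byrow = TRUE),
                     matrix(rep(c(2.0, 2.1, 1.9), 2), 2, byrow = TRUE))
    res <- deTest(st)
    expect_equal(res$log2fc, c(3, 3), tolerance = 1e-12)
    expect_lt(res$p[1], 0.001)
    expect_true(all(res$passed))
})

test_that("identical groups give log2fc 0 and no call", {
    v <- matrix(rnorm(40, 6), 4)
    st <- make_study(v[, 1:5], v[, 1:5])
    res <- deTest(st)
    expect_equal(res$log2fc, rep(0, 4))
    expect_false(any(res$passed))
})

test_that("zero-variance-in-both-groups genes get p = 1 and a flag", {
    m <- rbind(rep(c(1, 2), each = 3), matrix(rnorm(18), 3))
    st <- make_study(m[, 1:3], m[, 4:6])
    m2 <- SummarizedExperiment::assay(st, "log2")
    # first gene is constant within each group
    res <- deTest(st)
    flat <- res[res$gene == res$gene[which(res$zero_var)][1], ]
    expect_equal(flat$p, 1)
    expect_true(flat$zero_var)
})

test_that("BH adjustment keeps adj_p >= p and monotone along the p rank", {
    sim <- simExpression(simConfig(seed = 8, n_genes = 500,
                                   n_interactome_nodes = 100))
    res <- deTest(sim$study)
    expect_true(all(res$adj_p >= res$p - 1e-15))
    ord <- order(res$p)
    expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
})

test_that("p-values agree with t.test for both test variants", {
    set.seed(42)
    m <- matrix(rnorm(20 * 12, 7), 20)
    rownames(m) <- sprintf("g%02d", 1:20)
    st <- ExpressionStudy(m, rep(c("tumor", "normal"), each = 6))
    for (tst in c("student_t", "welch_t")) {
        res <- deTest(st, deConfig(test = tst))
        ref <- apply(m, 1, function(x)
            t.test(x[1:6], x[7:12], var.equal = tst == "student_t")$p.value)
        expect_equal(res$p, unname(ref[res$gene]), tolerance = 1e-12)
    }
})

test_that("the raw-p preset changes which genes pass", {
    sim <- simExpression(simConfig(seed = 13, n_genes = 400,
                                   n_interactome_nodes = 100,
                                   de_log2fc = 1.2))
    adj <- deTest(sim$study, deConfig())
    raw <- deTest(sim$study, deConfig(alpha = 0.01, p_column = "raw"))
    # both rules respect their own definition
    expect_true(all(abs(adj$log2fc[adj$passed]) >= 1))
    expect_true(all(raw$p[raw$passed] < 0.01))
})

test_that("groups with fewer than two samples are rejected", {
    m <- matrix(rnorm(8), 2, dimnames = list(c("a", "b"), NULL))
    expect_error(ExpressionStudy(m, c("tumor", "normal", "normal", "normal")),
                 "2 samples")
})

test_that("duplicate gene rows collapse to the strongest effect", {
    m <- rbind(c(5, 5, 5, 1, 1, 1), c(2, 2, 2, 1, 1, 1))
    rownames(m) <- c("GX", "GX")
    colnames(m) <- sprintf("s%d", 1:6)
    st <- ExpressionStudy(m, rep(c("tumor", "normal"), each = 3))
    expect_equal(nrow(st), 1)
    expect_equal(unname(SummarizedExperiment::assay(st, "log2")[1, 1]), 5)
})

test_that("intersection keeps exactly the genes passing in all studies", {
    mk <- function(genes_pass, all_genes, sid) {
        r <- data.frame(gene = all_genes, log2fc = 2, p = 0.5, adj_p = 0.5,
                        passed = all_genes %in% genes_pass, zero_var = FALSE)
        attr(r, "study_id") <- sid
        class(r) <- c("DEResult", "data.frame")
        r
    }
    u <- c("A", "B", "C", "D")
    r1 <- mk(c("A", "B"), u, "s1"); r2 <- mk(c("B", "C"), u, "s2")
    ts <- intersectTargets(list(r1, r2))
    expect_equal(targetGenes(ts), "B")
    expect_equal(targetSupport(ts)$B, c("s1:up", "s2:up"))
    # order-invariant and idempotent
    expect_equal(targetGenes(intersectTargets(list(r2, r1))), "B")
    expect_equal(targetGenes(intersectTargets(list(r1, r1, r2))), "B")
    # single study: identity on its passing set
    expect_equal(sort(targetGenes(intersectTargets(list(r1)))), c("A", "B"))
    expect_error(intersectTargets(list()), "at least one")
})
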