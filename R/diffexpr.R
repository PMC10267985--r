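#' Differential-expression screening configuration
#'
#' The fold-change threshold is on the linear scale (the test uses
#' |log2FC| >= log2(fc_threshold), so both up- and down-regulation count).
#' The p-value column the pass flag uses is configurable because published
#' screens vary between an adjusted cut (BH FDR < 0.05, the default here)
#' and a raw cut (often p < 0.01); `deConfig(alpha = 0.01, p_column = "raw")`
#' reproduces the latter.
#'
#' @param fc_threshold linear fold change >= 1 (default 2).
#' @param alpha significance level in (0,1) (default 0.05).
#' @param p_column `"adjusted"` (BH) or `"raw"`.
#' @param test `"student_t"` (pooled-variance two-sample t, the default: it
#'   is exactly calibrated under the homoscedastic noise model the simulator
#'   and most array pipelines assume, and with equal group sizes shares its
#'   statistic with Welch) or `"welch_t"` (Satterthwaite df; robust to
#'   unequal variances but slightly conservative in small samples).
#' @return A list of class `DEConfig`.
#' @export
deConfig <- function(fc_threshold = 2, alpha = 0.05,
                     p_column = c("adjusted", "raw"),
                     test = c("student_t", "welch_t")) {
    p_column <- match.arg(p_column)
    test <- match.arg(test)
    if (fc_threshold < 1) stop("fc_threshold must be >= 1")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
    structure(list(fc_threshold = fc_threshold, alpha = alpha,
                   p_column = p_column, test = test),
              class = "DEConfig")
}

# vectorised two-sample t over matrix rows (pooled or Welch)
.t_rows <- function(xt, xn, test = "student_t") {
    nt <- ncol(xt); nn <- ncol(xn)
    mt <- rowMeans(xt); mn <- rowMeans(xn)
    vt <- rowSums((xt - mt)^2) / (nt - 1)
    vn <- rowSums((xn - mn)^2) / (nn - 1)
    if (test == "welch_t") {
        se2 <- vt / nt + vn / nn
        zero <- se2 == 0
        df <- ifelse(zero, nt + nn - 2,
                     se2^2 / ((vt / nt)^2 / (nt - 1) +
                              (vn / nn)^2 / (nn - 1)))
    } else {
        sp2 <- ((nt - 1) * vt + (nn - 1) * vn) / (nt + nn - 2)
        se2 <- sp2 * (1 / nt + 1 / nn)
        zero <- se2 == 0
        df <- rep(nt + nn - 2, length(se2))
    }
    tstat <- ifelse(zero, 0, (mt - mn) / sqrt(se2))
    p <- ifelse(zero, 1, 2 * pt(-abs(tstat), df))
    list(log2fc = mt - mn, t = tstat, df = df, p = p, zero_var = zero)
}

#' Per-gene differential-expression test
#'
#' Two-sample t-test on log2 values (tumour vs normal; pooled-variance by
#' default, Welch optional — see [deConfig()]), two-sided,
#' with Benjamini-Hochberg adjustment over all tested genes. Genes with zero
#' variance in both groups cannot be tested and get p = 1 with `zero_var`
#' set. A gene passes when |log2FC| >= log2(fc_threshold) and the selected
#' p-column is below alpha.
#'
#' @param study an [ExpressionStudy] (>= 2 samples per group).
#' @param cfg a [deConfig()].
#' @return data.frame of class `DEResult` with columns `gene`, `log2fc`
#'   (tumour mean - normal mean), `p`, `adj_p`, `passed`, `zero_var`, plus
#'   attributes `study_id` and `config`.
#' @examples
#' sim <- simExpression(simConfig(seed = 1, n_genes = 100,
#'                                n_interactome_nodes = 50))
#' res <- deTest(sim$study)
#' table(res$passed)
#' @export
deTest <- function(study, cfg = deConfig()) {
    stopifnot(is(study, "ExpressionStudy"), inherits(cfg, "DEConfig"))
    validObject(study)
    vals <- SummarizedExperiment::assay(study, "log2")
    grp <- as.character(SummarizedExperiment::colData(study)$group)
    w <- .t_rows(vals[, grp == "tumor", drop = FALSE],
                 vals[, grp == "normal", drop = FALSE], test = cfg$test)
    adj_p <- p.adjust(w$p, method = "BH")
    p_used <- if (cfg$p_column == "adjusted") adj_p else w$p
    res <- data.frame(gene = rownames(vals), log2fc = w$log2fc,
                      p = w$p, adj_p = adj_p,
                      passed = abs(w$log2fc) >= log2(cfg$fc_threshold) &
                          p_used < cfg$alpha,
                      zero_var = w$zero_var,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(res, "study_id") <- studyId(study)
    attr(res, "config") <- cfg
    class(res) <- c("DEResult", "data.frame")
    res
}

#' Intersect per-study differential-expression calls into a disease TargetSet
#'
#' Keeps the genes that pass the screen in every supplied study; each kept
#' gene's support records the per-study regulation direction
#' (`"<study>:up"` / `"<study>:down"`).
#'
#' @param results list of `DEResult` data.frames from [deTest()].
#' @param name label for the resulting set.
#' @return A [TargetSet] with provenance `"disease"`.
#' @export
intersectTargets <- function(results, name = "disease") {
    if (!length(results)) stop("at least one DE result required")
    if (inherits(results, "DEResult")) results <- list(results)
    passed <- lapply(results, function(r) r$gene[r$passed])
    common <- Reduce(intersect, passed)
    support <- setNames(vector("list", length(common)), common)
    for (r in results) {
        sid <- attr(r, "study_id")
        if (is.null(sid)) sid <- "study"
        hit <- r[match(common, r$gene), ]
        dir <- ifelse(hit$log2fc >= 0, "up", "down")
        for (i in seq_along(common))
            support[[i]] <- c(support[[i]], paste0(sid, ":", dir[i]))
    }
    TargetSet(common, name = name, provenance = "disease", support = support)
}
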