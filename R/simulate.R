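#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generators. A single
#' integer `seed` drives all of them; each generator derives its own child
#' seed deterministically (seed + a fixed offset), so the same configuration
#' always yields byte-identical outputs while the generators stay independent
#' of the order in which they are called.
#'
#' Defaults describe a desk-scale study: a gene universe of 2,000 symbols, a
#' 1,500-node scale-free interactome grown with 3 edges per node, three
#' expression studies of 10 tumour vs 10 normal samples with 10% of genes
#' differentially expressed at |log2FC| = 3 over noise sd 0.3, a six-herb
#' prescription with 4 ingredients each and 25 targets per ingredient, and a
#' two-arm cohort of 50 patients per arm with hazard ratio 0.62.
#'
#' @param seed integer master seed.
#' @param n_genes size of the gene universe (symbols `G000001`...).
#' @param n_interactome_nodes nodes of the background interactome
#'   (must be <= `n_genes` and > `attachment_edges`).
#' @param attachment_edges edges added per new node during preferential
#'   attachment growth (>= 1).
#' @param n_tumor,n_normal samples per group in each expression study (>= 2).
#' @param n_studies number of expression studies sharing the planted core.
#' @param de_fraction fraction of genes differentially expressed, in [0,1].
#' @param de_log2fc planted shift of the tumour mean, log2 units; the sign is
#'   random per gene but fixed across studies.
#' @param noise_sd log2-scale noise standard deviation (> 0).
#' @param n_herbs,ingredients_per_herb,targets_per_ingredient shape of the
#'   herb-ingredient-target table.
#' @param hub_bias fraction of each ingredient's targets drawn from the
#'   top-decile-degree interactome nodes (remainder uniform), in [0,1].
#' @param n_genesets,geneset_size,n_planted_enriched gene-set collection
#'   shape; planted terms draw >= 50% of members from a core-like set.
#' @param surv_n_per_arm patients per survival arm.
#' @param surv_hazard_ratio treated/control hazard ratio (> 0); control event
#'   times are exponential with median 250 days.
#' @param surv_censor_max if finite, censoring times are Uniform(0, this)
#'   days; `NA` disables censoring.
#' @return A validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, n_interactome_nodes = 100, n_genes = 200)
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 2000L,
                      n_interactome_nodes = 1500L,
                      attachment_edges = 3L,
                      n_tumor = 10L, n_normal = 10L, n_studies = 3L,
                      de_fraction = 0.1, de_log2fc = 3, noise_sd = 0.3,
                      n_herbs = 6L, ingredients_per_herb = 4L,
                      targets_per_ingredient = 25L, hub_bias = 0.3,
                      n_genesets = 50L, geneset_size = 20L,
                      n_planted_enriched = 5L,
                      surv_n_per_arm = 50L, surv_hazard_ratio = 0.62,
                      surv_censor_max = NA_real_) {
    cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                n_interactome_nodes = as.integer(n_interactome_nodes),
                attachment_edges = as.integer(attachment_edges),
                n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                n_studies = as.integer(n_studies),
                de_fraction = de_fraction, de_log2fc = de_log2fc,
                noise_sd = noise_sd, n_herbs = as.integer(n_herbs),
                ingredients_per_herb = as.integer(ingredients_per_herb),
                targets_per_ingredient = as.integer(targets_per_ingredient),
                hub_bias = hub_bias, n_genesets = as.integer(n_genesets),
                geneset_size = as.integer(geneset_size),
                n_planted_enriched = as.integer(n_planted_enriched),
                surv_n_per_arm = as.integer(surv_n_per_arm),
                surv_hazard_ratio = surv_hazard_ratio,
                surv_censor_max = surv_censor_max)
    counts <- c("n_genes", "n_interactome_nodes", "attachment_edges",
                "n_tumor", "n_normal", "n_studies", "n_herbs",
                "ingredients_per_herb", "targets_per_ingredient",
                "n_genesets", "geneset_size", "surv_n_per_arm")
    for (nm in counts)
        if (cfg[[nm]] < 1L) stop("configuration error: ", nm, " must be >= 1")
    if (cfg$n_planted_enriched < 0L || cfg$n_planted_enriched > cfg$n_genesets)
        stop("configuration error: n_planted_enriched out of range")
    if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
        stop("configuration error: de_fraction must lie in [0,1]")
    if (cfg$hub_bias < 0 || cfg$hub_bias > 1)
        stop("configuration error: hub_bias must lie in [0,1]")
    if (cfg$noise_sd <= 0)
        stop("configuration error: noise_sd must be > 0")
    if (cfg$surv_hazard_ratio <= 0)
        stop("configuration error: surv_hazard_ratio must be > 0")
    if (cfg$n_interactome_nodes <= cfg$attachment_edges)
        stop("configuration error: n_interactome_nodes must exceed attachment_edges")
    if (cfg$n_interactome_nodes > cfg$n_genes)
        stop("configuration error: interactome larger than gene universe")
    if (cfg$n_tumor < 2L || cfg$n_normal < 2L)
        stop("configuration error: need >= 2 samples per group")
    class(cfg) <- "SimConfig"
    cfg
}

# fixed child-seed offsets; order of generator calls never matters
.child_seed <- function(cfg, what, index = 0L) {
    off <- c(universe = 900L, interactome = 1000L, planted = 1900L,
             expression = 2000L, drug = 3000L, genesets = 4000L,
             survival = 5000L)
    cfg$seed + off[[what]] + as.integer(index)
}

#' Gene universe of a simulation
#'
#' Synthetic uppercase symbols `G000001 ... G<n_genes>`; the interactome node
#' set and all generated tables draw from this universe only.
#'
#' @param cfg a [simConfig()].
#' @return Character vector of `n_genes` symbols.
#' @export
simGeneUniverse <- function(cfg) {
    sprintf("G%06d", seq_len(cfg$n_genes))
}

# planted DE structure is shared across studies so the multi-study
# intersection has a non-degenerate core
.planted_de <- function(cfg) {
    n_de <- round(cfg$de_fraction * cfg$n_genes)
    if (n_de == 0)
        return(list(genes = character(0), sign = numeric(0)))
    universe <- simGeneUniverse(cfg)
    set.seed(.child_seed(cfg, "planted"))
    genes <- sort(sample(universe, n_de))
    sign <- sample(c(-1, 1), n_de, replace = TRUE)
    list(genes = genes, sign = setNames(sign, genes))
}

#' Generate a scale-free background interactome
#'
#' Grows an undirected simple graph by preferential attachment
#' (Barabasi-Albert style: each new node attaches `attachment_edges` edges,
#' preferring high-degree nodes), then labels the nodes with a random subset
#' of the gene universe. The result is connected with a heavy-tailed degree
#' distribution, the regime in which a median-adaptive centrality cascade is
#' meaningful.
#'
#' @param cfg a [simConfig()].
#' @return An [Interactome] with `n_interactome_nodes` nodes.
#' @examples
#' g <- simInteractome(simConfig(seed = 7, n_interactome_nodes = 10,
#'                               attachment_edges = 1, n_genes = 50))
#' numEdges(g)  # m = 1 growth yields a tree: n - 1 edges
#' @export
simInteractome <- function(cfg) {
    set.seed(.child_seed(cfg, "interactome"))
    g <- igraph::sample_pa(cfg$n_interactome_nodes, m = cfg$attachment_edges,
                           directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(.child_seed(cfg, "universe"))
    igraph::V(g)$name <- sample(simGeneUniverse(cfg), cfg$n_interactome_nodes)
    new("Interactome", graph = g)
}

#' Generate one tumour/normal expression study
#'
#' Log2-scale values: every gene gets a study-specific baseline
#' N(8, 1.5^2) plus N(0, noise_sd^2) sample noise; for the planted
#' differentially expressed genes the tumour-group mean is shifted by
#' `de_log2fc` with a per-gene sign that is fixed across studies (so the
#' multi-study intersection recovers a common core).
#'
#' @param cfg a [simConfig()].
#' @param study_index which study (1 .. `n_studies`); changes baselines and
#'   noise but not the planted DE genes or their signs.
#' @return List with `study` (an [ExpressionStudy]) and `truth` (list with
#'   `de_genes` and per-gene `sign`).
#' @export
simExpression <- function(cfg, study_index = 1L) {
    planted <- .planted_de(cfg)
    universe <- simGeneUniverse(cfg)
    nt <- cfg$n_tumor; nn <- cfg$n_normal
    set.seed(.child_seed(cfg, "expression", study_index))
    baseline <- rnorm(cfg$n_genes, mean = 8, sd = 1.5)
    mu <- matrix(baseline, nrow = cfg$n_genes, ncol = nt + nn)
    if (length(planted$genes)) {
        idx <- match(planted$genes, universe)
        mu[idx, seq_len(nt)] <- mu[idx, seq_len(nt)] +
            planted$sign * cfg$de_log2fc
    }
    vals <- mu + matrix(rnorm(cfg$n_genes * (nt + nn), sd = cfg$noise_sd),
                        nrow = cfg$n_genes)
    sid <- sprintf("SYN%02d", study_index)
    colnames(vals) <- c(sprintf("%s_T%02d", sid, seq_len(nt)),
                        sprintf("%s_N%02d", sid, seq_len(nn)))
    rownames(vals) <- universe
    groups <- c(rep("tumor", nt), rep("normal", nn))
    list(study = ExpressionStudy(vals, groups, study_id = sid),
         truth = list(de_genes = planted$genes, sign = planted$sign))
}

#' Generate a herb-ingredient-target table
#'
#' Emulates pooled database output for a multi-herb prescription: each herb
#' contributes `ingredients_per_herb` ingredients and each ingredient
#' `targets_per_ingredient` targets. A `hub_bias` fraction of every
#' ingredient's targets is drawn from the top-decile-degree interactome nodes
#' (hubs), the remainder uniformly from all nodes; sampling is independent
#' across ingredients, so overlapping targets between ingredients arise
#' naturally.
#'
#' @param cfg a [simConfig()].
#' @param interactome the background [Interactome] targets are drawn from.
#' @return List with `table` (data.frame `herb`/`ingredient`/`target`) and
#'   `truth` (list with `hub_targets`, the hub-drawn symbols).
#' @export
simDrugTable <- function(cfg, interactome) {
    if (numNodes(interactome) == 0) stop("interactome is empty")
    deg <- igraph::degree(asIgraph(interactome))
    nodes <- nodeNames(interactome)
    hubs <- nodes[order(-deg)][seq_len(ceiling(length(nodes) / 10))]
    n_hub <- round(cfg$hub_bias * cfg$targets_per_ingredient)
    set.seed(.child_seed(cfg, "drug"))
    rows <- list()
    hub_drawn <- character(0)
    for (h in seq_len(cfg$n_herbs)) {
        for (i in seq_len(cfg$ingredients_per_herb)) {
            from_hub <- sample(hubs, min(n_hub, length(hubs)))
            rest <- sample(setdiff(nodes, from_hub),
                           cfg$targets_per_ingredient - length(from_hub))
            hub_drawn <- c(hub_drawn, from_hub)
            rows[[length(rows) + 1L]] <- data.frame(
                herb = sprintf("Herb%d", h),
                ingredient = sprintf("H%d_I%d", h, i),
                target = c(from_hub, rest), stringsAsFactors = FALSE)
        }
    }
    list(table = do.call(rbind, rows),
         truth = list(hub_targets = sort(unique(hub_drawn))))
}

#' Generate a gene-set collection with planted enriched terms
#'
#' `n_genesets` sets of `geneset_size` genes over the simulation's gene
#' universe. The first `n_planted_enriched` terms over-sample a supplied
#' core-like gene set (60% of members, i.e. >= 50%); all other members are
#' uniform draws from the universe.
#'
#' @param cfg a [simConfig()].
#' @param core_like a [TargetSet] or character vector the planted terms
#'   over-sample from.
#' @return List with `collection` (a [GeneSetCollection] whose universe is
#'   the simulation gene universe) and `truth` (list with
#'   `planted_enriched_terms`).
#' @export
simGeneSets <- function(cfg, core_like) {
    if (is(core_like, "TargetSet")) core_like <- targetGenes(core_like)
    universe <- simGeneUniverse(cfg)
    if (cfg$geneset_size > length(universe))
        stop("configuration error: geneset_size exceeds the gene universe")
    core_like <- intersect(core_like, universe)
    set.seed(.child_seed(cfg, "genesets"))
    sets <- vector("list", cfg$n_genesets)
    names(sets) <- sprintf("TERM%04d", seq_len(cfg$n_genesets))
    for (j in seq_len(cfg$n_genesets)) {
        if (j <= cfg$n_planted_enriched && length(core_like)) {
            k <- min(max(1L, round(0.6 * cfg$geneset_size)), length(core_like))
            from_core <- sample(core_like, k)
            rest <- sample(setdiff(universe, from_core),
                           cfg$geneset_size - k)
            sets[[j]] <- c(from_core, rest)
        } else {
            sets[[j]] <- sample(universe, cfg$geneset_size)
        }
    }
    planted <- names(sets)[seq_len(cfg$n_planted_enriched)]
    desc <- setNames(
        ifelse(names(sets) %in% planted, "planted enriched process",
               "background process"), names(sets))
    list(collection = GeneSetCollection(sets, descriptions = desc,
                                        universe = universe),
         truth = list(planted_enriched_terms = planted))
}

#' Generate a two-arm survival table
#'
#' Exponential event times: control (nonexposure) hazard
#' lambda = log(2)/250 per day (median survival 250 days), exposure hazard
#' lambda x `surv_hazard_ratio`. If `surv_censor_max` is finite, independent
#' Uniform(0, `surv_censor_max`) censoring is applied.
#'
#' @param cfg a [simConfig()].
#' @return data.frame with columns `id`, `time_days`, `event` (1 death,
#'   0 censored), `arm` (`exposure`/`nonexposure`).
#' @export
simSurvival <- function(cfg) {
    n <- cfg$surv_n_per_arm
    lambda0 <- log(2) / 250
    set.seed(.child_seed(cfg, "survival"))
    t_exp <- rexp(n, rate = lambda0 * cfg$surv_hazard_ratio)
    t_non <- rexp(n, rate = lambda0)
    time <- c(t_exp, t_non)
    event <- rep(1L, 2L * n)
    if (is.finite(cfg$surv_censor_max)) {
        cens <- runif(2L * n, 0, cfg$surv_censor_max)
        event <- as.integer(time <= cens)
        time <- pmin(time, cens)
    }
    data.frame(id = sprintf("P%03d", seq_len(2L * n)),
               time_days = time, event = event,
               arm = rep(c("exposure", "nonexposure"), each = n),
               stringsAsFactors = FALSE)
}
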