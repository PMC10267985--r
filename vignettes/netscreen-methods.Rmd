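---
title: "Methods: network-pharmacology core-target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology core-target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscreen)
```

# The screening model

Multi-herb prescriptions act through many ingredients hitting many proteins
at once, so candidate mechanism studies in this field converge on the same
screening scheme: collect the prescription's predicted protein targets,
collect the disease's differentially expressed genes, project both onto a
background protein–protein interactome, and mine the shared neighbourhood
for topologically central nodes. `netscreen` implements that scheme as six
composable stages (see `runPipeline()`), each usable on its own.

The statistical assumptions, stage by stage:

* **Drug-target pooling** (`poolTargets()`) is purely set-theoretic: the
  prescription's target set is the union over ingredients, deduplicated,
  with ingredient support retained. Overlap between ingredients is a
  *feature* (synergy candidates), not noise, and is reported.
* **Differential expression** (`deTest()`) models log2 expression as
  gene-wise normal with a group mean shift. The default test is the
  pooled-variance two-sample t: microarray-style log2 data are routinely
  modelled with a common within-group variance (the same assumption the
  moderated-t tools make), the pooled t is exactly calibrated under that
  model, and with equal group sizes its statistic coincides with Welch's —
  only the degrees of freedom differ. Welch's variant
  (`deConfig(test = "welch_t")`) is available for unequal-variance data; in
  small samples its Satterthwaite approximation is mildly conservative,
  which is why it is not the default. Multiplicity is handled by BH FDR
  over all tested genes. The pass rule is
  |log2FC| ≥ log2(`fc_threshold`) **and** p-column < `alpha`; both the
  column (adjusted vs raw) and `alpha` are configurable because published
  screens state both "adjusted p < 0.05" and "p < 0.01" conventions —
  `deConfig()` defaults to adjusted/0.05 and
  `deConfig(alpha = 0.01, p_column = "raw")` is the documented raw-p
  preset. Genes constant in both groups are untestable: they get p = 1 and
  a `zero_var` flag. Duplicate symbols (multi-probe genes) are collapsed
  before testing by keeping the row with the largest absolute group-mean
  difference — deterministic and conventional.
* **Intersection** (`intersectTargets()`) keeps genes passing in *all*
  studies, the strictest and most reproducible multi-study rule; per-study
  regulation direction is kept as provenance.
* **Seed expansion** (`expandSeeds()`) emulates seed-based PPI network
  construction: seeds plus their direct interactors (depth 1 by default,
  the behaviour implied by typical seed-to-network size ratios in published
  runs; `depth` is a knob). Seeds missing from the background are reported,
  not fatal — an expression platform always measures genes the interactome
  lacks.
* **Merging** (`mergeNetworks()`) uses node *intersection* with
  union-induced edges. Published merged networks of this kind are smaller
  than either input network, which only intersection semantics produce;
  the intersection is also the natural "relevant to both drug and disease"
  region. This is the one stage whose rule had to be inferred from printed
  network sizes rather than stated definitions, so it is called out
  prominently here.
* **Centrality cascade** (`screenCore()`): stage 1 keeps nodes with degree
  strictly above 2× the median degree; stage 2 recomputes degree,
  betweenness and closeness on the stage-1 network and keeps nodes strictly
  above all three medians. Thresholds are *median-adaptive* — derived from
  the data at hand, never hard-coded constants — so the cascade transfers
  across network scales.
* **Enrichment** (`enrichTargets()`) is the one-sided hypergeometric
  over-representation test P(X ≥ k), BH-adjusted across terms. The
  significance column uses the raw p < 0.05 convention of common annotation
  servers, with the FDR always reported next to it. The jackknifed EASE
  variant (k − 1 in the tail) is deliberately *not* used; this is a
  documented divergence from DAVID's default score. The default background
  is the union of the collection's genes — the DAVID-like choice when no
  explicit background is given — and an explicit universe can be passed.

# Numerical and convention choices

* **Centralities**: degree is the raw integer degree (published degree
  thresholds are integers); betweenness is Brandes' exact algorithm
  normalised by (n−1)(n−2)/2 (published betweenness thresholds are ≪ 1,
  implying normalisation); closeness is (n−1)/Σ distances. Medians use the
  average-of-middle-two convention for even n. Betweenness and closeness
  are only defined on connected graphs, so `centralities()` refuses
  disconnected input and `screenCore()` restricts to the largest connected
  component before each pass (logged). The centrality backend is verified
  in the test suite against an independent exhaustive shortest-path
  enumeration oracle on hundreds of small random graphs to 1e-10.
* **Strictness and ties**: all cascade cuts use strict `>` ("higher than");
  tied-at-threshold nodes are excluded.
* **Degenerate inputs**: if a strict cut would empty a network (a regular
  graph at stage 1, a single-node network at stage 2) the stage returns its
  input unchanged and sets a `fallback` flag in the `ScreenReport` — a
  pipeline never silently yields an empty core, and the flag makes the
  degeneracy auditable.
* **Graph hygiene**: self-loops and duplicate edges are dropped at
  `Interactome()` construction with a logged count; all graphs are simple
  and undirected.
* **KM median**: smallest observed time t with S(t) ≤ 0.5, stated
  explicitly because ties matter on small cohorts; if S never reaches 0.5
  the median is flagged undefined rather than guessed.
* **2×2 tests**: Pearson chi-square with Yates correction by default (the
  conservative convention for 2×2 tables); the uncorrected variant is a
  flag. Zero-margin tables are rejected with a pointer to exact tests.
* **Incidence display**: percentages round half-up to integers, matching
  clinical-table display (not R's round-half-even).
* **Configuration**: runs are configured by plain R objects
  (`simConfig()`, `deConfig()`) rather than a config-file dialect, and the
  machine-readable run report is JSON; both choices keep runs diffable and
  scriptable with no extra parsers. The package's functions are the
  interface; `scripts/acceptance.R` shows a complete scripted run.

# What the simulator emulates — and what it does not

`simConfig()` + the `sim*()` generators produce every pipeline input with
ground truth, under one master seed (child generators derive fixed seed
offsets, so outputs are byte-identical per configuration and independent of
call order).

* **Interactome**: preferential-attachment growth (`attachment_edges` = 3
  per node), giving the heavy-tailed degree distribution real interactomes
  have — the regime where a median-adaptive cascade is meaningful. Default
  1,500 nodes drawn from a 2,000-symbol universe: a background that covers
  most, not all, measured genes, as curated interactomes do.
* **Expression**: gene-wise normal baselines N(8, 1.5²) with N(0, 0.3²)
  noise on the log2 scale; 10 tumour vs 10 normal samples per study, three
  studies; 10% of genes differentially expressed with a ±3 log2-unit shift
  whose per-gene sign is fixed across studies, emulating consistent tumour
  biology so the multi-study intersection has a common planted core. These
  are clean-signal conditions (a t of ≈ 22 at the planted effect): they
  test the machinery's correctness, *not* its behaviour under realistic
  effect sizes. No probe-level structure, batch effects, normalisation
  artefacts or correlated genes are simulated — so passing recovery tests
  show the screen is implemented correctly, not that real microarray series
  would yield comparable recovery.
* **Drug tables**: six herbs × four ingredients × 25 targets, sized so the
  pooled set lands near the few-hundred-target scale of real prescription
  screens. `hub_bias` draws that fraction of each ingredient's targets from
  the top-degree decile of the interactome, emulating the well-known
  literature/curation bias of drug targets toward highly studied, highly
  connected proteins.
* **Gene sets**: 50 sets of 20 genes; planted enriched terms draw 60% of
  members from a supplied core-like set. In `runPipeline()` the collection
  is generated *after* screening, planted around the discovered core — the
  collection emulates an annotation input, not a result.
* **Survival**: exponential event times with control median 250 days
  (late-stage liver-cancer scale) and a configurable hazard ratio (default
  0.62); optional uniform censoring. No competing risks or
  non-proportional hazards.

# Known limitations

* The cascade is *selective by construction*: two strict median cuts retain
  roughly 5–10% of the merged network (in the synthetic default, a 40-node
  core from a 684-node merged network — the same shrinkage ratio real
  published chains show). A consequence worth stating plainly: any planted
  target group larger than the core — e.g. the full top-degree decile under
  `hub_bias = 1`, 10% of the interactome — cannot be recovered at high
  sensitivity *in the core* no matter how well the cascade ranks it. What
  the cascade does deliver, and what the tests verify, is precision: in
  hub-planted runs ~99% of core nodes are planted hubs, and recovery is
  many-fold above the uniform baseline, with stage-1 (key network)
  sensitivity around 65%. Users wanting sensitivity to a broad target class
  should read the key network, not the core.
* Exact reproduction of published target counts from this workflow family
  additionally requires the original databases' versions (ingredient-target
  predictions, interactome snapshot) and a moderated-t differential
  expression tool; those counts are treated as shape references (the
  monotone chain), not reproduction targets.
* The log-rank and KM utilities are two-arm summaries; Cox modelling,
  competing risks and stratified tests are out of scope.
* Printed p-values in clinical adverse-event tables often come from
  unstated test variants; the package reproduces the counts → percentages
  arithmetic exactly and the Yates chi-square statistic, but does not claim
  to match any particular printed p-value.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite exercises every stage in well under a half hour on one core:
a 1,500-node interactome (2,000-symbol universe) for pipeline runs, 100
null studies of 2,000 genes for type-I calibration, 10 seeds for
recovery-style properties, 20 seeds for enrichment ranking, exhaustive
oracles on graphs of ≤ 8 nodes and universes of ≤ 15 genes. All are
configuration values, not limits of the implementation; the cascade and
tests are O(nm) (Brandes) and run comfortably on networks of tens of
thousands of edges.
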