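# hccnet

Integrative network analysis for gene prioritization in hepatocellular
carcinoma (HCC), with expression-dichotomized survival validation.

HCC expression studies individually report long, poorly overlapping
lists of differentially expressed genes. `hccnet` is for computational
biologists who want to integrate many such studies and ask a different
question: among the genes *consistently* dysregulated across cohorts,
which ones occupy topologically critical positions in the physical
protein-interaction network? The package implements the full chain —
cross-study consensus voting, tissue-filtered network construction,
exact betweenness ranking, pathway over-representation, and
best-cutoff survival analysis — as tested, reusable functions, plus a
synthetic-data module that plants a known truth so every stage can be
verified end to end.

## The method

**Consensus voting.** Each study's DEG table is filtered: adjusted
p < 0.05 and tumor/non-tumor fold change FC ≤ 0.5 (down) or FC ≥ 1.5
(up), boundaries inclusive (a log2 mode with |log2FC| > 1 is also
provided). A gene with the same direction in ≥ 10 of 19 studies enters
the consensus set.

**Network ranking.** Consensus genes are mapped into a physical
interactome restricted to liver-expressed genes; seeds with at least
`min_degree` interactors (250 at full scale) are expanded to the
subgraph induced by the seeds and all their interaction partners.
Every node is scored by exact (Brandes) betweenness centrality

&nbsp;&nbsp;&nbsp;&nbsp; g(v) = Σ_{s≠t≠v} σ_st(v) / σ_st ,

the number of shortest s–t paths through v as a fraction of all
shortest s–t paths, summed over unordered pairs, unnormalized. The
top-ranked node is the headline candidate.

**Enrichment.** The consensus list is tested per pathway with a
one-sided hypergeometric test, P(X ≥ k) for X ~ Hypergeom(N, K, n),
with Benjamini–Hochberg FDR control across pathways.

**Survival.** A continuous marker is dichotomized at the best cutoff —
the candidate value between the expression quartiles minimizing the
log-rank p — and the groups are compared by Kaplan–Meier curves,
log-rank and Gehan–Breslow–Wilcoxon tests, and a proportional-hazards
hazard ratio (HR < 1: high expression protective) with 95% CI. Because
best-cutoff selection is a minimum over many tests, a permutation-based
corrected p is available (`n_perm`).

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
synthetic dataset with planted ground truth (written under
`results/`):

```sh
Rscript analysis/01_make_fixtures.R    # generate inputs, seed 1
Rscript analysis/02_deg_consensus.R
Rscript analysis/03_network_centrality.R
Rscript analysis/04_pathway_enrichment.R
Rscript analysis/05_survival.R
Rscript analysis/06_full_pipeline.R    # same analysis via run_pipeline()
```

Output of the stages (abridged):

```
800 genes voted across 19 studies; 40 reach direction-consistent support >= 10
40 consensus seeds; 27 with >= 30 interactors
neighborhood: 296 nodes, 1575 edges
highest betweenness: ESR1 with score 29124 - 11.1 x the runner-up
32 of 40 consensus genes are annotated with at least one pathway
top hit: PATH001 - planted enriched pathway (k=32/60, q=8.11e-37)
364 patients; 182 candidate cutoffs between the quartiles
best cutoff 2.399 splits 187 low / 177 high
HR (high vs low) = 0.48 (95%CI 0.37-0.62)
log-rank p = 1.56e-08 | Gehan-Breslow-Wilcoxon p = 7.62e-07
median survival: high 53.4 vs low 25.2 months
```

Reading this: of 800 genes, exactly the 40 planted consensus genes
survive the ≥ 10/19 vote; the 27 planted high-degree seeds pass the
interactor filter; the planted hub (labelled ESR1) tops the
betweenness ranking by an order of magnitude, because it is the sole
bridge between network communities; the planted pathway is the only
one below FDR 0.05; and the survival stage estimates HR 0.48
(95% CI 0.37–0.62) for a planted true hazard ratio of 0.45, with the
high-expression group living about twice as long at the median.

The same run through the orchestrator:

```r
library(hccnet)
fx <- make_fixtures("demo", seed = 1)
report <- run_pipeline(pipeline_config(
  study_paths = "demo/studies",
  interactome_path = "demo/interactome.tsv",
  tissue_path = "demo/tissue_genes.txt",
  gmt_path = "demo/pathways.gmt",
  survival_path = "demo/survival.tsv",
  min_support = 10, min_degree = 30))
report$top_node
#> [1] "ESR1"
```

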