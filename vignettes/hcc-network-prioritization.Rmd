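---
title: "Network-based gene prioritization in HCC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based gene prioritization in HCC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccnet)
```

## The analysis this package implements

Hepatocellular carcinoma (HCC) expression studies individually report
hundreds of differentially expressed genes (DEGs) with limited overlap
between studies. This package implements an integrative strategy that
trades per-study depth for cross-study consistency, then uses network
topology rather than expression magnitude to decide which of the
consistent genes matter:

1. **Consensus voting.** Each study's DEG table is filtered (adjusted
   p < 0.05; tumor/non-tumor fold change ≤ 0.5 or ≥ 1.5) and a gene
   earns one vote per study per direction. Genes dysregulated in the
   *same* direction in at least 10 of 19 studies form the consensus
   list.
2. **Network mapping.** Consensus genes are placed in a physical
   protein-interaction network restricted to liver-expressed genes, and
   only seeds with a large interactor count (≥ 250 at full scale) are
   kept — frequency of dysregulation selects candidates, connectivity
   selects the ones in a position to matter.
3. **Betweenness ranking.** On the subnetwork induced by the surviving
   seeds and their interaction partners, each node's betweenness
   centrality is computed exactly; the top node is the analysis
   headline. Betweenness finds *bottlenecks* — a gene can rank first
   while having neither the largest fold change nor the highest degree.
4. **Pathway over-representation.** The consensus list is tested
   against a pathway collection with one-sided hypergeometric tests,
   FDR-controlled by Benjamini–Hochberg.
5. **Survival validation.** A continuous expression marker is
   dichotomized at the best cutoff between the quartiles; the groups
   are compared by Kaplan–Meier curves, log-rank and
   Gehan–Breslow–Wilcoxon tests, and a proportional-hazards hazard
   ratio with 95% CI.

Every stage is driven by the synthetic-data module, which plants a
known truth (consensus set, hub, enriched pathway, hazard ratio) so the
pipeline's recovery behavior is testable end to end without downloads.

## Filtering and voting

`filter_criteria()` holds the thresholds. Two dialects exist because
the field uses both: the default ratio scale (`0.5`/`1.5`, *inclusive*,
matching GEO2R-style tables where "≤ 0.5 or ≥ 1.5" is the published
rule) and a log2 scale (`|log2FC| > 1`, *strict*, the convention used
for the mouse-array analysis). The p threshold is strict (`< 0.05`) in
both. These asymmetries are deliberate and boundary-tested: a record at
FC = 1.5 is kept, a record at p = 0.05 is not.

Design choices the data forced:

* **Probe collapse.** Array tables may carry several rows per gene.
  Rows are collapsed *before* filtering to the row with the smallest
  adjusted p (ties to the more extreme fold change). Collapsing after
  filtering would let one gene pass in both directions within a study.
* **Support denominator.** The vote threshold is an absolute count
  ("10 of 19"), not a fraction of the studies measuring the gene. A
  gene absent from a study simply contributes no vote; this penalizes
  poorly measured genes, which is the conservative reading.
* **Tie rule.** Equal up and down support yields consensus direction
  `none` and exclusion — "consistent modulation" requires a majority
  direction, and the consensus support counts only that direction.

## Network construction and centrality

`read_edges()` normalizes an edge list to an undirected simple graph:
symbols upper-cased, self-interactions dropped, A–B and B–A collapsed.
Tissue filtering keeps an edge only when both endpoints are
liver-expressed, with one exception: consensus seeds are protected via
`always_keep`, because a dysregulated tumor gene should not vanish from
its own analysis for lacking a normal-tissue annotation.

Three decisions here were genuinely open:

* **Induced subgraph.** The seed neighborhood keeps *all* edges among
  seeds and partners, including partner–partner edges. The alternative
  (star expansion) makes every partner a leaf, which zeroes partner
  betweenness and reduces the ranking to seed degree — it would make
  the centrality stage vacuous.
* **Degree on the global network.** A seed's interactor count is its
  degree in the full tissue-filtered interactome, not in the induced
  subgraph, because "number of known interactors" is a property of the
  protein, not of the subnetwork we happen to draw.
* **Cutoff transparency.** The degree threshold (default 250) is a
  parameter; `seed_degree_knee()` reports the largest drop in the
  sorted degree curve for transparency but is never applied
  automatically.

Betweenness is computed by Brandes' algorithm (single-source BFS with
dependency back-propagation), with the classical unordered-pair,
unnormalized convention: score(v) = Σ over pairs s ≠ t ≠ v of
σ_st(v)/σ_st. Only rank order matters downstream, and raw scores match
the defaults of the common graph libraries, which makes ranks easy to
reproduce elsewhere. Edges are unweighted (the input carries no
interaction confidence), disconnected graphs are handled by summing
within components (no largest-component restriction; a component count
is logged), and ranking ties break lexicographically so output is
deterministic. An independent brute force (`betweenness_bruteforce()`,
Floyd–Warshall distances plus explicit geodesic enumeration, capped at
15 nodes) exists purely as an oracle; the suite checks the fast
implementation against it on 50 seeded random graphs to 1e-9, and
against closed forms (star center = C(k, 2); leaves = 0).

```{r}
path <- tibble::tibble(a = c("A", "B"), b = c("B", "C"))
betweenness_centrality(path)$scores
```

## Enrichment

`enrich()` is a one-sided over-representation test: for a pathway with
K genes in a universe of N, a query of n annotated genes, and overlap
k, p = P(X ≥ k), X ~ Hypergeometric(N, K, n), evaluated by the stable
tail routine in `stats`. q-values are Benjamini–Hochberg across the
tested pathways. The universe defaults to the union of all pathway
genes (optionally intersected with a measured-gene list): the
annotation service the field uses does not publish its universe, so
the choice is explicit rather than implicit, and query genes outside
the universe are dropped and counted (the familiar "m of n genes were
annotated" accounting). Pathways with fewer than 3 universe genes are
not tested — overlap with a 1–2 gene set is not evidence. Enrichment
q-values are therefore methodologically parallel, not numerically
identical, to any specific annotation service's output.

## Survival analysis

The survival stage is deliberately self-contained:

* **Kaplan–Meier** via the product-limit estimator; the median is the
  smallest event time with S(t) ≤ 0.5 and is undefined (NA) when the
  curve never reaches 0.5 — it is never extrapolated.
* **Log-rank and Gehan–Breslow–Wilcoxon** share one weighted O/E/V
  tabulation over pooled event times, with weight 1 (log-rank) or the
  number at risk n_i (GBW, which emphasizes early differences). The
  GBW weight is not available in the rho-family of standard survival
  software, which is why the tabulation is implemented here; the
  log-rank special case is cross-checked against
  `survival::survdiff()` in the tests.
* **Hazard ratio** from a univariate proportional-hazards fit
  (`survival::coxph`, Breslow ties — the simplest consistent tie rule;
  ties are rare for continuous simulated times). CI is
  exp(log HR ± 1.96 SE). A group with zero events yields a flagged
  degenerate estimate (0 or Inf), not a crash.
* **Best-cutoff scan.** Candidates are every distinct observed
  expression value within [Q1, Q3] (quartiles by linear interpolation,
  the common statistical default — the quantile rule is otherwise
  arbitrary). For each candidate v, low is expression < v and high is
  ≥ v; the best cutoff minimizes the log-rank p, ties toward the
  smaller cutoff. HR is oriented high-vs-low, so HR < 1 means high
  expression is protective.

The scan's `best_p` is a minimum over many correlated tests and is
**anticonservative by construction**: on null cohorts (true HR = 1,
n = 364) the suite measures a rejection rate at 0.05 several times
nominal. This is the documented behavior of best-cutoff tools, not a
bug; `n_perm > 0` provides a permutation-based corrected p (min-p
null) for when a calibrated significance statement is needed.

## What the generators emulate — and what they do not

`generate_study_tables()` plants each consensus gene to pass the
filters in its direction in ≥ `consensus_support` studies (the number
of supporting studies is drawn uniformly from support..n_studies) and
lets every other gene pass with per-study probability `noise_rate`
(default 0.02), capped below the support threshold so the planted set
is exactly recoverable. `generate_interactome()` plants the hub as the
sole articulation vertex joining otherwise disconnected communities:
every cross-community shortest path runs through it, so its top
betweenness rank is a structural guarantee — planting by articulation
rather than by degree means hub recovery genuinely tests betweenness,
not degree. `generate_survival_cohort()` uses exponential event times
(hazard `baseline_hazard`, default 0.025/month, times `true_hr` in the
high-expression half), bimodal expression (unit-SD normals separated
by `expression_gap`, default 4), and independent exponential censoring
with the rate solved per group so the expected censored fraction
equals `censor_rate`. Exponential times are the minimal model
supporting a hazard ratio and median survival, which is all the
downstream stages consume. All generators are pure functions of
(config, seed) via `withr::with_seed`.

What they do *not* emulate: probe-level intensities, normalization or
batch effects, correlated genes, study-specific sample sizes or
platform biases, scale-free interactome topology, database
version drift, or non-proportional hazards. A pipeline that recovers
planted truth here is verified as *correctly implementing its own
contract*; that is a necessary, not sufficient, condition for correct
conclusions on real data, where the filters meet messier failure
modes.

## Study conditions and problem sizes

The packaged fixture (`generate_pipeline_fixture()` /
`make_fixtures()`) fixes the study conditions: 19 studies, support
threshold 10, 40 planted consensus genes, a 3-community interactome
(~310 nodes) with 27 seeds planted at degree ≥ 30 and the hub bridging
communities, one planted pathway among 40, and a 364-patient cohort
with true HR 0.45 and 30% censoring. The degree threshold is 30 rather
than the full-scale 250 because the synthetic interactome has hundreds
rather than tens of thousands of nodes; the inclusive-threshold
semantics are identical and the full-scale value remains the pipeline
default. The cohort's baseline hazard (0.025/month) puts the
low-expression median near 28 months, the scale reported for HCC
cohorts of this size. Calibration checks use 500 null replicates
(type-I error), 200 replicates for hazard-ratio recovery and coverage,
and 50 random graphs against the exhaustive centrality oracle — sizes
at which the Monte-Carlo error is comfortably inside the asserted
bands.

## Numerical and degenerate-input choices

* Vote and ranking ties break lexicographically by symbol; output
  ordering is fully deterministic everywhere.
* Non-positive fold changes on the ratio scale are invalid records:
  dropped with a warning, never silently kept or fatal.
* Malformed edge-list and GMT lines are skipped with counted warnings;
  an input yielding *zero* valid records is an error.
* A cutoff candidate that empties a group is skipped and logged;
  constant expression is an error (no cutoff exists).
* `pipeline_config()` validates thresholds against the inputs (e.g.
  min_support vs study count) before any stage runs; a stage failure
  aborts with the stage name.

## Known limitations

* Betweenness is exact, single-threaded, O(nm); comfortable to a few
  thousand nodes, not for a full 20k-node interactome with hundreds of
  thousands of edges.
* The hazard ratio is univariate; clinical covariates, competing risks
  and interval censoring are out of scope.
* The enrichment universe choice materially affects p-values and is
  the caller's responsibility when mirroring a specific annotation
  service.
* Cutoff-scan p-values are reported raw to match common practice;
  consumers who need calibrated inference must use the permutation
  option.
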