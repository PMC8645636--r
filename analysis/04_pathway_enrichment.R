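#!/usr/bin/env Rscript

# Stage 3: pathway over-representation of the consensus genes.
#
# One-sided hypergeometric test of the consensus list against each
# pathway, FDR-controlled with Benjamini-Hochberg across the tested
# pathways.

suppressPackageStartupMessages(library(hccnet))

consensus <- readr::read_tsv("results/consensus.tsv",
                             show_col_types = FALSE)
coll <- read_gmt("results/fixture/pathways.gmt")
res <- enrich(consensus$gene, coll)
write_enrichment(res, "results/enrichment.tsv")

cat(attr(res, "n_query_annotated"), "of", nrow(consensus),
    "consensus genes are annotated with at least one pathway\n")
cat(sum(res$q < 0.05), "of", nrow(res),
    "pathways enriched at FDR < 0.05\n")
cat("top hit:", res$id[1], "-", res$name[1],
    sprintf("(k=%d/%d, q=%.2e)\n", res$k[1], res$K[1], res$q[1]))
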