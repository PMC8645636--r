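#!/usr/bin/env Rscript

# Stage 2: tissue-filtered interaction network and betweenness ranking.
#
# Maps the consensus genes onto the physical-interaction network
# restricted to liver-expressed genes, keeps seeds with at least 30
# interactors (the demo-scale analogue of the 250-interactor rule),
# expands them to their interaction neighborhood, and ranks every node
# by exact betweenness centrality.

suppressPackageStartupMessages(library(hccnet))

consensus <- readr::read_tsv("results/consensus.tsv",
                             show_col_types = FALSE)
net <- read_edges("results/fixture/interactome.tsv")
tissue <- readLines("results/fixture/tissue_genes.txt")

filtered <- apply_tissue_filter(net, tissue, always_keep = consensus$gene)
nb_all <- build_neighborhood(filtered, consensus$gene)
seeds <- filter_seeds_by_degree(nb_all, min_degree = 30)
knee <- seed_degree_knee(nb_all)

nb <- build_neighborhood(filtered, seeds)
cent <- betweenness_centrality(nb$graph, nodes = nb$nodes)

write_neighborhood(nb, "results/network_edges.tsv",
                   "results/network_nodes.tsv", net = filtered)
write_centrality(cent, "results/centrality.tsv", seeds = seeds,
                 degrees = nb_all$degree_by_seed)

cat(nrow(consensus), "consensus seeds;", length(seeds),
    "with >= 30 interactors (largest degree drop after",
    knee$largest_drop_after, ")\n")
cat("neighborhood:", length(nb$nodes), "nodes,", nrow(nb$graph),
    "edges\n")
cat("highest betweenness:", cent$top_node, "with score",
    round(cent$ranking$score[1]), "-",
    round(cent$ranking$score[1] / cent$ranking$score[2], 1),
    "x the runner-up\n")
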