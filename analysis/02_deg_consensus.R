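#!/usr/bin/env Rscript

# Stage 1: cross-study differential-expression consensus.
#
# Filters every study table (adjusted p < 0.05; fold change <= 0.5 or
# >= 1.5) and counts direction-consistent votes; genes dysregulated the
# same way in at least 10 of the 19 studies form the consensus list.

suppressPackageStartupMessages(library(hccnet))

tables <- lapply(list.files("results/fixture/studies", full.names = TRUE),
                 read_study_table)
votes <- vote_count(tables)
consensus <- select_consensus(votes, min_support = 10)

readr::write_tsv(votes, "results/votes.tsv", progress = FALSE)
write_consensus(consensus, "results/consensus.tsv")

cat(nrow(votes), "genes voted across", length(tables), "studies;",
    nrow(consensus), "reach direction-consistent support >= 10\n")
cat("top of the consensus list:\n")
print(utils::head(as.data.frame(consensus), 5))
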