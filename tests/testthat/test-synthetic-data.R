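test_that("generators are pure functions of configuration and seed", {
  cfg <- study_gen_config(n_studies = 5, n_genes = 60,
                          consensus_support = 3, noise_rate = 0.1,
                          seed = 5)
  expect_identical(generate_study_tables(cfg, five_gene_truth()),
                   generate_study_tables(cfg, five_gene_truth()))

  i1 <- generate_interactome(30, "HUB", seed = 9)
  i2 <- generate_interactome(30, "HUB", seed = 9)
  expect_identical(i1$interactome, i2$interactome)

  ccfg <- cohort_gen_config(n_patients = 50, seed = 12)
  expect_identical(generate_survival_cohort(ccfg),
                   generate_survival_cohort(ccfg))
})

test_that("invalid generator configurations are refused", {
  expect_error(study_gen_config(n_studies = 5, consensus_support = 6),
               "invalid configuration")
  expect_error(cohort_gen_config(n_patients = 10), "n_patients")
  expect_error(cohort_gen_config(censor_rate = 1))
  expect_error(synthetic_truth(tibble::tibble(gene = character(),
                                              direction = character()),
                               "HUB"))
})

test_that("noise-free tables yield exactly the planted consensus", {
  truth <- five_gene_truth()
  cfg <- study_gen_config(n_studies = 19, n_genes = 300,
                          consensus_support = 10, noise_rate = 0,
                          seed = 21)
  tables <- generate_study_tables(cfg, truth)
  consensus <- select_consensus(vote_count(tables), 10)
  expect_setequal(consensus$gene, truth$consensus_genes$gene)
  dirs <- stats::setNames(consensus$direction, consensus$gene)
  expect_equal(unname(dirs[truth$consensus_genes$gene]),
               truth$consensus_genes$direction)
  # and no other gene reaches 10 direction-consistent passes
  votes <- vote_count(tables)
  others <- votes[!votes$gene %in% truth$consensus_genes$gene, ]
  expect_true(all(others$consensus_support < 10))
})

test_that("chance passes of noise genes match the binomial rate", {
  truth <- five_gene_truth()
  cfg <- study_gen_config(n_studies = 19, n_genes = 2000,
                          consensus_support = 10, noise_rate = 0.05,
                          seed = 23)
  tables <- generate_study_tables(cfg, truth)
  n_noise <- cfg$n_genes - nrow(truth$consensus_genes)
  expected <- n_noise * cfg$noise_rate
  sigma <- sqrt(n_noise * cfg$noise_rate * (1 - cfg$noise_rate))
  for (tab in tables) {
    # brute-force tally of filter passes among non-consensus genes
    noise <- tab[!tab$gene %in% truth$consensus_genes$gene, ]
    passes <- sum(noise$adj_p < 0.05 &
                    (noise$fold_change <= 0.5 | noise$fold_change >= 1.5))
    expect_lt(abs(passes - expected), 3 * sigma)
  }
})

test_that("two cliques joined only through the hub give betweenness 100", {
  clique_edges <- function(nodes) {
    pairs <- utils::combn(nodes, 2)
    tibble::tibble(a = pairs[1, ], b = pairs[2, ])
  }
  left <- sprintf("L%02d", 1:10)
  right <- sprintf("R%02d", 1:10)
  edges <- dplyr::bind_rows(
    clique_edges(left), clique_edges(right),
    tibble::tibble(a = "HUB", b = c(left[1], right[1])))
  res <- betweenness_centrality(edges)
  # every left-right pair (10 x 10) routes through the hub
  expect_equal(res$scores[["HUB"]], 100)
  expect_equal(res$top_node, "HUB")
  expect_true(res$scores[["HUB"]] > max(res$scores[names(res$scores) != "HUB"]))
})

test_that("the generated interactome plants the hub as betweenness rank 1", {
  for (seed in c(3, 14, 15)) {
    gen <- generate_interactome(50, "HUB", seed = seed)
    nodes <- unique(c(gen$interactome$a, gen$interactome$b))
    expect_true("HUB" %in% nodes)
    res <- betweenness_centrality(gen$interactome)
    expect_equal(res$top_node, "HUB", info = seed)
    scores <- sort(res$scores, decreasing = TRUE)
    expect_gt(scores[1], scores[2])  # unique maximum
    # tissue list covers every emitted node plus decoys
    expect_true(all(unique(c(gen$interactome$a, gen$interactome$b))
                    %in% gen$tissue))
    expect_true(any(grepl("^DECOY", gen$tissue)))
  }
})

test_that("survival cohorts honor censoring and planted group structure", {
  co <- generate_survival_cohort(cohort_gen_config(
    n_patients = 100, true_hr = 0.5, censor_rate = 0, seed = 33))
  expect_true(all(co$event == 1L))
  expect_equal(sum(co$group == "high"), 50)

  co2 <- generate_survival_cohort(cohort_gen_config(
    n_patients = 2000, true_hr = 0.5, censor_rate = 0.4, seed = 34))
  expect_equal(mean(co2$event == 0), 0.4, tolerance = 0.05)
  # bimodal expression: the gap midpoint recovers the planted groups
  gap_mid <- 2
  expect_gt(mean((co2$expression > gap_mid) == (co2$group == "high")),
            0.97)
})

test_that("log-rank type-I error is nominal on null cohorts", {
  rej <- vapply(1:200, function(i) {
    co <- generate_survival_cohort(cohort_gen_config(
      n_patients = 200, true_hr = 1, censor_rate = 0, seed = 1000 + i))
    a <- co[co$group == "low", c("time", "event")]
    b <- co[co$group == "high", c("time", "event")]
    logrank(a, b)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
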