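edge_tbl <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(a = m[, 1], b = m[, 2])
}

test_that("closed forms hold on path, star, triangle, and square", {
  path <- edge_tbl("A", "B", "B", "C")
  expect_equal(betweenness_centrality(path)$scores,
               c(A = 0, B = 1, C = 0))

  star <- edge_tbl("C0", "L1", "C0", "L2", "C0", "L3", "C0", "L4")
  expect_equal(betweenness_centrality(star)$scores[["C0"]], choose(4, 2))
  expect_true(all(betweenness_centrality(star)$scores[c("L1", "L2")] == 0))

  triangle <- edge_tbl("A", "B", "B", "C", "A", "C")
  expect_true(all(betweenness_centrality(triangle)$scores == 0))
  expect_true(all(betweenness_bruteforce(triangle) == 0))

  # 4-cycle: two geodesics between each diagonal pair, one through each
  # intermediate -> every node carries 2 * (1/2) * ... = 0.5
  square <- edge_tbl("A", "B", "B", "C", "C", "D", "D", "A")
  expect_equal(unname(betweenness_centrality(square)$scores),
               rep(0.5, 4))
  expect_equal(betweenness_bruteforce(square),
               betweenness_centrality(square)$scores)
})

test_that("Brandes equals exhaustive enumeration on random graphs", {
  for (i in 1:50) {
    n <- 5 + (i %% 8)  # 5..12 nodes
    g <- rand_graph(n, 0.3, seed = 100 + i)
    fast <- betweenness_centrality(g, nodes = sprintf("V%02d", 1:n))$scores
    slow <- betweenness_bruteforce(g, nodes = sprintf("V%02d", 1:n))
    expect_equal(fast, slow[names(fast)], tolerance = 1e-9, info = i)
  }
})

test_that("Brandes agrees with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(21, 22, 23)) {
    g <- rand_graph(30, 0.15, seed = seed)
    mine <- betweenness_centrality(g)$scores
    ig <- igraph::graph_from_data_frame(g, directed = FALSE)
    ref <- igraph::betweenness(ig, directed = FALSE)
    expect_equal(mine[names(ref)], ref[names(ref)], tolerance = 1e-9)
  }
})

test_that("tree betweenness sums to sum over pairs of (path length - 1)", {
  # on a tree each pair has a unique geodesic, so the total betweenness
  # mass equals the number of interior vertices over all pairs
  pair_dists <- function(edges) {
    nodes <- sort(unique(c(edges$a, edges$b)))
    adj <- lapply(nodes, function(v) {
      c(edges$b[edges$a == v], edges$a[edges$b == v])
    })
    names(adj) <- nodes
    total <- 0
    for (s in nodes) {
      dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
      dist[s] <- 0
      frontier <- s
      while (length(frontier) > 0) {
        nxt <- unique(unlist(adj[frontier]))
        nxt <- nxt[!is.finite(dist[nxt])]
        dist[nxt] <- dist[frontier[1]] + 1
        frontier <- nxt
      }
      total <- total + sum(dist[dist > 1] - 1)
    }
    total / 2  # each unordered pair visited from both ends
  }
  for (seed in c(31, 32, 33)) {
    tr <- rand_tree(10, seed)
    scores <- betweenness_centrality(tr)$scores
    expect_equal(sum(scores), pair_dists(tr), tolerance = 1e-9)
  }
})

test_that("scores are invariant under node relabeling", {
  g <- rand_graph(10, 0.35, seed = 41)
  perm <- withr::with_seed(42, sample(sprintf("W%02d", 1:10)))
  names(perm) <- sprintf("V%02d", 1:10)
  g2 <- tibble::tibble(a = unname(perm[g$a]), b = unname(perm[g$b]))
  s1 <- betweenness_centrality(g, nodes = names(perm))$scores
  s2 <- betweenness_centrality(g2, nodes = unname(perm))$scores
  expect_equal(unname(s1[names(perm)]), unname(s2[perm]),
               tolerance = 1e-12)
})

test_that("disconnected graphs sum within components; isolated nodes score 0", {
  two_paths <- edge_tbl("A", "B", "B", "C", "X", "Y", "Y", "Z")
  scores <- betweenness_centrality(two_paths, nodes = "LONE")$scores
  expect_equal(scores[["B"]], 1)
  expect_equal(scores[["Y"]], 1)
  expect_equal(scores[["LONE"]], 0)
  # singleton graph
  single <- betweenness_centrality(tibble::tibble(a = character(),
                                                  b = character()),
                                   nodes = "ONLY")
  expect_equal(single$scores, c(ONLY = 0))
})

test_that("ranking is score-descending with lexicographic tie breaks", {
  r <- rank_nodes(c(A = 6, B = 0, C = 0))
  expect_equal(r$node, c("A", "B", "C"))
  expect_equal(r$rank, 1:3)
  tie <- rank_nodes(c(B = 2, A = 2))
  expect_equal(tie$node, c("A", "B"))
  restricted <- rank_nodes(c(A = 6, B = 3, C = 1), restrict_to = c("B", "C"))
  expect_equal(restricted$node, c("B", "C"))
  expect_equal(restricted$rank, 1:2)
})

test_that("brute force refuses graphs beyond its size cap", {
  g <- rand_graph(16, 0.3, seed = 51)
  expect_error(betweenness_bruteforce(g), "refuses")
})

test_that("leaf nodes always score zero", {
  g <- rand_tree(12, seed = 61)
  scores <- betweenness_centrality(g)$scores
  deg <- table(c(g$a, g$b))
  leaves <- names(deg)[deg == 1]
  expect_true(all(scores[leaves] == 0))
})
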