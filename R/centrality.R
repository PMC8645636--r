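# Normalize an edge table (two character columns) into an internal graph:
# uppercase symbols, self-loops removed, unordered duplicates collapsed,
# adjacency stored as integer index lists. `nodes` may add isolated nodes.
graph_from_edges <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- toupper(as.character(edges[[1]]))
  b <- toupper(as.character(edges[[2]]))
  keep <- !is.na(a) & !is.na(b) & a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  a <- lo[!dup]; b <- hi[!dup]

  node_names <- sort(unique(c(a, b, toupper(as.character(nodes)))))
  ai <- match(a, node_names)
  bi <- match(b, node_names)
  n <- length(node_names)
  adj <- vector("list", n)
  if (length(ai) > 0) {
    adj_all <- split(c(bi, ai), c(ai, bi))
    idx <- as.integer(names(adj_all))
    for (j in seq_along(idx)) adj[[idx[j]]] <- sort(unique(adj_all[[j]]))
  }
  for (j in seq_len(n)) if (is.null(adj[[j]])) adj[[j]] <- integer(0)
  list(nodes = node_names, adj = adj,
       edges = tibble::tibble(a = a, b = b))
}

#' Exact betweenness centrality by Brandes' algorithm
#'
#' Computes unnormalized betweenness centrality on an undirected,
#' unweighted simple graph: for each node v, the sum over unordered node
#' pairs \eqn{s \ne t \ne v} of the fraction of shortest s--t paths that
#' pass through v. Pairs in different components contribute zero;
#' disconnected graphs are handled without restriction to the largest
#' component. Implemented as single-source breadth-first search with
#' dependency back-propagation.
#'
#' @param edges A data frame whose first two columns are gene symbols
#'   forming undirected edges. Self-loops and duplicate pairs (in either
#'   order) are ignored.
#' @param nodes Optional character vector of additional (possibly
#'   isolated) nodes to include with score 0.
#' @return A list of class `centrality_result` with elements `scores`
#'   (named numeric vector), `ranking` (tibble `node`, `score`, `rank`,
#'   descending score, ties broken by symbol), and `top_node`.
#' @export
betweenness_centrality <- function(edges, nodes = NULL) {
  g <- graph_from_edges(edges, nodes)
  n <- length(g$nodes)
  stopifnot(n >= 1)
  bc <- numeric(n)
  adj <- g$adj

  for (s in seq_len(n)) {
    # BFS from s, counting shortest paths
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    order_visited <- integer(n); n_visited <- 0L
    queue <- integer(n); queue[1] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      n_visited <- n_visited + 1L
      order_visited[n_visited] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    # back-propagate dependencies in reverse BFS order
    delta <- numeric(n)
    for (i in rev(seq_len(n_visited))) {
      w <- order_visited[i]
      if (w == s) next
      for (v in adj[[w]]) {
        if (dist[v] == dist[w] - 1L) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
      }
      bc[w] <- bc[w] + delta[w]
    }
  }
  scores <- bc / 2  # each unordered pair counted from both endpoints
  names(scores) <- g$nodes
  ranking <- rank_nodes_from_scores(scores)
  res <- list(scores = scores, ranking = ranking,
              top_node = ranking$node[1])
  class(res) <- "centrality_result"
  res
}

rank_nodes_from_scores <- function(scores) {
  ord <- order(-scores, names(scores))
  tibble::tibble(node = names(scores)[ord],
                 score = unname(scores)[ord],
                 rank = seq_along(scores))
}

#' Rank nodes by betweenness score
#'
#' Orders nodes by descending score with ties broken lexicographically by
#' symbol. With `restrict_to`, ranks are reported among the given nodes
#' only (e.g. the consensus seeds), using the same ordering rule.
#'
#' @param res A `centrality_result` from [betweenness_centrality()], or a
#'   named numeric score vector.
#' @param restrict_to Optional character vector restricting the ranking.
#' @return A tibble with columns `node`, `score`, `rank`.
#' @export
rank_nodes <- function(res, restrict_to = NULL) {
  scores <- if (inherits(res, "centrality_result")) res$scores else res
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (!is.null(restrict_to)) {
    restrict_to <- toupper(restrict_to)
    scores <- scores[names(scores) %in% restrict_to]
    if (length(scores) == 0) stop("no node in `restrict_to` has a score")
  }
  rank_nodes_from_scores(scores)
}

#' Brute-force betweenness by explicit geodesic enumeration
#'
#' Independent reference implementation used as a test oracle: computes
#' all-pairs shortest-path distances by Floyd--Warshall, enumerates every
#' geodesic for every node pair by recursive backtracking, and tallies the
#' interior vertices. Refuses graphs with more than `max_n` nodes because
#' the enumeration cost grows combinatorially.
#'
#' @param edges Edge data frame as in [betweenness_centrality()].
#' @param nodes Optional extra isolated nodes.
#' @param max_n Node-count cap (default 15).
#' @return Named numeric vector of betweenness scores.
#' @export
betweenness_bruteforce <- function(edges, nodes = NULL, max_n = 15) {
  g <- graph_from_edges(edges, nodes)
  n <- length(g$nodes)
  if (n > max_n) {
    stop("betweenness_bruteforce refuses graphs with more than ",
         max_n, " nodes")
  }
  A <- matrix(FALSE, n, n)
  if (nrow(g$edges) > 0) {
    ai <- match(g$edges$a, g$nodes); bi <- match(g$edges$b, g$nodes)
    A[cbind(ai, bi)] <- TRUE
    A[cbind(bi, ai)] <- TRUE
  }
  D <- matrix(Inf, n, n); diag(D) <- 0; D[A] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }

  # enumerate all geodesics s -> t by following distance-decreasing edges
  paths_to <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in which(A[s, ])) {
      if (D[w, t] == D[s, t] - 1) {
        for (p in paths_to(w, t)) out[[length(out) + 1]] <- c(s, p)
      }
    }
    out
  }

  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      geos <- paths_to(s, t)
      interior <- unlist(lapply(geos, function(p) p[-c(1, length(p))]))
      tally <- tabulate(interior, nbins = n)
      bc <- bc + tally / length(geos)
    }
  }
  names(bc) <- g$nodes
  bc
}

#' Export a centrality ranking as TSV
#'
#' Writes `node`, `betweenness`, `rank`, plus `is_seed` and `degree`
#' columns when seed and degree information is supplied.
#'
#' @param res A `centrality_result`.
#' @param path Destination file.
#' @param seeds Optional character vector of seed symbols.
#' @param degrees Optional named degree vector.
#' @return `path`, invisibly.
#' @export
write_centrality <- function(res, path, seeds = NULL, degrees = NULL) {
  out <- res$ranking
  names(out)[names(out) == "score"] <- "betweenness"
  if (!is.null(seeds)) out$is_seed <- out$node %in% toupper(seeds)
  if (!is.null(degrees)) out$degree <- unname(degrees[out$node])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
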