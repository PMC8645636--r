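#' Normalize an edge table into an interactome
#'
#' Upper-cases gene symbols, drops self-pairs, and collapses duplicate
#' pairs regardless of endpoint order (A-B and B-A are the same physical
#' interaction). The result stores each edge once with `a <= b`
#' lexicographically.
#'
#' @param edges A data frame whose first two columns are gene symbols.
#' @return A tibble with columns `a`, `b`, one row per undirected edge.
#' @export
as_interactome <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- toupper(trimws(as.character(edges[[1]])))
  b <- toupper(trimws(as.character(edges[[2]])))
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  dup <- duplicated(paste(lo, hi, sep = "\t"))
  out <- tibble::tibble(a = lo[!dup], b = hi[!dup])
  out[order(out$a, out$b), , drop = FALSE]
}

interactome_nodes <- function(net) sort(unique(c(net$a, net$b)))

#' Read a physical-interaction edge list
#'
#' Reads a tab-delimited file whose first two columns are interacting gene
#' symbols (IID-style export; extra columns are ignored). A header line is
#' auto-detected when its first two fields look like column labels
#' (`symbol1`, `gene_a`, `protein2`, ...). Malformed lines (fewer than two
#' non-empty fields) are skipped with a warning reporting the count.
#'
#' @param path Path to the edge-list file.
#' @return An interactome tibble (see [as_interactome()]).
#' @export
read_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no edges in ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]]))
  header_like <- "^(symbol|gene|protein|node|interactor|partner|source|target|uniprot|entrez)"
  if (length(first) >= 2 &&
      any(grepl(header_like, first[1:2]))) {
    fields <- fields[-1]
  }

  ok <- vapply(fields, function(f) {
    length(f) >= 2 && all(nzchar(trimws(f[1:2])))
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " malformed line(s) skipped in ", basename(path))
  }
  fields <- fields[ok]
  if (length(fields) == 0) stop("no valid edges in ", path)

  net <- as_interactome(tibble::tibble(
    a = vapply(fields, function(f) trimws(f[1]), character(1)),
    b = vapply(fields, function(f) trimws(f[2]), character(1))
  ))
  if (nrow(net) == 0) stop("no valid edges in ", path)
  net
}

#' Restrict an interactome to tissue-expressed genes
#'
#' Keeps an edge only when both endpoints are expressed in the tissue of
#' interest or are protected seeds. Seeds are protected via `always_keep`
#' so that a dysregulated tumor gene is not discarded merely for lacking a
#' tissue annotation.
#'
#' @param net An interactome tibble.
#' @param expressed Character vector of tissue-expressed gene symbols.
#' @param always_keep Character vector of symbols retained regardless of
#'   tissue annotation (typically the consensus seeds).
#' @return The filtered interactome.
#' @export
apply_tissue_filter <- function(net, expressed, always_keep = character()) {
  stopifnot(length(expressed) > 0)
  keepset <- unique(toupper(c(expressed, always_keep)))
  net[net$a %in% keepset & net$b %in% keepset, , drop = FALSE]
}

#' Expand seeds to their interaction neighborhood
#'
#' Builds the subnetwork comprising the seeds and all their first
#' neighbors, as the *induced* subgraph: every interactome edge among that
#' node set is retained, including partner-partner edges. Each seed's
#' interactor count (`degree_by_seed`) is its degree in the full supplied
#' interactome, not in the induced subgraph.
#'
#' @param net An interactome tibble (typically already tissue-filtered).
#' @param seeds Character vector of seed gene symbols. Seeds absent from
#'   the network trigger a warning (degree 0); if no seed is present an
#'   error is raised.
#' @return A list of class `seed_neighborhood` with elements `seeds`,
#'   `degree_by_seed` (named integer), `nodes`, and `graph` (induced edge
#'   tibble).
#' @export
build_neighborhood <- function(net, seeds) {
  stopifnot(length(seeds) > 0)
  seeds <- unique(toupper(seeds))
  nodes <- interactome_nodes(net)
  present <- seeds %in% nodes
  if (!any(present)) stop("no seed present in the interactome")
  if (any(!present)) {
    warning(sum(!present), " seed(s) absent from the interactome: ",
            paste(utils::head(seeds[!present], 5), collapse = ", "))
  }

  deg_tab <- table(c(net$a, net$b))
  degree_by_seed <- structure(rep.int(0L, length(seeds)), names = seeds)
  found <- seeds[seeds %in% names(deg_tab)]
  degree_by_seed[found] <- as.integer(deg_tab[found])

  in_seed_a <- net$a %in% seeds
  in_seed_b <- net$b %in% seeds
  partners <- unique(c(net$b[in_seed_a], net$a[in_seed_b]))
  node_set <- sort(unique(c(seeds[present], partners)))
  graph <- net[net$a %in% node_set & net$b %in% node_set, , drop = FALSE]

  structure(
    list(seeds = seeds, degree_by_seed = degree_by_seed,
         nodes = node_set, graph = graph),
    class = "seed_neighborhood"
  )
}

#' Filter seeds by interactor count
#'
#' Keeps seeds whose interactor count in the full tissue-filtered
#' interactome is at least `min_degree` (inclusive). Returned in
#' descending-degree order, ties broken by symbol.
#'
#' @param nb A `seed_neighborhood` from [build_neighborhood()] (or a named
#'   degree vector).
#' @param min_degree Minimum interactor count (default 250, the threshold
#'   beyond which the number of retained proteins stops growing steeply in
#'   the full-scale analysis).
#' @return Character vector of retained seed symbols.
#' @export
filter_seeds_by_degree <- function(nb, min_degree = 250) {
  stopifnot(min_degree >= 0)
  deg <- if (inherits(nb, "seed_neighborhood")) nb$degree_by_seed else nb
  stopifnot(is.numeric(deg), !is.null(names(deg)))
  deg <- deg[deg >= min_degree]
  names(deg)[order(-deg, names(deg))]
}

#' Report the largest drop in the sorted seed-degree curve
#'
#' Transparency aid for choosing a degree cutoff: sorts seed degrees in
#' decreasing order and reports the position of the largest drop (the
#' "knee"). The report is informational only and never applied
#' automatically.
#'
#' @param nb A `seed_neighborhood` or named degree vector.
#' @return A list with `sorted_degrees`, `largest_drop_after` (symbol) and
#'   `suggested_min_degree` (the degree just above the largest drop).
#' @export
seed_degree_knee <- function(nb) {
  deg <- if (inherits(nb, "seed_neighborhood")) nb$degree_by_seed else nb
  deg <- sort(deg, decreasing = TRUE)
  if (length(deg) < 2) {
    return(list(sorted_degrees = deg, largest_drop_after = NA_character_,
                suggested_min_degree = NA_real_))
  }
  drops <- -diff(deg)
  i <- which.max(drops)
  list(sorted_degrees = deg,
       largest_drop_after = names(deg)[i],
       suggested_min_degree = unname(deg[i]))
}

#' Export a seed neighborhood as edge and node tables
#'
#' Writes the induced subnetwork as an edge TSV and a node-attribute TSV
#' (`node`, `is_seed`, `degree` in the full interactome), suitable for
#' external visualization tools.
#'
#' @param nb A `seed_neighborhood`.
#' @param edge_path,node_path Destination files.
#' @param net Optional full interactome for non-seed degrees; if omitted,
#'   degrees are computed on the induced subgraph for non-seeds.
#' @return Invisibly, a list of the two paths.
#' @export
write_neighborhood <- function(nb, edge_path, node_path, net = NULL) {
  readr::write_tsv(nb$graph, edge_path, progress = FALSE)
  deg_src <- if (is.null(net)) nb$graph else net
  deg_tab <- table(c(deg_src$a, deg_src$b))
  nodes <- tibble::tibble(
    node = nb$nodes,
    is_seed = nb$nodes %in% nb$seeds,
    degree = as.integer(deg_tab[nb$nodes])
  )
  nodes$degree[is.na(nodes$degree)] <- 0L
  readr::write_tsv(nodes, node_path, progress = FALSE)
  invisible(list(edges = edge_path, nodes = node_path))
}
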