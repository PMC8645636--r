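#' Read a pathway collection in GMT format
#'
#' One pathway per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are collapsed (set semantics); lines with
#' fewer than three fields are skipped with a warning. Gene symbols are
#' upper-cased.
#'
#' @param path Path to the GMT file.
#' @return A list of class `pathway_collection` with elements `sets`
#'   (named list of gene-symbol vectors), `descriptions` (named character)
#'   and `universe` (union of all member genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 3
  if (any(!ok)) {
    warning(sum(!ok), " GMT line(s) with fewer than 3 fields skipped")
  }
  fields <- fields[ok]
  if (length(fields) == 0) stop("no valid pathway lines in ", path)

  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in ", path)
  sets <- lapply(fields, function(f) {
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes[nzchar(genes)]
  })
  names(sets) <- ids
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  names(descriptions) <- ids

  structure(
    list(sets = sets, descriptions = descriptions,
         universe = sort(unique(unlist(sets)))),
    class = "pathway_collection"
  )
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more query genes in a pathway of size
#' `K` when `n` genes are drawn without replacement from a universe of
#' size `N`: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Delegates to
#' [stats::phyper()], which evaluates the tail stably on the log-gamma
#' scale.
#'
#' @param k Overlap count.
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The tail probability (1 when `k = 0`).
#' @export
hypergeom_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts (need 0 <= k <= min(K, n), ",
         "K <= N, n <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns BH-adjusted q-values in the input order:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Thresholding the
#' result at `alpha` reproduces the classical step-up rejection set.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the query genes with a
#' one-sided hypergeometric test, then controls the FDR across the tested
#' pathways with Benjamini-Hochberg. The universe defaults to the union of
#' all pathway genes (optionally intersected with a measured-gene list via
#' `universe`); query genes outside the universe are dropped before
#' testing and reported in the `n_query_annotated` attribute, mirroring
#' the usual "genes annotated with at least one pathway" accounting.
#'
#' @param query Character vector of gene symbols.
#' @param coll A `pathway_collection` from [read_gmt()].
#' @param universe Optional character vector to intersect with the
#'   collection universe (e.g. all measured genes).
#' @param min_size,max_size Pathway size bounds (within the universe)
#'   for testing. Defaults 3 and `Inf`.
#' @return A tibble with columns `id`, `name`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, sorted by ascending `q` then `p`; attributes `n_query_annotated`
#'   and `universe_size`.
#' @export
enrich <- function(query, coll, universe = NULL, min_size = 3,
                   max_size = Inf) {
  stopifnot(inherits(coll, "pathway_collection"), length(query) > 0)
  query <- unique(toupper(query))
  uni <- coll$universe
  if (!is.null(universe)) uni <- intersect(uni, toupper(universe))
  if (length(uni) == 0) stop("empty universe after restriction")

  query_in <- intersect(query, uni)
  if (length(query_in) == 0) {
    stop("no query gene is in the pathway universe")
  }

  N <- length(uni)
  n <- length(query_in)
  sets <- lapply(coll$sets, intersect, y = uni)
  sizes <- lengths(sets)
  test <- sizes >= min_size & sizes <= max_size
  if (!any(test)) stop("no pathway within the size bounds")

  ids <- names(sets)[test]
  K <- sizes[test]
  k <- vapply(sets[test], function(s) length(intersect(s, query_in)),
              integer(1))
  p <- vapply(seq_along(ids),
              function(i) hypergeom_p(k[i], K[i], n, N), numeric(1))
  out <- tibble::tibble(
    id = ids,
    name = unname(coll$descriptions[ids]),
    k = unname(k), K = unname(K), n = n, N = N,
    p = unname(p), q = bh_adjust(unname(p))
  )
  out <- out[order(out$q, out$p, out$id), , drop = FALSE]
  attr(out, "n_query_annotated") <- n
  attr(out, "universe_size") <- N
  out
}

#' Write enrichment results as TSV
#'
#' @param results Output of [enrich()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
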