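#' Filtering criteria for differential-expression records
#'
#' Bundles the significance and fold-change thresholds used to call a gene
#' differentially expressed in one study. Two fold-change dialects are
#' supported: `scale = "ratio"` treats `fold_change` as a tumor/non-tumor
#' expression ratio and keeps records with FC at or below `low_fc` (down)
#' or at or above `high_fc` (up); `scale = "log2"` treats the column as a
#' log2 fold change and keeps records with |log2FC| strictly greater than
#' `log2_abs_threshold`. In both dialects the adjusted p-value must be
#' strictly below `max_adj_p`.
#'
#' @param max_adj_p Adjusted p-value cutoff (strict `<`). Default 0.05.
#' @param low_fc Down-regulation ratio threshold (inclusive `<=`). Default 0.5.
#' @param high_fc Up-regulation ratio threshold (inclusive `>=`). Default 1.5.
#' @param scale `"ratio"` (default) or `"log2"`.
#' @param log2_abs_threshold Absolute log2 fold-change threshold (strict `>`)
#'   used when `scale = "log2"`. Default 1.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(max_adj_p = 0.05, low_fc = 0.5, high_fc = 1.5,
                            scale = c("ratio", "log2"),
                            log2_abs_threshold = 1) {
  scale <- match.arg(scale)
  stopifnot(max_adj_p > 0, max_adj_p <= 1)
  if (scale == "ratio" && !(0 < low_fc && low_fc < 1 && high_fc > 1)) {
    stop("ratio-scale criteria require 0 < low_fc < 1 < high_fc")
  }
  if (scale == "log2" && log2_abs_threshold <= 0) {
    stop("log2_abs_threshold must be positive")
  }
  structure(
    list(max_adj_p = max_adj_p, low_fc = low_fc, high_fc = high_fc,
         scale = scale, log2_abs_threshold = log2_abs_threshold),
    class = "filter_criteria"
  )
}

as_filter_criteria <- function(x) {
  if (inherits(x, "filter_criteria")) return(x)
  do.call(filter_criteria, as.list(x))
}

#' Filter one study's differential-expression table
#'
#' Applies the significance and fold-change thresholds to a single study
#' table and returns the retained genes with their direction of
#' dysregulation. Multiple rows for the same gene (e.g. multiple probes)
#' are collapsed, before filtering, to the row with the smallest adjusted
#' p-value (ties broken by the more extreme fold change).
#'
#' Boundary semantics on the ratio scale: `fold_change == low_fc` and
#' `fold_change == high_fc` are retained (inclusive thresholds), while
#' `adj_p == max_adj_p` is excluded (strict threshold). Records with a
#' non-positive fold change on the ratio scale are invalid and dropped
#' with a warning.
#'
#' @param table A study table: a data frame with columns `gene`,
#'   `fold_change`, `adj_p` (an optional `study_id` column is carried
#'   along but ignored).
#' @param criteria A [filter_criteria()] object.
#' @return A tibble with columns `gene` and `direction` (`"up"`/`"down"`).
#' @export
filter_degs <- function(table, criteria = filter_criteria()) {
  criteria <- as_filter_criteria(criteria)
  stopifnot(is.data.frame(table), nrow(table) > 0,
            all(c("gene", "fold_change", "adj_p") %in% names(table)))
  tab <- tibble::as_tibble(table)
  tab$gene <- toupper(as.character(tab$gene))

  if (criteria$scale == "ratio") {
    bad <- !is.finite(tab$fold_change) | tab$fold_change <= 0
  } else {
    bad <- !is.finite(tab$fold_change)
  }
  bad <- bad | !is.finite(tab$adj_p) | tab$adj_p < 0 | tab$adj_p > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with invalid fold change or adjusted ",
            "p-value dropped")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0) {
    return(tibble::tibble(gene = character(), direction = character()))
  }

  # probe collapse: smallest adj_p wins; ties go to the more extreme FC
  extremity <- if (criteria$scale == "ratio") {
    abs(log2(tab$fold_change))
  } else {
    abs(tab$fold_change)
  }
  ord <- order(tab$gene, tab$adj_p, -extremity)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]

  if (criteria$scale == "ratio") {
    up <- tab$fold_change >= criteria$high_fc
    down <- tab$fold_change <= criteria$low_fc
  } else {
    up <- tab$fold_change > criteria$log2_abs_threshold
    down <- tab$fold_change < -criteria$log2_abs_threshold
  }
  keep <- tab$adj_p < criteria$max_adj_p & (up | down)

  out <- tibble::tibble(
    gene = tab$gene[keep],
    direction = ifelse(up[keep], "up", "down")
  )
  dplyr::arrange(out, .data$gene)
}

#' Count direction-consistent dysregulation votes across studies
#'
#' Runs [filter_degs()] on every study table and tallies, per gene, in how
#' many studies it passed the filters in the up and the down direction.
#' The consensus direction is the majority direction; an exact tie (or no
#' passing study) yields `"none"`. The support denominator is the total
#' number of studies in the run: a gene absent from a study simply
#' contributes no vote there.
#'
#' @param tables A list of study tables; each must carry a distinct
#'   `study_id` (column or `study_id` attribute), otherwise a gene could
#'   vote twice.
#' @param criteria A [filter_criteria()] object.
#' @return A tibble with columns `gene`, `support_up`, `support_down`,
#'   `n_studies`, `consensus_direction`, `consensus_support`, one row per
#'   gene appearing in any table.
#' @export
vote_count <- function(tables, criteria = filter_criteria()) {
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- vapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    if (is.data.frame(t) && "study_id" %in% names(t) && nrow(t) > 0) {
      as.character(t$study_id[[1]])
    } else if (!is.null(attr(t, "study_id"))) {
      as.character(attr(t, "study_id"))
    } else {
      paste0("study_", i)
    }
  }, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate study_id: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  }

  all_genes <- sort(unique(toupper(unlist(
    lapply(tables, function(t) as.character(t$gene))
  ))))
  n_studies <- length(tables)

  hits <- dplyr::bind_rows(lapply(tables, filter_degs, criteria = criteria))
  counts <- if (nrow(hits) > 0) {
    dplyr::summarise(
      dplyr::group_by(hits, .data$gene),
      support_up = sum(.data$direction == "up"),
      support_down = sum(.data$direction == "down"),
      .groups = "drop"
    )
  } else {
    tibble::tibble(gene = character(), support_up = integer(),
                   support_down = integer())
  }

  out <- dplyr::left_join(tibble::tibble(gene = all_genes), counts,
                          by = "gene")
  out$support_up[is.na(out$support_up)] <- 0L
  out$support_down[is.na(out$support_down)] <- 0L
  out$n_studies <- n_studies
  out$consensus_direction <- dplyr::case_when(
    out$support_up > out$support_down ~ "up",
    out$support_down > out$support_up ~ "down",
    TRUE ~ "none"
  )
  out$consensus_support <- pmax(out$support_up, out$support_down)
  out
}

#' Select the consensus gene list from vote summaries
#'
#' Keeps genes with an untied consensus direction supported by at least
#' `min_support` studies, ordered by descending support and then gene
#' symbol.
#'
#' @param votes Output of [vote_count()].
#' @param min_support Minimum number of direction-consistent studies
#'   (inclusive). Default 10, the threshold used with 19 studies.
#' @return A tibble with columns `gene`, `direction`, `support`.
#' @export
select_consensus <- function(votes, min_support = 10) {
  stopifnot(is.data.frame(votes), min_support >= 1)
  keep <- votes$consensus_direction != "none" &
    votes$consensus_support >= min_support
  out <- tibble::tibble(
    gene = votes$gene[keep],
    direction = votes$consensus_direction[keep],
    support = votes$consensus_support[keep]
  )
  out[order(-out$support, out$gene), , drop = FALSE]
}

#' Read a tab-delimited study table
#'
#' Expects a header line `gene<TAB>fold_change<TAB>adj_p` (a `study_id`
#' column is accepted and carried along). The study identifier defaults to
#' the file name without extension when no column supplies it.
#'
#' @param path Path to the TSV file.
#' @param study_id Optional study identifier overriding the default.
#' @return A tibble with columns `study_id`, `gene`, `fold_change`, `adj_p`.
#' @export
read_study_table <- function(path, study_id = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    fold_change = readr::col_double(),
    adj_p = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  stopifnot(all(c("gene", "fold_change", "adj_p") %in% names(tab)))
  if (is.null(study_id)) {
    study_id <- if ("study_id" %in% names(tab) && nrow(tab) > 0) {
      tab$study_id[[1]]
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  tab$study_id <- study_id
  tab[, c("study_id", "gene", "fold_change", "adj_p")]
}

#' Write a consensus gene list as TSV
#'
#' @param consensus Output of [select_consensus()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  readr::write_tsv(consensus, path, progress = FALSE)
  invisible(path)
}
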