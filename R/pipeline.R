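#' Pipeline configuration
#'
#' Collects the input paths and run-level thresholds for an end-to-end
#' run. The defaults are the full-scale analysis constants: consensus
#' support 10 (of 19 studies), seed degree threshold 250, and FDR level
#' 0.05.
#'
#' @param study_paths Character vector of study-table TSV paths, or a
#'   directory containing them.
#' @param interactome_path Edge-list TSV.
#' @param tissue_path Tissue-expressed gene list, one symbol per line.
#' @param gmt_path Pathway collection in GMT format (optional; `NULL`
#'   skips the enrichment stage).
#' @param survival_path Survival table TSV (optional; `NULL` skips the
#'   survival stage).
#' @param criteria A [filter_criteria()].
#' @param min_support Consensus vote threshold (default 10).
#' @param min_degree Seed interactor-count threshold (default 250).
#' @param alpha FDR level for reporting enriched pathways (default 0.05).
#' @param seed Integer seed (used by the optional permutation correction
#'   of the cutoff scan).
#' @param n_perm Permutations for the cutoff-scan corrected p (0 = skip).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(study_paths, interactome_path, tissue_path,
                            gmt_path = NULL, survival_path = NULL,
                            criteria = filter_criteria(),
                            min_support = 10, min_degree = 250,
                            alpha = 0.05, seed = 1, n_perm = 0) {
  if (length(study_paths) == 1 && dir.exists(study_paths)) {
    study_paths <- sort(list.files(study_paths, pattern = "\\.tsv$",
                                   full.names = TRUE))
  }
  stopifnot(length(study_paths) >= 1, min_support >= 1, min_degree >= 0,
            alpha > 0, alpha <= 1)
  for (p in c(study_paths, interactome_path, tissue_path,
              gmt_path, survival_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  if (min_support > length(study_paths)) {
    stop("invalid configuration: min_support (", min_support,
         ") exceeds the number of studies (", length(study_paths), ")")
  }
  structure(
    list(study_paths = study_paths, interactome_path = interactome_path,
         tissue_path = tissue_path, gmt_path = gmt_path,
         survival_path = survival_path,
         criteria = as_filter_criteria(criteria),
         min_support = min_support, min_degree = min_degree,
         alpha = alpha, seed = seed, n_perm = n_perm),
    class = "pipeline_config"
  )
}

# count connected components of an edge table (+ isolated nodes)
n_components <- function(edges, nodes = NULL) {
  g <- graph_from_edges(edges, nodes)
  n <- length(g$nodes)
  if (n == 0) return(0L)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- g$adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comps
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full gene-prioritization pipeline
#'
#' Executes the stages in order: (1) filter each study table and count
#' direction-consistent votes; (2) select the consensus genes at
#' `min_support`; (3) read the interactome, restrict it to
#' tissue-expressed genes (consensus seeds always kept), and record every
#' seed's interactor count; (4) keep seeds with at least `min_degree`
#' interactors; (5) build the induced subnetwork of the surviving seeds
#' and their partners and rank nodes by betweenness centrality; (6)
#' optionally test the consensus list for pathway over-representation;
#' (7) optionally run the best-cutoff survival analysis on the supplied
#' cohort. The headline output is the top-betweenness node.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `run_report`; see Details for the main
#'   elements (`consensus`, `seed_degrees`, `seeds`, `centrality`,
#'   `enrichment`, `survival`, `counts`, `provenance`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  counts <- list()

  tables <- run_stage("read_studies", lapply(cfg$study_paths, read_study_table))
  counts$n_studies <- length(tables)
  counts$rows_per_study <- vapply(tables, nrow, integer(1))

  votes <- run_stage("vote_count", vote_count(tables, cfg$criteria))
  consensus <- run_stage("select_consensus",
                         select_consensus(votes, cfg$min_support))
  counts$n_genes_voted <- nrow(votes)
  counts$n_consensus <- nrow(consensus)
  if (nrow(consensus) == 0) stop("no consensus gene at min_support = ",
                                 cfg$min_support)

  net <- run_stage("read_edges", read_edges(cfg$interactome_path))
  tissue <- run_stage("read_tissue", {
    x <- toupper(trimws(readLines(cfg$tissue_path, warn = FALSE)))
    x[nzchar(x)]
  })
  counts$n_edges_raw <- nrow(net)
  filtered <- run_stage("tissue_filter",
                        apply_tissue_filter(net, tissue,
                                            always_keep = consensus$gene))
  counts$n_edges_tissue <- nrow(filtered)

  nb_all <- run_stage("seed_degrees",
                      build_neighborhood(filtered, consensus$gene))
  seeds <- run_stage("degree_filter",
                     filter_seeds_by_degree(nb_all, cfg$min_degree))
  counts$n_seeds <- length(seeds)
  knee <- seed_degree_knee(nb_all)
  if (length(seeds) == 0) stop("no seed reaches min_degree = ",
                               cfg$min_degree)

  nb <- run_stage("neighborhood", build_neighborhood(filtered, seeds))
  counts$n_network_nodes <- length(nb$nodes)
  counts$n_network_edges <- nrow(nb$graph)
  counts$n_components <- n_components(nb$graph, nb$nodes)
  cent <- run_stage("betweenness",
                    betweenness_centrality(nb$graph, nodes = nb$nodes))

  enrichment <- NULL
  if (!is.null(cfg$gmt_path)) {
    enrichment <- run_stage("enrichment", {
      coll <- read_gmt(cfg$gmt_path)
      enrich(consensus$gene, coll)
    })
    counts$n_query_annotated <- attr(enrichment, "n_query_annotated")
    counts$n_pathways_significant <- sum(enrichment$q < cfg$alpha)
  }

  surv <- NULL
  if (!is.null(cfg$survival_path)) {
    surv <- run_stage("survival", {
      cohort <- read_survival_table(cfg$survival_path)
      scan <- best_cutoff_scan(cohort, n_perm = cfg$n_perm,
                               seed = cfg$seed)
      high <- scan$groups
      lo <- cohort[!high, c("time", "event")]
      hi <- cohort[high, c("time", "event")]
      list(scan = scan,
           logrank = logrank(lo, hi),
           gbw = gbw_test(lo, hi),
           hr = scan$hr,
           km_low = km_estimate(lo$time, lo$event),
           km_high = km_estimate(hi$time, hi$event),
           n = nrow(cohort))
    })
  }

  provenance <- list(
    config = cfg,
    checksums = tools::md5sum(unlist(c(cfg$study_paths,
                                       cfg$interactome_path,
                                       cfg$tissue_path, cfg$gmt_path,
                                       cfg$survival_path))),
    package_version = as.character(utils::packageVersion("hccnet")),
    seed = cfg$seed
  )

  structure(
    list(consensus = consensus,
         votes = votes,
         seed_degrees = nb_all$degree_by_seed,
         degree_knee = knee,
         seeds = seeds,
         network = nb,
         centrality = cent,
         top_node = cent$top_node,
         seed_ranking = rank_nodes(cent, restrict_to = seeds),
         enrichment = enrichment,
         survival = surv,
         counts = counts,
         provenance = provenance),
    class = "run_report"
  )
}

#' Write a run report as a TSV/JSON bundle
#'
#' Writes the consensus list, seed degrees, centrality ranking,
#' enrichment table, survival summaries, and a JSON report with the
#' headline results and provenance.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Destination directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_consensus(report$consensus, file.path(dir, "consensus.tsv"))
  readr::write_tsv(tibble::tibble(
    seed = names(report$seed_degrees),
    degree = unname(report$seed_degrees),
    selected = names(report$seed_degrees) %in% report$seeds
  ), file.path(dir, "seed_degrees.tsv"), progress = FALSE)
  write_centrality(report$centrality, file.path(dir, "centrality.tsv"),
                   seeds = report$seeds)
  if (!is.null(report$enrichment)) {
    write_enrichment(report$enrichment, file.path(dir, "enrichment.tsv"))
  }
  summary <- list(
    top_node = report$top_node,
    n_consensus = nrow(report$consensus),
    n_seeds = length(report$seeds),
    counts = report$counts,
    seed = report$provenance$seed,
    package_version = report$provenance$package_version
  )
  if (!is.null(report$survival)) {
    s <- report$survival
    summary$survival <- list(
      best_cutoff = s$scan$best_cutoff,
      logrank_p = s$logrank$p,
      gbw_p = s$gbw$p,
      hr = s$hr$hr, ci_low = s$hr$ci_low, ci_high = s$hr$ci_high,
      median_low = s$km_low$median, median_high = s$km_high$median,
      perm_p = s$scan$perm_p
    )
    readr::write_tsv(s$scan$scan, file.path(dir, "cutoff_scan.tsv"),
                     progress = FALSE)
    write_km_curve(s$km_low, file.path(dir, "km_low.tsv"))
    write_km_curve(s$km_high, file.path(dir, "km_high.tsv"))
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
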