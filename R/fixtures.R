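#' Generate a complete synthetic analysis dataset with planted truth
#'
#' Builds, in memory, a coherent set of inputs for the whole pipeline:
#' 19 study tables with a planted consensus gene set, a tissue-annotated
#' interactome in which 27 consensus genes are planted with high
#' interactor counts and the hub gene is the sole bridge between
#' communities (hence the unique betweenness maximum), a pathway
#' collection with one planted enriched pathway, and a
#' proportional-hazards survival cohort with a planted hazard ratio.
#'
#' The defaults mirror the full-scale study conditions at a size where
#' every planted structure is exactly recoverable: 19 studies with a
#' consensus-support threshold of 10, 27 high-degree seeds, and a true
#' hazard ratio of 0.45 with 364 patients and 30% censoring. The degree
#' threshold is 30 rather than 250 because the synthetic interactome has
#' hundreds, not tens of thousands, of nodes; the inclusive-threshold
#' semantics are identical.
#'
#' @param seed Integer master seed; stage seeds are derived as small
#'   offsets from it.
#' @param n_studies,min_support,n_genes,noise_rate Study-table settings
#'   (see [study_gen_config()]).
#' @param n_consensus Number of planted consensus genes (default 40).
#' @param n_high_seeds How many consensus genes receive a planted high
#'   interactor count (default 27).
#' @param min_degree Seed degree threshold the high seeds are planted to
#'   exceed (default 30).
#' @param hub Hub gene symbol (default `"ESR1"`).
#' @param true_hr,n_patients,censor_rate Survival-cohort settings.
#' @return A list with `tables`, `interactome`, `tissue`, `pathway_sets`,
#'   `pathway_descriptions`, `cohort`, `truth` (a [synthetic_truth()]),
#'   and `params`.
#' @export
generate_pipeline_fixture <- function(seed = 1, n_studies = 19,
                                      min_support = 10, n_genes = 800,
                                      noise_rate = 0.02, n_consensus = 40,
                                      n_high_seeds = 27, min_degree = 30,
                                      hub = "ESR1", true_hr = 0.45,
                                      n_patients = 364, censor_rate = 0.3) {
  stopifnot(n_high_seeds <= n_consensus, n_consensus < n_genes)
  hub <- toupper(hub)
  cons_names <- c(hub, sprintf("G%04d", seq_len(n_consensus - 1)))
  cons <- withr::with_seed(seed, tibble::tibble(
    gene = cons_names,
    direction = c("down",
                  sample(c("up", "down"), n_consensus - 1, replace = TRUE))
  ))
  truth <- synthetic_truth(cons, hub_gene = hub,
                           enriched_pathways = "PATH001",
                           true_hr = true_hr)

  scfg <- study_gen_config(n_studies = n_studies, n_genes = n_genes,
                           consensus_support = min_support,
                           noise_rate = noise_rate, seed = seed + 1)
  tables <- generate_study_tables(scfg, truth)
  universe <- attr(tables, "universe")

  high_seeds <- cons_names[seq_len(n_high_seeds)]
  low_cons <- setdiff(cons_names, high_seeds)
  pool <- setdiff(universe, cons_names)

  net <- withr::with_seed(seed + 2, {
    n_comm <- 3
    per_comm <- 90
    stopifnot(length(pool) >= n_comm * per_comm)
    partners <- split(pool[seq_len(n_comm * per_comm)],
                      rep(seq_len(n_comm), each = per_comm))
    edges <- list()
    for (c_i in seq_len(n_comm)) {
      pc <- partners[[c_i]]
      # connect the partner web: spanning tree + sparse random edges
      parent <- vapply(2:per_comm, function(i) sample.int(i - 1, 1),
                       integer(1))
      edges[[length(edges) + 1]] <-
        tibble::tibble(a = pc[parent], b = pc[2:per_comm])
      pairs <- utils::combn(pc, 2)
      extra <- stats::runif(ncol(pairs)) < 0.03
      edges[[length(edges) + 1]] <-
        tibble::tibble(a = pairs[1, extra], b = pairs[2, extra])
    }
    # hub: the only node touching more than one community
    for (c_i in seq_len(n_comm)) {
      edges[[length(edges) + 1]] <-
        tibble::tibble(a = hub, b = sample(partners[[c_i]],
                                           min_degree %/% 2 - 3))
    }
    # remaining high seeds: many partners inside a single community
    comm_of <- rep_len(seq_len(n_comm), length(high_seeds) - 1)
    for (i in seq_along(comm_of)) {
      edges[[length(edges) + 1]] <-
        tibble::tibble(a = high_seeds[i + 1],
                       b = sample(partners[[comm_of[i]]], min_degree + 5))
    }
    # low-support consensus genes: degree safely below the threshold
    comm_of_low <- rep_len(seq_len(n_comm), length(low_cons))
    for (i in seq_along(low_cons)) {
      edges[[length(edges) + 1]] <-
        tibble::tibble(a = low_cons[i],
                       b = sample(partners[[comm_of_low[i]]],
                                  min_degree %/% 2))
    }
    as_interactome(dplyr::bind_rows(edges))
  })
  tissue <- c(interactome_nodes(net), sprintf("DECOY%03d", 1:25))

  pathway_sets <- withr::with_seed(seed + 3, {
    planted <- unique(c(sample(cons_names, 32),
                        sample(pool, 28)))
    others <- lapply(seq_len(39), function(i) {
      sample(pool, sample(15:60, 1))
    })
    sets <- c(list(planted), others)
    names(sets) <- sprintf("PATH%03d", seq_along(sets))
    sets
  })
  descriptions <- stats::setNames(
    c("planted enriched pathway", sprintf("random pathway %d", 2:40)),
    names(pathway_sets))

  cohort <- generate_survival_cohort(cohort_gen_config(
    n_patients = n_patients, true_hr = true_hr,
    censor_rate = censor_rate, seed = seed + 4
  ))

  list(tables = tables, interactome = net, tissue = tissue,
       pathway_sets = pathway_sets, pathway_descriptions = descriptions,
       cohort = cohort, truth = truth,
       params = list(seed = seed, n_studies = n_studies,
                     min_support = min_support, min_degree = min_degree,
                     n_high_seeds = n_high_seeds, high_seeds = high_seeds,
                     alpha = 0.05))
}

#' Materialize a synthetic dataset as a fixture directory
#'
#' Writes the output of [generate_pipeline_fixture()] in the same
#' plain-text formats the ingestion functions read: per-study TSV tables
#' under `studies/`, an edge-list TSV, a one-symbol-per-line tissue gene
#' list, a GMT pathway file, a survival TSV, and the planted truth as
#' JSON.
#'
#' @param dir Destination directory (created if missing).
#' @param seed Master seed passed to [generate_pipeline_fixture()].
#' @param ... Further arguments to [generate_pipeline_fixture()].
#' @return Invisibly, a list with the `fixture` and the file `paths`.
#' @export
make_fixtures <- function(dir, seed = 1, ...) {
  fx <- generate_pipeline_fixture(seed = seed, ...)
  dir.create(file.path(dir, "studies"), recursive = TRUE,
             showWarnings = FALSE)
  study_paths <- vapply(fx$tables, function(tab) {
    p <- file.path(dir, "studies", paste0(tab$study_id[[1]], ".tsv"))
    readr::write_tsv(tab, p, progress = FALSE)
    p
  }, character(1))

  paths <- list(
    studies = study_paths,
    interactome = file.path(dir, "interactome.tsv"),
    tissue = file.path(dir, "tissue_genes.txt"),
    gmt = file.path(dir, "pathways.gmt"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.json")
  )
  # IID-style header, auto-detected and skipped by read_edges()
  readr::write_tsv(
    stats::setNames(fx$interactome, c("symbol1", "symbol2")),
    paths$interactome, progress = FALSE)
  writeLines(fx$tissue, paths$tissue)
  write_gmt(fx$pathway_sets, paths$gmt, fx$pathway_descriptions)
  readr::write_tsv(fx$cohort[, c("patient", "time", "event",
                                 "expression", "sex")],
                   paths$survival, progress = FALSE)
  jsonlite::write_json(
    list(consensus_genes = fx$truth$consensus_genes,
         hub_gene = fx$truth$hub_gene,
         enriched_pathways = fx$truth$enriched_pathways,
         true_hr = fx$truth$true_hr,
         high_seeds = fx$params$high_seeds,
         min_support = fx$params$min_support,
         min_degree = fx$params$min_degree),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(fixture = fx, paths = paths))
}
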