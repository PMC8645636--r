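#' Planted ground truth for a synthetic dataset
#'
#' Records what the generators planted so that downstream stages can be
#' checked against it: the consensus genes and their directions, the hub
#' gene constructed to have maximal betweenness, the enriched pathway
#' identifiers, and the true hazard ratio of the high-expression group.
#'
#' @param consensus_genes A data frame with columns `gene` and
#'   `direction` (`"up"`/`"down"`), nonempty.
#' @param hub_gene Gene symbol planted as the top-betweenness node.
#' @param enriched_pathways Character vector of planted pathway ids.
#' @param true_hr Positive hazard ratio of the high- vs low-expression
#'   group.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(consensus_genes, hub_gene,
                            enriched_pathways = character(),
                            true_hr = 1) {
  stopifnot(is.data.frame(consensus_genes), nrow(consensus_genes) > 0,
            all(c("gene", "direction") %in% names(consensus_genes)),
            all(consensus_genes$direction %in% c("up", "down")),
            is.character(hub_gene), length(hub_gene) == 1,
            true_hr > 0)
  consensus_genes$gene <- toupper(consensus_genes$gene)
  structure(
    list(consensus_genes = tibble::as_tibble(consensus_genes),
         hub_gene = toupper(hub_gene),
         enriched_pathways = enriched_pathways,
         true_hr = true_hr),
    class = "synthetic_truth"
  )
}

#' Configuration for study-table generation
#'
#' @param n_studies Number of studies (default 19).
#' @param n_genes Size of the gene universe (consensus genes included).
#' @param consensus_support Minimum number of studies in which each
#'   planted consensus gene passes the filters in its direction
#'   (default 10).
#' @param noise_rate Per-study probability that a non-consensus gene
#'   passes the filters by chance (default 0.02).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `study_gen_config`.
#' @export
study_gen_config <- function(n_studies = 19, n_genes = 2000,
                             consensus_support = 10, noise_rate = 0.02,
                             seed = 1) {
  stopifnot(n_studies >= 1, n_genes >= 1,
            consensus_support >= 1,
            noise_rate >= 0, noise_rate < 1)
  if (consensus_support > n_studies) {
    stop("invalid configuration: consensus_support (", consensus_support,
         ") exceeds n_studies (", n_studies, ")")
  }
  structure(
    list(n_studies = n_studies, n_genes = n_genes,
         consensus_support = consensus_support,
         noise_rate = noise_rate, seed = seed),
    class = "study_gen_config"
  )
}

# Draw a pass/fail matrix for noise genes and cap any gene that would
# reach `support` chance passes in one direction at support - 1, so the
# planted consensus set remains exactly recoverable.
cap_noise_passes <- function(pass, support) {
  over <- which(rowSums(pass) >= support)
  for (i in over) {
    hits <- which(pass[i, ])
    pass[i, hits[support:length(hits)]] <- FALSE
  }
  pass
}

#' Generate per-study differential-expression tables with planted truth
#'
#' Emulates GEO2R-style output for `cfg$n_studies` studies over a shared
#' gene universe. Each planted consensus gene passes the default filters
#' (adjusted p < 0.05, ratio fold change <= 0.5 or >= 1.5) in its planted
#' direction in at least `cfg$consensus_support` studies; every other
#' gene passes in a given study with probability `cfg$noise_rate`
#' (random direction), capped so that no noise gene ever reaches
#' `consensus_support` direction-consistent passes. Deterministic given
#' the seed.
#'
#' @param cfg A [study_gen_config()].
#' @param truth A [synthetic_truth()]; its consensus genes become part of
#'   the universe of size `cfg$n_genes`.
#' @return A list of `cfg$n_studies` tibbles with columns `study_id`,
#'   `gene`, `fold_change`, `adj_p`; the gene universe is attached as the
#'   `universe` attribute.
#' @export
generate_study_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "study_gen_config"),
            inherits(truth, "synthetic_truth"))
  cons <- truth$consensus_genes
  if (nrow(cons) > cfg$n_genes) {
    stop("more consensus genes than the gene universe holds")
  }
  n_fill <- cfg$n_genes - nrow(cons)
  universe <- c(cons$gene,
                setdiff(sprintf("G%04d", seq_len(n_fill + nrow(cons))),
                        cons$gene)[seq_len(n_fill)])
  noise_genes <- setdiff(universe, cons$gene)
  n_noise <- length(noise_genes)
  S <- cfg$n_studies

  withr::with_seed(cfg$seed, {
    # planted pass pattern: each consensus gene passes in m >= support
    # studies drawn uniformly
    cons_pass <- matrix(FALSE, nrow(cons), S)
    for (i in seq_len(nrow(cons))) {
      m <- if (cfg$consensus_support == S) S else
        sample(cfg$consensus_support:S, 1)
      cons_pass[i, sample.int(S, m)] <- TRUE
    }

    # chance passes for noise genes, direction drawn per (gene, study)
    pass <- matrix(stats::runif(n_noise * S) < cfg$noise_rate, n_noise, S)
    up_dir <- matrix(stats::runif(n_noise * S) < 0.5, n_noise, S)
    pass_up <- cap_noise_passes(pass & up_dir, cfg$consensus_support)
    pass_down <- cap_noise_passes(pass & !up_dir, cfg$consensus_support)

    draw_fc_up <- function(n) stats::runif(n, 1.5, 6)
    draw_fc_down <- function(n) stats::runif(n, 0.1, 0.5)
    draw_fc_null <- function(n) stats::runif(n, 0.6, 1.4)
    draw_p_sig <- function(n) stats::runif(n, 1e-8, 0.049)

    tables <- lapply(seq_len(S), function(s) {
      fc <- draw_fc_null(cfg$n_genes)
      p <- stats::runif(cfg$n_genes)
      names(fc) <- names(p) <- universe

      ci <- which(cons_pass[, s])
      if (length(ci) > 0) {
        up <- cons$direction[ci] == "up"
        fc[cons$gene[ci[up]]] <- draw_fc_up(sum(up))
        fc[cons$gene[ci[!up]]] <- draw_fc_down(sum(!up))
        p[cons$gene[ci]] <- draw_p_sig(length(ci))
      }
      nu <- which(pass_up[, s]); nd <- which(pass_down[, s])
      fc[noise_genes[nu]] <- draw_fc_up(length(nu))
      fc[noise_genes[nd]] <- draw_fc_down(length(nd))
      p[noise_genes[c(nu, nd)]] <- draw_p_sig(length(nu) + length(nd))

      tibble::tibble(study_id = sprintf("S%02d", s), gene = universe,
                     fold_change = unname(fc), adj_p = unname(p))
    })
    attr(tables, "universe") <- universe
    tables
  })
}

#' Generate an interactome with a planted top-betweenness hub
#'
#' Builds an undirected simple graph of `n_communities` internally
#' connected communities joined *only* through the hub node, making the
#' hub the sole articulation vertex between communities and hence the
#' unique betweenness maximum (every cross-community shortest path passes
#' through it). Community internals are random connected graphs. A
#' tissue-expression gene list covering all emitted nodes plus decoy
#' non-expressed symbols is returned alongside.
#'
#' @param n_nodes Total node count including the hub (>= 10).
#' @param hub Hub gene symbol.
#' @param seed Integer seed.
#' @param n_communities Number of communities (default 3).
#' @param within_prob Extra-edge probability inside a community beyond
#'   the connecting spanning tree (default 0.25).
#' @param hub_links Hub attachment points per community (default 3).
#' @return A list with `interactome` (edge tibble), `tissue` (character
#'   vector), `hub`, and `communities` (list of node vectors).
#' @export
generate_interactome <- function(n_nodes, hub, seed = 1,
                                 n_communities = 3, within_prob = 0.25,
                                 hub_links = 3) {
  stopifnot(n_nodes >= 10, n_communities >= 2)
  hub <- toupper(hub)
  others <- sprintf("N%04d", seq_len(n_nodes - 1))
  withr::with_seed(seed, {
    comm <- split(others, rep_len(seq_len(n_communities), length(others)))
    edges <- list()
    for (nodes in comm) {
      k <- length(nodes)
      # random spanning tree: each node attaches to a random predecessor
      if (k >= 2) {
        parent <- vapply(2:k, function(i) sample.int(i - 1, 1), integer(1))
        edges[[length(edges) + 1]] <-
          tibble::tibble(a = nodes[parent], b = nodes[2:k])
      }
      if (k >= 3) {
        pairs <- utils::combn(nodes, 2)
        extra <- stats::runif(ncol(pairs)) < within_prob
        edges[[length(edges) + 1]] <-
          tibble::tibble(a = pairs[1, extra], b = pairs[2, extra])
      }
      # hub attaches inside this community; no other cross edges exist
      att <- sample(nodes, min(hub_links, k))
      edges[[length(edges) + 1]] <- tibble::tibble(a = hub, b = att)
    }
    net <- as_interactome(dplyr::bind_rows(edges))
    tissue <- c(sort(c(hub, others)), sprintf("DECOY%03d", 1:20))
    list(interactome = net, tissue = tissue, hub = hub,
         communities = comm)
  })
}

#' Configuration for survival-cohort generation
#'
#' @param n_patients Cohort size (>= 20; default 364).
#' @param true_hr Planted hazard ratio of the high-expression group
#'   (default 0.45, i.e. high expression protective).
#' @param baseline_hazard Event hazard per month in the low-expression
#'   group (default 0.025, giving a median survival near 28 months).
#' @param censor_rate Expected fraction of censored patients in `[0, 1)`
#'   (default 0.3).
#' @param expression_gap Separation between the means of the low and high
#'   expression subpopulations (default 4, each with unit SD).
#' @param seed Integer seed.
#' @return A list of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n_patients = 364, true_hr = 0.45,
                              baseline_hazard = 0.025, censor_rate = 0.3,
                              expression_gap = 4, seed = 1) {
  stopifnot(n_patients >= 20, true_hr > 0, baseline_hazard > 0,
            censor_rate >= 0, censor_rate < 1)
  structure(
    list(n_patients = n_patients, true_hr = true_hr,
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         expression_gap = expression_gap, seed = seed),
    class = "cohort_gen_config"
  )
}

#' Generate a proportional-hazards survival cohort
#'
#' Exactly half the patients (rounded down) form the high-expression
#' subpopulation. Expression is bimodal: low ~ N(0, 1), high ~
#' N(`expression_gap`, 1). Event times are exponential with hazard
#' `baseline_hazard` in the low group and `baseline_hazard * true_hr` in
#' the high group. Censoring is independent exponential with a
#' group-specific rate chosen so that the expected censored fraction is
#' `censor_rate` in each group; with `censor_rate = 0` every record is an
#' event.
#'
#' @param cfg A [cohort_gen_config()].
#' @return A tibble with columns `patient`, `time` (months), `event`,
#'   `expression`, `sex`, and the planted `group` (`"low"`/`"high"`).
#' @export
generate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_gen_config"))
  n <- cfg$n_patients
  withr::with_seed(cfg$seed, {
    high <- rep(FALSE, n)
    high[sample.int(n, n %/% 2)] <- TRUE
    expression <- stats::rnorm(n, mean = ifelse(high, cfg$expression_gap, 0))
    rate <- cfg$baseline_hazard * ifelse(high, cfg$true_hr, 1)
    t_event <- stats::rexp(n, rate)
    if (cfg$censor_rate > 0) {
      c_rate <- rate * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- stats::rexp(n, c_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    tibble::tibble(
      patient = sprintf("P%04d", seq_len(n)),
      time = time, event = event, expression = expression,
      sex = sample(c("M", "F"), n, replace = TRUE),
      group = ifelse(high, "high", "low")
    )
  })
}

#' Write a pathway collection in GMT format
#'
#' @param sets Named list of gene-symbol vectors.
#' @param path Destination file.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
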