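# Independent oracle implementations and small generators used across the
# suite. These deliberately avoid the package's own code paths.

# random simple graph as an edge tibble over nodes V1..Vn
rand_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n))
    pairs <- utils::combn(nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p
    tibble::tibble(a = pairs[1, keep], b = pairs[2, keep])
  })
}

# random labelled tree via random attachment
rand_tree <- function(n, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("T%02d", seq_len(n))
    parent <- vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))
    tibble::tibble(a = nodes[parent], b = nodes[2:n])
  })
}

# BH step-up coded directly from the rejection-threshold definition
oracle_stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# classical step-up rejection set at level alpha, straight from the rule:
# reject p_(1..k*) where k* = max{k : p_(k) <= k/m * alpha}
oracle_stepup_rejections <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# brute-force recount of direction-consistent support over raw tables,
# written as plain per-gene loops over the records
oracle_support_recount <- function(tables, gene,
                                   max_p = 0.05, lo = 0.5, hi = 1.5) {
  up <- 0L; down <- 0L
  for (tab in tables) {
    rows <- tab[toupper(tab$gene) == toupper(gene), , drop = FALSE]
    if (nrow(rows) == 0) next
    best <- rows[which.min(rows$adj_p), ]
    if (best$adj_p < max_p && best$fold_change >= hi) up <- up + 1L
    if (best$adj_p < max_p && best$fold_change <= lo) down <- down + 1L
  }
  c(up = up, down = down)
}

# weighted log-rank O/E/V oracle written as one explicit 2x2 table per
# event time, looping over a long-format risk table
oracle_weighted_logrank_chi2 <- function(time, event, in_a,
                                         gehan = FALSE) {
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    r <- data.frame(time = time, event = event, in_a = in_a)
    r <- r[r$time >= t, ]
    n1 <- sum(r$in_a); n2 <- sum(!r$in_a); n <- n1 + n2
    d1 <- sum(r$in_a & r$event == 1 & r$time == t)
    d2 <- sum(!r$in_a & r$event == 1 & r$time == t)
    d <- d1 + d2
    w <- if (gehan) n else 1
    U <- U + w * (d1 - d * n1 / n)
    if (n > 1) {
      V <- V + w^2 * d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    }
  }
  U^2 / V
}

# two equally sized survival arms with a hazard ratio between them
two_arm_cohort <- function(n_per_arm, hr, seed, censor = 0) {
  withr::with_seed(seed, {
    t_a <- stats::rexp(n_per_arm, 0.03)
    t_b <- stats::rexp(n_per_arm, 0.03 * hr)
    dat <- data.frame(
      time = c(t_a, t_b),
      event = 1L,
      arm = rep(c("a", "b"), each = n_per_arm)
    )
    if (censor > 0) {
      c_time <- stats::rexp(2 * n_per_arm, 0.03 * censor)
      dat$event <- as.integer(dat$time <= c_time)
      dat$time <- pmin(dat$time, c_time)
    }
    dat
  })
}

five_gene_truth <- function() {
  synthetic_truth(
    tibble::tibble(gene = sprintf("CONS%d", 1:5),
                   direction = c("up", "up", "down", "up", "down")),
    hub_gene = "CONS1"
  )
}
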