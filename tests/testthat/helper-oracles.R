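# Independent oracles, deliberately written as direct transcriptions of the
# definitions and kept separate from the package's code paths.

# Poisson LRT via full log-likelihoods (factorial terms included; they
# cancel in the ratio, so this cross-checks the package's reduced form).
oracle_poisson_lrt <- function(a, b) {
  a <- round(a)
  b <- round(b)
  loglik <- function(x, mu) {
    if (mu == 0) return(sum(stats::dpois(x, 0, log = TRUE)))
    sum(stats::dpois(x, mu, log = TRUE))
  }
  ll0 <- loglik(c(a, b), mean(c(a, b)))
  ll1 <- loglik(a, mean(a)) + loglik(b, mean(b))
  max(0, 2 * (ll1 - ll0))
}

# Pearson r through the textbook sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Correlation-change category, straight through the definition,
# scalar-only and branch-by-branch.
oracle_classify <- function(rn, rc, tau, dmin) {
  if (rn > tau) {
    start <- "pos"
  } else if (rn < -tau) {
    start <- "neg"
  } else {
    return("undefined")
  }
  if (abs(rn - rc) < dmin) return("null_change")
  if (start == "pos") {
    if (rc > rn) return("pos_more_pos")
    if (rc < -tau) return("pos_to_neg")
    return("pos_less_pos")
  }
  if (rc < rn) return("neg_more_neg")
  if (rc > tau) return("neg_to_pos")
  "neg_less_neg"
}

# Seed-incident interaction count by brute-force scan of an edge list
# (two-column character matrix).
oracle_direct_count <- function(edges, seeds) {
  sum(edges[, 1] %in% seeds | edges[, 2] %in% seeds)
}

# Brute-force degree of one vertex within the seed-incident edge set.
oracle_degree <- function(edges, seeds, v) {
  inc <- edges[edges[, 1] %in% seeds | edges[, 2] %in% seeds, ,
               drop = FALSE]
  sum(inc[, 1] == v) + sum(inc[, 2] == v)
}
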