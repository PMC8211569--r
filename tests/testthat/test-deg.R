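test_that("library normalization equalizes column sums to the median", {
  expr <- make_expr(list(A = c(10, 30), B = c(90, 270)))
  out <- normalize_library(expr)
  # median of {100, 300} is 200 (mean of the two middle values)
  expect_equal(colSums(as.matrix(out[-1])), c(s1 = 200, s2 = 200))

  # already-equal sums pass through unchanged
  eq <- make_expr(list(A = c(10, 20), B = c(90, 80)))
  expect_equal(normalize_library(eq), eq, tolerance = 1e-12)

  # equal-within-tolerance invariant on arbitrary matrices
  set.seed(1)
  m <- make_expr(list(A = runif(7), B = runif(7), C = runif(7)))
  cs <- colSums(as.matrix(normalize_library(m)[-1]))
  expect_lt(diff(range(cs)) / mean(cs), 1e-9)

  z <- make_expr(list(A = c(1, 0), B = c(2, 0)))
  expect_error(normalize_library(z), "all-zero sample column.*s2")
})

test_that("log2 fold-change matches its closed form and sign convention", {
  # equal means -> 0 for any pseudocount
  pair <- make_pair(list(A = c(2, 4, 6)), list(A = c(4, 4, 4)))
  expect_equal(compute_log2fc(pair, "A", pseudocount = 0.5,
                              normalize = FALSE), 0)

  # mean_cancer = 4 * mean_normal -> 2 in the small-pseudocount limit
  pair <- make_pair(list(A = c(1, 3), B = c(5, 5)),
                    list(A = c(8, 8), B = c(5, 5)))
  expect_equal(compute_log2fc(pair, "A", pseudocount = 1e-12,
                              normalize = FALSE), 2, tolerance = 1e-9)

  # positive = upregulated in cancer; arm swap flips the sign exactly
  swapped <- structure(list(cancer_type = pair$cancer_type,
                            normal = pair$cancer, cancer = pair$normal),
                       class = "cohort_pair")
  expect_equal(compute_log2fc(swapped, "A", normalize = FALSE),
               -compute_log2fc(pair, "A", normalize = FALSE))

  # absent gene is unavailable, not an error
  expect_true(is.na(compute_log2fc(pair, "ZZZ")))

  # planted log2FC recovered from a generated cohort within +-0.3
  spec <- synthetic_spec(40, "ONE", 50, 50,
                         planted_degs = tibble::tibble(gene = "G001",
                                                       log2fc = -3),
                         seed = 99)
  gen <- generate_cohorts(spec)
  est <- compute_log2fc(gen$pairs[[1]], "G001")
  expect_lt(abs(est - (-3)), 0.3)
})

test_that("two-group Poisson LRT agrees with the brute-force likelihood", {
  # identical groups: statistic exactly 0, p exactly 1
  r0 <- lrt_two_group(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # frozen value computed from the full Poisson log-likelihoods
  r <- lrt_two_group(c(10, 12, 11), c(30, 28, 31))
  expect_equal(r$statistic, 26.6935500108, tolerance = 1e-9)
  expect_equal(r$statistic, oracle_poisson_lrt(c(10, 12, 11), c(30, 28, 31)),
               tolerance = 1e-10)

  # random small-count instances against the oracle
  set.seed(20)
  for (i in 1:50) {
    a <- rpois(sample(2:10, 1), runif(1, 0, 30))
    b <- rpois(sample(2:10, 1), runif(1, 0, 30))
    got <- lrt_two_group(a, b)
    expect_equal(got$statistic, oracle_poisson_lrt(a, b), tolerance = 1e-8)
    # exchanging the groups leaves the statistic unchanged
    expect_equal(lrt_two_group(b, a)$statistic, got$statistic,
                 tolerance = 1e-12)
    # zero statistic iff the rounded group means are equal
    expect_equal(got$statistic == 0, mean(round(a)) == mean(round(b)))
  }

  # p-value is monotone decreasing in the statistic
  stats <- c(0.1, 1, 5, 20)
  ps <- pchisq(stats, 1, lower.tail = FALSE)
  expect_true(all(diff(ps) < 0))

  # degenerate all-zero case is flagged
  rz <- lrt_two_group(c(0, 0), c(0, 0, 0))
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p_value, 1)
  expect_true(attr(rz, "degenerate"))

  expect_error(lrt_two_group(numeric(), 1:3), "non-empty")
  expect_error(lrt_two_group(c(-1, 2), 1:3), "nonnegative")
})

test_that("trend screen uses strict sign over available cohorts", {
  rec <- tibble::tibble(
    gene = c("UP", "UP", "MIX", "MIX", "NAOK", "NAOK", "NAOK",
             "FLAT", "GONE"),
    cancer_type = c("C1", "C2", "C1", "C2", "C1", "C2", "C3",
                    "C1", "C1"),
    log2fc = c(1.1, 0.2, 0.5, -0.2, 1.1, NA, 0.3, 0, NA),
    p_value = NA_real_,
    available = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  tr <- screen_trend(rec)
  get <- function(g) tr[tr$gene == g, ]
  expect_true(get("UP")$trend_consistent)
  expect_equal(get("UP")$direction, "up")
  expect_false(get("MIX")$trend_consistent)
  expect_equal(get("MIX")$direction, "mixed")
  # unavailable cohorts are ignored
  expect_true(get("NAOK")$trend_consistent)
  expect_equal(get("NAOK")$n_available, 2L)
  # zero counts as neither direction
  expect_false(get("FLAT")$trend_consistent)
  # genes available nowhere are excluded but reported
  expect_false("GONE" %in% tr$gene)
  expect_equal(attr(tr, "excluded"), "GONE")
})

test_that("differential screen applies both cut-offs and is monotone", {
  rec <- grid_to_records(pan_cancer_log2fc_grid())
  out <- screen_differential(rec, fc_cutoff = 1, p_cutoff = 0.05)
  expect_true(attr(out, "p_waived"))
  expect_equal(out$gene[out$hit], "ADH1B")
  # PDHA2 fails only through its sub-threshold cohort
  pdha2 <- out[out$gene == "PDHA2", ]
  expect_equal(pdha2$n_available - pdha2$n_cohorts_differential, 1L)

  # vacuous threshold admits every gene (p waived on printed grids)
  all_in <- screen_differential(rec, fc_cutoff = 0)
  expect_true(all(all_in$hit))

  # sorted by cohort count, then symbol
  expect_true(!is.unsorted(rev(out$n_cohorts_differential)))

  # monotonicity: raising fc_cutoff or lowering p_cutoff never adds a gene
  spec <- small_spec()
  gen <- generate_cohorts(spec)
  drec <- purrr::map_dfr(gen$pairs, deg_table)
  hits_at <- function(fc, p) {
    h <- screen_differential(drec, fc_cutoff = fc, p_cutoff = p)
    h$gene[h$hit]
  }
  base <- hits_at(1, 0.05)
  expect_true(all(hits_at(2, 0.05) %in% base))
  expect_true(all(hits_at(1, 0.001) %in% base))
  expect_true(all(base %in% hits_at(0.5, 0.05)))
})

test_that("planted DEGs are recovered with no false positives across seeds", {
  for (s in 1:5) {
    spec <- synthetic_spec(
      55, c("C1", "C2"), 30, 60,
      planted_degs = tibble::tibble(
        gene = sprintf("G%03d", 1:5),
        log2fc = c(3, -3, 3, -3, 3)),
      seed = 100 + s)
    gen <- generate_cohorts(spec)
    drec <- purrr::map_dfr(gen$pairs, deg_table)
    out <- screen_differential(drec, fc_cutoff = 1, p_cutoff = 0.05)
    expect_setequal(out$gene[out$hit], sprintf("G%03d", 1:5))
  }
})

test_that("fold-change grids reshape losslessly between wide and long", {
  grid <- pan_cancer_log2fc_grid()
  rec <- grid_to_records(grid)
  expect_equal(sum(!rec$available), 1L)  # one unavailable cell
  back <- log2fc_grid(rec)
  expect_equal(back, dplyr::arrange(grid, gene))
})
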