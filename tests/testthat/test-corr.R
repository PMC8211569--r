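test_that("correlation matrices match the textbook formula and flag degeneracies", {
  # duplicated gene -> r = 1; negation around the mean -> r = -1
  x <- c(1, 4, 2, 8, 5)
  expr <- make_expr(list(A = x, Adup = x, Aneg = 2 * mean(x) - x,
                         FLAT = rep(3, 5)))
  cm <- correlation_matrix(expr, transform = "none")
  expect_equal(cm$r["A", "Adup"], 1)
  expect_equal(cm$r["A", "Aneg"], -1)
  # zero-variance gene undefined against everything, including itself
  expect_false(any(cm$defined["FLAT", ]))
  expect_true(all(is.na(cm$r["FLAT", ])))
  # defined diagonal is exactly 1
  expect_equal(unname(diag(cm$r)[1:3]), rep(1, 3))

  # entrywise agreement with the sum-formula oracle on a 5 x 30 fixture
  set.seed(33)
  rows <- purrr::map(1:5, ~ runif(30, 0, 50))
  names(rows) <- sprintf("g%d", 1:5)
  expr <- make_expr(rows)
  cm <- correlation_matrix(expr, transform = "none")
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(cm$r[i, j], oracle_pearson(rows[[i]], rows[[j]]),
                   tolerance = 1e-10)
    }
  }
  expect_lt(max(abs(cm$r - t(cm$r))), 1e-12)

  # the log2p1 transform is what correlations see by default
  cm_t <- correlation_matrix(expr)
  expect_equal(cm_t$r[1, 2],
               oracle_pearson(log2(rows[[1]] + 1), log2(rows[[2]] + 1)),
               tolerance = 1e-10)

  expect_error(correlation_matrix(make_expr(list(A = c(1, 2), B = c(2, 1)))),
               "at least 3 samples")
})

test_that("change classification matches the definition on an exhaustive grid", {
  # the canonical weakening-negative pattern
  expect_equal(classify_change(-0.60, -0.20,
                               screen_config(sign_tau = 0.1,
                                             delta_min = 0.1)),
               "neg_less_neg")
  # no change at all
  expect_equal(classify_change(0.70, 0.70), "null_change")
  # dead zone start
  expect_equal(classify_change(0.05, 0.9), "undefined")
  # boundary r_cancer == -sign_tau weakens rather than crosses
  expect_equal(classify_change(0.8, -0.1), "pos_less_pos")
  expect_equal(classify_change(0.8, -0.100001), "pos_to_neg")

  grid <- seq(-1, 1, length.out = 41)
  for (cfg in list(screen_config(0.1, 0.1), screen_config(0, 0),
                   screen_config(0.3, 0.05), screen_config(0.05, 0.5))) {
    for (rn in grid) {
      got <- classify_change(rep(rn, 41), grid, cfg)
      want <- vapply(grid, function(rc)
        oracle_classify(rn, rc, cfg$sign_tau, cfg$delta_min), character(1))
      expect_identical(got, want)
    }
  }
})

test_that("change classification is antisymmetric under global sign flip", {
  mirror <- c(pos_more_pos = "neg_more_neg", pos_less_pos = "neg_less_neg",
              pos_to_neg = "neg_to_pos", neg_more_neg = "pos_more_pos",
              neg_less_neg = "pos_less_pos", neg_to_pos = "pos_to_neg",
              null_change = "null_change", undefined = "undefined")
  set.seed(5)
  rn <- runif(500, -1, 1)
  rc <- runif(500, -1, 1)
  cfg <- screen_config(0.1, 0.1)
  expect_identical(classify_change(-rn, -rc, cfg),
                   unname(mirror[classify_change(rn, rc, cfg)]))
})

test_that("pair records use canonical pair order and propagate undefined", {
  pair <- make_pair(
    list(B = c(1, 2, 3, 4), A = c(2, 4, 6, 9), FLAT = rep(1, 4)),
    list(B = c(5, 1, 4, 2), A = c(1, 5, 2, 4), FLAT = c(1, 1, 2, 1)))
  rec <- pair_change_table(pair, screen_config(transform = "none"))
  expect_equal(nrow(rec), 3L)
  expect_true(all(rec$gene_a < rec$gene_b))
  # FLAT has zero variance in the normal arm -> undefined with NA r
  und <- rec[rec$gene_a == "A" & rec$gene_b == "FLAT", ]
  expect_equal(und$category, "undefined")
  expect_true(is.na(und$r_normal))
})

test_that("consistency screen intersects categories across cohorts", {
  mk <- function(ct, cat, a = "A", b = "B") {
    tibble::tibble(gene_a = a, gene_b = b, cancer_type = ct,
                   r_normal = 0.8, r_cancer = 0.3, category = cat)
  }
  # same real category everywhere -> hit
  rec <- dplyr::bind_rows(mk("C1", "pos_less_pos"), mk("C2", "pos_less_pos"),
                          mk("C3", "pos_less_pos"))
  hit <- screen_consistent_pairs(rec)
  expect_equal(hit$category, "pos_less_pos")
  expect_equal(hit$n_cohorts_defined, 3L)

  # one null_change cohort breaks consistency
  rec2 <- dplyr::bind_rows(mk("C1", "pos_less_pos"), mk("C2", "pos_less_pos"),
                           mk("C3", "null_change"))
  expect_equal(nrow(screen_consistent_pairs(rec2)), 0L)

  # undefined cohorts: excluded under require_all, allowed otherwise
  rec3 <- dplyr::bind_rows(mk("C1", "pos_less_pos"), mk("C2", "pos_less_pos"),
                           mk("C3", "undefined"))
  expect_equal(nrow(screen_consistent_pairs(rec3, require_all = TRUE)), 0L)
  relaxed <- screen_consistent_pairs(rec3, require_all = FALSE)
  expect_equal(relaxed$n_cohorts_defined, 2L)

  # output sorted by gene_a then gene_b
  rec4 <- dplyr::bind_rows(
    mk("C1", "neg_less_neg", "X", "Y"), mk("C1", "pos_less_pos"),
    mk("C2", "neg_less_neg", "X", "Y"), mk("C2", "pos_less_pos"))
  out <- screen_consistent_pairs(rec4)
  expect_equal(out$gene_a, c("A", "X"))
})

test_that("the hit set shrinks as thresholds tighten and cohorts accumulate", {
  gen <- generate_cohorts(small_spec(seed = 77))
  recs_at <- function(cfg) purrr::map_dfr(gen$pairs, pair_change_table,
                                          cfg = cfg)
  key <- function(h) paste(h$gene_a, h$gene_b)
  base <- screen_consistent_pairs(recs_at(screen_config(0.1, 0.1)))
  expect_true(all(key(screen_consistent_pairs(recs_at(screen_config(0.3, 0.1))))
                  %in% key(base)))
  expect_true(all(key(screen_consistent_pairs(recs_at(screen_config(0.1, 0.4))))
                  %in% key(base)))
  # adding a cohort under require_all can only remove hits
  rec_all <- recs_at(screen_config(0.1, 0.1))
  rec_sub <- dplyr::filter(rec_all, cancer_type != "C03")
  expect_true(all(key(screen_consistent_pairs(rec_all))
                  %in% key(screen_consistent_pairs(rec_sub))))
})

test_that("planted correlated pairs are stronger in normal arms than cancer", {
  gen <- generate_cohorts(small_spec(seed = 13))
  rec <- purrr::map_dfr(gen$pairs, pair_change_table)
  planted <- dplyr::semi_join(rec, gen$truth$planted_pairs,
                              by = c("gene_a", "gene_b"))
  expect_gt(mean(abs(planted$r_normal)), mean(abs(planted$r_cancer)))
})

test_that("hit tables render the arrow-style category labels", {
  hits <- tibble::tibble(gene_a = c("ADH6", "ENO1"),
                         gene_b = c("GYC1", "PPP2R1A"),
                         category = c("neg_less_neg", "pos_less_pos"),
                         n_cohorts_defined = 12L)
  ht <- format_hit_table(hits)
  expect_equal(ht$gene_pair, c("ADH6 – GYC1", "ENO1 – PPP2R1A"))
  expect_equal(ht$change, c("Negative → Less negative",
                            "Positive → Less positive"))
})

test_that("Fisher z difference test matches its closed form and null rate", {
  # equal correlations: exactly no evidence
  r0 <- fisher_z_difference(0.5, 30, 0.5, 999)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)

  # frozen closed-form value: atanh difference over its standard error
  r <- fisher_z_difference(0.8, 50, 0.1, 50)
  expect_equal(r$z, 4.8393270187, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * pnorm(-abs(r$z)))

  expect_error(fisher_z_difference(1, 10, 0.5, 10), "< 1")
  expect_error(fisher_z_difference(0.5, 3, 0.5, 10), "n1 >= 4")

  # type-I error near nominal under a shared bivariate-normal correlation
  set.seed(88)
  n <- 50
  rej <- 0
  reps <- 2000
  for (i in seq_len(reps)) {
    z1 <- matrix(rnorm(2 * n), n)
    z2 <- matrix(rnorm(2 * n), n)
    rho <- 0.4
    mix <- function(z) cor(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
    p <- fisher_z_difference(mix(z1), n, mix(z2), n)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gte(rej / reps, 0.035)
  expect_lte(rej / reps, 0.065)
})

test_that("correlation dot plots render to non-empty files", {
  gen <- generate_cohorts(small_spec(k = 1))
  p <- gen$pairs[[1]]
  sub <- list(normal = p$normal[1:10, ], cancer = p$cancer[1:10, ],
              cancer_type = p$cancer_type)
  class(sub) <- "cohort_pair"
  cmn <- correlation_matrix(sub$normal)
  cmc <- correlation_matrix(sub$cancer)
  out <- withr::local_tempfile(fileext = ".png")
  render_corr_dotplot(cmn, cmc, out, width = 5, height = 3)
  expect_true(file.exists(out))
  expect_gt(file.size(out), 0)

  # identity matrix: only the diagonal carries (maximal, positive) dots
  eye <- structure(list(gene_ids = c("A", "B"),
                        r = diag(2) * 1,
                        n_samples = 10,
                        defined = matrix(TRUE, 2, 2)),
                   class = "corr_mat")
  eye$r[eye$r == 0] <- 0
  gg <- plot_corr_dots(eye)
  expect_s3_class(gg, "ggplot")
  mismatched <- structure(list(gene_ids = c("A", "C"), r = diag(2),
                               n_samples = 10,
                               defined = matrix(TRUE, 2, 2)),
                          class = "corr_mat")
  expect_error(plot_corr_dots(eye, mismatched), "different gene sets")
})
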