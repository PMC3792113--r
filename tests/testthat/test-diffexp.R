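test_that("pooled t-test matches the textbook computation and stats::t.test", {
  # frozen oracle: pooled two-sample t on {4,5,6} vs {1,2,3}
  res <- gene_t_test(c(4, 5, 6), c(1, 2, 3), log2_transform = FALSE)
  expect_equal(res$t_stat, 3.6742346, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)

  # randomised cross-check against stats::t.test, pooled and Welch
  withr::with_seed(42, {
    for (i in 1:25) {
      a <- rnorm(sample(3:8, 1), mean = 8, sd = runif(1, 0.2, 2))
      b <- rnorm(sample(3:8, 1), mean = 8.5, sd = runif(1, 0.2, 2))
      for (pooled in c(TRUE, FALSE)) {
        mine <- gene_t_test(a, b, log2_transform = FALSE, var_equal = pooled)
        ref <- stats::t.test(a, b, var.equal = pooled)
        expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
        expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
      }
    }
  })
})

test_that("t-test handles degenerate and reordered groups", {
  # identical constant groups: no difference, not an error
  res <- gene_t_test(c(5, 5, 5), c(5, 5, 5), log2_transform = FALSE)
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_value, 1)
  # antisymmetry: swapping groups negates t, p unchanged
  fwd <- gene_t_test(c(4, 5, 6), c(1, 2, 3), log2_transform = FALSE)
  rev <- gene_t_test(c(1, 2, 3), c(4, 5, 6), log2_transform = FALSE)
  expect_equal(rev$t_stat, -fwd$t_stat)
  expect_equal(rev$p_value, fwd$p_value)
  # a group below 2 finite values: gene unmeasured, NA statistics
  res <- gene_t_test(c(4, NA, NA), c(1, 2, 3), log2_transform = FALSE)
  expect_true(is.na(res$t_stat) && is.na(res$p_value))
})

test_that("fold change follows the signed linear Oncomine convention", {
  expect_equal(fold_change(c(22, 18), c(12, 8)), 2)
  expect_equal(fold_change(c(12, 8), c(22, 18)), -2)
  expect_equal(fold_change(c(5, 5), c(5, 5)), 1)
  # reciprocal antisymmetry and |fc| >= 1 on random pairs
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- runif(5, 1, 100)
      b <- runif(5, 1, 100)
      expect_equal(fold_change(a, b), -fold_change(b, a))
      expect_gte(abs(fold_change(a, b)), 1)
    }
  })
  expect_warning(fc <- fold_change(c(-1, 1), c(2, 2)), "non-positive")
  expect_true(is.na(fc))
})

test_that("ranking and percentiles match a brute-force sort oracle", {
  rp <- rank_and_percentile(c(A = 0.001, B = 0.01, C = 0.0001))
  expect_equal(rp$rank, c(2L, 3L, 1L))

  expect_equal(rank_and_percentile(0.5)$percentile, 100L)
  expect_equal(rank_and_percentile(0.5)$rank, 1L)
  # rank 140 of 14000 genes sits exactly at percentile 1
  p <- seq_len(14000) / 14001
  rp <- rank_and_percentile(p)
  expect_equal(rp$percentile[140], 1L)
  expect_equal(rp$percentile[141], 2L)

  # brute force on random vectors: rank by sorted order, ceiling percentile
  withr::with_seed(99, {
    for (i in 1:10) {
      n <- sample(5:400, 1)
      pv <- round(runif(n), 3)  # provoke ties
      ids <- sprintf("g%04d", sample.int(n))
      rp <- rank_and_percentile(pv, ids)
      ord <- order(pv, ids)
      brute <- integer(n)
      brute[ord] <- seq_len(n)
      expect_equal(rp$rank, brute)
      expect_equal(rp$percentile, as.integer(ceiling(100 * brute / n)))
    }
  })
  expect_error(rank_and_percentile(numeric(0)), "empty")
})

test_that("Q = NP/R, with the monotone mode matching Benjamini-Hochberg", {
  expect_equal(fdr_q(1e-4, n_genes = 10000, rank = 5), 0.2)
  expect_equal(fdr_q(0.37, n_genes = 500, rank = 500), 0.37)  # R = N -> Q = P
  expect_error(fdr_q(0.5, n_genes = 10, rank = 11), "\\[1, n_genes\\]")

  pv <- c(0.001, 0.002, 0.9, 0.91)
  qm <- fdr_q(pv, 4, 1:4, monotone = TRUE)
  expect_true(all(diff(qm) >= 0))
  expect_true(all(qm <= fdr_q(pv, 4, 1:4) + 1e-12))
  expect_equal(qm, stats::p.adjust(pv, method = "BH"))

  withr::with_seed(31, {
    for (i in 1:15) {
      n <- sample(3:200, 1)
      pv <- sort(runif(n))
      q_raw <- fdr_q(pv, n, seq_len(n))
      expect_true(all(q_raw >= pv))  # Q >= P since N/R >= 1
      expect_equal(fdr_q(pv, n, seq_len(n), monotone = TRUE),
                   stats::p.adjust(pv, method = "BH"))
    }
  })
})

test_that("analyze_study composes the per-gene statistics coherently", {
  st <- make_toy_study(n_genes = 3, n_per_group = 5, shift_genes = 2,
                       shift = 3, seed = 21)
  res <- analyze_study(st)
  expect_equal(res$gene_id[res$rank == 1], "G002")  # planted gene ranks first
  expect_equal(res$direction[res$gene_id == "G002"], "over")
  expect_true(all(res$q_value >= res$p_value))
  expect_equal(res$n_genes, rep(3L, 3))
  expect_equal(res$percentile, as.integer(ceiling(100 * res$rank / 3)))

  # identical groups across the board: p = 1, fold +1, nothing can gate
  m <- matrix(rep(c(4, 6, 8), 4), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  flat <- expression_study(m, c("cancer", "cancer", "normal", "normal"),
                           study_id = "flat")
  res_flat <- analyze_study(flat)
  expect_equal(res_flat$p_value, rep(1, 3))
  expect_equal(res_flat$fold_change, rep(1, 3))
  expect_false(any(passes_threshold(res_flat)))
})

test_that("analyze_study is invariant to row and within-group column order", {
  st <- make_toy_study(n_genes = 20, n_per_group = 4, shift_genes = 1:2,
                       shift = 2, seed = 33)
  base <- analyze_study(st)

  perm <- st
  ord <- withr::with_seed(1, sample.int(nrow(st$values)))
  perm$values <- perm$values[ord, ]
  expect_equal(dplyr::arrange(analyze_study(perm), gene_id),
               dplyr::arrange(base, gene_id), ignore_attr = TRUE)

  swapped <- st
  swapped$values <- swapped$values[, c(2, 1, 3, 4, 8, 7, 6, 5)]
  swapped$samples <- swapped$samples[c(2, 1, 3, 4, 8, 7, 6, 5), ]
  expect_equal(analyze_study(swapped), base, ignore_attr = TRUE)
})

test_that("genes starved of data by missingness drop out of N", {
  st <- make_toy_study(n_genes = 6, n_per_group = 3, seed = 44)
  st$values[4, 1:2] <- NA  # one finite cancer value left
  res <- analyze_study(st)
  expect_false("G004" %in% res$gene_id)
  expect_equal(unique(res$n_genes), 5L)
  expect_equal(attr(res, "n_unmeasured"), 1L)
})
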