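make_gene_es <- function(scores_by_gene, cells) {
  m <- do.call(rbind, scores_by_gene)
  dimnames(m) <- list(names(scores_by_gene), cells)
  es_from_matrix(m, "gene")
}

test_that("an extreme partner reaches the exact SL threshold", {
  cells <- paste0("CL", 1:7)
  panel <- tibble::tibble(cell_line = cells,
                          DRV = c(1, 1, 1, 0, 0, 0, 0))
  ges <- make_gene_es(list(
    DRV = rep(0, 7),
    PARTNER = c(-3, -2, -2.5, 0, 0.1, -0.2, 0.3),
    FLAT = c(1, 2, 3, 1.5, 2.5, 3.5, 2)), cells)
  res <- detect_partners(ges, panel, "DRV")
  p <- res[res$partner == "PARTNER", ]
  # mutants occupy the three lowest ranks: exactly 1 of C(7,3) assignments
  expect_equal(p$p_one_sided_neg, 1 / 35)
  expect_true(p$sl_hit)
  expect_equal(p$p_two_sided, 2 / 35)
  expect_false(p$gi_hit)         # two-sided 2/35 just misses 0.05
  expect_false(res$sl_hit[res$partner == "FLAT"])
  expect_false("DRV" %in% res$partner)
})

test_that("driver preconditions are enforced and skipped drivers reported", {
  cells <- paste0("CL", 1:6)
  panel <- tibble::tibble(cell_line = cells,
                          ONE = c(1, 0, 0, 0, 0, 0),
                          OK = c(1, 1, 1, 0, 0, 0))
  ges <- make_gene_es(list(A = stats::rnorm(6), B = stats::rnorm(6)), cells)
  expect_error(detect_partners(ges, panel, "ONE"), "at least 2")
  expect_error(detect_partners(ges, panel, "MISSING"), "not in genotype panel")
  expect_message(all_res <- detect_partners_all(ges, panel), "skipping driver 'ONE'")
  expect_setequal(unique(all_res$driver), "OK")
})

test_that("SL direction and label-swap symmetry hold", {
  set.seed(42)
  cells <- paste0("CL", 1:12)
  panel <- tibble::tibble(cell_line = cells,
                          DRV = rep(c(1, 0), each = 6))
  genes <- lapply(1:40, function(i) stats::rnorm(12))
  names(genes) <- c("DRV", sprintf("g%02d", 2:40))
  ges <- make_gene_es(genes, cells)
  res <- detect_partners(ges, panel, "DRV", sl_alpha = 0.2)
  m <- es_scores(ges)
  for (g in res$partner[res$sl_hit]) {
    expect_lte(stats::median(m[g, 1:6]), stats::median(m[g, 7:12]))
  }
  # swapping the groups flips the one-sided tail exactly
  x <- m["g05", 1:6]; y <- m["g05", 7:12]
  expect_equal(wilcoxon_rank_sum(x, y, "one_sided_less")$p_value,
               wilcoxon_rank_sum(y, x, "one_sided_greater")$p_value)
})

test_that("BH adjustment can only reduce the hit set", {
  sim <- sim_smoke()
  idx <- gene_index(sim$annotations, sim$screen_a)
  ges <- garp(sim$screen_a, idx)
  raw <- detect_partners_all(ges, sim$genotypes)
  adj <- detect_partners_all(ges, sim$genotypes, adjust = "BH")
  expect_lte(sum(adj$sl_hit), sum(raw$sl_hit))
  expect_lte(sum(adj$gi_hit), sum(raw$gi_hit))
})

test_that("overlap analysis counts per-driver intersections and tests the shift", {
  hits <- function(driver, partners, flag) {
    tibble::tibble(driver = driver, partner = partners,
                   gi_hit = flag, sl_hit = flag)
  }
  a_b <- dplyr::bind_rows(hits("d1", c("p1", "p2", "p3"), c(TRUE, TRUE, FALSE)),
                          hits("d2", c("p1", "p2", "p3"), c(TRUE, TRUE, FALSE)))
  b_b <- dplyr::bind_rows(hits("d1", c("p1", "p2", "p3"), c(TRUE, FALSE, FALSE)),
                          hits("d2", c("p1", "p2", "p3"), c(TRUE, TRUE, TRUE)))
  a_a <- dplyr::bind_rows(hits("d1", c("p1", "p2", "p3"), c(TRUE, TRUE, TRUE)),
                          hits("d2", c("p1", "p2", "p3"), c(TRUE, TRUE, TRUE)))
  b_a <- a_a
  ov <- overlap_analysis(a_b, b_b, a_a, b_a, "gi_hit")
  # before: d1 overlap {p1}, d2 overlap {p1,p2}; after: 3 and 3
  expect_equal(ov$per_driver$overlap_before, c(1L, 2L))
  expect_equal(ov$per_driver$overlap_after, c(3L, 3L))
  # differences {+2, +1}: one-sided exact sign enumeration p = 1/4
  expect_equal(ov$comparison$p_value, 0.25)

  same <- overlap_analysis(a_b, b_b, a_b, b_b, "gi_hit")
  expect_equal(same$comparison$p_value, 1)
  expect_identical(same$comparison$method, "degenerate")
})

test_that("precision and recall against planted truth handle edge cases", {
  truth <- list(sl_pairs = tibble::tibble(driver = c("d1", "d1"),
                                          partner = c("p1", "p2"),
                                          delta = -1))
  exact <- tibble::tibble(driver = "d1", partner = c("p1", "p2"),
                          sl_hit = TRUE)
  pr <- precision_recall_vs_truth(exact, truth)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  none <- tibble::tibble(driver = "d1", partner = "p9", sl_hit = FALSE)
  pr0 <- precision_recall_vs_truth(none, truth)
  expect_true(is.na(pr0$precision))
  expect_equal(pr0$recall, 0)

  expect_error(precision_recall_vs_truth(exact, list(sl_pairs = NULL)),
               "no planted")

  pooled <- pooled_precision_recall(exact, none, truth)
  expect_equal(pooled$tp, 2L)
  expect_equal(pooled$recall, 0.5)
})
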