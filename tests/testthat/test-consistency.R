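make_reps <- function(cell_line, scores_by_rep) {
  dplyr::bind_rows(lapply(names(scores_by_rep), function(r) {
    tibble::tibble(cell_line = cell_line, replicate = r,
                   shrna_id = paste0("s", seq_along(scores_by_rep[[r]])),
                   score = scores_by_rep[[r]])
  }))
}

test_that("replicate QC computes mean pairwise correlation and applies the cut", {
  base <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  identical_reps <- make_reps("cl_good", list(r1 = base, r2 = base))
  reversed <- make_reps("cl_bad", list(r1 = base, r2 = rev(sort(base))[rank(base)]))
  qc <- replicate_qc(dplyr::bind_rows(identical_reps, reversed))
  expect_equal(qc$rho_rep[qc$cell_line == "cl_good"], 1)
  expect_true(qc$keep[qc$cell_line == "cl_good"])
  expect_equal(qc$rho_rep[qc$cell_line == "cl_bad"], -1)
  expect_false(qc$keep[qc$cell_line == "cl_bad"])

  # three replicates: mean of the three pairwise correlations
  set.seed(31)
  r1 <- stats::rnorm(30); r2 <- r1 + stats::rnorm(30); r3 <- stats::rnorm(30)
  three <- make_reps("cl3", list(r1 = r1, r2 = r2, r3 = r3))
  qc3 <- replicate_qc(three)
  manual <- mean(c(spearman_rho(r1, r2), spearman_rho(r1, r3), spearman_rho(r2, r3)))
  expect_equal(qc3$rho_rep, manual)

  single <- make_reps("cl1", list(r1 = base))
  qc1 <- replicate_qc(single)
  expect_true(qc1$keep)
  expect_true(qc1$flagged_single_replicate)
  expect_true(is.na(qc1$rho_rep))
})

test_that("matched correlation is exact under identity and monotone maps", {
  set.seed(32)
  m <- matrix(stats::rnorm(200), 50, 4,
              dimnames = list(sprintf("s%02d", 1:50), paste0("CL", 1:4)))
  a <- es_from_matrix(m, "shrna")
  matched <- tibble::tibble(cell_line_a = paste0("CL", 1:4),
                            cell_line_b = paste0("CL", 1:4))
  self <- matched_correlation(a, a, matched)
  expect_true(all(self$rho$rho == 1))
  mono <- es_from_matrix(exp(m) * 3 - 1, "shrna")
  expect_true(all(matched_correlation(a, mono, matched)$rho$rho == 1))

  b_gene <- es_from_matrix(m, "gene")
  expect_error(matched_correlation(a, b_gene, matched), "level mismatch")
  expect_error(matched_correlation(a, a, tibble::tibble(cell_line_a = "CLX",
                                                        cell_line_b = "CL1")),
               "CLX")
})

test_that("non-matched baseline counts pairs and finds no signal on independent data", {
  set.seed(33)
  ids <- sprintf("s%02d", 1:60)
  a <- es_from_matrix(matrix(stats::rnorm(180), 60, 3,
                             dimnames = list(ids, paste0("A", 1:3))), "shrna")
  b <- es_from_matrix(matrix(stats::rnorm(180), 60, 3,
                             dimnames = list(ids, paste0("B", 1:3))), "shrna")
  matched <- tibble::tibble(cell_line_a = "A1", cell_line_b = "B1")
  nb <- nonmatched_baseline(a, b, matched)
  expect_equal(nrow(nb$nonmatched), 3 * 3 - 1)
  expect_gt(nb$comparison$p_value, 0.05)   # independent screens: no signal

  # simulated screens: matched far exceeds non-matched
  sim <- sim_smoke()
  nb2 <- nonmatched_baseline(sim$screen_a, sim$screen_b, sim$matched)
  expect_gt(mean(nb2$matched_report$rho$rho), mean(nb2$nonmatched$rho))
  expect_lt(nb2$comparison$p_value, 1e-4)
})

test_that("report comparison gates between t-test and signed-rank", {
  mk <- function(rho) {
    structure(list(level = "shrna",
                   rho = tibble::tibble(cell_line_a = paste0("CL", seq_along(rho)),
                                        cell_line_b = paste0("CL", seq_along(rho)),
                                        rho = rho),
                   mean_rho = mean(rho), grouping = NULL, comparison = NULL),
              class = "consistency_report")
  }
  r1 <- mk(seq(0.4, 0.6, length.out = 17))
  expect_equal(compare_reports(r1, r1)$p_value, 1)
  expect_identical(compare_reports(r1, r1)$method, "degenerate")

  set.seed(34)
  shift <- mk(r1$rho$rho + 0.1 + stats::rnorm(17, 0, 0.002))
  cmp <- compare_reports(shift, r1, "one_sided_greater")
  expect_lt(cmp$p_value, 0.01)
  expect_identical(cmp$method, "paired_t")

  # heavy-tailed differences fail the normality gate -> signed-rank branch
  heavy <- mk(r1$rho$rho + c(rep(0.001, 16), 0.3))
  cmp2 <- compare_reports(heavy, r1, "one_sided_greater")
  expect_identical(cmp2$method, "wilcoxon_signed_rank_normal")

  r_other <- mk(seq(0.1, 0.2, length.out = 5))
  expect_error(compare_reports(r1, r_other), "different cell-line pairs")
})

test_that("family-size curve at size 1 equals the singleton-family correlation", {
  set.seed(35)
  ann <- tibble::tibble(
    shrna_id = sprintf("s%02d", 1:40),
    guide_sequence = vapply(1:40, function(i)
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
      character(1)),
    target_gene = sprintf("g%02d", 1:40))
  fam <- build_families(ann)
  singles <- fam$shrna_id[fam$family_size == 1]
  m <- matrix(stats::rnorm(80), 40, 2,
              dimnames = list(ann$shrna_id, c("CL1", "CL2")))
  a <- es_from_matrix(m, "shrna")
  b <- es_from_matrix(m + stats::rnorm(80, 0, 0.5), "shrna")
  matched <- tibble::tibble(cell_line_a = c("CL1", "CL2"),
                            cell_line_b = c("CL1", "CL2"))
  curve <- family_size_curve(a, b, fam, matched, min_bin = 1L)
  sub_a <- es_mat(a[a$entity %in% singles, ], "shrna")
  sub_b <- es_mat(b[b$entity %in% singles, ], "shrna")
  direct <- matched_correlation(sub_a, sub_b, matched)$mean_rho
  expect_equal(curve$mean_rho[curve$family_size == 1], direct)
  expect_error(family_size_curve(a, b, fam, matched, min_bin = 1000L), "no family-size bin")
})

test_that("class stratification reports absent subsets instead of failing", {
  sim <- sim_smoke()
  props <- sim$seed_properties
  props$sps_class <- "strong"   # every seed in one class
  props$ta_class <- "neither"
  strat <- class_stratified_consistency(sim$screen_a, sim$screen_b,
                                        sim$annotations, props, sim$matched)
  expect_true(is.na(strat$mean_rho[strat$axis == "sps" & strat$class == "weak" &
                                     strat$window == "seed"]))
  expect_false(is.na(strat$mean_rho[strat$axis == "sps" & strat$class == "strong" &
                                      strat$window == "seed"]))
})

test_that("reports are tidy-able and plottable", {
  sim <- sim_smoke()
  rep <- matched_correlation(sim$screen_a, sim$screen_b, sim$matched)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("cell_line_a", "cell_line_b", "rho", "n_entities"))
  gl <- glance(rep)
  expect_equal(gl$mean_rho, rep$mean_rho)
  expect_equal(gl$n_pairs, nrow(td))
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
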