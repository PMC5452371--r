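test_that("percentile thresholds interpolate order statistics as documented", {
  props <- tibble::tibble(seed = strrep(c("A", "C", "G", "T", "AC"), 7)[1:5],
                          sps = c(-12, -10, -8, -6, -4),
                          ta = c(1, 2, 3, 4, 5))
  th <- derive_thresholds(props, pct = 20)
  expect_equal(th$sps_strong, -11.2)
  expect_equal(th$sps_weak, -4.8)
  # literal TA direction: low cut in the upper tail
  expect_equal(th$ta_low, 4.6)
  expect_equal(th$ta_high, 1.4)
  expect_identical(th$quantile_rule, "linear_interpolation_type8")

  # pct = 0: cuts at the extremes, nothing beyond them on a continuum
  th0 <- derive_thresholds(props, pct = 0)
  expect_equal(th0$sps_strong, -12)
  expect_equal(th0$sps_weak, -4)
  cls0 <- classify_seeds(props, th0)
  expect_false(any(cls0$sps_class %in% c("strong", "weak")))

  expect_error(derive_thresholds(tibble::tibble(seed = "A", sps = rep(1, 12),
                                                ta = rep(2, 12))),
               "degenerate")
})

test_that("seed classification follows the reference threshold conventions", {
  th <- tibble::tibble(sps_strong = -9.82, sps_weak = -5.16,
                       ta_low = 3.72, ta_high = 2.89, pct = 10,
                       quantile_rule = "linear_interpolation_type8",
                       ta_direction = "literal")
  props <- tibble::tibble(seed = c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT"),
                          sps = c(-10.5, -5.0, -7.0, NA),
                          ta = c(4.0, 2.0, 3.0, 3.0))
  cls <- classify_seeds(props, th)
  expect_identical(cls$sps_class, c("strong", "weak", "neither", "unknown"))
  expect_identical(cls$ta_class, c("low", "high", "neither", "neither"))

  bad <- th
  bad$sps_strong <- -5; bad$sps_weak <- -9
  expect_error(classify_seeds(props, bad), "inverted")
})

test_that("cleaning removes exactly the flagged shRNAs and reports them", {
  ann <- tibble::tibble(
    shrna_id = paste0("s", 1:5),
    guide_sequence = paste0("T", c("AAAAAAA", "CCCCCCC", "GGGGGGG",
                                   "AAAAAAA", "TTTTTTT"),
                            "ACGTACGTACGTA"),
    target_gene = c("g1", "g1", "g2", "g3", "g3"))
  cls <- tibble::tibble(seed = c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT"),
                        sps = c(-11, -6, -7, -7), ta = c(3, 4, 3, 3),
                        sps_class = c("strong", "neither", "neither", "neither"),
                        ta_class = c("neither", "low", "neither", "neither"))
  m <- matrix(stats::rnorm(10), 5, 2,
              dimnames = list(paste0("s", 1:5), c("CL1", "CL2")))
  shes <- es_from_matrix(m, "shrna")

  out <- clean_dataset(shes, ann, cls)
  expect_setequal(out$cleaned$entity, c("s3", "s5"))
  expect_equal(nrow(out$report), 3L)
  expect_setequal(out$report$reason, c("strong_sps", "low_ta"))
  expect_equal(sum(out$summary$n), nrow(shes) - nrow(out$cleaned))
  expect_identical(out$lost_genes, "g1")   # both g1 shRNAs flagged

  # idempotence
  again <- clean_dataset(out$cleaned, ann, cls)
  expect_identical(again$cleaned$entity, out$cleaned$entity)
  expect_equal(nrow(again$report), 0L)

  # nothing flagged: identity
  cls_none <- cls
  cls_none$sps_class <- "neither"; cls_none$ta_class <- "neither"
  ident <- clean_dataset(shes, ann, cls_none)
  expect_identical(ident$cleaned$entity, shes$entity)

  # policies
  expect_setequal(clean_dataset(shes, ann, cls, policy = "sps")$report$shrna_id,
                  c("s1", "s4"))
  expect_setequal(clean_dataset(shes, ann, cls, policy = "ta")$report$shrna_id,
                  "s2")
  expect_equal(nrow(clean_dataset(shes, ann, cls, policy = "and")$report), 0L)

  # removing everything is an error
  cls_all <- cls
  cls_all$sps_class <- "strong"
  expect_error(clean_dataset(shes, ann, cls_all), "every shRNA")
})

test_that("truth-aligned cleaning improves gene-level consistency on simulation", {
  sim <- sim_smoke()
  cls <- classify_seeds(sim$seed_properties, sim$truth$thresholds)
  ca <- clean_dataset(sim$screen_a, sim$annotations, cls)
  cb <- clean_dataset(sim$screen_b, sim$annotations, cls)
  idx <- gene_index(sim$annotations, sim$screen_a)
  before <- matched_correlation(garp(sim$screen_a, idx), garp(sim$screen_b, idx),
                                sim$matched)
  after <- matched_correlation(garp(ca$cleaned, idx), garp(cb$cleaned, idx),
                               sim$matched)
  expect_gt(after$mean_rho, before$mean_rho)
  cmp <- compare_reports(after, before, "one_sided_greater")
  expect_lt(cmp$p_value, 0.05)
})

test_that("cleaning never hurts gene-level consistency across simulator seeds", {
  for (s in 1:5) {
    sim <- simulate_screens(smoke_config(rng_seed = 100 + s))
    cls <- classify_seeds(sim$seed_properties, sim$truth$thresholds)
    ca <- clean_dataset(sim$screen_a, sim$annotations, cls)
    cb <- clean_dataset(sim$screen_b, sim$annotations, cls)
    idx <- gene_index(sim$annotations, sim$screen_a)
    before <- matched_correlation(garp(sim$screen_a, idx),
                                  garp(sim$screen_b, idx), sim$matched)
    after <- matched_correlation(garp(ca$cleaned, idx),
                                 garp(cb$cleaned, idx), sim$matched)
    expect_gte(after$mean_rho, before$mean_rho, label = paste("seed", 100 + s))
  }
})
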