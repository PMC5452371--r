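test_that("simulation is deterministic and structurally correct", {
  s1 <- simulate_screens(smoke_config(rng_seed = 99))
  s2 <- simulate_screens(smoke_config(rng_seed = 99))
  expect_identical(es_scores(s1$screen_a), es_scores(s2$screen_a))
  expect_identical(es_scores(s1$screen_b), es_scores(s2$screen_b))
  expect_identical(s1$annotations, s2$annotations)
  s3 <- simulate_screens(smoke_config(rng_seed = 100))
  expect_false(identical(es_scores(s1$screen_a), es_scores(s3$screen_a)))

  sim <- sim_smoke()
  expect_equal(nrow(sim$screen_a), 1000L)            # 200 genes x 5 shRNAs
  expect_equal(ncol(sim$screen_a) - 1L, 8L)
  expect_true(all(nchar(sim$annotations$guide_sequence) == 21L))
  expect_true(all(grepl("^[ACGT]+$", sim$annotations$guide_sequence)))
  fam <- build_families(sim$annotations)
  expect_lte(max(fam$family_size), 14L)
  # every shRNA's window 2-8 is its assigned seed
  expect_identical(extract_window(sim$annotations$guide_sequence),
                   sim$truth$mixing_weight$seed)
  expect_equal(nrow(sim$seed_properties), 16384L)
  # genotype panel: 2 drivers, mutated in 3-4 of 8 lines
  expect_equal(ncol(sim$genotypes) - 1L, 2L)
  muts <- colSums(sim$genotypes[-1])
  expect_true(all(muts >= 3 & muts <= 4))
  expect_true(all(sim$truth$sl_pairs$delta < 0))
})

test_that("the noise-free on-target limit returns the gene effects exactly", {
  cfg <- smoke_config(w_flagged_shape = c(1e-9, 1), w_other_shape = c(1e-9, 1),
                      toxic_frac_flagged = 0, offtarget_dev_sd = 0,
                      screen_effect_sd_a = 0, screen_effect_sd_b = 0,
                      noise_sd_a = 0, noise_sd_b = 0,
                      n_drivers = 0L, rng_seed = 51)
  sim <- simulate_screens(cfg)
  g <- sim$truth$gene_effect[sim$annotations$target_gene, ]
  expect_lt(max(abs(es_scores(sim$screen_a) - g)), 1e-9)
  rep <- matched_correlation(sim$screen_a, sim$screen_b, sim$matched)
  expect_true(all(rep$rho$rho > 1 - 1e-12))
})

test_that("the pure off-target limit reproduces the seed effects", {
  cfg <- smoke_config(w_flagged_shape = c(1, 1e-9), w_other_shape = c(1, 1e-9),
                      toxic_frac_flagged = 0, offtarget_dev_sd = 0,
                      screen_effect_sd_a = 0, screen_effect_sd_b = 0,
                      noise_sd_a = 0, noise_sd_b = 0,
                      n_drivers = 0L, rng_seed = 52)
  sim <- simulate_screens(cfg)
  fam <- build_families(sim$annotations)
  fes <- family_es(sim$screen_a, fam)
  s_truth <- sim$truth$seed_effect[fes$entity, ]
  expect_lt(max(abs(es_scores(fes) - s_truth)), 1e-9)
  rep <- matched_correlation(fes, family_es(sim$screen_b, fam), sim$matched)
  expect_true(all(rep$rho$rho > 1 - 1e-12))
})

test_that("rank-based outputs ignore the screen-B transform when noise is fixed off", {
  base <- list(screen_effect_sd_a = 0, screen_effect_sd_b = 0,
               noise_sd_a = 0, noise_sd_b = 0, rng_seed = 53)
  cube <- simulate_screens(do.call(smoke_config, c(base, transform_b_cube_root = TRUE)))
  lin <- simulate_screens(do.call(smoke_config, c(base, transform_b_cube_root = FALSE)))
  m1 <- matched_correlation(cube$screen_a, cube$screen_b, cube$matched)
  m2 <- matched_correlation(lin$screen_a, lin$screen_b, lin$matched)
  expect_equal(m1$rho$rho, m2$rho$rho)
})

test_that("mixing weights follow the flagged seed classes", {
  sim <- sim_smoke()
  mw <- sim$truth$mixing_weight
  expect_true(all(mw$w >= 0 & mw$w <= 1))
  expect_gt(mean(mw$w[mw$flagged]), 0.6)
  expect_lt(mean(mw$w[!mw$flagged]), 0.4)
  expect_setequal(unique(mw$seed[mw$flagged]),
                  intersect(unique(mw$seed), sim$truth$flagged_seeds))
})

test_that("exported fixtures are byte-stable and the config echo reproduces them", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- smoke_config(rng_seed = 54)
  files1 <- export_fixture(simulate_screens(cfg), dir1)
  files2 <- export_fixture(simulate_screens(cfg), dir2)
  for (f in names(files1)) {
    expect_identical(unname(tools::md5sum(files1[[f]])),
                     unname(tools::md5sum(files2[[f]])), label = f)
  }
  expect_equal(nrow(read_es_matrix(files1[["screen_a.tsv"]], "shrna")), 1000L)

  cfg2 <- read_sim_config(files1[["config.txt"]])
  resim <- simulate_screens(cfg2)
  orig <- simulate_screens(cfg)
  expect_identical(es_scores(resim$screen_a), es_scores(orig$screen_a))
  expect_identical(resim$annotations, orig$annotations)

  # exported tables re-read through the package readers
  ann <- read_shrna_annotations(files1[["annotations.tsv"]])
  expect_equal(nrow(ann), 1000L)
  panel <- read_genotype_panel(files1[["genotypes.tsv"]])
  expect_equal(nrow(panel), 8L)
  props <- read_seed_properties(files1[["seed_properties.tsv"]])
  expect_equal(nrow(props), 16384L)
  pairs <- read_matched_pairs(files1[["matched_pairs.tsv"]])
  expect_equal(nrow(pairs), 8L)
  reps <- read_replicates(files1[["replicates_a.tsv"]])
  expect_equal(nrow(reps), 1000L * 8L * 4L)
})

test_that("simulated replicates pass the quality-control threshold", {
  sim <- sim_smoke()
  qc <- replicate_qc(sim$replicates_a)
  expect_true(all(qc$keep))
  expect_true(all(qc$rho_rep > 0.5))
})
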