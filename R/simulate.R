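#' Simulation configuration
#'
#' Defaults describe a realistic two-screen study: ~1000 genes with 5
#' shRNAs each over 20 common cell lines, quadruplicate/triplicate
#' replicates, seed families following a truncated-geometric size
#' distribution over 1..14, a panel of 15 driver genes each mutated in
#' 6-10 cell lines, and 8 planted synthetic-lethal partners per driver
#' with an essentiality shift `sl_delta` in mutated lines. Noise levels
#' are set so the baseline matched shRNA-level rank correlation falls
#' in the moderate (~0.55-0.6) regime reported for matched pan-cancer
#' shRNA screens.
#'
#' The generative model per shRNA i, cell line c, screen k is
#' \deqn{shES = m_k((1 - w_i) G_{g(i),c} + w_i (S_{s(i),c} + d_{i,c,k})) + \epsilon}
#' with gene effect G, seed effect S shared between screens, a
#' screen-specific off-target deviation d (the part of an shRNA's
#' off-target phenotype its seed does not capture), mixing weight w
#' drawn from a high-mean Beta for seeds classified strong-SPS or
#' low-TA and a low-mean Beta otherwise, replicate noise
#' \eqn{\epsilon}, and a monotone screen transform (identity for A;
#' affine plus optional signed cube root for B, emulating fold-change
#' vs shARP-style scoring).
#'
#' @param n_genes,shrnas_per_gene,n_cell_lines Library dimensions.
#' @param family_geom_prob Success probability of the truncated
#'   geometric family-size distribution over 1..`max_family_size`.
#' @param max_family_size Largest family size generated (default 14).
#' @param replicates_a,replicates_b Replicates per screen.
#' @param frac_essential Fraction of genes drawn from the essential
#'   effect prior.
#' @param essential_mean,essential_sd,nonessential_sd Gene base-effect
#'   priors (unitless score scale).
#' @param gene_cell_sd Cell-line-specific spread of gene effects.
#' @param seed_base_sd,seed_cell_sd Seed-effect priors.
#' @param toxic_frac_flagged Probability that a flagged (strong-SPS or
#'   low-TA) seed carries a toxic base effect: pervasive seed-mediated
#'   repression that depresses growth in every cell line, the way
#'   promiscuous seeds behave in real libraries.
#' @param toxic_mean Mean of the toxic seed base-effect prior.
#' @param offtarget_dev_sd SD of the screen-specific per-shRNA
#'   off-target deviation.
#' @param w_flagged_shape,w_other_shape Beta shapes for the mixing
#'   weight of flagged (strong-SPS or low-TA) vs other seeds.
#' @param screen_effect_sd_a,screen_effect_sd_b SD of the screen-level
#'   effect: screen-specific but shared across that screen's replicates
#'   (protocol, timing and batch structure), the main source of
#'   between-screen discordance.
#' @param noise_sd_a,noise_sd_b Per-replicate measurement noise SD.
#' @param transform_b_slope,transform_b_offset,transform_b_cube_root
#'   Screen-B monotone transform parameters.
#' @param sps_mean,sps_sd,ta_mean,ta_sd Property priors for the
#'   heptamer SPS/TA table.
#' @param sps_ta_cor Correlation between sps and ta values (default
#'   -0.5: strongly pairing seeds tend to have abundant target sites,
#'   so the two high-propensity classes co-occur).
#' @param class_pct Percentile used to classify seeds (default 10).
#' @param n_drivers,driver_mut_min,driver_mut_max Driver panel layout.
#' @param sl_partners_per_driver,sl_delta Planted synthetic lethality;
#'   `sl_delta` must be negative (partner more essential in mutants).
#' @param rng_seed Integer seed; everything is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L, shrnas_per_gene = 5L, n_cell_lines = 20L,
                       family_geom_prob = 0.1, max_family_size = 14L,
                       replicates_a = 4L, replicates_b = 3L,
                       frac_essential = 0.2, essential_mean = -2,
                       essential_sd = 1, nonessential_sd = 1,
                       gene_cell_sd = 0.6,
                       seed_base_sd = 0.8, seed_cell_sd = 0.05,
                       toxic_frac_flagged = 0.8, toxic_mean = -2,
                       offtarget_dev_sd = 1.2,
                       w_flagged_shape = c(8, 2), w_other_shape = c(2, 8),
                       screen_effect_sd_a = 0.8, screen_effect_sd_b = 0.7,
                       noise_sd_a = 1.0, noise_sd_b = 0.9,
                       transform_b_slope = 2, transform_b_offset = 0.5,
                       transform_b_cube_root = TRUE,
                       sps_mean = -7.5, sps_sd = 1.8,
                       ta_mean = 3.3, ta_sd = 0.33, sps_ta_cor = -0.5,
                       class_pct = 10,
                       n_drivers = 15L, driver_mut_min = 6L, driver_mut_max = 10L,
                       sl_partners_per_driver = 8L, sl_delta = -1.8,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, shrnas_per_gene >= 1, n_cell_lines >= 2,
            family_geom_prob > 0, family_geom_prob < 1,
            max_family_size >= 1, replicates_a >= 1, replicates_b >= 1,
            sl_delta < 0, n_drivers >= 0,
            n_drivers == 0 || (driver_mut_min >= 2 && driver_mut_max <= n_cell_lines),
            length(w_flagged_shape) == 2, length(w_other_shape) == 2)
  structure(cfg, class = "sim_config")
}

#' The smoke-test preset
#'
#' A small configuration (200 genes x 5 shRNAs, 8 cell lines, 2
#' drivers) that runs the full pipeline in well under a minute.
#'
#' @param ... Overrides passed to [sim_config()].
#' @export
smoke_config <- function(...) {
  preset <- list(n_genes = 200L, n_cell_lines = 8L, n_drivers = 2L,
                 driver_mut_min = 3L, driver_mut_max = 4L)
  do.call(sim_config, utils::modifyList(preset, list(...)))
}

all_heptamers <- function() {
  nt <- c("A", "C", "G", "T")
  grid <- expand.grid(p7 = nt, p6 = nt, p5 = nt, p4 = nt, p3 = nt, p2 = nt, p1 = nt,
                      stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3, grid$p4, grid$p5, grid$p6, grid$p7)
}

#' Enumerate the DNA 7-mer space
#'
#' @return Character vector of all 4^7 = 16384 heptamers over
#'   \{A,C,G,T\}.
#' @export
enumerate_heptamers <- function() all_heptamers()

rand_seq <- function(n, len) {
  nt <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) paste(sample(nt, len, replace = TRUE), collapse = ""),
         character(1))
}

#' Simulate a paired two-screen shRNA study
#'
#' Generates two screens over a common shRNA library with shared
#' on-target gene effects, shared seed-mediated off-target effects,
#' screen-specific off-target deviations and noise, replicate
#' structure, a driver genotype panel with planted synthetic-lethal
#' partners, and a heptamer property table whose strong-SPS / low-TA
#' classes drive the off-target mixing weights. See [sim_config()] for
#' the generative model.
#'
#' @param config A [sim_config()].
#' @return List of class `seedscreen_sim`: `screen_a`, `screen_b`
#'   (shRNA-level [es_mat()]), `replicates_a`, `replicates_b` (long
#'   tibbles), `annotations`, `seed_properties` (all 16384 heptamers),
#'   `genotypes`, `matched` (cell-line pair tibble), `truth` (list:
#'   `gene_effect`, `seed_effect` matrices, `mixing_weight` tibble,
#'   `sl_pairs`, `thresholds`, `flagged_seeds`), and `config`.
#' @export
simulate_screens <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$rng_seed)
  n_sh <- cf$n_genes * cf$shrnas_per_gene
  genes <- sprintf("g%04d", seq_len(cf$n_genes))
  cells <- sprintf("CL%02d", seq_len(cf$n_cell_lines))
  shrna_ids <- sprintf("sh%05d", seq_len(n_sh))
  target_gene <- rep(genes, each = cf$shrnas_per_gene)

  # --- seed families: truncated-geometric sizes over 1..max ---
  sizes <- integer(0)
  total <- 0L
  probs <- stats::dgeom(0:(cf$max_family_size - 1L), cf$family_geom_prob)
  probs <- probs / sum(probs)
  while (total < n_sh) {
    s <- sample.int(cf$max_family_size, 1L, prob = probs)
    s <- min(s, n_sh - total)
    sizes <- c(sizes, s)
    total <- total + s
  }
  n_fam <- length(sizes)
  hept <- all_heptamers()
  fam_seeds <- sample(hept, n_fam)
  seed_of <- rep(fam_seeds, times = sizes)[sample.int(n_sh)]

  # guide strands: 21-nt, positions 2-8 carry the family seed. The
  # position-12-18 control heptamer is drawn from a pool of the same
  # cardinality as the seed pool: in a genome-scale library 7-mer reuse
  # at every position is combinatorially forced, and the control-window
  # analyses need non-trivial family sizes there too.
  left <- rand_seq(n_sh, 1L)
  mid <- rand_seq(n_sh, 3L)
  ctrl_pool <- sample(hept, n_fam)
  ctrl_of <- sample(ctrl_pool, n_sh, replace = TRUE)
  right <- rand_seq(n_sh, 3L)
  guide <- paste0(left, seed_of, mid, ctrl_of, right)
  annotations <- tibble::tibble(shrna_id = shrna_ids, guide_sequence = guide,
                                target_gene = target_gene)

  # --- heptamer property table and classes ---
  z1 <- stats::rnorm(length(hept))
  z2 <- stats::rnorm(length(hept))
  props <- tibble::tibble(
    seed = hept,
    sps = cf$sps_mean + cf$sps_sd * z1,
    ta = cf$ta_mean + cf$ta_sd * (cf$sps_ta_cor * z1 +
                                    sqrt(1 - cf$sps_ta_cor^2) * z2))
  th <- derive_thresholds(props, pct = cf$class_pct)
  cls <- classify_seeds(props, th)
  flagged <- cls$seed[cls$sps_class == "strong" | cls$ta_class == "low"]
  sh_flagged <- seed_of %in% flagged
  w <- numeric(n_sh)
  w[sh_flagged] <- stats::rbeta(sum(sh_flagged), cf$w_flagged_shape[1], cf$w_flagged_shape[2])
  w[!sh_flagged] <- stats::rbeta(sum(!sh_flagged), cf$w_other_shape[1], cf$w_other_shape[2])

  # --- shared biology: gene and seed effects ---
  ess <- stats::runif(cf$n_genes) < cf$frac_essential
  b_g <- ifelse(ess,
                stats::rnorm(cf$n_genes, cf$essential_mean, cf$essential_sd),
                stats::rnorm(cf$n_genes, 0, cf$nonessential_sd))
  G <- b_g + matrix(stats::rnorm(cf$n_genes * cf$n_cell_lines, 0, cf$gene_cell_sd),
                    cf$n_genes, cf$n_cell_lines,
                    dimnames = list(genes, cells))
  fam_flagged <- fam_seeds %in% flagged
  toxic <- fam_flagged & stats::runif(n_fam) < cf$toxic_frac_flagged
  b_s <- stats::rnorm(n_fam, 0, cf$seed_base_sd)
  b_s[toxic] <- stats::rnorm(sum(toxic), cf$toxic_mean, cf$seed_base_sd)
  S <- b_s + matrix(stats::rnorm(n_fam * cf$n_cell_lines, 0, cf$seed_cell_sd),
                    n_fam, cf$n_cell_lines,
                    dimnames = list(fam_seeds, cells))

  # --- genotype panel and planted synthetic lethality ---
  drivers <- character(0)
  sl_pairs <- tibble::tibble(driver = character(0), partner = character(0),
                             delta = numeric(0))
  genotypes <- tibble::tibble(cell_line = cells)
  if (cf$n_drivers > 0) {
    n_needed <- cf$n_drivers * (1L + cf$sl_partners_per_driver)
    picked <- sample(genes, n_needed)
    drivers <- picked[seq_len(cf$n_drivers)]
    partners <- picked[-seq_len(cf$n_drivers)]
    sl_pairs <- tibble::tibble(
      driver = rep(drivers, each = cf$sl_partners_per_driver),
      partner = partners,
      delta = cf$sl_delta)
    for (d in drivers) {
      n_mut <- sample(seq(cf$driver_mut_min, cf$driver_mut_max), 1L)
      mut_cells <- sample(cells, n_mut)
      genotypes[[d]] <- as.integer(cells %in% mut_cells)
      for (p in sl_pairs$partner[sl_pairs$driver == d]) {
        G[p, mut_cells] <- G[p, mut_cells] + cf$sl_delta
      }
    }
  }

  # --- assemble screens ---
  gene_idx <- match(target_gene, genes)
  seed_idx <- match(seed_of, fam_seeds)
  transform_b <- function(x) {
    if (cf$transform_b_cube_root) {
      cf$transform_b_offset + cf$transform_b_slope * sign(x) * abs(x)^(1 / 3)
    } else {
      cf$transform_b_offset + cf$transform_b_slope * x
    }
  }
  build_screen <- function(screen_sd, noise_sd, n_rep, transform, rep_prefix) {
    dev <- matrix(stats::rnorm(n_sh * cf$n_cell_lines, 0, cf$offtarget_dev_sd),
                  n_sh, cf$n_cell_lines)
    latent <- (1 - w) * G[gene_idx, , drop = FALSE] +
      w * (S[seed_idx, , drop = FALSE] + dev)
    signal <- transform(latent) +
      matrix(stats::rnorm(n_sh * cf$n_cell_lines, 0, screen_sd),
             n_sh, cf$n_cell_lines)
    reps <- lapply(seq_len(n_rep), function(r) {
      signal + matrix(stats::rnorm(n_sh * cf$n_cell_lines, 0, noise_sd),
                      n_sh, cf$n_cell_lines)
    })
    shes_mat <- Reduce(`+`, reps) / n_rep
    dimnames(shes_mat) <- list(shrna_ids, cells)
    rep_long <- dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
      tibble::tibble(cell_line = rep(cells, each = n_sh),
                     replicate = paste0(rep_prefix, r),
                     shrna_id = rep(shrna_ids, times = cf$n_cell_lines),
                     score = as.vector(reps[[r]]))
    }))
    list(shes = es_from_matrix(shes_mat, "shrna"), replicates = rep_long)
  }
  a <- build_screen(cf$screen_effect_sd_a, cf$noise_sd_a, cf$replicates_a,
                    identity, "repA")
  b <- build_screen(cf$screen_effect_sd_b, cf$noise_sd_b, cf$replicates_b,
                    transform_b, "repB")

  structure(list(
    screen_a = a$shes, screen_b = b$shes,
    replicates_a = a$replicates, replicates_b = b$replicates,
    annotations = annotations,
    seed_properties = props,
    genotypes = genotypes,
    matched = tibble::tibble(cell_line_a = cells, cell_line_b = cells),
    truth = list(gene_effect = G, seed_effect = S,
                 mixing_weight = tibble::tibble(shrna_id = shrna_ids,
                                                seed = seed_of,
                                                target_gene = target_gene,
                                                w = w, flagged = sh_flagged),
                 sl_pairs = sl_pairs,
                 drivers = drivers,
                 toxic_seeds = fam_seeds[toxic],
                 thresholds = th,
                 flagged_seeds = flagged),
    config = cf), class = "seedscreen_sim")
}

#' Write a simulated study to disk
#'
#' Exports every table of a simulation in the package's TSV schemas
#' (screens, replicate scores, annotations, seed properties, genotype
#' panel, matched pairs), plus the planted truth and a key=value echo
#' of the configuration from which the identical simulation can be
#' regenerated.
#'
#' @param sim A `seedscreen_sim` from [simulate_screens()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
export_fixture <- function(sim, out_dir) {
  stopifnot(inherits(sim, "seedscreen_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(out_dir, name)
  write_es_matrix(sim$screen_a, f("screen_a.tsv"))
  write_es_matrix(sim$screen_b, f("screen_b.tsv"))
  wt <- function(tbl, path) {
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
  }
  wt(sim$annotations, f("annotations.tsv"))
  wt(sim$replicates_a, f("replicates_a.tsv"))
  wt(sim$replicates_b, f("replicates_b.tsv"))
  wt(sim$seed_properties, f("seed_properties.tsv"))
  wt(sim$genotypes, f("genotypes.tsv"))
  wt(sim$matched, f("matched_pairs.tsv"))
  wt(sim$truth$sl_pairs, f("truth_sl_pairs.tsv"))
  wt(sim$truth$mixing_weight, f("truth_mixing_weights.tsv"))
  cfg <- sim$config
  scalar <- vapply(cfg, function(v) length(v) == 1L, logical(1))
  lines <- c(
    vapply(names(cfg)[scalar], function(k) paste0(k, "=", format(cfg[[k]], digits = 15)),
           character(1)),
    vapply(names(cfg)[!scalar], function(k) {
      paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ","))
    }, character(1)))
  writeLines(lines, f("config.txt"))
  files <- c("screen_a.tsv", "screen_b.tsv", "annotations.tsv",
             "replicates_a.tsv", "replicates_b.tsv", "seed_properties.tsv",
             "genotypes.tsv", "matched_pairs.tsv", "truth_sl_pairs.tsv",
             "truth_mixing_weights.tsv", "config.txt")
  invisible(stats::setNames(file.path(out_dir, files), files))
}

#' Re-read an exported configuration echo
#'
#' @param path `config.txt` written by [export_fixture()].
#' @return A [sim_config()] equal to the one exported.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  defaults <- sim_config()
  out <- lapply(stats::setNames(vals, keys), identity)
  cfg <- defaults
  for (k in keys) {
    template <- defaults[[k]]
    v <- strsplit(out[[k]], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    cfg[[k]] <- if (is.numeric(template)) {
      x <- as.numeric(v)
      if (is.integer(template)) as.integer(x) else x
    } else if (is.logical(template)) as.logical(v) else v
  }
  do.call(sim_config, cfg[names(formals(sim_config))])
}
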