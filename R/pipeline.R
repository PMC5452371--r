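#' Run the full screen-cleaning workflow
#'
#' Executes the end-to-end analysis on a pair of screens sharing an
#' shRNA library: replicate QC, shRNA-level baseline consistency,
#' seed-family scoring (seedES) with the position-12-18 heptamer
#' control, SPS/TA threshold derivation and seed classification,
#' off-target cleaning, GARP gene summarization before and after
#' cleaning with gene-level consistency, per-driver GI/SL detection in
#' both screens before and after cleaning, and the overlap comparison.
#' Accepts either a [simulate_screens()] result or the individual
#' tables. When `out_dir` is given every report is written as TSV along
#' with a JSON manifest (parameters, input digests, package version,
#' timestamp).
#'
#' @param x A `seedscreen_sim`, or an shRNA-level [es_mat()] for screen
#'   A (then supply the remaining tables).
#' @param screen_b,annotations,seed_properties,genotypes,matched
#'   Remaining inputs when `x` is an [es_mat()].
#' @param replicates_a,replicates_b Optional long replicate tibbles for
#'   QC.
#' @param qc_threshold Replicate-correlation cut (default 0.5) applied
#'   to the matched cell lines used in consistency analyses.
#' @param seed_min_size Smallest family size entering the headline
#'   seedES consistency (default 6: families larger than five shRNAs).
#' @param max_family_size Family-size cap (default 14).
#' @param pct Classification percentile (default 10).
#' @param policy Cleaning policy, see [clean_dataset()].
#' @param gi_alpha,sl_alpha GI/SL thresholds (defaults 0.05, 0.03).
#' @param drivers Driver genes to test (default: all genotype columns).
#' @param truth Optional simulation truth for precision/recall.
#' @param out_dir Optional output directory.
#' @return List of stage results (see the vignette for a walk-through).
#' @export
run_pipeline <- function(x, screen_b = NULL, annotations = NULL,
                         seed_properties = NULL, genotypes = NULL,
                         matched = NULL, replicates_a = NULL,
                         replicates_b = NULL, qc_threshold = 0.5,
                         seed_min_size = 6L, max_family_size = 14L,
                         pct = 10, policy = "or",
                         gi_alpha = 0.05, sl_alpha = 0.03,
                         drivers = NULL, truth = NULL, out_dir = NULL) {
  if (inherits(x, "seedscreen_sim")) {
    screen_b <- x$screen_b; annotations <- x$annotations
    seed_properties <- x$seed_properties; genotypes <- x$genotypes
    matched <- x$matched
    replicates_a <- x$replicates_a; replicates_b <- x$replicates_b
    truth <- x$truth
    screen_a <- x$screen_a
  } else {
    screen_a <- x
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  qc <- NULL
  matched_qc <- matched
  if (!is.null(replicates_a) || !is.null(replicates_b)) {
    qc <- stage("replicate_qc", {
      q <- dplyr::bind_rows(
        if (!is.null(replicates_a)) dplyr::mutate(replicate_qc(replicates_a, qc_threshold), screen = "a"),
        if (!is.null(replicates_b)) dplyr::mutate(replicate_qc(replicates_b, qc_threshold), screen = "b"))
      q
    })
    bad_a <- qc$cell_line[qc$screen == "a" & !qc$keep]
    bad_b <- qc$cell_line[qc$screen == "b" & !qc$keep]
    matched_qc <- matched[!(matched$cell_line_a %in% bad_a) &
                            !(matched$cell_line_b %in% bad_b), , drop = FALSE]
  }

  baseline <- stage("shrna_consistency",
                    matched_correlation(screen_a, screen_b, matched_qc))
  fam <- stage("seed_families", build_families(annotations, 2L, 7L))
  seed_a <- stage("seed_es_a", family_es(screen_a, fam, seed_min_size, max_family_size))
  seed_b <- stage("seed_es_b", family_es(screen_b, fam, seed_min_size, max_family_size))
  seed_consistency <- stage("seed_consistency",
                            matched_correlation(seed_a, seed_b, matched_qc))
  ctrl_fam <- stage("control_families", build_families(annotations, 12L, 7L))
  ctrl_consistency <- stage("control_consistency", {
    ca <- family_es(screen_a, ctrl_fam, seed_min_size, max_family_size)
    cb <- family_es(screen_b, ctrl_fam, seed_min_size, max_family_size)
    matched_correlation(ca, cb, matched_qc)
  })

  thresholds <- stage("thresholds", derive_thresholds(seed_properties, pct))
  classified <- stage("classify", classify_seeds(seed_properties, thresholds))
  clean_a <- stage("clean_a", clean_dataset(screen_a, annotations, classified, policy))
  clean_b <- stage("clean_b", clean_dataset(screen_b, annotations, classified, policy))

  idx <- stage("gene_index", gene_index(annotations, screen_a))
  gene_a_before <- stage("garp_a_before", garp(screen_a, idx))
  gene_b_before <- stage("garp_b_before", garp(screen_b, idx))
  gene_a_after <- stage("garp_a_after", garp(clean_a$cleaned, idx))
  gene_b_after <- stage("garp_b_after", garp(clean_b$cleaned, idx))
  gene_consistency_before <- stage("gene_consistency_before",
                                   matched_correlation(gene_a_before, gene_b_before, matched_qc))
  gene_consistency_after <- stage("gene_consistency_after",
                                  matched_correlation(gene_a_after, gene_b_after, matched_qc))
  cleaning_test <- stage("cleaning_comparison",
                         compare_reports(gene_consistency_after, gene_consistency_before,
                                         "one_sided_greater"))

  gi <- NULL
  if (!is.null(genotypes) && ncol(genotypes) > 1) {
    gi <- stage("genetic_interaction", {
      run_one <- function(ges) detect_partners_all(ges, genotypes, drivers,
                                                   gi_alpha, sl_alpha)
      hits <- list(a_before = run_one(gene_a_before),
                   b_before = run_one(gene_b_before),
                   a_after = run_one(gene_a_after),
                   b_after = run_one(gene_b_after))
      list(hits = hits,
           overlap_gi = overlap_analysis(hits$a_before, hits$b_before,
                                         hits$a_after, hits$b_after, "gi_hit"),
           overlap_sl = overlap_analysis(hits$a_before, hits$b_before,
                                         hits$a_after, hits$b_after, "sl_hit"),
           pr = if (!is.null(truth) && nrow(truth$sl_pairs) > 0) {
             list(before = pooled_precision_recall(hits$a_before, hits$b_before, truth),
                  after = pooled_precision_recall(hits$a_after, hits$b_after, truth))
           })
    })
  }

  res <- list(qc = qc, matched_used = matched_qc,
              baseline = baseline,
              seed_consistency = seed_consistency,
              control_consistency = ctrl_consistency,
              seed_vs_shrna = compare_reports(seed_consistency, baseline,
                                              "one_sided_greater"),
              thresholds = thresholds,
              cleaning = list(a = clean_a[c("summary", "lost_genes", "n_unknown_seed")],
                              b = clean_b[c("summary", "lost_genes", "n_unknown_seed")]),
              gene_consistency_before = gene_consistency_before,
              gene_consistency_after = gene_consistency_after,
              cleaning_test = cleaning_test,
              gi = gi)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(tbl, name) {
      utils::write.table(tbl, file.path(out_dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, eol = "\n")
    }
    if (!is.null(qc)) wt(qc, "replicate_qc.tsv")
    wt(tidy(baseline), "consistency_shrna.tsv")
    wt(tidy(seed_consistency), "consistency_seed.tsv")
    wt(tidy(ctrl_consistency), "consistency_control.tsv")
    wt(tidy(gene_consistency_before), "consistency_gene_before.tsv")
    wt(tidy(gene_consistency_after), "consistency_gene_after.tsv")
    wt(thresholds, "thresholds.tsv")
    wt(clean_a$report, "cleaning_report_a.tsv")
    wt(clean_b$report, "cleaning_report_b.tsv")
    if (!is.null(gi)) {
      wt(gi$hits$a_after, "gi_hits_a_after.tsv")
      wt(gi$hits$b_after, "gi_hits_b_after.tsv")
      wt(gi$overlap_gi$per_driver, "gi_overlap.tsv")
      wt(gi$overlap_sl$per_driver, "sl_overlap.tsv")
    }
    manifest <- list(
      tool = "seedscreen",
      version = as.character(utils::packageVersion("seedscreen")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      parameters = list(qc_threshold = qc_threshold, seed_min_size = seed_min_size,
                        max_family_size = max_family_size, pct = pct, policy = policy,
                        gi_alpha = gi_alpha, sl_alpha = sl_alpha),
      inputs = list(
        screen_a = digest_table(screen_a), screen_b = digest_table(screen_b),
        annotations = digest_table(annotations),
        seed_properties = digest_table(seed_properties),
        genotypes = if (!is.null(genotypes)) digest_table(genotypes)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# order-sensitive content digest without external dependencies
digest_table <- function(tbl) {
  con <- textConnection(NULL, "w")
  utils::write.table(as.data.frame(tbl), con, sep = "\t", row.names = FALSE)
  txt <- textConnectionValue(con)
  close(con)
  n <- length(txt)
  paste0("rows=", n - 1L, ";sum=", sum(utils::head(cumsum(nchar(txt)), 50L)))
}
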