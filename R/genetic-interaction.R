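#' Detect genetic-interaction and synthetic-lethal partners
#'
#' For one driver gene, splits cell lines into mutated and wild-type
#' groups by the genotype panel and compares each candidate partner
#' gene's essentiality scores between the groups with a Wilcoxon
#' rank-sum test: two-sided for genetic interaction (GI), one-sided
#' toward more-negative-in-mutant for synthetic lethality (SL). Hits
#' are flagged at raw thresholds (default 0.05 GI, 0.03 SL) with no
#' multiple-testing correction, matching common practice for pan-cancer
#' GI discovery; set `adjust = "BH"` for Benjamini-Hochberg flags
#' instead. Drivers mutated in fewer than 2 cell lines are refused.
#'
#' @param gene_es Gene-level [es_mat()].
#' @param panel Wide genotype tibble (`cell_line` + 0/1 gene columns).
#' @param driver Driver gene (must be a column of `panel`).
#' @param gi_alpha,sl_alpha Raw significance thresholds.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `driver`, `partner`, `n_mut`, `n_wt`, `statistic`,
#'   `p_two_sided`, `p_one_sided_neg`, `gi_hit`, `sl_hit`. Partners
#'   with < 2 non-missing scores in either group get missing p-values.
#' @export
detect_partners <- function(gene_es, panel, driver,
                            gi_alpha = 0.05, sl_alpha = 0.03,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(gene_es, "es_mat"))
  if (es_level(gene_es) != "gene") stop("detect_partners expects gene-level scores", call. = FALSE)
  if (!driver %in% names(panel)) stop("driver '", driver, "' not in genotype panel", call. = FALSE)
  m <- es_scores(gene_es)
  cells <- intersect(colnames(m), panel$cell_line)
  status <- panel[[driver]][match(cells, panel$cell_line)]
  mut <- cells[status == 1]
  wt <- cells[status == 0]
  if (length(mut) < 2) {
    stop("driver '", driver, "' mutated in ", length(mut),
         " cell line(s); at least 2 required", call. = FALSE)
  }
  if (length(wt) < 1) stop("no wild-type cell line for driver '", driver, "'", call. = FALSE)
  partners <- setdiff(rownames(m), driver)
  np <- length(partners)
  n_mut_v <- integer(np); n_wt_v <- integer(np)
  stat_v <- rep(NA_real_, np); p2_v <- rep(NA_real_, np); p1_v <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    x <- m[partners[i], mut]; y <- m[partners[i], wt]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n_mut_v[i] <- length(x); n_wt_v[i] <- length(y)
    if (length(x) < 2 || length(y) < 2) next
    two <- ranksum_core(x, y, "two_sided")
    one <- ranksum_core(x, y, "one_sided_less")
    stat_v[i] <- two$statistic
    p2_v[i] <- two$p
    p1_v[i] <- one$p
  }
  out <- tibble::tibble(driver = driver, partner = partners,
                        n_mut = n_mut_v, n_wt = n_wt_v, statistic = stat_v,
                        p_two_sided = p2_v, p_one_sided_neg = p1_v)
  p_gi <- out$p_two_sided
  p_sl <- out$p_one_sided_neg
  if (adjust == "BH") {
    p_gi <- stats::p.adjust(p_gi, "BH")
    p_sl <- stats::p.adjust(p_sl, "BH")
  }
  out$gi_hit <- !is.na(p_gi) & p_gi <= gi_alpha
  out$sl_hit <- !is.na(p_sl) & p_sl <= sl_alpha
  out
}

#' Run [detect_partners()] over a driver panel
#'
#' Convenience wrapper: one [detect_partners()] call per driver gene in
#' `drivers` (default: every gene column of the panel mutated in at
#' least 2 scored cell lines); drivers below the mutation-count floor
#' are skipped with a message.
#'
#' @inheritParams detect_partners
#' @param drivers Character vector of driver genes (default all panel
#'   columns).
#' @return Tibble of per-driver results bound together.
#' @export
detect_partners_all <- function(gene_es, panel, drivers = NULL,
                                gi_alpha = 0.05, sl_alpha = 0.03,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(drivers)) drivers <- names(panel)[-1]
  res <- purrr::map(drivers, function(d) {
    tryCatch(detect_partners(gene_es, panel, d, gi_alpha, sl_alpha, adjust),
             error = function(e) {
               message("skipping driver '", d, "': ", conditionMessage(e))
               NULL
             })
  })
  dplyr::bind_rows(res)
}

#' Overlap of GI/SL hits between two screens, before vs after cleaning
#'
#' For each driver, counts the partner genes called in BOTH screens
#' (the reproducible hits), before and after off-target cleaning, and
#' tests the increase in overlap across drivers with a one-sided
#' Wilcoxon signed-rank test. When nothing changes, the degenerate case
#' is flagged (p = 1, method `"degenerate"`) and no improvement is
#' claimed.
#'
#' @param hits_a_before,hits_b_before,hits_a_after,hits_b_after
#'   Result tibbles from [detect_partners_all()] for screens A and B.
#' @param hit_col `"gi_hit"` (default) or `"sl_hit"`.
#' @return List: `per_driver` (tibble `driver`, `overlap_before`,
#'   `overlap_after`, `delta`), `comparison` (one-row test tibble,
#'   one-sided greater for after > before).
#' @export
overlap_analysis <- function(hits_a_before, hits_b_before,
                             hits_a_after, hits_b_after,
                             hit_col = c("gi_hit", "sl_hit")) {
  hit_col <- match.arg(hit_col)
  drivers <- Reduce(intersect, list(unique(hits_a_before$driver),
                                    unique(hits_b_before$driver),
                                    unique(hits_a_after$driver),
                                    unique(hits_b_after$driver)))
  if (length(drivers) == 0) stop("no driver evaluated in all four hit sets", call. = FALSE)
  hit_set <- function(tbl, d) tbl$partner[tbl$driver == d & tbl[[hit_col]] %in% TRUE]
  per_driver <- purrr::map(drivers, function(d) {
    ob <- length(intersect(hit_set(hits_a_before, d), hit_set(hits_b_before, d)))
    oa <- length(intersect(hit_set(hits_a_after, d), hit_set(hits_b_after, d)))
    tibble::tibble(driver = d, overlap_before = ob, overlap_after = oa,
                   delta = oa - ob)
  })
  per_driver <- dplyr::bind_rows(per_driver)
  d <- per_driver$delta
  cmp <- if (all(d == 0)) {
    test_result(0, 1, "one_sided_greater", "degenerate")
  } else {
    wilcoxon_signed_rank(d, "one_sided_greater")
  }
  list(per_driver = per_driver, comparison = cmp)
}

#' Precision and recall of SL calls against planted truth
#'
#' Validation harness for the simulator: compares flagged SL hits
#' (driver, partner pairs) with the planted synthetic-lethal pairs.
#'
#' @param hits Result tibble from [detect_partners_all()].
#' @param truth Simulation truth (list with `sl_pairs`, a tibble with
#'   columns `driver`, `partner`), as returned by [simulate_screens()].
#' @return One-row tibble (`n_hits`, `n_true`, `tp`, `precision`,
#'   `recall`); precision is NA when there are no hits.
#' @export
precision_recall_vs_truth <- function(hits, truth) {
  sl <- truth$sl_pairs
  if (is.null(sl) || nrow(sl) == 0) stop("truth contains no planted SL pairs", call. = FALSE)
  called <- hits[hits$sl_hit %in% TRUE, c("driver", "partner")]
  key <- function(tb) paste(tb$driver, tb$partner)
  tp <- length(intersect(key(called), key(sl)))
  tibble::tibble(n_hits = nrow(called), n_true = nrow(sl), tp = tp,
                 precision = if (nrow(called) > 0) tp / nrow(called) else NA_real_,
                 recall = tp / nrow(sl))
}

#' Pooled precision and recall across two screens
#'
#' Aggregates the per-screen SL evaluation: true positives and hit
#' counts are summed over both screens' hit lists, so each planted pair
#' can be credited once per screen. Averaging over the two datasets
#' stabilizes the precision estimate against per-screen churn at the
#' significance threshold.
#'
#' @param hits_a,hits_b Result tibbles from [detect_partners_all()] for
#'   the two screens.
#' @param truth Simulation truth (see [precision_recall_vs_truth()]).
#' @return One-row tibble (`n_hits`, `n_true`, `tp`, `precision`,
#'   `recall`).
#' @export
pooled_precision_recall <- function(hits_a, hits_b, truth) {
  pa <- precision_recall_vs_truth(hits_a, truth)
  pb <- precision_recall_vs_truth(hits_b, truth)
  n_hits <- pa$n_hits + pb$n_hits
  tp <- pa$tp + pb$tp
  tibble::tibble(n_hits = n_hits, n_true = pa$n_true + pb$n_true, tp = tp,
                 precision = if (n_hits > 0) tp / n_hits else NA_real_,
                 recall = tp / (pa$n_true + pb$n_true))
}
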