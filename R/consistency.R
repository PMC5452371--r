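new_consistency_report <- function(rho_tbl, level, grouping = NULL, comparison = NULL) {
  structure(list(level = level,
                 rho = rho_tbl,
                 mean_rho = mean(rho_tbl$rho),
                 grouping = grouping,
                 comparison = comparison),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency report: level=", x$level, ", ",
      nrow(x$rho), " cell-line pair(s), mean rho = ",
      formatC(x$mean_rho, digits = 3, format = "f"), ">\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname matched_correlation
#' @param x A `consistency_report`.
#' @param ... Unused.
#' @method tidy consistency_report
#' @export
tidy.consistency_report <- function(x, ...) x$rho

#' @rdname matched_correlation
#' @method glance consistency_report
#' @export
glance.consistency_report <- function(x, ...) {
  tibble::tibble(level = x$level,
                 n_pairs = nrow(x$rho),
                 mean_rho = x$mean_rho,
                 sem_rho = stats::sd(x$rho$rho) / sqrt(nrow(x$rho)))
}

#' Replicate-level quality control
#'
#' Computes `rho_rep`, the mean pairwise Spearman correlation across a
#' cell line's screen replicates, and drops cell lines below the
#' threshold (default 0.5), the standard cut for discarding noisy
#' screen data. Cell lines with a single replicate pass with `rho_rep`
#' undefined and are flagged.
#'
#' @param replicates Long tibble (`cell_line`, `replicate`, `shrna_id`,
#'   `score`), as from [read_replicates()].
#' @param threshold Minimum acceptable `rho_rep` (default 0.5).
#' @return Tibble (`cell_line`, `n_replicates`, `rho_rep`, `keep`,
#'   `flagged_single_replicate`).
#' @export
replicate_qc <- function(replicates, threshold = 0.5) {
  need <- c("cell_line", "replicate", "shrna_id", "score")
  stopifnot(all(need %in% names(replicates)))
  per_line <- split(tibble::as_tibble(replicates[need]), replicates$cell_line)
  rows <- purrr::map(per_line, function(tb) {
    wide <- tidyr::pivot_wider(tb, id_cols = "shrna_id",
                               names_from = "replicate", values_from = "score")
    reps <- as.matrix(wide[, -1, drop = FALSE])
    k <- ncol(reps)
    if (k < 2) {
      return(tibble::tibble(cell_line = tb$cell_line[1], n_replicates = k,
                            rho_rep = NA_real_, keep = TRUE,
                            flagged_single_replicate = TRUE))
    }
    pairs <- utils::combn(k, 2)
    rhos <- apply(pairs, 2, function(ij) spearman_rho(reps[, ij[1]], reps[, ij[2]]))
    rho_rep <- mean(rhos)
    tibble::tibble(cell_line = tb$cell_line[1], n_replicates = k,
                   rho_rep = rho_rep, keep = rho_rep >= threshold,
                   flagged_single_replicate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Between-screen consistency over matched cell lines
#'
#' For each matched cell-line pair, the Spearman correlation of the two
#' screens' scores over their shared entities (pairwise-complete; pairs
#' missing in either screen are dropped per entity).
#'
#' @param a,b [es_mat()] tables at the same level.
#' @param matched Tibble (`cell_line_a`, `cell_line_b`).
#' @return A `consistency_report`: list with `level`, `rho` (tibble
#'   `cell_line_a`, `cell_line_b`, `rho`, `n_entities`), `mean_rho`.
#' @export
matched_correlation <- function(a, b, matched) {
  stopifnot(inherits(a, "es_mat"), inherits(b, "es_mat"))
  if (es_level(a) != es_level(b)) {
    stop("level mismatch: ", es_level(a), " vs ", es_level(b), call. = FALSE)
  }
  shared <- intersect(a$entity, b$entity)
  if (length(shared) < 3) stop("fewer than 3 shared entities", call. = FALSE)
  ma <- es_scores(a)[shared, , drop = FALSE]
  mb <- es_scores(b)[shared, , drop = FALSE]
  miss_a <- setdiff(matched$cell_line_a, colnames(ma))
  miss_b <- setdiff(matched$cell_line_b, colnames(mb))
  if (length(miss_a) > 0 || length(miss_b) > 0) {
    stop("matched cell line(s) absent from screen: ",
         paste(c(miss_a, miss_b), collapse = ", "), call. = FALSE)
  }
  rho <- purrr::map2_dbl(matched$cell_line_a, matched$cell_line_b,
                         function(ca, cb) spearman_rho(ma[, ca], mb[, cb]))
  n_ent <- purrr::map2_int(matched$cell_line_a, matched$cell_line_b,
                           function(ca, cb) sum(!is.na(ma[, ca]) & !is.na(mb[, cb])))
  new_consistency_report(
    tibble::tibble(cell_line_a = matched$cell_line_a,
                   cell_line_b = matched$cell_line_b,
                   rho = rho, n_entities = n_ent),
    level = es_level(a))
}

#' Non-matched cell-line baseline
#'
#' Correlates every cell line of screen A with every NON-matching cell
#' line of screen B, giving the background concordance attributable to
#' shared library structure rather than cell-line identity, and tests
#' matched vs non-matched rho distributions by Wilcoxon rank-sum.
#'
#' @inheritParams matched_correlation
#' @return List: `nonmatched` (tibble `cell_line_a`, `cell_line_b`,
#'   `rho`), `matched_report` (a `consistency_report`), `comparison`
#'   (one-row test tibble, matched greater).
#' @export
nonmatched_baseline <- function(a, b, matched) {
  rep_m <- matched_correlation(a, b, matched)
  shared <- intersect(a$entity, b$entity)
  ma <- es_scores(a)[shared, , drop = FALSE]
  mb <- es_scores(b)[shared, , drop = FALSE]
  grid <- expand.grid(cell_line_a = colnames(ma), cell_line_b = colnames(mb),
                      stringsAsFactors = FALSE)
  is_matched <- paste(grid$cell_line_a, grid$cell_line_b) %in%
    paste(matched$cell_line_a, matched$cell_line_b)
  grid <- grid[!is_matched, , drop = FALSE]
  if (nrow(grid) < 2) stop("fewer than 2 non-matched pairs", call. = FALSE)
  rho <- purrr::map2_dbl(grid$cell_line_a, grid$cell_line_b,
                         function(ca, cb) spearman_rho(ma[, ca], mb[, cb]))
  cmp <- wilcoxon_rank_sum(rep_m$rho$rho, rho, "one_sided_greater")
  list(nonmatched = tibble::tibble(grid, rho = rho),
       matched_report = rep_m,
       comparison = cmp)
}

#' Consistency as a function of shRNA family size
#'
#' Computes the mean matched-cell-line Spearman correlation of family-
#' averaged scores separately for each family size, over sizes with at
#' least `min_bin` families (default 50, below which a size bin is too
#' sparse to compare), plus an optional permuted-map reference trace in
#' which family membership is destroyed while the size multiset is
#' kept.
#'
#' @param shes_a,shes_b shRNA-level [es_mat()] for the two screens.
#' @param fam `seed_fam` map from [build_families()].
#' @param matched Matched-pair tibble.
#' @param min_bin Minimum families per size bin (default 50).
#' @param max_size Largest family size considered (default 14).
#' @param n_perm Permuted maps for the reference trace (0 = skip).
#' @param n_boot Bootstrap resamples of the families within each bin
#'   used for `boot_se` (0 = skip). `sem_rho` is the cell-line SEM and
#'   describes spread over the matched panel; `boot_se` quantifies the
#'   bin-composition uncertainty (which seed families fell in the bin),
#'   which is the relevant error when comparing adjacent bins.
#' @param rng_seed Seed for the permutations and bootstrap.
#' @return Tibble (`family_size`, `n_families`, `mean_rho`, `sem_rho`,
#'   `boot_se`, `perm_mean_rho`).
#' @export
family_size_curve <- function(shes_a, shes_b, fam, matched,
                              min_bin = 50L, max_size = 14L,
                              n_perm = 0L, n_boot = 0L, rng_seed = 1L) {
  shared <- intersect(intersect(shes_a$entity, shes_b$entity), fam$shrna_id)
  fam_shared <- fam[fam$shrna_id %in% shared, , drop = FALSE]
  class(fam_shared) <- class(fam)
  attr(fam_shared, "window") <- attr(fam, "window")
  sizes_tbl <- table(table(fam_shared$seed))
  sizes <- as.integer(names(sizes_tbl))[sizes_tbl >= min_bin]
  sizes <- sizes[sizes >= 1 & sizes <= max_size]
  if (length(sizes) == 0) {
    stop("no family-size bin with at least ", min_bin, " families", call. = FALSE)
  }
  bin_members <- function(map) {
    fa <- family_es(shes_a, map, min_size = 1L, max_size = max_size)
    fb <- family_es(shes_b, map, min_size = 1L, max_size = max_size)
    fs <- attr(fa, "family_size")
    ma <- es_scores(fa); mb <- es_scores(fb)
    list(ma = ma, mb = mb, fs = fs)
  }
  bin_rhos <- function(bm, keep) {
    purrr::map2_dbl(matched$cell_line_a, matched$cell_line_b, function(ca, cb) {
      spearman_rho(bm$ma[keep, ca], bm$mb[keep, cb])
    })
  }
  bm <- bin_members(fam_shared)
  mean_rho <- sem_rho <- boot_se <- rep(NA_real_, length(sizes))
  set.seed(rng_seed)
  for (i in seq_along(sizes)) {
    keep <- names(bm$fs)[bm$fs == sizes[i]]
    r <- bin_rhos(bm, keep)
    mean_rho[i] <- mean(r)
    sem_rho[i] <- stats::sd(r) / sqrt(length(r))
    if (n_boot > 0) {
      bmeans <- vapply(seq_len(n_boot), function(b) {
        mean(bin_rhos(bm, sample(keep, replace = TRUE)))
      }, numeric(1))
      boot_se[i] <- stats::sd(bmeans)
    }
  }
  perm_mean <- rep(NA_real_, length(sizes))
  if (n_perm > 0) {
    perms <- permute_seed_map(fam_shared, n_perm = n_perm, rng_seed = rng_seed)
    traces <- purrr::map(perms, function(map) {
      pm <- bin_members(map)
      vapply(sizes, function(s) {
        keep <- names(pm$fs)[pm$fs == s]
        mean(bin_rhos(pm, keep))
      }, numeric(1))
    })
    perm_mean <- Reduce(`+`, traces) / length(traces)
  }
  n_fam <- as.integer(sizes_tbl[as.character(sizes)])
  tibble::tibble(family_size = sizes, n_families = n_fam,
                 mean_rho = mean_rho, sem_rho = sem_rho, boot_se = boot_se,
                 perm_mean_rho = perm_mean)
}

#' Compare two consistency reports
#'
#' Paired comparison of per-cell-line correlations: paired t-test when
#' the Shapiro-Wilk gate accepts normality of the differences at
#' `alpha`, Wilcoxon signed-rank otherwise; the method used is recorded.
#' Identical reports short-circuit to p = 1 with method `"degenerate"`.
#'
#' @param r1,r2 `consistency_report` objects over the same cell-line
#'   pairs.
#' @param sidedness Test sidedness for r1 vs r2 (default two-sided).
#' @param alpha Normality-gate level (default 0.05).
#' @return One-row test tibble (see [wilcoxon_rank_sum()]).
#' @export
compare_reports <- function(r1, r2, sidedness = .sidedness, alpha = 0.05) {
  sidedness <- match.arg(sidedness)
  stopifnot(inherits(r1, "consistency_report"), inherits(r2, "consistency_report"))
  key1 <- paste(r1$rho$cell_line_a, r1$rho$cell_line_b)
  key2 <- paste(r2$rho$cell_line_a, r2$rho$cell_line_b)
  if (!setequal(key1, key2)) stop("reports cover different cell-line pairs", call. = FALSE)
  x <- r1$rho$rho
  y <- r2$rho$rho[match(key1, key2)]
  d <- x - y
  if (all(d == 0)) {
    return(test_result(0, 1, sidedness, "degenerate"))
  }
  use_t <- tryCatch(normality_gate(d, alpha), error = function(e) FALSE)
  if (use_t) paired_t(x, y, sidedness) else wilcoxon_signed_rank(d, sidedness)
}

#' Consistency stratified by seed class
#'
#' Recomputes the matched-cell-line shRNA-level consistency separately
#' for the strong/weak SPS and low/high TA seed classes, and repeats
#' the same stratification using the position-12-18 control heptamer's
#' classes as a negative control (that window does not drive target
#' recognition, so no class ordering is expected there).
#'
#' @param shes_a,shes_b shRNA-level [es_mat()] for the two screens.
#' @param annotations Annotation tibble.
#' @param classified_props Output of [classify_seeds()]; must cover the
#'   control-window heptamers too for the control rows to be computed.
#' @param matched Matched-pair tibble.
#' @param control_start Start of the control window (default 12).
#' @return Tibble (`window`, `axis`, `class`, `n_shrnas`, `mean_rho`)
#'   with a list-column `report` of `consistency_report`s; subsets with
#'   fewer than 3 shRNAs are reported as absent (NA mean_rho).
#' @export
class_stratified_consistency <- function(shes_a, shes_b, annotations,
                                         classified_props, matched,
                                         control_start = 12L) {
  shared <- intersect(shes_a$entity, shes_b$entity)
  ann <- annotations[annotations$shrna_id %in% shared, , drop = FALSE]
  strata <- list(
    c(window = "seed", axis = "sps", class = "strong"),
    c(window = "seed", axis = "sps", class = "weak"),
    c(window = "seed", axis = "ta", class = "low"),
    c(window = "seed", axis = "ta", class = "high"),
    c(window = "control", axis = "sps", class = "strong"),
    c(window = "control", axis = "sps", class = "weak"),
    c(window = "control", axis = "ta", class = "low"),
    c(window = "control", axis = "ta", class = "high"))
  seed_kmer <- extract_window(ann$guide_sequence, 2L, 7L, ids = ann$shrna_id)
  ctrl_kmer <- extract_window(ann$guide_sequence, control_start, 7L, ids = ann$shrna_id)
  cls_seed <- classified_props[match(seed_kmer, classified_props$seed),
                               c("sps_class", "ta_class")]
  cls_ctrl <- classified_props[match(ctrl_kmer, classified_props$seed),
                               c("sps_class", "ta_class")]
  all_report <- matched_correlation(shes_a, shes_b, matched)
  rows <- purrr::map(strata, function(st) {
    cls <- if (st[["window"]] == "seed") cls_seed else cls_ctrl
    col <- paste0(st[["axis"]], "_class")
    ids <- ann$shrna_id[!is.na(cls[[col]]) & cls[[col]] == st[["class"]]]
    if (length(ids) < 3) {
      return(tibble::tibble(window = st[["window"]], axis = st[["axis"]],
                            class = st[["class"]], n_shrnas = length(ids),
                            mean_rho = NA_real_, report = list(NULL)))
    }
    sub_a <- es_mat(shes_a[shes_a$entity %in% ids, , drop = FALSE], "shrna")
    sub_b <- es_mat(shes_b[shes_b$entity %in% ids, , drop = FALSE], "shrna")
    rep <- matched_correlation(sub_a, sub_b, matched)
    tibble::tibble(window = st[["window"]], axis = st[["axis"]],
                   class = st[["class"]], n_shrnas = length(ids),
                   mean_rho = rep$mean_rho, report = list(rep))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(
    tibble::tibble(window = "seed", axis = "all", class = "all",
                   n_shrnas = length(shared), mean_rho = all_report$mean_rho,
                   report = list(all_report)),
    out)
  out
}
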