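#' Derive SPS/TA classification thresholds
#'
#' Computes strong/weak seed-pairing-stability (SPS) cuts and low/high
#' target-abundance (TA) cuts as the top and bottom `pct` percentile of
#' the observed distributions, by linear interpolation between order
#' statistics. Conventions follow the screening literature: strong SPS = most negative tail (strongest
#' seed-target duplex, highest off-target proficiency); weak SPS = least
#' negative tail; low TA = LARGEST ta tail; high TA = smallest ta tail.
#' Quantiles use the median-unbiased linear-interpolation rule
#' (`stats::quantile` type 8), recorded in the output so thresholds are
#' reproducible across tools.
#' The TA direction looks inverted at first sight but is the stated
#' convention of the source heptamer tables; `ta_direction` allows the
#' opposite reading for property tables that use the intuitive one.
#' On the reference TargetScan-derived distributions this procedure
#' gives cuts near -9.82 / -5.16 for SPS and 3.72 / 2.89 for TA.
#'
#' @param props Seed-property tibble (`seed`, `sps`, `ta`).
#' @param pct Tail percentile in (0, 50\] (default 10).
#' @param ta_direction `"literal"` (default; low TA = large ta values)
#'   or `"reversed"`.
#' @return One-row tibble: `sps_strong`, `sps_weak`, `ta_low`,
#'   `ta_high`, `pct`, `quantile_rule`.
#' @export
derive_thresholds <- function(props, pct = 10, ta_direction = c("literal", "reversed")) {
  ta_direction <- match.arg(ta_direction)
  stopifnot(all(c("sps", "ta") %in% names(props)), pct >= 0, pct <= 50)
  sps <- props$sps[!is.na(props$sps)]
  ta <- props$ta[!is.na(props$ta)]
  if (length(unique(sps)) < 2 || length(unique(ta)) < 2) {
    stop("degenerate (constant) sps or ta axis", call. = FALSE)
  }
  q <- pct / 100
  sps_strong <- unname(stats::quantile(sps, q, type = 8))
  sps_weak <- unname(stats::quantile(sps, 1 - q, type = 8))
  if (ta_direction == "literal") {
    ta_low <- unname(stats::quantile(ta, 1 - q, type = 8))
    ta_high <- unname(stats::quantile(ta, q, type = 8))
  } else {
    ta_low <- unname(stats::quantile(ta, q, type = 8))
    ta_high <- unname(stats::quantile(ta, 1 - q, type = 8))
  }
  tibble::tibble(sps_strong = sps_strong, sps_weak = sps_weak,
                 ta_low = ta_low, ta_high = ta_high, pct = pct,
                 quantile_rule = "linear_interpolation_type8",
                 ta_direction = ta_direction)
}

#' Classify seeds by SPS and TA
#'
#' Labels each seed on both axes: `sps_class` is `"strong"` when
#' `sps < sps_strong`, `"weak"` when `sps > sps_weak`, else
#' `"neither"`; `ta_class` (literal direction) is `"low"` when
#' `ta > ta_low`, `"high"` when `ta < ta_high`, else `"neither"`.
#'
#' @param props Seed-property tibble (`seed`, `sps`, `ta`).
#' @param thresholds One-row tibble from [derive_thresholds()].
#' @return `props` with `sps_class` and `ta_class` columns added.
#' @export
classify_seeds <- function(props, thresholds) {
  stopifnot(all(c("seed", "sps", "ta") %in% names(props)))
  th <- thresholds
  if (th$sps_strong >= th$sps_weak) {
    stop("inverted SPS thresholds: strong cut must lie below weak cut", call. = FALSE)
  }
  literal <- !("ta_direction" %in% names(th)) || th$ta_direction == "literal"
  if (literal && th$ta_high >= th$ta_low) {
    stop("inverted TA thresholds: high cut must lie below low cut", call. = FALSE)
  }
  if (!literal && th$ta_low >= th$ta_high) {
    stop("inverted TA thresholds", call. = FALSE)
  }
  props <- tibble::as_tibble(props)
  props$sps_class <- dplyr::case_when(
    is.na(props$sps) ~ "unknown",
    props$sps < th$sps_strong ~ "strong",
    props$sps > th$sps_weak ~ "weak",
    TRUE ~ "neither")
  if (literal) {
    props$ta_class <- dplyr::case_when(
      is.na(props$ta) ~ "unknown",
      props$ta > th$ta_low ~ "low",
      props$ta < th$ta_high ~ "high",
      TRUE ~ "neither")
  } else {
    props$ta_class <- dplyr::case_when(
      is.na(props$ta) ~ "unknown",
      props$ta < th$ta_low ~ "low",
      props$ta > th$ta_high ~ "high",
      TRUE ~ "neither")
  }
  props
}

#' Remove high off-target-propensity shRNAs
#'
#' Cleans an shRNA score matrix by removing constructs whose seed falls
#' in the flagged classes. The default policy removes shRNAs whose seed
#' has strong SPS OR low TA (the union of the two high-propensity
#' classes); `"and"`, `"sps"` and `"ta"` policies are available because
#' either axis alone is a defensible filter. Seeds absent from the
#' property table are treated as unflagged and reported.
#'
#' @param shes shRNA-level [es_mat()].
#' @param annotations Annotation tibble for the shRNAs.
#' @param classified_props Output of [classify_seeds()].
#' @param policy `"or"` (default), `"and"`, `"sps"` or `"ta"`.
#' @param start,length Seed window used to join shRNAs to seeds.
#' @return List: `cleaned` ([es_mat()]), `report` (one row per removed
#'   shRNA with `shrna_id`, `seed`, `target_gene`, `reason`), `summary`
#'   (counts per reason), `lost_genes` (genes losing all their shRNAs),
#'   `n_unknown_seed` (shRNAs whose seed had no property entry).
#' @export
clean_dataset <- function(shes, annotations, classified_props,
                          policy = c("or", "and", "sps", "ta"),
                          start = 2L, length = 7L) {
  policy <- match.arg(policy)
  stopifnot(inherits(shes, "es_mat"),
            all(c("sps_class", "ta_class") %in% names(classified_props)))
  ann <- annotations[annotations$shrna_id %in% shes$entity, , drop = FALSE]
  seeds <- extract_window(ann$guide_sequence, start, length, ids = ann$shrna_id)
  cls <- classified_props[match(seeds, classified_props$seed), c("sps_class", "ta_class")]
  sps_flag <- !is.na(cls$sps_class) & cls$sps_class == "strong"
  ta_flag <- !is.na(cls$ta_class) & cls$ta_class == "low"
  n_unknown <- sum(is.na(cls$sps_class))
  remove <- switch(policy,
                   or = sps_flag | ta_flag,
                   and = sps_flag & ta_flag,
                   sps = sps_flag,
                   ta = ta_flag)
  removed <- tibble::tibble(
    shrna_id = ann$shrna_id[remove],
    seed = seeds[remove],
    target_gene = ann$target_gene[remove],
    reason = dplyr::case_when(
      sps_flag[remove] & ta_flag[remove] ~ "strong_sps+low_ta",
      sps_flag[remove] ~ "strong_sps",
      TRUE ~ "low_ta"))
  keep_ids <- setdiff(shes$entity, removed$shrna_id)
  if (base::length(keep_ids) == 0) {
    stop("cleaning removed every shRNA; nothing left to analyze", call. = FALSE)
  }
  cleaned <- shes[match(keep_ids, shes$entity), , drop = FALSE]
  cleaned <- es_mat(cleaned, es_level(shes))
  genes_before <- unique(ann$target_gene)
  genes_after <- unique(ann$target_gene[!remove])
  list(cleaned = cleaned,
       report = removed,
       summary = dplyr::count(removed, reason, name = "n"),
       lost_genes = setdiff(genes_before, genes_after),
       n_unknown_seed = n_unknown)
}
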