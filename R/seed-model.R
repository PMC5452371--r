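#' Extract a guide-strand window
#'
#' Returns the contiguous substring at a 1-based inclusive window of
#' each guide sequence. The canonical miRNA-like seed is positions 2-8
#' of the guide strand, i.e. `start = 2, length = 7`; positions 12-18
#' give the off-target-inert control heptamer. Positions are counted
#' from the 5' end of the supplied sequence.
#'
#' @param guide_sequence Character vector of guide sequences.
#' @param start 1-based start position (default 2).
#' @param length Window length in nucleotides (default 7).
#' @param ids Optional identifiers used in error messages.
#' @return Character vector of window k-mers.
#' @examples
#' extract_window("TGGAAGGACTTAAGGAACCTT")           # "GGAAGGA"
#' extract_window("TGGAAGGACTTAAGGAACCTT", 12, 7)    # "AAGGAAC"
#' @export
extract_window <- function(guide_sequence, start = 2L, length = 7L, ids = NULL) {
  stopifnot(start >= 1, length >= 1)
  end <- start + length - 1L
  short <- nchar(guide_sequence) < end
  if (any(short)) {
    lab <- if (!is.null(ids)) ids[short][1] else guide_sequence[short][1]
    stop("window ", start, "-", end, " exceeds sequence length for shRNA '",
         lab, "'", call. = FALSE)
  }
  substr(guide_sequence, start, end)
}

#' Group shRNAs into seed families
#'
#' Partitions shRNAs by the identity of the k-mer at a guide-strand
#' window (default the seed, positions 2-8). shRNAs sharing a seed form
#' one "shRNA family"; the family size is the number of member shRNAs.
#' Sequences too short to cover the window are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param annotations Annotation tibble with `shrna_id` and
#'   `guide_sequence` (see [read_shrna_annotations()]).
#' @param start,length Window, as in [extract_window()].
#' @return A `seed_fam` tibble with columns `shrna_id`, `seed`,
#'   `family_size`, plus attributes `window` and `n_excluded`.
#' @export
build_families <- function(annotations, start = 2L, length = 7L) {
  stopifnot(all(c("shrna_id", "guide_sequence") %in% names(annotations)))
  if (nrow(annotations) == 0) stop("empty annotation set", call. = FALSE)
  end <- start + length - 1L
  covered <- nchar(annotations$guide_sequence) >= end
  n_excluded <- sum(!covered)
  if (all(!covered)) {
    stop("no guide sequence covers window ", start, "-", end, call. = FALSE)
  }
  ann <- annotations[covered, , drop = FALSE]
  seed <- substr(ann$guide_sequence, start, end)
  fam <- tibble::tibble(shrna_id = ann$shrna_id, seed = seed)
  fam <- dplyr::mutate(dplyr::group_by(fam, seed), family_size = dplyr::n())
  fam <- dplyr::ungroup(fam)
  structure(fam, window = c(start = as.integer(start), length = as.integer(length)),
            n_excluded = n_excluded,
            class = c("seed_fam", class(fam)))
}

#' Family-averaged essentiality scores (seedES / heptamerES)
#'
#' For each seed family, averages the member shRNA scores per cell line
#' (arithmetic mean of non-missing members; a family's score is missing
#' only if every member is missing). Families whose size falls outside
#' `[min_size, max_size]` are dropped; the default cap of 14 mirrors the
#' point at which larger families become too rare to compare. Family
#' sizes are recomputed on the shRNAs actually present in the score
#' matrix.
#'
#' @param shes shRNA-level [es_mat()].
#' @param fam A `seed_fam` map from [build_families()].
#' @param min_size,max_size Family-size range retained (defaults 1, 14).
#' @return An [es_mat()] at level `"seed"` when the map's window is the
#'   canonical seed (2-8), otherwise `"heptamer"`, with a `family_size`
#'   attribute (named integer vector, per retained seed).
#' @export
family_es <- function(shes, fam, min_size = 1L, max_size = 14L) {
  stopifnot(inherits(shes, "es_mat"), inherits(fam, "seed_fam"),
            min_size >= 1, min_size <= max_size)
  if (es_level(shes) != "shrna") {
    stop("family_es expects shRNA-level scores; got level '", es_level(shes), "'",
         call. = FALSE)
  }
  m <- es_scores(shes)
  map <- fam[fam$shrna_id %in% rownames(m), , drop = FALSE]
  if (nrow(map) == 0) stop("no family member present in the score matrix", call. = FALSE)
  m <- m[map$shrna_id, , drop = FALSE]
  grp <- map$seed
  obs <- !is.na(m)
  msum <- rowsum(ifelse(obs, m, 0), grp)
  mcnt <- rowsum(obs + 0L, grp)
  means <- msum / mcnt
  means[mcnt == 0] <- NA_real_
  sizes <- table(grp)[rownames(means)]
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    stop("no family with size in [", min_size, ", ", max_size, "]", call. = FALSE)
  }
  means <- means[keep, , drop = FALSE]
  w <- attr(fam, "window")
  level <- if (identical(unname(w), c(2L, 7L))) "seed" else "heptamer"
  out <- es_from_matrix(means, level)
  attr(out, "family_size") <- stats::setNames(as.integer(sizes[keep]),
                                              rownames(means))
  out
}

#' Permute the shRNA-to-seed mapping
#'
#' Generates null family maps by shuffling which shRNA carries which
#' seed, preserving the multiset of family sizes exactly (equivalent to
#' permuting the id column of the map). Used to show that the
#' consistency gain of family averaging vanishes when family membership
#' is destroyed.
#'
#' @param fam A `seed_fam` map.
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Integer seed; the full sequence of maps is
#'   reproducible from it.
#' @return List of `n_perm` permuted `seed_fam` maps.
#' @export
permute_seed_map <- function(fam, n_perm = 1000L, rng_seed = 1L) {
  stopifnot(inherits(fam, "seed_fam"), n_perm >= 1)
  old <- fam$shrna_id
  set.seed(rng_seed)
  lapply(seq_len(n_perm), function(i) {
    out <- fam
    out$shrna_id <- sample(old)
    out
  })
}

#' Sliding-window consistency scan
#'
#' Repeats the family-averaging analysis for every 7-mer window start
#' position along the guide, computing the mean matched-cell-line
#' Spearman correlation between two screens for each start. With real
#' seed-mediated off-target structure, the canonical seed window
#' (start 2) stands out against the mean over all other starts.
#'
#' @param shes_a,shes_b shRNA-level [es_mat()] for the two screens.
#' @param annotations Annotation tibble covering both screens.
#' @param matched Matched-pair tibble (`cell_line_a`, `cell_line_b`).
#' @param length Window length (default 7).
#' @param min_size,max_size Family-size range passed to [family_es()].
#' @return Tibble (`start`, `mean_rho`, `n_families`) with attribute
#'   `mean_nonseed_rho`, the mean over all windows except start 2.
#' @export
sliding_window_scan <- function(shes_a, shes_b, annotations, matched,
                                length = 7L, min_size = 1L, max_size = 14L) {
  seq_len_min <- min(nchar(annotations$guide_sequence))
  n_starts <- seq_len_min - length + 1L
  if (n_starts < 1) stop("window length exceeds shortest guide sequence", call. = FALSE)
  rows <- purrr::map(seq_len(n_starts), function(s) {
    fam <- build_families(annotations, start = s, length = length)
    fa <- family_es(shes_a, fam, min_size, max_size)
    fb <- family_es(shes_b, fam, min_size, max_size)
    rep <- matched_correlation(fa, fb, matched)
    tibble::tibble(start = s, mean_rho = rep$mean_rho,
                   n_families = base::length(intersect(fa$entity, fb$entity)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_nonseed_rho") <- mean(out$mean_rho[out$start != 2L])
  out
}
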