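#' Build a gene-to-shRNA index
#'
#' Maps each intended target gene to the shRNA clones annotated against
#' it, keeping only members present in the score matrix and dropping
#' genes left without members.
#'
#' @param annotations Annotation tibble (`shrna_id`, `target_gene`).
#' @param shes Optional shRNA-level [es_mat()] to restrict members to.
#' @return Tibble (`target_gene`, `shrna_id`).
#' @export
gene_index <- function(annotations, shes = NULL) {
  stopifnot(all(c("shrna_id", "target_gene") %in% names(annotations)))
  idx <- tibble::as_tibble(annotations[, c("target_gene", "shrna_id")])
  if (!is.null(shes)) idx <- idx[idx$shrna_id %in% shes$entity, , drop = FALSE]
  if (nrow(idx) == 0) stop("empty gene index", call. = FALSE)
  idx
}

#' GARP gene essentiality scores
#'
#' For each gene and cell line, the mean of the two most essential
#' (most negative) non-missing member shRNA scores. A gene with a
#' single shRNA keeps that shRNA's score verbatim; a gene whose members
#' are all missing in a cell line gets a missing score. No sign gating:
#' with only non-essential members the mean of the two smallest scores
#' is still returned.
#'
#' @param shes shRNA-level [es_mat()].
#' @param index Gene index from [gene_index()].
#' @return Gene-level [es_mat()].
#' @examples
#' m <- es_mat(data.frame(entity = paste0("s", 1:3), c1 = c(-2, -1.5, 0.1)), "shrna")
#' idx <- data.frame(target_gene = "G1", shrna_id = paste0("s", 1:3))
#' garp(m, idx)  # G1 score -1.75
#' @export
garp <- function(shes, index) {
  stopifnot(inherits(shes, "es_mat"))
  if (es_level(shes) != "shrna") {
    stop("garp expects shRNA-level scores", call. = FALSE)
  }
  m <- es_scores(shes)
  idx <- index[index$shrna_id %in% rownames(m), , drop = FALSE]
  if (nrow(idx) == 0) stop("no indexed shRNA present in the score matrix", call. = FALSE)
  genes <- unique(idx$target_gene)
  members <- split(idx$shrna_id, idx$target_gene)[genes]
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in seq_along(genes)) {
    sub <- m[members[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0) return(NA_real_)
      mean(sort(v, partial = seq_len(min(2L, length(v))))[seq_len(min(2L, length(v)))])
    })
  }
  es_from_matrix(out, "gene")
}

#' RIGER-style KS enrichment gene scores
#'
#' Rank-based gene summarization: per cell line, shRNAs are ranked
#' ascending by score (most essential first, ties broken by entity id
#' for determinism), and each gene's members are scored by the
#' unweighted Kolmogorov-Smirnov running sum over that ranking (hits
#' step up by 1/m, misses down by 1/(N - m); the score is the signed
#' deviation of maximal magnitude, in \[-1, 1\]). Members concentrated
#' at the essential (most negative) end of the ranking give a score
#' near +1, so unlike [garp()] a HIGHER riger_ks score means a more
#' essential gene. With `n_norm_perm > 0` each score is divided
#' by the mean |score| of size-matched random member sets, giving a
#' normalized enrichment score.
#'
#' This is the unweighted KS variant; it does not claim bit
#' compatibility with the GENE-E implementation, whose internals are
#' unpublished.
#'
#' @param shes shRNA-level [es_mat()].
#' @param index Gene index from [gene_index()].
#' @param n_norm_perm Size-matched permutations for normalization
#'   (default 0 = raw scores).
#' @param rng_seed Seed for the normalization permutations.
#' @return Gene-level [es_mat()].
#' @export
riger_ks <- function(shes, index, n_norm_perm = 0L, rng_seed = 1L) {
  stopifnot(inherits(shes, "es_mat"))
  if (es_level(shes) != "shrna") stop("riger_ks expects shRNA-level scores", call. = FALSE)
  m <- es_scores(shes)
  if (nrow(m) < 2) stop("riger_ks needs at least 2 shRNAs", call. = FALSE)
  idx <- index[index$shrna_id %in% rownames(m), , drop = FALSE]
  if (nrow(idx) == 0) stop("no indexed shRNA present in the score matrix", call. = FALSE)
  genes <- unique(idx$target_gene)
  members <- split(idx$shrna_id, idx$target_gene)[genes]
  sizes <- lengths(members)
  if (any(sizes > nrow(m))) stop("gene set larger than the ranked list", call. = FALSE)
  N <- nrow(m)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  row_pos <- stats::setNames(seq_len(N), rownames(m))
  for (cl in seq_len(ncol(m))) {
    # ascending score, stable id tie-break; missing scores sink to the end
    ord <- order(m[, cl], rownames(m), na.last = TRUE)
    pos_of <- integer(N)
    pos_of[ord] <- seq_len(N)
    for (g in seq_along(genes)) {
      hits <- sort(pos_of[row_pos[members[[g]]]])
      out[g, cl] <- ks_running_sum(hits, N)
    }
  }
  if (n_norm_perm > 0) {
    set.seed(rng_seed)
    norm_for_size <- vapply(sort(unique(sizes)), function(sz) {
      mean(vapply(seq_len(n_norm_perm), function(i) {
        abs(ks_running_sum(sort(sample.int(N, sz)), N))
      }, numeric(1)))
    }, numeric(1))
    names(norm_for_size) <- sort(unique(sizes))
    out <- out / norm_for_size[as.character(sizes)]
  }
  es_from_matrix(out, "gene")
}

# signed KS running-sum extreme for hit positions in 1..N
ks_running_sum <- function(hits, N) {
  m <- length(hits)
  if (m == 0) return(NA_real_)
  if (m == N) return(1)
  j <- seq_len(m)
  at_hit <- j / m - (hits - j) / (N - m)        # running sum right after each hit
  before_hit <- (j - 1) / m - (hits - j) / (N - m)  # right before each hit
  hi <- max(at_hit)
  lo <- min(c(before_hit, 0))
  if (abs(hi) >= abs(lo)) hi else lo
}
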