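#' Read an essentiality score matrix
#'
#' Reads a wide TSV (first column entity ids, header row of cell-line
#' ids) or a GCT 1.2 file (two preamble lines, `Name`/`Description`
#' columns) into an [es_mat()]. Achilles-style matrices ship as GCT,
#' so that dialect is supported behind a flag; plain TSV is the primary
#' format.
#'
#' @param path File to read.
#' @param level Level tag for the entities (see [es_mat()]).
#' @param format `"tsv"` (default) or `"gct"`.
#' @param missing Token that encodes a missing score (default `"NA"`).
#' @return An [es_mat()].
#' @export
read_es_matrix <- function(path, level = c("shrna", "seed", "heptamer", "gene"),
                           format = c("tsv", "gct"), missing = "NA") {
  level <- match.arg(level)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  skip <- 0L
  if (format == "gct") {
    head2 <- readLines(path, n = 2L)
    if (length(head2) < 2L || !startsWith(head2[1], "#1.2")) {
      stop("not a GCT 1.2 file (missing '#1.2' preamble): ", path, call. = FALSE)
    }
    skip <- 2L
  }
  raw <- utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (format == "gct") {
    # drop the Description column; Name is the entity id
    if (!all(c("Name", "Description") %in% names(raw)[1:2])) {
      stop("GCT file lacks Name/Description columns: ", path, call. = FALSE)
    }
    raw <- raw[, -2, drop = FALSE]
  }
  names(raw)[1] <- "entity"
  cells <- names(raw)[-1]
  dup_cells <- unique(cells[duplicated(cells)])
  if (length(dup_cells) > 0) {
    stop("duplicate cell-line header(s): ", paste(dup_cells, collapse = ", "),
         call. = FALSE)
  }
  for (j in seq_along(cells)) {
    v <- raw[[j + 1L]]
    is_na <- v == missing | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is_na & is.na(num))
    if (length(bad) > 0) {
      stop("non-numeric value '", v[bad[1]], "' at row ", bad[1],
           ", column '", cells[j], "' of ", path, call. = FALSE)
    }
    num[is_na] <- NA_real_
    raw[[j + 1L]] <- num
  }
  es_mat(raw, level)
}

#' Write an essentiality score matrix
#'
#' Inverse of [read_es_matrix()]: tab-separated, header row of cell-line
#' ids, one row per entity, missing scores written as `missing`.
#'
#' @param x An [es_mat()].
#' @param path Output file.
#' @param missing Token used for missing scores.
#' @param digits Significant digits for scores (default 6).
#' @return `path`, invisibly.
#' @export
write_es_matrix <- function(x, path, missing = "NA", digits = 6) {
  stopifnot(inherits(x, "es_mat"))
  out <- as.data.frame(x)
  for (j in seq_along(out)[-1]) {
    v <- signif(out[[j]], digits)
    s <- as.character(v)
    s[is.na(v)] <- missing
    out[[j]] <- s
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read an shRNA annotation table
#'
#' Expects a TSV with columns `shrna_id`, `guide_sequence`,
#' `target_gene`. Guide sequences are uppercased and U is normalized to
#' T so RNA- and DNA-alphabet libraries are interchangeable.
#'
#' @param path File to read.
#' @return Tibble with columns `shrna_id`, `guide_sequence`,
#'   `target_gene`.
#' @export
read_shrna_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE, quote = "")
  need <- c("shrna_id", "guide_sequence", "target_gene")
  if (!all(need %in% names(tbl))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_annotations(tibble::as_tibble(tbl[need]))
}

#' Validate an shRNA annotation table
#'
#' @param tbl Data frame with columns `shrna_id`, `guide_sequence`,
#'   `target_gene`.
#' @return The validated tibble (sequences uppercased, U normalized to T).
#' @export
validate_annotations <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("shrna_id", "guide_sequence", "target_gene")
  stopifnot(all(need %in% names(tbl)))
  dup <- unique(tbl$shrna_id[duplicated(tbl$shrna_id)])
  if (length(dup) > 0) {
    stop("duplicate shrna_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- chartr("u", "U", toupper(tbl$guide_sequence))
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty guide_sequence for shrna_id ",
         tbl$shrna_id[!nzchar(seqs)][1], call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character '", substr(seqs[i], bad[i], bad[i]),
         "' at position ", bad[i], " of guide_sequence for shrna_id ",
         tbl$shrna_id[i], call. = FALSE)
  }
  tbl$guide_sequence <- seqs
  tbl
}

#' Read a binary genotype panel
#'
#' Accepts either a long-format TSV (`cell_line`, `gene`, `status`) or a
#' wide binary matrix (first column `cell_line`, one 0/1 column per
#' driver gene); the format is auto-detected from the header. Absent
#' (cell line, gene) pairs in long format default to wild type (0).
#'
#' @param path File to read.
#' @return Wide tibble: `cell_line` plus one integer 0/1 column per gene.
#' @export
read_genotype_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "")
  if (all(c("cell_line", "gene", "status") %in% names(tbl))) {
    tbl$status <- as.numeric(tbl$status)
    if (any(!tbl$status %in% c(0, 1))) {
      stop("genotype status outside {0,1} at row ",
           which(!tbl$status %in% c(0, 1))[1], call. = FALSE)
    }
    key <- paste(tbl$cell_line, tbl$gene, sep = "\r")
    for (k in unique(key[duplicated(key)])) {
      st <- unique(tbl$status[key == k])
      if (length(st) > 1) {
        parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
        stop("conflicting duplicate genotype for cell line '", parts[1],
             "', gene '", parts[2], "'", call. = FALSE)
      }
    }
    tbl <- tbl[!duplicated(key), , drop = FALSE]
    wide <- tidyr::pivot_wider(tibble::as_tibble(tbl),
                               id_cols = "cell_line", names_from = "gene",
                               values_from = "status", values_fill = 0)
    return(validate_genotype_panel(wide))
  }
  names(tbl)[1] <- "cell_line"
  validate_genotype_panel(tibble::as_tibble(tbl))
}

#' Validate a wide genotype panel
#'
#' @param panel Data frame: `cell_line` column plus 0/1 gene columns.
#' @return Validated tibble with integer 0/1 entries.
#' @export
validate_genotype_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  stopifnot(identical(names(panel)[1], "cell_line"))
  panel$cell_line <- as.character(panel$cell_line)
  dup <- unique(panel$cell_line[duplicated(panel$cell_line)])
  if (length(dup) > 0) {
    stop("duplicate cell line(s) in genotype panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (g in names(panel)[-1]) {
    v <- as.numeric(panel[[g]])
    if (any(is.na(v)) || any(!v %in% c(0, 1))) {
      stop("genotype status outside {0,1} for gene '", g, "'", call. = FALSE)
    }
    panel[[g]] <- as.integer(v)
  }
  panel
}

#' Read replicate-level scores
#'
#' Long TSV with columns `cell_line`, `replicate`, `shrna_id`, `score`,
#' as used by [replicate_qc()].
#'
#' @param path File to read.
#' @return Long tibble.
#' @export
read_replicates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                             check.names = FALSE, quote = ""))
  need <- c("cell_line", "replicate", "shrna_id", "score")
  if (!all(need %in% names(tbl))) {
    stop("replicate file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl$score <- as.numeric(tbl$score)
  tbl[need]
}

#' Read a seed-property table
#'
#' TargetScan-style heptamer table: columns `seed` (7-mer), `sps`
#' (seed pairing stability, kcal/mol-like; more negative = stronger
#' pairing) and `ta` (target-site abundance, log10-like scale).
#'
#' @param path File to read.
#' @return Tibble with columns `seed`, `sps`, `ta`.
#' @export
read_seed_properties <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                             check.names = FALSE, quote = ""))
  need <- c("seed", "sps", "ta")
  if (!all(need %in% names(tbl))) {
    stop("seed property file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl$seed <- toupper(as.character(tbl$seed))
  if (nrow(tbl) > 0 && !all(grepl("^[ACGT]{7}$", tbl$seed))) {
    stop("seed ids must be 7-mers over {A,C,G,T}", call. = FALSE)
  }
  tbl$sps <- as.numeric(tbl$sps)
  tbl$ta <- as.numeric(tbl$ta)
  tbl[need]
}

#' Read a matched cell-line pair table
#'
#' Two-column TSV (`cell_line_a`, `cell_line_b`) naming which cell line
#' of screen A corresponds to which of screen B. Matches are always
#' explicit, never inferred from name similarity.
#'
#' @param path File to read.
#' @return Tibble with columns `cell_line_a`, `cell_line_b`.
#' @export
read_matched_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                             colClasses = "character",
                                             check.names = FALSE, quote = ""))
  need <- c("cell_line_a", "cell_line_b")
  if (!all(need %in% names(tbl))) {
    stop("matched-pair file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tbl[need]
}
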