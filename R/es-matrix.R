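#' Essentiality score tables
#'
#' The common currency of the package is a wide tibble of essentiality
#' scores: one row per entity (shRNA clone, seed 7-mer, control heptamer,
#' or gene), a first column `entity`, and one numeric column per cell
#' line. More negative scores mean more essential. The table carries a
#' `level` attribute, one of `"shrna"`, `"seed"`, `"heptamer"` or
#' `"gene"`, which downstream functions use to check that they are fed
#' scores at the level they expect.
#'
#' @param x A data frame whose first column is `entity` (character,
#'   no duplicates) and whose remaining columns are numeric cell-line
#'   scores. `NA` encodes missing measurements; missing values propagate,
#'   they are never imputed.
#' @param level Level tag for the entities.
#' @return A tibble of class `es_mat` with a `level` attribute.
#' @examples
#' es_mat(data.frame(entity = c("s1", "s2"), c1 = c(-1, 0.2)), "shrna")
#' @export
es_mat <- function(x, level = c("shrna", "seed", "heptamer", "gene")) {
  level <- match.arg(level)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) {
    stop("an essentiality table needs an `entity` column plus at least one cell line", call. = FALSE)
  }
  names(x)[1] <- "entity"
  x$entity <- as.character(x$entity)
  dup <- x$entity[duplicated(x$entity)]
  if (length(dup) > 0) {
    stop("duplicate entity id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  cells <- names(x)[-1]
  dup_cells <- cells[duplicated(cells)]
  if (length(dup_cells) > 0) {
    stop("duplicate cell-line id(s): ", paste(unique(dup_cells), collapse = ", "), call. = FALSE)
  }
  for (cl in cells) {
    if (!is.numeric(x[[cl]])) {
      stop("cell-line column '", cl, "' is not numeric", call. = FALSE)
    }
  }
  if (level %in% c("seed", "heptamer") && nrow(x) > 0 &&
      !all(grepl("^[ACGT]{7}$", x$entity))) {
    bad <- x$entity[!grepl("^[ACGT]{7}$", x$entity)][1]
    stop("level '", level, "' requires 7-mer entity ids over {A,C,G,T}; found '", bad, "'",
         call. = FALSE)
  }
  structure(x, level = level, class = c("es_mat", class(x)))
}

#' @export
print.es_mat <- function(x, ...) {
  cat("<essentiality scores: level=", es_level(x), ", ",
      nrow(x), " entities x ", ncol(x) - 1L, " cell lines>\n", sep = "")
  NextMethod()
}

# keep the class/attribute through dplyr-style subsetting of columns
#' @export
`[.es_mat` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out)[1], "entity")) {
    attr(out, "level") <- attr(x, "level")
    class(out) <- c("es_mat", setdiff(class(out), "es_mat"))
  }
  out
}

#' @rdname es_mat
#' @export
es_level <- function(x) {
  lv <- attr(x, "level")
  if (is.null(lv)) stop("not an essentiality table (no level attribute)", call. = FALSE)
  lv
}

#' @rdname es_mat
#' @export
es_cell_lines <- function(x) names(x)[-1]

#' Convert an essentiality table to a base matrix
#'
#' @param x An `es_mat`.
#' @return Numeric matrix, rownames = entity ids, colnames = cell lines.
#' @export
es_scores <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$entity
  storage.mode(m) <- "double"
  m
}

#' @rdname es_mat
#' @param m Numeric matrix with entity rownames and cell-line colnames.
#' @export
es_from_matrix <- function(m, level) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  es_mat(tibble::tibble(entity = rownames(m), !!!as.data.frame(m, optional = TRUE)), level)
}
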