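#' Gene presence/absence matrices
#'
#' A `pav_matrix` is a genes x accessions integer matrix with entries in
#' `{0, 1}` (1 = present, 0 = absent), row names holding gene identifiers and
#' column names holding accession identifiers. It is the central container of
#' the map-to-pan pipeline: [build_pav_matrix()] produces one from coverage
#' evidence, and classification, rarefaction and population-structure
#' functions consume it.
#'
#' @param x For `pav_matrix()`, a numeric/integer/logical matrix. For
#'   `as_pav_matrix()`, a matrix or a data frame; a data frame may be *long*
#'   (columns `gene_id`, `accession_id`, `present`) or *wide* (first column
#'   gene ids, remaining columns one per accession).
#' @param gene_ids,accession_ids Optional row/column labels used when `x`
#'   carries no dimnames.
#'
#' @return An integer matrix of class `pav_matrix`.
#' @examples
#' m <- pav_matrix(matrix(c(1, 1, 0, 1), 2, 2),
#'                 gene_ids = c("g1", "g2"),
#'                 accession_ids = c("a1", "a2"))
#' tidy(m)
#' @export
pav_matrix <- function(x, gene_ids = NULL, accession_ids = NULL) {
  if (!is.matrix(x)) abort("`x` must be a matrix.")
  m <- x
  storage.mode(m) <- "integer"
  if (!is.null(gene_ids)) rownames(m) <- gene_ids
  if (!is.null(accession_ids)) colnames(m) <- accession_ids
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("acc", seq_len(ncol(m)))
  validate_pav_matrix(m)
  structure(m, class = c("pav_matrix", "matrix", "array"))
}

validate_pav_matrix <- function(m) {
  if (anyNA(m) || !all(m == 0L | m == 1L)) {
    bad <- which(is.na(m) | (m != 0L & m != 1L), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-binary cell at (gene '%s', accession '%s').",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (anyDuplicated(rownames(m))) abort("Duplicate gene ids.")
  if (anyDuplicated(colnames(m))) abort("Duplicate accession ids.")
  invisible(m)
}

#' @rdname pav_matrix
#' @export
as_pav_matrix <- function(x, ...) UseMethod("as_pav_matrix")

#' @export
as_pav_matrix.pav_matrix <- function(x, ...) x

#' @export
as_pav_matrix.matrix <- function(x, ...) pav_matrix(x, ...)

#' @export
as_pav_matrix.data.frame <- function(x, ...) {
  if (all(c("gene_id", "accession_id", "present") %in% names(x))) {
    wide <- tidyr::pivot_wider(x, id_cols = "gene_id",
                               names_from = "accession_id",
                               values_from = "present")
  } else {
    wide <- x
    names(wide)[1] <- "gene_id"
  }
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[1]])
  pav_matrix(m)
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("<pav_matrix> %d genes x %d accessions (%.1f%% present)\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' @describeIn pav_matrix long-format tibble with one row per
#'   gene-by-accession cell.
#' @param ... Unused.
#' @export
tidy.pav_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    accession_id = rep(colnames(x), each = nrow(x)),
    present = as.integer(x)
  )
}

#' @describeIn pav_matrix one-row tibble of matrix-level summaries.
#' @export
glance.pav_matrix <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_accessions = ncol(x),
    frac_present = mean(x),
    n_fixed_present = sum(rowSums(x) == ncol(x)),
    n_all_absent = sum(rowSums(x) == 0L)
  )
}

#' Read and write PAV matrices as tab-separated text
#'
#' The on-disk dialect mirrors deposited pan-genome PAV tables: a header row
#' of accession ids, a first column of gene ids, and cells that are 0
#' (absent) or 1 (present). Some deposits store the transpose (accessions as
#' rows); `transpose = TRUE` reads such files into the canonical genes x
#' accessions orientation.
#'
#' @param path File path.
#' @param transpose If `TRUE`, the file rows are accessions and columns are
#'   genes; the matrix is transposed after reading (or before writing).
#' @param matrix A [pav_matrix()] (or coercible object) to write.
#' @return `read_pav_matrix()` returns a [pav_matrix()]; `write_pav_matrix()`
#'   returns `path` invisibly. Writing then reading reproduces the matrix
#'   exactly.
#' @export
read_pav_matrix <- function(path, transpose = FALSE) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  cells <- as.matrix(tb[, -1, drop = FALSE])
  rownames(cells) <- as.character(tb[[1]])
  ok <- cells == "0" | cells == "1"
  if (anyNA(ok) || !all(ok)) {
    bad <- which(is.na(ok) | !ok, arr.ind = TRUE)[1, ]
    abort(sprintf("Non-binary cell at row '%s', column '%s' in %s.",
                  rownames(cells)[bad[1]], colnames(cells)[bad[2]], path))
  }
  m <- matrix(as.integer(cells), nrow = nrow(cells), dimnames = dimnames(cells))
  if (transpose) m <- t(m)
  pav_matrix(m)
}

#' @rdname read_pav_matrix
#' @export
write_pav_matrix <- function(matrix, path, transpose = FALSE) {
  m <- as_pav_matrix(matrix)
  if (transpose) m <- t(unclass(m))
  tb <- tibble::as_tibble(as.data.frame(unclass(m)), .name_repair = "minimal")
  tb <- dplyr::bind_cols(tibble(gene_id = rownames(m)), tb)
  if (transpose) names(tb)[1] <- "accession_id"
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
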