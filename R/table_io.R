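#' Read a sample-by-feature abundance table
#'
#' Reads a tab-separated abundance table (one header row, one leading id
#' column, numeric body) into the tidy community-table format used
#' throughout the package: a tibble whose first column is `sample_id` and
#' whose remaining columns are non-negative numeric feature abundances
#' (counts or relative abundances of e.g. KEGG orthologs, GO terms or
#' taxa).
#'
#' @param path Path to a tab-separated text file.
#' @param orientation Either `"samples_in_rows"` (default; rows are
#'   samples, columns are features) or `"features_in_rows"` (the file is
#'   transposed on read so the returned table is always samples x
#'   features).
#' @return A tibble with a `sample_id` character column followed by one
#'   numeric column per feature.  The attribute `is_relative` is `TRUE`
#'   when every row sums to 1 (within 1e-9).
#' @seealso [to_relative_abundance()], [write_community_table()]
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "features_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("abundance table needs one id column and at least one value column")
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids in column 1: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort("duplicate ids in the header row")
  }
  body <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                 dimnames = dimnames(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric cell '%s' at row %d (id '%s'), column '%s'",
                  body[bad[1, 1], bad[1, 2]], bad[1, 1], ids[bad[1, 1]],
                  colnames(body)[bad[1, 2]]))
  }
  if (anyNA(num)) abort("missing values are not allowed in the table body")
  rownames(num) <- ids
  if (orientation == "features_in_rows") num <- t(num)
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative abundance at sample '%s', feature '%s'",
                  rownames(num)[bad[1]], colnames(num)[bad[2]]))
  }
  as_community_table(num)
}

#' Convert a samples-by-features matrix to a community tibble
#'
#' @param mat Numeric matrix with sample ids as rownames and feature ids
#'   as colnames.
#' @return A community-table tibble (see [read_abundance_table()]).
#' @export
as_community_table <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (any(mat < 0)) abort("abundances must be non-negative")
  if (anyDuplicated(rownames(mat))) abort("duplicate sample ids")
  if (anyDuplicated(colnames(mat))) abort("duplicate feature ids")
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(mat)), out)
  rel <- nrow(mat) > 0 && all(abs(rowSums(mat) - 1) <= 1e-9)
  attr(out, "is_relative") <- rel
  out
}

#' Extract the numeric samples-by-features matrix from a community table
#'
#' @param table A community-table tibble.
#' @return Numeric matrix with sample ids as rownames.
#' @export
community_matrix <- function(table) {
  stopifnot(is.data.frame(table), "sample_id" %in% names(table))
  m <- as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
  if (!is.numeric(m)) abort("feature columns must be numeric")
  rownames(m) <- as.character(table$sample_id)
  m
}

#' Convert abundances to relative abundances
#'
#' Divides each sample row by its row sum, so rows are compositions
#' summing to 1.  Idempotent.  Features observed in no sample are kept.
#'
#' @param table A community-table tibble.
#' @return The same tibble with each row normalised; attribute
#'   `is_relative` set to `TRUE`.
#' @export
to_relative_abundance <- function(table) {
  m <- community_matrix(table)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(paste0("sample(s) with all-zero abundances: ",
                 paste(rownames(m)[rs <= 0], collapse = ", ")))
  }
  as_community_table(m / rs)
}

#' Is a community table in relative-abundance form?
#'
#' @param table A community-table tibble.
#' @return `TRUE` when every row sums to 1 within 1e-9.
#' @export
is_relative_abundance <- function(table) {
  m <- community_matrix(table)
  nrow(m) > 0 && all(abs(rowSums(m) - 1) <= 1e-9)
}

#' Read a sample metadata table
#'
#' Tab-separated text with a header that must contain a `sample_id`
#' column; all other columns are carried along (read as text, then
#' converted to numeric where the whole column parses as numbers, so
#' `generation` and `timepoint` behave as integers).
#'
#' @param path Path to a tab-separated text file.
#' @return A tibble keyed by `sample_id` (unique).
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"sample_id" %in% names(md)) abort("metadata must contain a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) {
    abort(paste0("duplicated sample_id in metadata: ",
                 paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", ")))
  }
  md %>% dplyr::mutate(dplyr::across(
    -"sample_id",
    function(x) {
      num <- suppressWarnings(as.numeric(x))
      if (all(is.na(num) == is.na(x))) num else x
    }
  ))
}

#' Write a community table or metadata tibble as TSV
#'
#' Plain tab-separated output with a `.` decimal mark; round-trips through
#' [read_abundance_table()] / [read_metadata()].
#'
#' @param table A community-table or metadata tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
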