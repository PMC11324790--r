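#' Write a labelled matrix as TSV
#'
#' Tab-separated with a header row and a first column of region ids — the
#' interchange format for connectomes, adjacencies, harmonic bases, and time
#' series.
#'
#' @param M Matrix with rownames.
#' @param path Output file.
#' @param id_col Name of the first (id) column.
#' @export
write_matrix_tsv <- function(M, path, id_col = "region_id") {
  df <- data.frame(id = rownames(M) %||% seq_len(nrow(M)),
                   as.data.frame(unclass(M), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a labelled matrix from TSV
#' @param path TSV written by [write_matrix_tsv()].
#' @return Numeric matrix with the first column as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  M <- as.matrix(df[, -1])
  rownames(M) <- as.character(df[[1]])
  M
}

#' Read a connectome from TSV
#' @param path Matrix TSV file.
#' @param normalized Whether the stored matrix has unit Frobenius norm.
#' @return A `connectome`.
#' @export
read_connectome_tsv <- function(path, normalized = FALSE) {
  M <- read_matrix_tsv(path)
  colnames(M) <- rownames(M)
  connectome(M, rownames(M), normalized = normalized)
}

#' Write a region table as TSV
#' @param region_table Tibble from [generate_region_table()].
#' @param path Output file.
#' @export
write_region_table <- function(region_table, path) {
  readr::write_tsv(region_table, path, progress = FALSE)
  invisible(path)
}

#' Read a region table from TSV
#' @param path TSV file.
#' @return Tibble.
#' @export
read_region_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    region_id = readr::col_character(),
                    hemisphere = readr::col_character()))
}

#' Write a JSON sidecar
#' @param x List of metadata (config echo, seed, conventions).
#' @param path Output `.json` file.
#' @export
write_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a harmonic basis (vectors + eigenvalues) with sidecar
#' @param basis A `harmonic_basis`.
#' @param prefix Output path prefix; writes `<prefix>_vectors.tsv`,
#'   `<prefix>_eigenvalues.tsv`, `<prefix>.json`.
#' @export
write_harmonics <- function(basis, prefix) {
  V <- basis$vectors
  colnames(V) <- paste0("h", seq_len(ncol(V)))
  write_matrix_tsv(V, paste0(prefix, "_vectors.tsv"))
  readr::write_tsv(tidy(basis), paste0(prefix, "_eigenvalues.tsv"),
                   progress = FALSE)
  write_sidecar(list(source_id = basis$source_id,
                     n_harmonics = length(basis$eigenvalues),
                     sign_convention = "largest-magnitude entry positive, ties to lowest index",
                     tie_tolerance = 1e-10),
                paste0(prefix, ".json"))
  invisible(prefix)
}
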