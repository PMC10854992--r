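# Reading and writing the package's plain-text interchange formats.
# Matrices travel as TSV with genes as rows and a leading "gene" column.

#' Read a gene-by-sample matrix from TSV/CSV
#'
#' The delimiter is sniffed from the header line (tab preferred, then comma)
#' unless given. The first column must hold gene identifiers.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` (default) sniffs tab vs comma.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a gene column plus >= 1 sample column",
                          call. = FALSE)
  genes <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m numeric matrix with gene rownames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker list (one gene symbol per line)
#'
#' Blank lines and lines starting with `#` are skipped; symbols are
#' canonicalized and de-duplicated, keeping first occurrence order.
#'
#' @param path file path.
#' @param provenance free-text note stored with the list.
#' @return character vector of unique symbols, with a `provenance` attribute.
#' @export
read_marker_list <- function(path, provenance = path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  syms <- unique(canonicalize_symbols(lines))
  attr(syms, "provenance") <- provenance
  syms
}

#' Write a ground-truth module assignment as two-column TSV
#'
#' @param truth `GroundTruth` data frame (columns `gene`, `module`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(truth, path) {
  utils::write.table(truth[, c("gene", "module")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed-precision formatting for deterministic table exports
format_num <- function(x, digits = 6L) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}
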