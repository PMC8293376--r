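#' Read a long-format peptide intensity table
#'
#' The canonical on-disk dialect is a TSV with header
#' `sample_id  protein_group  peptide_sequence  proteotypic  intensity`
#' (UTF-8, '.' decimal separator), the information content of a peptide-level
#' DIA software export. The proteotypicity flag is parsed case-insensitively;
#' a missing observation is an empty intensity field (or `NA`), never 0.
#'
#' @param path path to the TSV file.
#' @param labels optional path to a two-column TSV (`sample_id  fiber_type`)
#'   with the fiber-type label of every sample.
#' @return A [peptide_matrix] whose cells are `NA` for every
#'   (sample, peptide) pair absent from the file.
#' @export
read_long_table <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = c("", "NA"), quote = "",
                          fileEncoding = "UTF-8")
  required <- c("sample_id", "protein_group", "peptide_sequence",
                "proteotypic", "intensity")
  if (!all(required %in% names(df)))
    stop("header must contain columns: ", paste(required, collapse = ", "))

  line_no <- seq_len(nrow(df)) + 1L  # header is line 1

  key <- paste(df$sample_id, df$peptide_sequence, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (sample, peptide) pair at line %d: %s / %s",
                 line_no[dup[1]], df$sample_id[dup[1]],
                 df$peptide_sequence[dup[1]]))

  flag_chr <- toupper(trimws(df$proteotypic))
  bad_flag <- which(!is.na(flag_chr) & !flag_chr %in% c("TRUE", "FALSE"))
  if (length(bad_flag))
    stop(sprintf("unknown proteotypicity flag '%s' at line %d",
                 df$proteotypic[bad_flag[1]], line_no[bad_flag[1]]))
  flag <- flag_chr == "TRUE"

  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad_num <- which(!is.na(df$intensity) & is.na(intensity))
  if (length(bad_num))
    stop(sprintf("non-numeric intensity '%s' at line %d",
                 df$intensity[bad_num[1]], line_no[bad_num[1]]))
  neg <- which(!is.na(intensity) & intensity < 0)
  if (length(neg))
    stop(sprintf("negative intensity at line %d", line_no[neg[1]]))

  # one protein group per peptide
  map <- unique(df[, c("peptide_sequence", "protein_group")])
  multi <- map$peptide_sequence[duplicated(map$peptide_sequence)]
  if (length(multi))
    stop("peptide mapped to more than one protein group: ",
         paste(utils::head(unique(multi), 5), collapse = ", "))

  peptides <- unique(df$peptide_sequence)
  samples <- unique(df$sample_id)
  mat <- matrix(NA_real_, length(peptides), length(samples),
                dimnames = list(peptides, samples))
  mat[cbind(match(df$peptide_sequence, peptides),
            match(df$sample_id, samples))] <- intensity

  p2p <- stats::setNames(map$protein_group, map$peptide_sequence)
  proteo <- tapply(flag, df$peptide_sequence, function(f) {
    f <- f[!is.na(f)]
    if (!length(f)) NA else all(f)
  })[peptides]
  proteo <- stats::setNames(as.logical(proteo), peptides)

  sample_labels <- NULL
  if (!is.null(labels)) sample_labels <- read_sample_labels(labels)

  peptide_matrix(mat, p2p, proteo, sample_labels)
}

#' Write a peptide matrix as a long-format TSV
#'
#' Missing cells are not written, so a write/read round trip is lossless.
#' Unknown proteotypicity flags are written as `FALSE`.
#'
#' @param matrix a [peptide_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(matrix, path) {
  ints <- matrix$intensities
  idx <- which(!is.na(ints), arr.ind = TRUE)
  pep <- rownames(ints)[idx[, 1]]
  flag <- matrix$proteotypic[pep]
  flag[is.na(flag)] <- FALSE
  df <- data.frame(
    sample_id = colnames(ints)[idx[, 2]],
    protein_group = unname(matrix$peptide_to_protein[pep]),
    peptide_sequence = pep,
    proteotypic = ifelse(flag, "TRUE", "FALSE"),
    intensity = format(ints[idx], digits = 15, scientific = FALSE,
                       trim = TRUE),
    stringsAsFactors = FALSE)
  df <- df[order(df$sample_id, df$peptide_sequence), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample-to-fiber-type label table
#'
#' @param path two-column TSV `sample_id  fiber_type` with header.
#' @return named character vector, sample -> fiber type.
#' @export
read_sample_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("label table needs two columns (sample, fiber type)")
  if (anyDuplicated(df[[1]]))
    stop("duplicate sample in label table: ",
         df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Read a protein-to-category annotation map
#'
#' @param path two-column TSV `protein_group  category` with header.
#' @return named character vector, protein -> category.
#' @export
read_annotation_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("annotation map needs two columns (protein, category)")
  if (anyDuplicated(df[[1]]))
    stop("protein mapped to more than one category: ",
         df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Write a protein x sample matrix as TSV
#'
#' Missing cells are written as empty fields; the first column holds the row
#' (protein) identifiers under the header `protein_group`.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(protein_group = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a protein x sample matrix written by [write_matrix_tsv]
#'
#' @param path TSV path.
#' @return numeric matrix with protein row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = c("", "NA"), check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}
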