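#' Peptide-by-sample intensity matrix
#'
#' The central container of the package: a peptide x sample matrix of raw or
#' normalized linear-scale intensities together with the peptide-to-protein
#' mapping, per-peptide proteotypicity flags and (optionally) the fiber-type
#' label of every sample. Missing observations are `NA`, never 0.
#'
#' @param intensities numeric matrix, peptides in rows and samples in columns,
#'   with row and column names. Values must be non-negative where present;
#'   missing cells are `NA`.
#' @param peptide_to_protein named character vector mapping every peptide
#'   (names) to exactly one protein-group accession.
#' @param proteotypic named logical vector; `TRUE` marks peptides unique to
#'   one protein/isoform, usable as its quantitative surrogate.
#' @param sample_labels optional named character or factor vector giving the
#'   fiber type (e.g. `"I"`, `"IIa"`, `"IIb"`, `"IIx"`) of each sample.
#'
#' @return An object of class `peptide_matrix`: a list with elements
#'   `intensities`, `peptide_to_protein`, `proteotypic`, `sample_labels`.
#' @export
peptide_matrix <- function(intensities, peptide_to_protein,
                           proteotypic = NULL, sample_labels = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("'intensities' must have peptide row names and sample column names")
  if (anyDuplicated(colnames(intensities)))
    stop("sample identifiers must be unique")
  if (anyDuplicated(rownames(intensities)))
    stop("peptide identifiers must be unique")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be >= 0 where present")

  peps <- rownames(intensities)
  if (is.null(names(peptide_to_protein)))
    stop("'peptide_to_protein' must be named by peptide")
  missing_map <- setdiff(peps, names(peptide_to_protein))
  if (length(missing_map))
    stop("peptides without a protein mapping: ",
         paste(utils::head(missing_map, 5), collapse = ", "))
  peptide_to_protein <- peptide_to_protein[peps]

  if (is.null(proteotypic)) {
    proteotypic <- stats::setNames(rep(NA, length(peps)), peps)
  } else {
    if (is.null(names(proteotypic)))
      stop("'proteotypic' must be named by peptide")
    proteotypic <- as.logical(proteotypic[peps])
    names(proteotypic) <- peps
  }

  if (!is.null(sample_labels)) {
    if (is.null(names(sample_labels)))
      stop("'sample_labels' must be named by sample")
    missing_lab <- setdiff(colnames(intensities), names(sample_labels))
    if (length(missing_lab))
      stop("samples without a fiber-type label: ",
           paste(utils::head(missing_lab, 5), collapse = ", "))
    sample_labels <- as.character(sample_labels[colnames(intensities)])
    names(sample_labels) <- colnames(intensities)
  }

  structure(
    list(intensities = intensities,
         peptide_to_protein = peptide_to_protein,
         proteotypic = proteotypic,
         sample_labels = sample_labels),
    class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  ints <- x$intensities
  cat(sprintf("peptide_matrix: %d peptides x %d samples\n",
              nrow(ints), ncol(ints)))
  cat(sprintf("  proteins: %d; proteotypic peptides: %d\n",
              length(unique(x$peptide_to_protein)),
              sum(x$proteotypic, na.rm = TRUE)))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * mean(is.na(ints))))
  if (!is.null(x$sample_labels)) {
    tab <- table(x$sample_labels)
    cat("  fiber types:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.peptide_matrix <- function(x) dim(x$intensities)

# internal: protein accession per row, in row order
.protein_of <- function(matrix) unname(matrix$peptide_to_protein[rownames(matrix$intensities)])
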