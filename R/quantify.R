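#' Cyclic LOESS normalization of peptide intensities
#'
#' Removes intensity-dependent systematic differences between samples by
#' locally weighted regression on the log2 scale. Each sample is normalized
#' against the reference profile (per-peptide row mean of log2 intensities
#' over all samples): the lowess fit of the difference M = x - ref against
#' the average A = (x + ref)/2 is subtracted, and the cycle is repeated.
#' Missing cells take no part in the fits and are returned untouched.
#'
#' @param matrix a [peptide_matrix] (linear-scale intensities) or a plain
#'   numeric matrix of linear intensities.
#' @param span lowess smoother span (default 0.7).
#' @param iterations normalization cycles (default 3).
#' @return object of the same type with normalized linear-scale intensities.
#' @export
loess_normalize <- function(matrix, span = 0.7, iterations = 3) {
  is_pm <- inherits(matrix, "peptide_matrix")
  x <- if (is_pm) matrix$intensities else matrix
  if (ncol(x) < 2) stop("need >= 2 samples to normalize")
  lx <- log2(x)
  lx[!is.finite(lx)] <- NA  # zeros become missing

  ref <- rowMeans(lx, na.rm = TRUE)
  for (s in colnames(lx)) {
    shared <- sum(!is.na(lx[, s]) & is.finite(ref))
    if (shared < 10)
      stop("sample '", s, "' shares fewer than 10 non-missing peptides ",
           "with the reference")
  }

  for (it in seq_len(iterations)) {
    ref <- rowMeans(lx, na.rm = TRUE)
    for (s in seq_len(ncol(lx))) {
      ok <- !is.na(lx[, s]) & is.finite(ref)
      a <- ref[ok]
      m <- lx[ok, s] - a
      o <- order(a)
      lo <- stats::lowess(a, m, f = span, iter = 3)
      corr <- numeric(sum(ok))
      corr[o] <- lo$y
      lx[ok, s] <- lx[ok, s] - corr
    }
  }
  out <- 2^lx
  if (is_pm)
    peptide_matrix(out, matrix$peptide_to_protein, matrix$proteotypic,
                   matrix$sample_labels)
  else out
}

#' Count theoretically observable tryptic peptides
#'
#' Fully tryptic in-silico digestion: cleavage C-terminal of K or R, but not
#' when the next residue is P, with zero missed cleavages. Counts fragments
#' whose length falls in `[min_len, max_len]` — the denominator of the iBAQ
#' value.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param min_len minimum peptide length (default 6).
#' @param max_len maximum peptide length (default 30).
#' @return integer count of observable peptides.
#' @export
theoretical_peptide_count <- function(sequence, min_len = 6, max_len = 30) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    warning("empty sequence: theoretical peptide count is 0")
    return(0L)
  }
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    stop("illegal character in sequence: ",
         paste(unique(chars[!chars %in%
             strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]), collapse = ", "))
  n <- length(chars)
  cut_after <- chars %in% c("K", "R") &
    c(chars[-1], "") != "P"
  cut_after[n] <- TRUE
  lens <- diff(c(0L, which(cut_after)))
  sum(lens >= min_len & lens <= max_len)
}

#' Theoretical peptide counts from a protein FASTA
#'
#' Reads a standard multi-record amino-acid FASTA (accession taken as the
#' first whitespace-delimited token of each header) and applies
#' [theoretical_peptide_count] to every record.
#'
#' @param path FASTA file.
#' @param min_len,max_len observable-peptide length window (defaults 6-30).
#' @return named integer vector, accession -> observable tryptic peptide
#'   count.
#' @export
theoretical_counts_from_fasta <- function(path, min_len = 6, max_len = 30) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  seqs <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  counts <- vapply(as.character(seqs), theoretical_peptide_count,
                   integer(1), min_len = min_len, max_len = max_len,
                   USE.NAMES = FALSE)
  stats::setNames(counts, acc)
}

#' iBAQ values per protein and sample
#'
#' Intensity-based absolute quantification: for each protein and sample the
#' non-missing peptide intensities of that protein are summed and divided by
#' its number of theoretically observable tryptic peptides. A protein with no
#' observed peptide in a sample is missing there.
#'
#' When `theoretical_counts` is `NULL` the fallback denominator is the
#' number of distinct peptides observed for the protein anywhere in the data
#' set; this keeps the pipeline runnable from an intensity table alone and
#' is logged as an approximation.
#'
#' @param matrix a [peptide_matrix] of normalized linear intensities.
#' @param theoretical_counts named positive-integer vector, protein ->
#'   observable tryptic peptide count, or `NULL` for the fallback.
#' @return numeric protein x sample matrix of iBAQ values.
#' @export
ibaq <- function(matrix, theoretical_counts = NULL) {
  ints <- matrix$intensities
  prot <- .protein_of(matrix)
  proteins <- unique(prot)

  if (is.null(theoretical_counts)) {
    message("ibaq: no theoretical counts supplied; ",
            "using observed distinct-peptide counts as an approximation")
    theoretical_counts <- table(prot)[proteins]
    theoretical_counts <- stats::setNames(as.integer(theoretical_counts),
                                          proteins)
  }
  missing_cnt <- setdiff(proteins, names(theoretical_counts))
  if (length(missing_cnt))
    stop("no theoretical peptide count for: ",
         paste(utils::head(missing_cnt, 5), collapse = ", "))
  cnt <- theoretical_counts[proteins]
  if (any(is.na(cnt)) || any(cnt <= 0))
    stop("theoretical peptide counts must be positive")

  grp <- factor(prot, levels = proteins)
  sums <- rowsum(ifelse(is.na(ints), 0, ints), grp, reorder = FALSE)
  n_obs <- rowsum((!is.na(ints)) + 0, grp, reorder = FALSE)
  out <- sums / as.numeric(cnt)
  out[n_obs == 0] <- NA_real_
  rownames(out) <- proteins
  out
}

#' Per-sample aLFQ scaling to a fixed total protein amount
#'
#' Converts relative iBAQ values to absolute amounts by proportional
#' allocation of a known total protein mass, performed separately for each
#' sample so that every sample carries exactly `total_ng` of protein:
#' `quantity(p, s) = ibaq(p, s) / sum_q ibaq(q, s) * total_ng`.
#'
#' @param ibaq numeric protein x sample matrix of iBAQ values.
#' @param total_ng total protein amount per sample in ng (default 200).
#' @param per_sample if `FALSE`, the unmodified global behaviour is used
#'   instead: all iBAQ values are divided by the grand total so only the
#'   data-set-wide sum equals `total_ng * n_samples`.
#' @return numeric protein x sample matrix of quantities in ng.
#' @export
alfq_scale <- function(ibaq, total_ng = 200, per_sample = TRUE) {
  if (!is.numeric(total_ng) || total_ng <= 0)
    stop("'total_ng' must be a positive real")
  col_sums <- colSums(ibaq, na.rm = TRUE)
  empty <- colnames(ibaq)[colSums(!is.na(ibaq)) == 0]
  if (length(empty))
    stop("sample with no observed protein: ",
         paste(empty, collapse = ", "))
  if (per_sample) {
    sweep(ibaq, 2, col_sums, "/") * total_ng
  } else {
    ibaq / sum(ibaq, na.rm = TRUE) * total_ng * ncol(ibaq)
  }
}

#' Single-protein percentage values
#'
#' Expresses each protein's quantity as a percentage of its sample's total,
#' so every sample sums to 100.
#'
#' @param quantity_ng numeric protein x sample matrix (any proportional
#'   quantity works).
#' @return numeric protein x sample matrix of percentages.
#' @export
percentage <- function(quantity_ng) {
  tot <- colSums(quantity_ng, na.rm = TRUE)
  if (any(tot <= 0))
    stop("per-sample sums must be > 0")
  sweep(quantity_ng, 2, tot, "/") * 100
}

#' Full absolute-quantification chain
#'
#' Convenience wrapper: LOESS normalization, iBAQ, per-sample aLFQ scaling
#' and percentage values in one call.
#'
#' @param matrix a [peptide_matrix] of raw linear intensities.
#' @param theoretical_counts see [ibaq].
#' @param total_ng per-sample total protein amount in ng (default 200).
#' @param span,iterations passed to [loess_normalize].
#' @param normalize set `FALSE` to skip normalization (already-normalized
#'   input).
#' @return object of class `protein_quant`: list with `ibaq`, `quantity_ng`,
#'   `percentage` (protein x sample matrices), `total_ng` and
#'   `sample_labels`.
#' @export
quantify_proteins <- function(matrix, theoretical_counts = NULL,
                              total_ng = 200, span = 0.7, iterations = 3,
                              normalize = TRUE) {
  if (normalize)
    matrix <- loess_normalize(matrix, span = span, iterations = iterations)
  ib <- ibaq(matrix, theoretical_counts)
  ng <- alfq_scale(ib, total_ng = total_ng)
  structure(list(ibaq = ib, quantity_ng = ng, percentage = percentage(ng),
                 total_ng = total_ng, sample_labels = matrix$sample_labels),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant: %d proteins x %d samples (total %g ng/sample)\n",
              nrow(x$ibaq), ncol(x$ibaq), x$total_ng))
  invisible(x)
}
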