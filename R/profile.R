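#' Call fiber types from MYH proteotypic peptides
#'
#' The gold-standard assignment of skeletal muscle fiber types rests on the
#' dominant myosin heavy chain isoform: MYH7 marks type I, MYH2 type IIa,
#' MYH4 type IIb and MYH1 type IIx fibers. For each isoform the intensities
#' of its proteotypic peptides are summed within every fiber-type group
#' (over peptides and samples); the called type is the argmax across groups.
#' Hybrid fibers co-express isoforms, so ties report all maximizers.
#'
#' @param matrix a [peptide_matrix] with `sample_labels` and proteotypicity
#'   flags.
#' @param isoform_map named character vector, protein accession -> isoform
#'   name (e.g. `c(Q91Z83 = "MYH7")`). Proteins absent from the map are
#'   ignored.
#' @return object of class `myh_call`: list with `summed_intensity`
#'   (isoform x fiber-type matrix) and `called_type` (isoform -> character
#'   vector of maximizing types).
#' @export
myh_fiber_call <- function(matrix, isoform_map) {
  labels <- matrix$sample_labels
  if (is.null(labels)) stop("matrix must carry fiber-type sample labels")
  proteo <- matrix$proteotypic
  prot <- .protein_of(matrix)
  keep <- prot %in% names(isoform_map) & proteo %in% TRUE
  iso_all <- unique(unname(isoform_map))
  dropped <- setdiff(iso_all, unique(isoform_map[prot[keep]]))
  if (length(dropped))
    warning("isoform(s) without proteotypic peptides excluded: ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("no proteotypic peptide maps to any isoform")

  ints <- matrix$intensities[keep, , drop = FALSE]
  iso <- factor(unname(isoform_map[prot[keep]]))
  types <- sort(unique(labels))
  summed <- sapply(types, function(ft) {
    cols <- names(labels)[labels == ft]
    rowsum(rowSums(ints[, cols, drop = FALSE], na.rm = TRUE), iso)[, 1]
  })
  if (is.null(dim(summed)))
    summed <- matrix(summed, nrow = 1,
                     dimnames = list(levels(iso), types))
  called <- apply(summed, 1, function(v) {
    if (all(v == 0)) return(character(0))
    names(v)[v == max(v)]
  }, simplify = FALSE)
  structure(list(summed_intensity = summed, called_type = called),
            class = "myh_call")
}

#' @export
print.myh_call <- function(x, digits = 2, ...) {
  cat("MYH isoform fiber-type call (summed proteotypic peptide intensity)\n")
  print(round(x$summed_intensity, digits))
  for (iso in names(x$called_type))
    cat(sprintf("  %s -> type %s\n", iso,
                paste(x$called_type[[iso]], collapse = "/")))
  invisible(x)
}

#' Worked MYH example data
#'
#' Loads the packaged worked example: per-fiber-type summed intensities
#' (arbitrary units, x10^7) of five high-intensity proteotypic peptides for
#' each of the four murine MYH isoforms, as one pooled column per fiber
#' type.
#'
#' @return list with `matrix` (a [peptide_matrix], 20 peptides x 4 pooled
#'   samples) and `isoform_map` (the canonical isoform -> fiber-type marker
#'   set: MYH7, MYH2, MYH4, MYH1).
#' @export
myh_example <- function() {
  dir <- system.file("extdata", package = "fibertyper")
  mat <- read_long_table(file.path(dir, "myh_peptide_sums.tsv"),
                         labels = file.path(dir, "myh_sample_labels.tsv"))
  list(matrix = mat,
       isoform_map = c(MYH7 = "MYH7", MYH2 = "MYH2",
                       MYH4 = "MYH4", MYH1 = "MYH1"))
}

#' Slow/fast marker table across fiber types
#'
#' Summarizes the percentage values of known sarcomeric marker proteins per
#' fiber type, echoing each marker's slow/fast indication. No classification
#' decision is made here; the table is descriptive.
#'
#' @param quant a `protein_quant` (see [quantify_proteins]) with sample
#'   labels, or a plain protein x sample percentage matrix plus `labels`.
#' @param markers named character vector, protein -> `"slow"` or `"fast"`.
#' @param labels sample -> fiber type, required when `quant` is a matrix.
#' @param fun summary statistic across the samples of a type (default
#'   `mean`; `median` available).
#' @return data.frame with one row per marker: protein, indication, one
#'   column per fiber type. Markers absent from the data keep an all-`NA`
#'   row.
#' @export
marker_table <- function(quant, markers, labels = NULL, fun = mean) {
  if (inherits(quant, "protein_quant")) {
    pct <- quant$percentage
    labels <- quant$sample_labels
  } else pct <- quant
  if (is.null(labels)) stop("fiber-type sample labels are required")
  types <- sort(unique(labels))
  out <- matrix(NA_real_, length(markers), length(types),
                dimnames = list(names(markers), types))
  present <- intersect(names(markers), rownames(pct))
  for (ft in types) {
    cols <- names(labels)[labels == ft]
    out[present, ft] <- apply(pct[present, cols, drop = FALSE], 1,
                              fun, na.rm = TRUE)
  }
  data.frame(protein = names(markers), indicative_for = unname(markers),
             out, check.names = FALSE, row.names = NULL)
}

#' Filter rows by fraction of valid values
#'
#' Keeps rows quantified in at least `min_valid_fraction` of the samples
#' (default 50%), the usual prerequisite for imputation and clustering.
#'
#' @param matrix numeric matrix with possible `NA` cells.
#' @param min_valid_fraction required fraction of non-missing cells per row,
#'   in (0, 1].
#' @return the filtered matrix.
#' @export
filter_valid <- function(matrix, min_valid_fraction = 0.5) {
  if (min_valid_fraction <= 0 || min_valid_fraction > 1)
    stop("'min_valid_fraction' must be in (0, 1]")
  frac <- rowMeans(!is.na(matrix))
  matrix[frac >= min_valid_fraction, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Replaces left-censored missing values, per sample column, with draws from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)` where `mu_s`
#' and `sigma_s` are the observed mean and standard deviation of that
#' column. The narrowed, downshifted distribution mimics values below the
#' detection limit. Observed cells are returned bit-identical.
#'
#' @param matrix numeric log2-scale matrix with `NA` for missing values.
#' @param width width of the imputation distribution relative to the
#'   observed sd (default 0.3).
#' @param downshift shift below the observed mean in observed-sd units
#'   (default 1.8).
#' @param seed integer seed; fixed seed gives identical imputations.
#' @param per_column if `FALSE`, a single mean/sd over the whole matrix is
#'   used instead of per-sample moments.
#' @return the matrix with every `NA` replaced.
#' @export
impute_downshift <- function(matrix, width = 0.3, downshift = 1.8,
                             seed = 1, per_column = TRUE) {
  set.seed(seed)
  out <- matrix
  if (per_column) {
    for (j in seq_len(ncol(out))) {
      obs <- out[, j][!is.na(out[, j])]
      miss <- which(is.na(out[, j]))
      if (!length(miss)) next
      if (length(obs) < 2)
        stop("sample '", colnames(out)[j],
             "' has fewer than 2 observed values")
      out[miss, j] <- stats::rnorm(length(miss),
                                   mean(obs) - downshift * stats::sd(obs),
                                   width * stats::sd(obs))
    }
  } else {
    obs <- matrix[!is.na(matrix)]
    if (length(obs) < 2) stop("fewer than 2 observed values in the matrix")
    miss <- which(is.na(out))
    out[miss] <- stats::rnorm(length(miss),
                              mean(obs) - downshift * stats::sd(obs),
                              width * stats::sd(obs))
  }
  out
}

# deterministic k-means++ initial centers
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    p <- d2 / sum(d2)
    centers[i + 1] <- sample.int(n, 1, prob = p)
    d2_new <- rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x),
                                  byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  x[centers, , drop = FALSE]
}

#' Median profiles, Z-scoring and two-stage clustering
#'
#' The clustering chain applied to the filtered, imputed log2 protein
#' matrix: fiber-type group medians are computed per protein, rows are
#' Z-scored, pre-clustered by seeded k-means (k-means++ initialization,
#' bounded iteration count), and the pre-cluster centroids are joined by
#' Euclidean average-linkage hierarchical clustering whose tree is cut into
#' `n_final` clusters. Assignments are propagated back to the proteins.
#'
#' @param matrix filtered + imputed numeric log2 matrix, proteins x samples.
#' @param labels sample -> fiber-type map covering all columns.
#' @param k_pre number of k-means pre-clusters (default 300; capped at the
#'   row count, in which case the pre-clustering stage is the identity).
#' @param max_iter maximal k-means iterations (default 10).
#' @param n_final number of final clusters the tree is cut into (default 4).
#' @param seed integer seed for the k-means initialization.
#' @return object of class `cluster_result`: `assignment` (protein ->
#'   cluster id), `profiles` (cluster x fiber-type median Z-scores), `sizes`,
#'   `zscores` (the protein x fiber-type Z-scored median matrix) and the
#'   `hclust` tree over the pre-cluster centroids.
#' @export
cluster_profiles <- function(matrix, labels, k_pre = 300, max_iter = 10,
                             n_final = 4, seed = 1) {
  if (n_final > nrow(matrix))
    stop("'n_final' exceeds the number of rows")
  types <- sort(unique(labels[colnames(matrix)]))
  med <- sapply(types, function(ft) {
    cols <- colnames(matrix)[labels[colnames(matrix)] == ft]
    apply(matrix[, cols, drop = FALSE], 1, stats::median)
  })
  z <- t(scale(t(med)))  # row Z-score
  if (any(!is.finite(z)))
    stop("constant protein profile(s): Z-score undefined")

  set.seed(seed)
  k <- min(k_pre, nrow(z))
  if (k < nrow(z)) {
    km <- stats::kmeans(z, centers = .kmeanspp_centers(z, k),
                        iter.max = max_iter, algorithm = "Lloyd")
    centroids <- km$centers
    pre_assign <- km$cluster
  } else {
    centroids <- z
    pre_assign <- stats::setNames(seq_len(nrow(z)), rownames(z))
  }

  hc <- stats::hclust(stats::dist(centroids, method = "euclidean"),
                      method = "average")
  cut <- stats::cutree(hc, k = n_final)
  assignment <- stats::setNames(cut[pre_assign], rownames(z))

  profiles <- t(sapply(sort(unique(assignment)), function(cl) {
    apply(z[assignment == cl, , drop = FALSE], 2, stats::median)
  }))
  rownames(profiles) <- sort(unique(assignment))
  sizes <- table(assignment)
  structure(list(assignment = assignment, profiles = profiles,
                 sizes = stats::setNames(as.integer(sizes), names(sizes)),
                 zscores = z, tree = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d proteins in %d clusters\n",
              length(x$assignment), length(x$sizes)))
  cat("  sizes:", paste(sprintf("%s: %d", names(x$sizes), x$sizes),
                        collapse = ", "), "\n")
  cat("  median Z-score profiles:\n")
  print(round(x$profiles, 2))
  invisible(x)
}

#' Annotation-category percentages per cluster
#'
#' Counts the members of each functional category within every cluster and
#' expresses them as a percentage of the cluster size (reported rounded to 2
#' decimals). Proteins without a category are pooled as `"Other"`.
#'
#' @param result a `cluster_result` (see [cluster_profiles]) or a named
#'   vector protein -> cluster id.
#' @param categories named character vector, protein -> category.
#' @return object of class `annotation_table`: list with integer matrix
#'   `counts` and numeric matrix `percent` (both cluster x category) and
#'   `sizes`.
#' @export
annotate_percentages <- function(result, categories) {
  assignment <- if (inherits(result, "cluster_result")) result$assignment
                else result
  cat_of <- categories[names(assignment)]
  cat_of[is.na(cat_of)] <- "Other"
  counts <- table(cluster = assignment, category = cat_of)
  counts <- unclass(counts)
  sizes <- rowSums(counts)
  percent <- round(counts / sizes * 100, 2)
  structure(list(counts = counts, percent = percent,
                 sizes = stats::setNames(as.integer(sizes),
                                         rownames(counts))),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("annotation_table: category percentages per cluster\n")
  print(t(x$percent))
  invisible(x)
}

#' PCA scores and loadings for separator inspection
#'
#' Principal component analysis of the samples with per-protein loadings on
#' the first two components, ranked by absolute magnitude so that the
#' strongest fiber-type separators can be read off directly.
#'
#' @param matrix numeric protein x sample matrix without missing values.
#' @param scale. logical, scale proteins to unit variance (default `FALSE`).
#' @return list with `scores` (sample x PC1/PC2), `loadings` (protein x
#'   PC1/PC2), `ranked` (loadings ordered by decreasing
#'   `max(|PC1|, |PC2|)`) and `sdev` (all component standard deviations).
#' @export
pca_loadings <- function(matrix, scale. = FALSE) {
  if (ncol(matrix) < 3) stop("need >= 3 samples for PCA")
  if (any(is.na(matrix))) stop("matrix must not contain missing values")
  if (all(apply(matrix, 1, stats::sd) == 0))
    stop("constant matrix: PCA undefined")
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = scale.)
  scores <- pc$x[, 1:2, drop = FALSE]
  loadings <- pc$rotation[, 1:2, drop = FALSE]
  ord <- order(-pmax(abs(loadings[, 1]), abs(loadings[, 2])))
  list(scores = scores, loadings = loadings,
       ranked = loadings[ord, , drop = FALSE], sdev = pc$sdev)
}
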