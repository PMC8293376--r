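# Independent oracles and small fixture builders used across the suite.

# regex-based fully tryptic digest (cleave after K/R, not before P),
# independent of the package's character-scan implementation
oracle_tryptic_count <- function(sequence, min_len = 6, max_len = 30) {
  if (!nzchar(sequence)) return(0L)
  pieces <- strsplit(gsub("(?<=[KR])(?!P)", "|", sequence, perl = TRUE),
                     "|", fixed = TRUE)[[1]]
  sum(nchar(pieces) >= min_len & nchar(pieces) <= max_len)
}

# per-protein loop oracle for iBAQ
oracle_ibaq <- function(ints, protein_of, counts) {
  proteins <- unique(protein_of)
  out <- matrix(NA_real_, length(proteins), ncol(ints),
                dimnames = list(proteins, colnames(ints)))
  for (p in proteins) {
    rows <- which(protein_of == p)
    for (s in seq_len(ncol(ints))) {
      v <- ints[rows, s]
      if (all(is.na(v))) next
      out[p, s] <- sum(v, na.rm = TRUE) / counts[[p]]
    }
  }
  out
}

# naive O(n^3) average-linkage agglomeration; returns merge heights
oracle_average_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# a tiny labelled peptide_matrix with fully observed planted panel
panel_fixture <- function(n_per = 6, n_noise = 10, separation = 8,
                          sd = 0.3, seed = 11) {
  set.seed(seed)
  types <- rep(c("I", "IIa", "IIb", "IIx"), each = n_per)
  samples <- paste0("s", seq_along(types))
  names(types) <- samples
  mean_a <- c(I = 0, IIa = 0, IIb = 2, IIx = 1) * separation + 22
  mean_b <- c(I = 1, IIa = 0, IIb = 0, IIx = 0) * separation + 22
  X <- rbind(
    TINEVENQVLTR = mean_a[types] + rnorm(length(types), 0, sd),
    IAEQELLDASER = mean_b[types] + rnorm(length(types), 0, sd))
  log2_mat <- X
  if (n_noise > 0) {
    noise <- matrix(rnorm(n_noise * length(types), 22, 1),
                    n_noise, length(types),
                    dimnames = list(paste0("NOISEPEP", sprintf("%02d",
                                           seq_len(n_noise)), "K"), samples))
    log2_mat <- rbind(X, noise)
  }
  colnames(log2_mat) <- samples
  p2p <- setNames(c("ACTN3", "MYH1P",
                    if (n_noise > 0) paste0("BG", seq_len(n_noise))),
                  rownames(log2_mat))
  peptide_matrix(2^log2_mat, p2p,
                 setNames(rep(TRUE, nrow(log2_mat)), rownames(log2_mat)),
                 types)
}

# sample x feature view with labels, for classifier-level tests
panel_xy <- function(...) {
  pm <- panel_fixture(...)
  list(X = t(log2(pm$intensities)), y = pm$sample_labels)
}
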