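# ---- LOESS normalization ----------------------------------------------

make_pm <- function(log2_mat, labels = NULL) {
  peps <- rownames(log2_mat)
  peptide_matrix(2^log2_mat,
                 setNames(paste0("P", seq_along(peps)), peps),
                 setNames(rep(TRUE, length(peps)), peps), labels)
}

base_log2 <- function(n = 400, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n, 18, 30), n, 4) +
    matrix(rnorm(4 * n, 0, 0.2), n, 4)
  dimnames(m) <- list(paste0("PEP", sprintf("%03d", 1:n), "K"),
                      paste0("s", 1:4))
  m
}

test_that("identical samples come back unchanged", {
  lm2 <- base_log2()[, c(1, 1)]
  colnames(lm2) <- c("a", "b")
  out <- loess_normalize(make_pm(lm2))
  expect_equal(out$intensities, 2^lm2, tolerance = 1e-9)
})

test_that("a uniform log2 shift between samples is removed", {
  lm2 <- base_log2()
  lm2[, 2] <- lm2[, 1] + 1  # sample b = a shifted by +1 log2 unit
  out <- log2(loess_normalize(make_pm(lm2[, 1:2]))$intensities)
  expect_lt(abs(median(out[, 1]) - median(out[, 2])), 0.01)
})

test_that("an intensity-dependent bias is flattened below 0.05 log2", {
  lm2 <- base_log2(n = 800, seed = 2)
  lm2[, 3] <- lm2[, 3] + 0.5 * sin(lm2[, 3] / 3)
  out <- log2(loess_normalize(make_pm(lm2))$intensities)
  ref <- rowMeans(out)
  m <- out[, 3] - ref
  a <- (out[, 3] + ref) / 2
  fit <- lowess(a, m, f = 0.7)
  expect_lt(max(abs(fit$y)), 0.05)
})

test_that("a sample sharing < 10 peptides with the reference is refused", {
  lm2 <- base_log2(n = 50)
  lm2[1:45, 4] <- NA
  expect_error(loess_normalize(make_pm(lm2)), "s4")
})

test_that("normalization agrees with the cyclic-loess oracle on complete data", {
  skip_if_not_installed("limma")
  lm2 <- base_log2(n = 600, seed = 3)
  lm2[, 2] <- lm2[, 2] + 0.8
  lm2[, 4] <- lm2[, 4] - 0.3 + 0.04 * (lm2[, 4] - 24)
  ours <- log2(loess_normalize(make_pm(lm2))$intensities)
  theirs <- limma::normalizeCyclicLoess(lm2, span = 0.7, iterations = 3,
                                        method = "fast")
  expect_equal(ours, theirs, tolerance = 1e-8, ignore_attr = TRUE)
})

# ---- theoretical peptide counts ---------------------------------------

test_that("tryptic peptide counting follows the cleavage rule", {
  expect_equal(theoretical_peptide_count("KR"), 0)
  expect_equal(theoretical_peptide_count(strrep("A", 20)), 1)
  # K before P does not cleave
  expect_equal(theoretical_peptide_count("AAAAAKPAAAAA"), 1)
  expect_equal(theoretical_peptide_count("AAAAAKAAAAAA"), 2)
  expect_warning(expect_equal(theoretical_peptide_count(""), 0), "empty")
  expect_error(theoretical_peptide_count("AAAB"), "illegal")
})

test_that("counts equal a brute-force digest oracle on random sequences", {
  set.seed(42)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:50) {
    seq <- paste(sample(aas, sample(5:120, 1), replace = TRUE),
                 collapse = "")
    expect_equal(theoretical_peptide_count(seq),
                 oracle_tryptic_count(seq), info = seq)
  }
})

test_that("FASTA-derived counts match per-sequence digestion", {
  skip_if_not_installed("Biostrings")
  seqs <- c(P1 = "MAAAAAKAAAAAAR", P2 = paste(strrep("ACDEFG", 8), "K",
                                              sep = ""))
  path <- withr::local_tempfile(
    lines = unlist(lapply(names(seqs), function(a)
      c(paste0(">", a, " some description"), seqs[[a]]))),
    fileext = ".fasta")
  counts <- theoretical_counts_from_fasta(path)
  expect_identical(counts,
                   c(P1 = theoretical_peptide_count(seqs[["P1"]]),
                     P2 = theoretical_peptide_count(seqs[["P2"]])))
})

# ---- iBAQ --------------------------------------------------------------

test_that("iBAQ divides summed peptide intensity by the theoretical count", {
  m <- matrix(c(10), 1, 1, dimnames = list("AAAAAAK", "s1"))
  pm <- peptide_matrix(m, c(AAAAAAK = "P1"))
  expect_equal(ibaq(pm, c(P1 = 1))["P1", "s1"], 10)

  m2 <- matrix(c(4, 6), 2, 1,
               dimnames = list(c("AAAAAAK", "CCCCCCK"), "s1"))
  pm2 <- peptide_matrix(m2, c(AAAAAAK = "P1", CCCCCCK = "P1"))
  expect_equal(ibaq(pm2, c(P1 = 5))["P1", "s1"], 2.0)
  expect_error(ibaq(pm2, c(P1 = 0)), "positive")
})

test_that("iBAQ equals the per-protein loop oracle on a random matrix", {
  set.seed(8)
  n <- 50
  peps <- paste0("PEP", sprintf("%02d", 1:n), "R")
  prot <- setNames(paste0("P", sample(1:12, n, replace = TRUE)), peps)
  ints <- matrix(rlnorm(n * 8, 14, 1), n, 8,
                 dimnames = list(peps, paste0("s", 1:8)))
  ints[sample(length(ints), 60)] <- NA
  counts <- setNames(sample(3:20, 12), paste0("P", 1:12))
  pm <- peptide_matrix(ints, prot)
  expect_equal(ibaq(pm, counts),
               oracle_ibaq(ints, unname(prot), counts)[rownames(ibaq(pm, counts)), ])
})

test_that("iBAQ is homogeneous in one protein's peptide intensities", {
  set.seed(9)
  pm <- panel_fixture()
  counts <- setNames(rep(7, length(unique(pm$peptide_to_protein))),
                     unique(pm$peptide_to_protein))
  before <- ibaq(pm, counts)
  scaled <- pm$intensities
  rows <- which(pm$peptide_to_protein == "ACTN3")
  scaled[rows, ] <- scaled[rows, ] * 3
  after <- ibaq(peptide_matrix(scaled, pm$peptide_to_protein), counts)
  expect_equal(after["ACTN3", ], 3 * before["ACTN3", ])
  others <- setdiff(rownames(before), "ACTN3")
  expect_equal(after[others, ], before[others, ])
})

test_that("a protein with no observed peptide in a sample is missing", {
  m <- matrix(c(5, NA), 1, 2, dimnames = list("AAAAAAK", c("s1", "s2")))
  pm <- peptide_matrix(m, c(AAAAAAK = "P1"))
  ib <- ibaq(pm, c(P1 = 2))
  expect_equal(ib["P1", "s1"], 2.5)
  expect_true(is.na(ib["P1", "s2"]))
})

# ---- aLFQ scaling and percentages -------------------------------------

test_that("aLFQ allocates the total amount proportionally per sample", {
  ib <- matrix(c(1, 3), 2, 1, dimnames = list(c("P1", "P2"), "s1"))
  expect_equal(alfq_scale(ib, total_ng = 200)[, 1], c(P1 = 50, P2 = 150))

  one <- matrix(7, 1, 1, dimnames = list("P1", "s1"))
  expect_equal(alfq_scale(one, total_ng = 200)[1, 1], 200)

  all_na <- matrix(NA_real_, 2, 1, dimnames = list(c("P1", "P2"), "sX"))
  expect_error(alfq_scale(all_na), "sX")
})

test_that("per-sample mass conservation holds on random matrices", {
  set.seed(10)
  ib <- matrix(rlnorm(200, 10, 2), 40, 5,
               dimnames = list(paste0("P", 1:40), paste0("s", 1:5)))
  ib[sample(length(ib), 30)] <- NA
  ng <- alfq_scale(ib, total_ng = 200)
  expect_equal(colSums(ng, na.rm = TRUE),
               setNames(rep(200, 5), paste0("s", 1:5)), tolerance = 1e-9)
  # global mode preserves only the grand total
  glob <- alfq_scale(ib, total_ng = 200, per_sample = FALSE)
  expect_equal(sum(glob, na.rm = TRUE), 200 * 5, tolerance = 1e-9)
})

test_that("percentages sum to 100 and are scale invariant", {
  ng <- matrix(c(50, 150), 2, 1, dimnames = list(c("P1", "P2"), "s1"))
  expect_equal(percentage(ng)[, 1], c(P1 = 25, P2 = 75))
  one <- matrix(3, 1, 1, dimnames = list("P1", "s1"))
  expect_equal(percentage(one)[1, 1], 100)

  set.seed(11)
  ib <- matrix(rlnorm(120, 8, 1.5), 30, 4,
               dimnames = list(paste0("P", 1:30), paste0("s", 1:4)))
  pct <- percentage(ib)
  expect_equal(unname(colSums(pct)), rep(100, 4), tolerance = 1e-9)
  ib2 <- ib; ib2[, 2] <- ib2[, 2] * 17.3
  expect_equal(percentage(ib2), pct, tolerance = 1e-12)
})
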