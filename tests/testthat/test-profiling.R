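# ---- MYH fiber calling -------------------------------------------------

test_that("the packaged MYH worked example calls all four isoforms", {
  ex <- myh_example()
  call <- myh_fiber_call(ex$matrix, ex$isoform_map)
  expect_identical(call$called_type$MYH7, "I")
  expect_identical(call$called_type$MYH2, "IIa")
  expect_identical(call$called_type$MYH4, "IIb")
  expect_identical(call$called_type$MYH1, "IIx")
  # summed intensities reproduce the column sums of the worked table
  expect_equal(call$summed_intensity["MYH7", "I"],
               sum(c(226.57, 162.65, 137.41, 80.46, 74.67)))
})

test_that("an isoform seen in exactly one type is called there; ties report all", {
  labels <- setNames(rep(c("I", "IIa"), each = 2), paste0("s", 1:4))
  ints <- rbind(SOLOPEPK = c(0, 0, 5, 5),
                TIEDPEPK = c(3, 3, 3, 3))
  colnames(ints) <- names(labels)
  pm <- peptide_matrix(ints,
                       c(SOLOPEPK = "PA", TIEDPEPK = "PB"),
                       c(SOLOPEPK = TRUE, TIEDPEPK = TRUE), labels)
  call <- myh_fiber_call(pm, c(PA = "isoA", PB = "isoB"))
  expect_identical(call$called_type$isoA, "IIa")
  expect_setequal(call$called_type$isoB, c("I", "IIa"))
})

test_that("non-proteotypic peptides never contribute to the call", {
  labels <- setNames(rep(c("I", "IIa"), each = 2), paste0("s", 1:4))
  ints <- rbind(UNIQPEPK = c(5, 5, 1, 1),
                SHARPEPK = c(0, 0, 100, 100))
  colnames(ints) <- names(labels)
  pm <- peptide_matrix(ints, c(UNIQPEPK = "PA", SHARPEPK = "PA"),
                       c(UNIQPEPK = TRUE, SHARPEPK = FALSE), labels)
  call <- myh_fiber_call(pm, c(PA = "isoA"))
  expect_identical(call$called_type$isoA, "I")
  # an isoform left with no proteotypic peptide is excluded with a warning
  pm2 <- peptide_matrix(ints, c(UNIQPEPK = "PA", SHARPEPK = "PB"),
                        c(UNIQPEPK = TRUE, SHARPEPK = FALSE), labels)
  expect_warning(myh_fiber_call(pm2, c(PA = "isoA", PB = "isoB")), "isoB")
})

# ---- marker tables -----------------------------------------------------

test_that("marker tables summarize percentages per fiber type", {
  labels <- setNames(rep(c("I", "IIa", "IIb", "IIx"), each = 2),
                     paste0("s", 1:8))
  pct <- rbind(SLOW1 = c(4, 4, 0, 0, 0, 0, 0, 0),
               FLAT1 = rep(2, 8),
               OTHER = c(94, 94, 98, 98, 98, 98, 98, 98))
  colnames(pct) <- names(labels)
  tab <- marker_table(pct, c(SLOW1 = "slow", FLAT1 = "fast",
                             GONE1 = "slow"), labels = labels)
  expect_equal(tab[tab$protein == "SLOW1", "I"], 4)
  expect_equal(unlist(tab[tab$protein == "SLOW1", c("IIa", "IIb", "IIx")]),
               c(IIa = 0, IIb = 0, IIx = 0))
  expect_equal(unname(unlist(tab[tab$protein == "FLAT1",
                                 c("I", "IIa", "IIb", "IIx")])), rep(2, 4))
  expect_true(all(is.na(tab[tab$protein == "GONE1",
                            c("I", "IIa", "IIb", "IIx")])))
})

test_that("a synthetic slow marker is monotone along I, IIa, IIx, IIb", {
  sim <- simulate_fibers(sim_config(seed = 6, missing_fraction = 0))
  quant <- quantify_proteins(sim$matrix, normalize = FALSE)
  slow <- grep("^SLOWM", rownames(quant$percentage), value = TRUE)
  tab <- marker_table(quant, setNames(rep("slow", length(slow)), slow))
  means <- colMeans(tab[, c("I", "IIa", "IIx", "IIb")])
  expect_true(all(diff(means) < 0))
})

# ---- filtering and imputation -----------------------------------------

test_that("the valid-value filter keeps rows at or above the threshold", {
  m <- matrix(NA_real_, 3, 56,
              dimnames = list(c("at", "below", "full"), paste0("s", 1:56)))
  m["at", 1:28] <- 1       # 28/56 = 50.0%
  m["below", 1:27] <- 1    # 27/56 = 48.2%
  m["full", ] <- 1
  kept <- filter_valid(m, 0.5)
  expect_setequal(rownames(kept), c("at", "full"))
  expect_error(filter_valid(m, 0), "min_valid_fraction")
})

test_that("lowering the threshold never removes a previously kept row", {
  set.seed(14)
  m <- matrix(rnorm(600), 60, 10)
  rownames(m) <- paste0("p", 1:60)
  m[sample(length(m), 250)] <- NA
  for (f in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
    kept_hi <- rownames(filter_valid(m, f))
    kept_lo <- rownames(filter_valid(m, f - 0.05))
    expect_true(all(kept_hi %in% kept_lo))
  }
})

test_that("imputation is deterministic, leaves observed cells bit-exact", {
  set.seed(15)
  m <- matrix(rnorm(400, 25, 2), 80, 5)
  dimnames(m) <- list(paste0("p", 1:80), paste0("s", 1:5))
  complete <- impute_downshift(m, seed = 1)
  expect_identical(complete, m)  # nothing to impute

  m[sample(length(m), 80)] <- NA
  a <- impute_downshift(m, seed = 3)
  b <- impute_downshift(m, seed = 3)
  expect_identical(a, b)
  obs <- !is.na(m)
  expect_identical(a[obs], m[obs])
  expect_false(anyNA(a))
  expect_error(impute_downshift(cbind(c(1, NA, NA))), "2 observed")
})

test_that("imputed values sit below the observed distribution", {
  set.seed(16)
  m <- matrix(rnorm(3000, 25, 2), 600, 5)
  dimnames(m) <- list(paste0("p", 1:600), paste0("s", 1:5))
  m[sample(length(m), 600)] <- NA
  out <- impute_downshift(m, width = 0.3, downshift = 1.8, seed = 2)
  expect_lt(mean(out[is.na(m)]), mean(out[!is.na(m)]))
})

# ---- clustering --------------------------------------------------------

archetype_matrix <- function(n_each = 50, sd = 0.05, seed = 17) {
  set.seed(seed)
  labels <- setNames(rep(c("I", "IIa", "IIb", "IIx"), each = 2),
                     paste0("s", 1:8))
  arche <- rbind(c(2, 1, -1, -2), c(-2, 1, 2, -1),
                 c(1, -2, -1, 2), c(-1, -2, 2, 1))
  truth <- rep(1:4, each = n_each)
  prof <- arche[truth, ]
  prof <- prof[, rep(1:4, each = 2)] +
    matrix(rnorm(length(truth) * 8, 0, sd), length(truth), 8)
  dimnames(prof) <- list(paste0("prot", seq_along(truth)), names(labels))
  list(matrix = prof, labels = labels, truth = truth)
}

test_that("well-separated archetype profiles are recovered exactly", {
  skip_if_not_installed("mclust")
  fx <- archetype_matrix()
  res <- cluster_profiles(fx$matrix, fx$labels, k_pre = 300, n_final = 4,
                          seed = 1)
  expect_equal(mclust::adjustedRandIndex(res$assignment, fx$truth), 1.0)
  # partition property: every protein in exactly one cluster
  expect_setequal(names(res$assignment), rownames(fx$matrix))
  expect_equal(sum(res$sizes), nrow(fx$matrix))
  # Z-scored rows have mean 0 and sd 1
  expect_equal(unname(rowMeans(res$zscores)), rep(0, nrow(fx$matrix)),
               tolerance = 1e-9)
  expect_equal(unname(apply(res$zscores, 1, sd)), rep(1, nrow(fx$matrix)),
               tolerance = 1e-9)
})

test_that("with fewer rows than k_pre the pre-clustering is the identity", {
  fx <- archetype_matrix(n_each = 2, sd = 0.01)
  res <- cluster_profiles(fx$matrix, fx$labels, k_pre = 300, n_final = 4,
                          seed = 2)
  # direct average-linkage on the Z-scored rows gives the same partition
  z <- t(scale(t(sapply(c("I", "IIa", "IIb", "IIx"), function(ft) {
    cols <- names(fx$labels)[fx$labels == ft]
    apply(fx$matrix[, cols, drop = FALSE], 1, median)
  }))))
  direct <- cutree(hclust(dist(z), "average"), 4)
  expect_equal(mclust::adjustedRandIndex(res$assignment, direct), 1.0)
  expect_error(cluster_profiles(fx$matrix, fx$labels, n_final = 10), "n_final")
})

test_that("average-linkage merge heights match the brute-force oracle", {
  set.seed(18)
  x <- matrix(rnorm(8 * 4), 8, 4)
  ours <- hclust(dist(x), method = "average")$height
  expect_equal(sort(ours), sort(oracle_average_linkage_heights(x)),
               tolerance = 1e-9)
})

# ---- annotation percentages -------------------------------------------

test_that("annotation percentages are count over cluster size", {
  assignment <- setNames(rep(c(3, 4), c(77, 271)), paste0("p", 1:348))
  categories <- setNames(rep("Other", 348), names(assignment))
  categories[1:4] <- "Respiratory chain"
  categories[78:91] <- "Fatty acid beta oxidation"
  tab <- annotate_percentages(assignment, categories)
  expect_equal(tab$percent["3", "Respiratory chain"], 5.19)
  expect_equal(tab$percent["4", "Fatty acid beta oxidation"], 5.17)
  expect_equal(tab$counts["3", "Respiratory chain"], 4)
  expect_true(all(tab$counts <= matrix(tab$sizes, nrow(tab$counts),
                                       ncol(tab$counts))))
  one <- annotate_percentages(setNames(rep(1, 5), paste0("q", 1:5)),
                              setNames(rep("Ribosome", 5), paste0("q", 1:5)))
  expect_equal(unname(one$percent[1, "Ribosome"]), 100)
})

# ---- PCA ---------------------------------------------------------------

test_that("PCA loadings expose the separating protein", {
  set.seed(19)
  m <- matrix(rnorm(20 * 10, 0, 0.1), 20, 10)
  dimnames(m) <- list(paste0("p", 1:20), paste0("s", 1:10))
  m["p7", ] <- c(rep(5, 5), rep(-5, 5)) + rnorm(10, 0, 0.1)
  res <- pca_loadings(m)
  expect_equal(rownames(res$ranked)[1], "p7")
  expect_equal(which.max(abs(res$loadings[, "PC1"])), c(p7 = 7))
})

test_that("duplicated samples get identical scores; PC variances are ordered", {
  set.seed(20)
  m <- matrix(rnorm(15 * 6), 15, 6)
  dimnames(m) <- list(paste0("p", 1:15), paste0("s", 1:6))
  m[, 6] <- m[, 5]
  res <- pca_loadings(m)
  expect_equal(res$scores["s5", ], res$scores["s6", ], tolerance = 1e-9)
  # eigendecomposition oracle
  ev <- eigen(cov(t(m)), symmetric = TRUE)$values
  expect_gte(res$sdev[1], res$sdev[2])
  expect_equal(res$sdev[1:2]^2, ev[1:2], tolerance = 1e-9)
  expect_error(pca_loadings(matrix(1, 3, 4)), "constant")
})
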