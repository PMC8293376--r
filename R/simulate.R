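#' Configuration for the synthetic fiber-type data generator
#'
#' Defaults emulate the design of a laser-microdissection DIA fiber-type
#' experiment: 4 fiber types (I, IIa, IIb, IIx) with 14 samples each (56
#' total), four MYH-like isoform proteins whose expected intensity peaks in
#' their characteristic type, slow/fast sarcomeric marker proteins with
#' monotone gradients across types, and a background proteome with
#' log-normal intensities and left-censored missingness.
#'
#' @param n_samples_per_type samples per fiber type (default 14).
#' @param n_background_proteins background (non-marker) proteins (default 250).
#' @param peptides_per_protein integer range of peptides per protein,
#'   length-2 vector (default `c(2, 8)`).
#' @param log2_mean_range baseline protein abundance interval on the log2
#'   scale (default `c(18, 30)`).
#' @param within_type_sd biological + technical standard deviation within a
#'   fiber type, log2 units (default 0.4).
#' @param missing_fraction target overall fraction of missing cells (default
#'   0.2).
#' @param censoring_strength steepness of the intensity dependence of
#'   missingness; larger values concentrate missingness in low-intensity
#'   cells (default 1).
#' @param plant_panel if `TRUE`, plant the two jointly discriminative panel
#'   peptides (see [plant_panel]).
#' @param panel_separation between-class mean gap of the planted peptides in
#'   log2 units (default 4).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_type = 14,
                       n_background_proteins = 250,
                       peptides_per_protein = c(2, 8),
                       log2_mean_range = c(18, 30),
                       within_type_sd = 0.4,
                       missing_fraction = 0.2,
                       censoring_strength = 1,
                       plant_panel = FALSE,
                       panel_separation = 4,
                       seed = 1) {
  cfg <- list(n_samples_per_type = n_samples_per_type,
              n_background_proteins = n_background_proteins,
              peptides_per_protein = peptides_per_protein,
              log2_mean_range = log2_mean_range,
              within_type_sd = within_type_sd,
              missing_fraction = missing_fraction,
              censoring_strength = censoring_strength,
              plant_panel = isTRUE(plant_panel),
              panel_separation = panel_separation,
              seed = as.integer(seed))
  .check_pos_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop("invalid '", nm, "': must be a positive integer")
  }
  .check_pos_int(cfg$n_samples_per_type, "n_samples_per_type")
  .check_pos_int(cfg$n_background_proteins, "n_background_proteins")
  if (length(cfg$peptides_per_protein) != 2 ||
      any(cfg$peptides_per_protein < 1) ||
      cfg$peptides_per_protein[1] > cfg$peptides_per_protein[2])
    stop("invalid 'peptides_per_protein': must be an increasing range >= 1")
  if (length(cfg$log2_mean_range) != 2 ||
      diff(cfg$log2_mean_range) <= 0)
    stop("invalid 'log2_mean_range': must be a non-degenerate interval")
  if (!is.numeric(cfg$within_type_sd) || cfg$within_type_sd <= 0)
    stop("invalid 'within_type_sd': must be a positive real")
  if (!is.numeric(cfg$missing_fraction) || cfg$missing_fraction < 0 ||
      cfg$missing_fraction > 1)
    stop("invalid 'missing_fraction': must be in [0, 1]")
  if (!is.numeric(cfg$censoring_strength) || cfg$censoring_strength <= 0)
    stop("invalid 'censoring_strength': must be a positive real")
  if (!is.numeric(cfg$panel_separation) || cfg$panel_separation <= 0)
    stop("invalid 'panel_separation': must be a positive real")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (effective generator settings):\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, paste(format(val), collapse = "..")))
  }
  invisible(x)
}

# Fiber types in their physiological slow-to-fast order. Slow markers decay,
# fast markers rise along I -> IIa -> IIx -> IIb.
.FIBER_TYPES <- c("I", "IIa", "IIb", "IIx")
.SLOW_FAST_ORDER <- c("I", "IIa", "IIx", "IIb")

# Coarse cross-contamination profiles of the four MYH-like isoforms,
# linear-scale proportion of the peak type's expected intensity. Each
# isoform dominates its characteristic type; the type-I isoform is also
# present at ~20% in IIa and near-zero in IIb/IIx, the IIa isoform carries a
# sizeable type-I share, the IIx isoform leaks into all fast types.
.MYH_PROFILES <- rbind(
  MYH7_SYN = c(I = 1.00, IIa = 0.20, IIb = 0.002, IIx = 0.002),
  MYH2_SYN = c(I = 0.45, IIa = 1.00, IIb = 0.04,  IIx = 0.07),
  MYH4_SYN = c(I = 0.02, IIa = 0.02, IIb = 1.00,  IIx = 0.22),
  MYH1_SYN = c(I = 0.11, IIa = 0.17, IIb = 0.18,  IIx = 1.00))

# Log2 offsets of marker gradients along the slow->fast order I, IIa, IIx, IIb
.SLOW_GRADIENT <- c(I = 1.5, IIa = 0.75, IIx = -0.75, IIb = -1.5)
.FAST_GRADIENT <- -.SLOW_GRADIENT

.N_SLOW_MARKERS <- 5
.N_FAST_MARKERS <- 5

# random tryptic-ready peptide sequence ending in K/R
.random_peptide <- function(n, len_range = c(7, 18)) {
  aa <- strsplit("ACDEFGHILMNQSTVWY", "")[[1]]  # no K/R/P internally
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a synthetic fiber-type peptide data set
#'
#' Log2 intensities are drawn as Normal(protein mean + type effect,
#' within_type_sd) and exported on the linear scale, matching the log-normal
#' behaviour of MS peptide intensities. Missingness is left-censored: a cell
#' is deleted with probability `pnorm(strength * (threshold - log2 x) / sd)`,
#' the threshold solved so the expected missing fraction hits the target.
#'
#' @param config a [sim_config].
#' @return list with elements `matrix` (a [peptide_matrix]) and `truth`
#'   (ground truth: `fiber_type_of_sample`, `true_protein_class`,
#'   `planted_panel_peptides`, and the pre-deletion log2 matrix
#'   `log2_complete`).
#' @export
simulate_fibers <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  n_per <- config$n_samples_per_type
  types <- rep(.FIBER_TYPES, each = n_per)
  samples <- paste0("S", sprintf("%02d", seq_along(types)), "_", types)
  names(types) <- samples

  ## protein roster
  prot_class <- c(
    stats::setNames(rep("MYH-like", 4), rownames(.MYH_PROFILES)),
    stats::setNames(rep("slow-marker", .N_SLOW_MARKERS),
                    paste0("SLOWM", seq_len(.N_SLOW_MARKERS), "_SYN")),
    stats::setNames(rep("fast-marker", .N_FAST_MARKERS),
                    paste0("FASTM", seq_len(.N_FAST_MARKERS), "_SYN")),
    stats::setNames(rep("background", config$n_background_proteins),
                    paste0("BG", sprintf("%04d",
                           seq_len(config$n_background_proteins)), "_SYN")))
  proteins <- names(prot_class)

  ## per-protein log2 type-effect profiles (offset added to protein mean)
  peak_boost <- 2  # MYH peaks sit above the baseline mean
  effect <- matrix(0, length(proteins), 4,
                   dimnames = list(proteins, .FIBER_TYPES))
  effect[rownames(.MYH_PROFILES), ] <-
    log2(.MYH_PROFILES[, .FIBER_TYPES]) + peak_boost
  for (p in proteins[prot_class == "slow-marker"])
    effect[p, names(.SLOW_GRADIENT)] <- .SLOW_GRADIENT
  for (p in proteins[prot_class == "fast-marker"])
    effect[p, names(.FAST_GRADIENT)] <- .FAST_GRADIENT

  ## peptides
  n_pep <- sample(config$peptides_per_protein[1]:config$peptides_per_protein[2],
                  length(proteins), replace = TRUE)
  pep_protein <- rep(proteins, n_pep)
  peptides <- paste0(.random_peptide(length(pep_protein)), ".",
                     sprintf("%04d", seq_along(pep_protein)))
  names(pep_protein) <- peptides
  # markers and MYH isoforms are proteotypic; background peptides mostly so
  proteo <- stats::setNames(rep(TRUE, length(peptides)), peptides)
  bg_pep <- pep_protein %in% proteins[prot_class == "background"]
  proteo[bg_pep] <- stats::runif(sum(bg_pep)) < 0.9

  prot_mean <- stats::runif(length(proteins), config$log2_mean_range[1],
                            config$log2_mean_range[2])
  names(prot_mean) <- proteins
  # peptide-level ionization efficiency offset around the protein mean
  pep_offset <- stats::rnorm(length(peptides), 0, 1)

  mu <- matrix(prot_mean[pep_protein], length(peptides), length(samples)) +
    matrix(pep_offset, length(peptides), length(samples)) +
    effect[pep_protein, types, drop = FALSE]
  dimnames(mu) <- list(peptides, samples)

  log2_complete <- mu + matrix(
    stats::rnorm(length(mu), 0, config$within_type_sd), nrow(mu), ncol(mu))

  truth <- list(fiber_type_of_sample = types,
                true_protein_class = prot_class,
                planted_panel_peptides = character(0))

  mat <- peptide_matrix(2^log2_complete, pep_protein, proteo, types)

  if (config$plant_panel) {
    mat <- plant_panel(mat, separation = config$panel_separation,
                       seed = config$seed + 1L,
                       sd = config$within_type_sd)
    truth$planted_panel_peptides <- .PANEL_PEPTIDES
    planted_log2 <- log2(mat$intensities[.PANEL_PEPTIDES, , drop = FALSE])
    log2_complete <- rbind(log2_complete, planted_log2)
  }

  ## left-censored missingness
  x <- log2(mat$intensities)
  if (config$missing_fraction > 0) {
    p_missing <- function(thr)
      stats::pnorm(config$censoring_strength * (thr - x))
    thr <- stats::uniroot(
      function(t) mean(p_missing(t)) - config$missing_fraction,
      lower = min(x) - 40 / config$censoring_strength,
      upper = max(x) + 40 / config$censoring_strength,
      tol = 1e-10)$root
    drop <- matrix(stats::runif(length(x)) < p_missing(thr),
                   nrow(x), ncol(x))
    ints <- mat$intensities
    ints[drop] <- NA_real_
    mat <- peptide_matrix(ints, mat$peptide_to_protein, mat$proteotypic,
                          mat$sample_labels)
  }

  truth$log2_complete <- log2_complete
  list(matrix = mat, truth = truth)
}

# the two panel peptides are named after well-known fast-fiber marker
# peptides of alpha-actinin-3 and myosin-1
.PANEL_PEPTIDES <- c("TINEVENQVLTR", "IAEQELLDASER")

#' Plant a two-peptide discriminative panel
#'
#' Adds two peptides mirroring the structure of a minimal fiber-type panel:
#' peptide `TINEVENQVLTR` (alpha-actinin-3-like) takes three distinct levels
#' across the fast types IIa, IIb, IIx but cannot split type I from IIa;
#' peptide `IAEQELLDASER` (myosin-1-like) separates type I from all other
#' types but nothing else. Jointly — and only jointly — the pair
#' distinguishes all four fiber types.
#'
#' @param matrix a [peptide_matrix] with fiber-type `sample_labels`
#'   covering at least 2 classes.
#' @param separation between-class mean gap in log2 units (> 0).
#' @param seed integer seed for the within-class noise.
#' @param sd within-class standard deviation of the planted peptides in log2
#'   units (default 0.4).
#' @param base_log2 log2 intensity of the lowest class level (default 22).
#' @return the input matrix with the two planted peptides appended.
#' @export
plant_panel <- function(matrix, separation, seed = 1, sd = 0.4,
                        base_log2 = 22) {
  if (!is.numeric(separation) || separation <= 0)
    stop("'separation' must be > 0")
  labels <- matrix$sample_labels
  if (is.null(labels) || length(unique(labels)) < 2)
    stop("matrix must carry fiber-type labels with >= 2 classes")
  set.seed(seed)
  s <- separation
  # log2 class means: A splits {IIa, IIb, IIx}; B splits I vs rest
  mean_a <- c(I = 0, IIa = 0, IIb = 2 * s, IIx = s) + base_log2
  mean_b <- c(I = s, IIa = 0, IIb = 0, IIx = 0) + base_log2
  lv <- function(m) m[labels] + stats::rnorm(length(labels), 0, sd)
  planted <- rbind(2^lv(mean_a), 2^lv(mean_b))
  dimnames(planted) <- list(.PANEL_PEPTIDES, colnames(matrix$intensities))

  ints <- rbind(matrix$intensities, planted)
  p2p <- c(matrix$peptide_to_protein,
           stats::setNames(c("ACTN3_SYN", "MYH1P_SYN"), .PANEL_PEPTIDES))
  proteo <- c(matrix$proteotypic,
              stats::setNames(c(TRUE, TRUE), .PANEL_PEPTIDES))
  peptide_matrix(ints, p2p, proteo, labels)
}

#' Write a simulated data set to disk
#'
#' Emits the long-format peptide TSV plus two ground-truth tables:
#' `samples.tsv` (sample_id, fiber_type) and `peptides.tsv`
#' (peptide_sequence, planted flag).
#'
#' @param sim result of [simulate_fibers].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_long_table(sim$matrix, file.path(dir, "peptides_long.tsv"))
  utils::write.table(
    data.frame(sample_id = names(sim$truth$fiber_type_of_sample),
               fiber_type = unname(sim$truth$fiber_type_of_sample)),
    file.path(dir, "samples.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(peptide_sequence = rownames(sim$matrix$intensities),
               planted = rownames(sim$matrix$intensities) %in%
                 sim$truth$planted_panel_peptides),
    file.path(dir, "peptides.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
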