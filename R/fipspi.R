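# ---- cross-validation plumbing ----------------------------------------

#' Repeated stratified k-fold cross-validation scheme
#'
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 10).
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(folds = 5, repeats = 10) {
  if (folds < 2) stop("'folds' must be >= 2")
  if (repeats < 1) stop("'repeats' must be >= 1")
  structure(list(folds = folds, repeats = repeats), class = "cv_scheme")
}

# stratified fold assignment; samples are processed in canonical (sorted)
# order so that fold membership does not depend on input row order
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# canonicalize: rows sorted by sample name, columns by peptide name, so
# accuracy estimates are invariant to input ordering under a fixed seed
.canonical_xy <- function(X, y) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%05d", seq_len(nrow(X)))
  y <- stats::setNames(factor(y), rownames(X))
  ord_r <- order(rownames(X))
  ord_c <- order(colnames(X))
  X <- X[ord_r, ord_c, drop = FALSE]
  list(X = X, y = droplevels(y[rownames(X)]))
}

.fit_forest <- function(X, y, n_trees, seed, importance = "none") {
  ranger::ranger(x = X, y = y, num.trees = n_trees, seed = seed,
                 num.threads = 1, importance = importance,
                 respect.unordered.factors = TRUE)
}

# ---- operations --------------------------------------------------------

#' Random-forest permutation importances
#'
#' Fits a seeded random-forest classifier and returns permutation
#' importances (mean decrease in out-of-bag accuracy when the feature is
#' permuted). Deterministic under a fixed seed.
#'
#' @param X numeric sample x peptide matrix of log2 intensities, no missing
#'   values (impute upstream).
#' @param y fiber-type labels, one per row of `X`; >= 2 classes with >= 2
#'   samples each.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed.
#' @return named numeric vector, peptide -> importance.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  cc <- .canonical_xy(X, y)
  if (nlevels(cc$y) < 2) stop("need >= 2 classes")
  if (any(table(cc$y) < 2)) stop("every class needs >= 2 samples")
  if (anyNA(cc$X)) stop("X must not contain missing values; impute upstream")
  fit <- .fit_forest(cc$X, cc$y, n_trees, seed, importance = "permutation")
  imp <- fit$variable.importance
  imp[colnames(X)]  # original column order
}

#' Cross-validated accuracy of a peptide panel
#'
#' Estimates the classification accuracy of a peptide panel with a
#' random-forest classifier under repeated stratified k-fold
#' cross-validation.
#'
#' @param X_panel numeric sample x peptide matrix restricted to the panel.
#' @param y fiber-type labels.
#' @param cv a [cv_scheme] (default 5 folds x 10 repeats).
#' @param seed integer seed.
#' @param n_trees forest size per fold (default 500).
#' @return list with `accuracy` (mean over folds), `fold_accuracies`,
#'   `per_class` (per-class recall pooled over all held-out predictions).
#' @export
evaluate_panel <- function(X_panel, y, cv = cv_scheme(), seed = 1,
                           n_trees = 500) {
  if (is.null(dim(X_panel)) || ncol(X_panel) < 1)
    stop("panel must be non-empty")
  cc <- .canonical_xy(X_panel, y)
  X <- cc$X; y <- cc$y
  set.seed(seed)
  fold_acc <- numeric(0)
  pooled_pred <- pooled_true <- character(0)
  for (r in seq_len(cv$repeats)) {
    fold <- .stratified_folds(y, cv$folds)
    for (k in seq_len(cv$folds)) {
      test <- fold == k
      fit <- .fit_forest(X[!test, , drop = FALSE], y[!test], n_trees,
                         seed = seed + 1000L * r + k)
      pred <- stats::predict(fit, data = X[test, , drop = FALSE])$predictions
      fold_acc <- c(fold_acc, mean(pred == y[test]))
      pooled_pred <- c(pooled_pred, as.character(pred))
      pooled_true <- c(pooled_true, as.character(y[test]))
    }
  }
  per_class <- vapply(levels(y), function(cl)
    mean(pooled_pred[pooled_true == cl] == cl), numeric(1))
  list(accuracy = mean(fold_acc), fold_accuracies = fold_acc,
       per_class = per_class)
}

#' Random-forest recursive feature elimination over peptides
#'
#' Iteratively fits a random forest, scores the current panel's accuracy by
#' cross-validation, and removes the `ceiling(drop_fraction * current)`
#' least-important peptides (at least one per round), recording the
#' (panel, accuracy) trace down to `min_panel` peptides. The selected panel
#' is the smallest whose accuracy is within `tol` of the trace maximum;
#' among ties the smaller panel wins, then lexicographic peptide order.
#'
#' @param X numeric sample x peptide matrix, no missing values.
#' @param y fiber-type labels.
#' @param drop_fraction fraction of peptides removed per round, in (0, 1)
#'   (default 0.2).
#' @param min_panel smallest panel size to descend to (default 1).
#' @param cv a [cv_scheme] used for the per-round accuracy estimates.
#' @param seed integer seed.
#' @param n_trees forest size (default 500).
#' @param tol accuracy tolerance for panel selection (default 0.005, i.e.
#'   0.5 percentage points).
#' @return object of class `panel_result`: `elimination_trace` (list of
#'   `panel`, `accuracy`), `selected_panel`, `selected_accuracy`,
#'   `importances` (from the full panel).
#' @export
rfe <- function(X, y, drop_fraction = 0.2, min_panel = 1,
                cv = cv_scheme(folds = 5, repeats = 2), seed = 1,
                n_trees = 500, tol = 0.005) {
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("'drop_fraction' must be in (0, 1)")
  if (min_panel < 1) stop("'min_panel' must be >= 1")
  if (min_panel > ncol(X))
    stop("'min_panel' exceeds the number of peptides")
  cc <- .canonical_xy(X, y)
  X <- cc$X; y <- cc$y

  panel <- colnames(X)
  trace <- list()
  full_importance <- NULL
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    Xp <- X[, panel, drop = FALSE]
    acc <- evaluate_panel(Xp, y, cv = cv, seed = seed + round_i,
                          n_trees = n_trees)$accuracy
    trace[[length(trace) + 1L]] <- list(panel = panel, accuracy = acc)
    if (length(panel) <= min_panel) break
    imp <- rf_importance(Xp, y, n_trees = n_trees, seed = seed + round_i)
    if (is.null(full_importance)) full_importance <- imp
    n_drop <- max(1L, ceiling(drop_fraction * length(panel)))
    n_drop <- min(n_drop, length(panel) - min_panel)
    # least important first; ties broken by reverse lexicographic order so
    # that the retained set is deterministic
    ord <- order(imp, rank(panel))
    panel <- sort(setdiff(panel, panel[ord[seq_len(n_drop)]]))
  }

  accs <- vapply(trace, `[[`, numeric(1), "accuracy")
  sizes <- vapply(trace, function(t) length(t$panel), integer(1))
  best <- max(accs)
  eligible <- which(accs >= best - tol)
  sel <- eligible[order(sizes[eligible], -seq_along(eligible))][1]
  structure(list(elimination_trace = trace,
                 selected_panel = sort(trace[[sel]]$panel),
                 selected_accuracy = accs[sel],
                 importances = full_importance),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  sizes <- vapply(x$elimination_trace, function(t) length(t$panel),
                  integer(1))
  accs <- vapply(x$elimination_trace, `[[`, numeric(1), "accuracy")
  cat("panel_result: recursive feature elimination trace\n")
  cat(sprintf("  %d rounds: panel sizes %d -> %d\n",
              length(sizes), sizes[1], sizes[length(sizes)]))
  cat(sprintf("  selected panel (%d peptides, accuracy %.4f):\n",
              length(x$selected_panel), x$selected_accuracy))
  cat("   ", paste(x$selected_panel, collapse = ", "), "\n")
  invisible(x)
}

# ---- the fitting function ----------------------------------------------

#' Fit a discriminative fiber-type peptide panel (FiPSPi)
#'
#' The central fitting function of the package: given log2 peptide
#' intensities and fiber-type labels it runs random-forest recursive
#' feature elimination to select a minimal discriminative peptide panel,
#' scores the panel by repeated stratified cross-validation, and builds a
#' threshold decision tree over the panel peptides as a human-readable
#' classification rule.
#'
#' @param x numeric sample x peptide matrix of log2 intensities without
#'   missing values, or a [peptide_matrix] (linear scale; log2 is taken and
#'   fully observed peptides are used).
#' @param y fiber-type labels, one per sample; taken from the
#'   `sample_labels` of a [peptide_matrix] when omitted.
#' @param drop_fraction,min_panel,n_trees,tol see [rfe].
#' @param cv_trace [cv_scheme] used during elimination (default 5 x 2).
#' @param cv [cv_scheme] used for the final panel accuracy (default 5 x 10).
#' @param min_leaf decision-tree minimum leaf size (default 1).
#' @param seed integer seed governing all randomness.
#' @return object of class `fipspi`: the [rfe] result plus
#'   `panel_accuracy` (final [evaluate_panel] estimate), `tree` (a
#'   `decision_rule` over the selected panel), the training `panel_data`
#'   and `labels`, and the matched `call`.
#' @examples
#' sim <- simulate_fibers(sim_config(n_background_proteins = 10,
#'                                   plant_panel = TRUE, missing_fraction = 0,
#'                                   seed = 42))
#' X <- t(log2(sim$matrix$intensities))
#' fit <- fipspi(X, sim$truth$fiber_type_of_sample, seed = 42)
#' print(fit)
#' @export
fipspi <- function(x, y = NULL, drop_fraction = 0.2, min_panel = 1,
                   n_trees = 500, tol = 0.005,
                   cv_trace = cv_scheme(folds = 5, repeats = 2),
                   cv = cv_scheme(folds = 5, repeats = 10),
                   min_leaf = 1, seed = 1) {
  cl <- match.call()
  if (inherits(x, "peptide_matrix")) {
    if (is.null(y)) y <- x$sample_labels
    ints <- x$intensities
    keep <- rowSums(is.na(ints)) == 0
    x <- t(log2(ints[keep, , drop = FALSE]))
  }
  if (is.null(y)) stop("fiber-type labels 'y' are required")
  y <- stats::setNames(factor(y), rownames(x))

  sel <- rfe(x, y, drop_fraction = drop_fraction, min_panel = min_panel,
             cv = cv_trace, seed = seed, n_trees = n_trees, tol = tol)
  panel <- sel$selected_panel
  Xp <- x[, panel, drop = FALSE]
  acc <- evaluate_panel(Xp, y, cv = cv, seed = seed, n_trees = n_trees)
  tree <- build_decision_tree(Xp, y, min_leaf = min_leaf)
  forest <- .fit_forest(Xp, y, n_trees, seed)

  structure(list(selected_panel = panel,
                 panel_accuracy = acc,
                 elimination_trace = sel$elimination_trace,
                 importances = sel$importances,
                 tree = tree,
                 forest = forest,
                 panel_data = Xp,
                 labels = y,
                 seed = seed,
                 call = cl),
            class = "fipspi")
}

#' @export
print.fipspi <- function(x, ...) {
  cat("FiPSPi discriminative peptide panel\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Selected panel (%d peptides): %s\n",
              length(x$selected_panel),
              paste(x$selected_panel, collapse = ", ")))
  cat(sprintf("Cross-validated accuracy: %.2f%%\n",
              100 * x$panel_accuracy$accuracy))
  invisible(x)
}

#' @export
summary.fipspi <- function(object, ...) {
  sizes <- vapply(object$elimination_trace, function(t) length(t$panel),
                  integer(1))
  accs <- vapply(object$elimination_trace, `[[`, numeric(1), "accuracy")
  structure(list(panel = object$selected_panel,
                 accuracy = object$panel_accuracy$accuracy,
                 per_class = object$panel_accuracy$per_class,
                 trace = data.frame(panel_size = sizes, accuracy = accs),
                 tree = object$tree,
                 n_samples = length(object$labels),
                 classes = table(object$labels)),
            class = "summary.fipspi")
}

#' @export
print.summary.fipspi <- function(x, ...) {
  cat("FiPSPi panel summary\n")
  cat(sprintf("  samples: %d (%s)\n", x$n_samples,
              paste(sprintf("%s: %d", names(x$classes),
                            as.integer(x$classes)), collapse = ", ")))
  cat("  elimination trace:\n")
  print(x$trace, row.names = FALSE)
  cat(sprintf("  selected panel: %s\n", paste(x$panel, collapse = ", ")))
  cat(sprintf("  accuracy: %.2f%% (per class: %s)\n", 100 * x$accuracy,
              paste(sprintf("%s %.1f%%", names(x$per_class),
                            100 * x$per_class), collapse = ", ")))
  cat("  decision rule:\n")
  print(x$tree, indent = "    ")
  invisible(x)
}

#' Classify samples with a fitted panel
#'
#' @param object a `fipspi` fit.
#' @param newdata numeric sample x peptide log2 matrix containing the panel
#'   peptides (defaults to the training data).
#' @param method `"forest"` (random forest trained on the panel) or
#'   `"tree"` (the threshold decision rule).
#' @param ... unused.
#' @return factor of predicted fiber types.
#' @export
predict.fipspi <- function(object, newdata = NULL, method = c("forest", "tree"),
                           ...) {
  method <- match.arg(method)
  if (is.null(newdata)) newdata <- object$panel_data
  missing_pep <- setdiff(object$selected_panel, colnames(newdata))
  if (length(missing_pep))
    stop("panel peptides absent from newdata: ",
         paste(missing_pep, collapse = ", "))
  Xp <- newdata[, object$selected_panel, drop = FALSE]
  if (method == "forest")
    stats::predict(object$forest, data = Xp)$predictions
  else
    predict(object$tree, Xp)
}

#' Plot the elimination trace of a FiPSPi fit
#'
#' Accuracy of each panel along the recursive elimination, on a log-scaled
#' panel-size axis, with the selected panel marked.
#'
#' @param x a `fipspi` fit.
#' @param ... passed to [graphics::plot].
#' @export
plot.fipspi <- function(x, ...) {
  sizes <- vapply(x$elimination_trace, function(t) length(t$panel),
                  integer(1))
  accs <- vapply(x$elimination_trace, `[[`, numeric(1), "accuracy")
  graphics::plot(sizes, accs, type = "b", log = "x",
                 xlab = "panel size (peptides)",
                 ylab = "cross-validated accuracy", ...)
  sel <- length(x$selected_panel)
  graphics::abline(v = sel, lty = 2, col = "grey40")
  graphics::points(sel, x$panel_accuracy$accuracy, pch = 19, col = "red3")
  invisible(x)
}
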