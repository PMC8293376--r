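#' Confirm a peptide panel on an independent data set
#'
#' Applies a fitted panel to an external, labelled data set acquired with a
#' possibly different isolation technique and MS method. Panel peptides are
#' matched by sequence string. Classes with fewer than `min_class_n`
#' samples are excluded from the evaluation (too small for meaningful
#' accuracy) and listed in the report. To absorb platform-level intensity
#' differences, each panel peptide is standardized (Z-scored) within each
#' data set before the classifier is applied; the training-side rule is
#' rebuilt on the standardized training intensities.
#'
#' @param external a [peptide_matrix] with fiber-type `sample_labels`, or a
#'   numeric sample x peptide log2 matrix plus `labels`.
#' @param panel character vector of panel peptide sequences.
#' @param rules_or_model a `fipspi` fit (its stored training data is
#'   re-standardized and the rule refit) or a `decision_rule` already built
#'   on standardized intensities.
#' @param min_class_n smallest class size admitted to the evaluation
#'   (default 4).
#' @param labels external labels, required when `external` is a matrix.
#' @param standardize set `FALSE` to apply the rule on raw log2 intensities
#'   (only sensible for same-platform data).
#' @return object of class `confirmation_report`: `mapped_peptides`,
#'   `excluded_classes`, `accuracy`, `per_class_accuracy`, `n_evaluated`,
#'   `predictions`.
#' @export
confirm_panel <- function(external, panel, rules_or_model, min_class_n = 4,
                          labels = NULL, standardize = TRUE) {
  if (inherits(external, "peptide_matrix")) {
    labels <- external$sample_labels
    X <- t(log2(external$intensities))
  } else X <- external
  if (is.null(labels)) stop("external data set must carry class labels")
  if (!is.null(names(labels)) && !is.null(rownames(X)))
    labels <- labels[rownames(X)]
  if (length(labels) != nrow(X) || anyNA(labels))
    stop("every external sample needs a class label")
  labels <- factor(labels)

  mapped <- intersect(panel, colnames(X))
  if (!length(mapped))
    stop("no panel peptide present in the external set; missing: ",
         paste(panel, collapse = ", "))

  Xp <- X[, mapped, drop = FALSE]
  if (anyNA(Xp))
    stop("panel peptides carry missing values in the external set; ",
         "impute upstream")
  zs <- function(m) scale(m)  # per-column (per-peptide, per-data-set) Z-score
  Xz <- if (standardize) zs(Xp) else Xp

  ## classifier on the (standardized) training panel
  rule <- if (inherits(rules_or_model, "fipspi")) {
    tr <- rules_or_model$panel_data[, mapped, drop = FALSE]
    build_decision_tree(if (standardize) zs(tr) else tr,
                        rules_or_model$labels)
  } else if (inherits(rules_or_model, "decision_rule")) {
    rules_or_model
  } else stop("'rules_or_model' must be a fipspi fit or a decision_rule")

  sizes <- table(labels)
  excluded <- names(sizes)[sizes < min_class_n]
  keep <- !labels %in% excluded
  if (length(unique(labels[keep])) < 2)
    stop("fewer than 2 classes remain after the class-size exclusion")

  pred <- predict(rule, Xz[keep, , drop = FALSE])
  truth <- droplevels(labels[keep])
  per_class <- vapply(levels(truth), function(cl)
    mean(as.character(pred)[truth == cl] == cl), numeric(1))
  structure(list(mapped_peptides = mapped,
                 excluded_classes = excluded,
                 accuracy = mean(as.character(pred) == as.character(truth)),
                 per_class_accuracy = per_class,
                 n_evaluated = sum(keep),
                 predictions = stats::setNames(as.character(pred),
                                               rownames(Xz)[keep])),
            class = "confirmation_report")
}

#' @export
print.confirmation_report <- function(x, ...) {
  cat("confirmation_report: independent-data panel validation\n")
  cat(sprintf("  mapped peptides: %s\n",
              paste(x$mapped_peptides, collapse = ", ")))
  if (length(x$excluded_classes))
    cat(sprintf("  excluded classes (< min_class_n samples): %s\n",
                paste(x$excluded_classes, collapse = ", ")))
  cat(sprintf("  accuracy: %.1f%% over %d samples\n", 100 * x$accuracy,
              x$n_evaluated))
  cat("  per class:",
      paste(sprintf("%s %.1f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a panel report as plain text (JSON)
#'
#' @param fit a `fipspi` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(fit, path) {
  sizes <- vapply(fit$elimination_trace, function(t) length(t$panel),
                  integer(1))
  accs <- vapply(fit$elimination_trace, `[[`, numeric(1), "accuracy")
  lines <- c(
    "{",
    sprintf('  "selected_panel": [%s],',
            paste(sprintf('"%s"', fit$selected_panel), collapse = ", ")),
    sprintf('  "accuracy": %.6f,', fit$panel_accuracy$accuracy),
    '  "trace": [',
    paste(sprintf('    {"panel_size": %d, "accuracy": %.6f}%s',
                  sizes, accs,
                  c(rep(",", length(sizes) - 1), "")), collapse = "\n"),
    "  ]",
    "}")
  writeLines(lines, path)
  invisible(path)
}
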