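# recursive greedy CART on 1-3 features; thresholds at the midpoint
# between the two class-boundary-adjacent training values

.gini <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

.best_split <- function(X, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- y[ord]
    uq <- unique(vs)
    if (length(uq) < 2) next
    # candidate thresholds: midpoints between consecutive distinct values
    for (i in seq_len(length(uq) - 1)) {
      thr <- (uq[i] + uq[i + 1]) / 2
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      g <- (nl * .gini(y[left]) + (n - nl) * .gini(y[!left])) / n
      if (is.null(best) || g < best$gini - 1e-12) {
        best <- list(feature = colnames(X)[j], threshold = thr, gini = g,
                     left = left)
      }
    }
  }
  best
}

.grow_tree <- function(X, y, min_leaf, depth = 0) {
  counts <- table(y)
  if (length(unique(y)) == 1 || nrow(X) < 2 * min_leaf) {
    return(list(leaf = TRUE,
                label = names(counts)[which.max(counts)],
                counts = counts))
  }
  split <- .best_split(X, y, min_leaf)
  if (is.null(split) || split$gini >= .gini(y) - 1e-12) {
    # no impurity-reducing split (e.g. identical samples, different labels):
    # report the impure leaf rather than erroring
    return(list(leaf = TRUE,
                label = names(counts)[which.max(counts)],
                counts = counts))
  }
  list(leaf = FALSE, feature = split$feature, threshold = split$threshold,
       left = .grow_tree(X[split$left, , drop = FALSE], y[split$left],
                         min_leaf, depth + 1),
       right = .grow_tree(X[!split$left, , drop = FALSE], y[!split$left],
                          min_leaf, depth + 1))
}

#' Build a threshold decision tree over a peptide panel
#'
#' Constructs a human-readable classification rule from a small peptide
#' panel (designed for the two-peptide case, accepted for 1-3): CART-style
#' greedy binary splits minimizing Gini impurity, with every threshold
#' placed at the midpoint between the two class-boundary-adjacent training
#' intensities. On class-separable training data every terminal node is
#' pure; degenerate inputs (identical samples, different labels) yield an
#' impure leaf, not an error.
#'
#' @param X_panel numeric sample x peptide log2 matrix, 1-3 columns.
#' @param y fiber-type labels.
#' @param min_leaf minimum samples per leaf (default 1); must not exceed
#'   the smallest class.
#' @return object of class `decision_rule`: nested node list, each internal
#'   node `(feature, threshold, left, right)` with the `<=` branch on the
#'   left, each leaf carrying the majority `label` and class `counts`.
#' @export
build_decision_tree <- function(X_panel, y, min_leaf = 1) {
  if (is.null(dim(X_panel))) X_panel <- cbind(peptide = X_panel)
  if (ncol(X_panel) > 3)
    stop("decision rules are built over panels of 1-3 peptides")
  y <- factor(y)
  if (min_leaf > min(table(y)))
    stop("'min_leaf' exceeds the smallest class size")
  if (is.null(colnames(X_panel)))
    colnames(X_panel) <- paste0("peptide", seq_len(ncol(X_panel)))
  root <- .grow_tree(X_panel, y, min_leaf)
  structure(list(root = root, panel = colnames(X_panel),
                 classes = levels(y)),
            class = "decision_rule")
}

.predict_node <- function(node, x) {
  if (node$leaf) return(node$label)
  if (x[[node$feature]] <= node$threshold)
    .predict_node(node$left, x)
  else .predict_node(node$right, x)
}

#' @export
predict.decision_rule <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  missing_pep <- setdiff(object$panel, colnames(newdata))
  if (length(missing_pep))
    stop("panel peptides absent from newdata: ",
         paste(missing_pep, collapse = ", "))
  out <- vapply(seq_len(nrow(newdata)), function(i)
    .predict_node(object$root, as.list(newdata[i, , drop = TRUE])),
    character(1))
  factor(out, levels = object$classes)
}

.format_node <- function(node, indent) {
  if (node$leaf) {
    cnt <- paste(sprintf("%s:%d", names(node$counts),
                         as.integer(node$counts)), collapse = " ")
    purity <- if (sum(node$counts > 0) == 1) "pure" else "IMPURE"
    return(sprintf("%s-> type %s  [%s; %s]", indent, node$label, cnt, purity))
  }
  c(sprintf("%sif %s <= %.4g:", indent, node$feature, node$threshold),
    .format_node(node$left, paste0(indent, "  ")),
    sprintf("%selse:", indent),
    .format_node(node$right, paste0(indent, "  ")))
}

#' @export
print.decision_rule <- function(x, indent = "", ...) {
  cat(paste(.format_node(x$root, indent), collapse = "\n"), "\n")
  invisible(x)
}

#' Flatten a decision rule into a node table
#'
#' Machine-readable serialization: one row per node with parent linkage,
#' split feature and threshold for internal nodes, label and class counts
#' for leaves.
#'
#' @param rule a `decision_rule`.
#' @return data.frame with columns `node`, `parent`, `side`, `type`,
#'   `feature`, `threshold`, `label`, `counts`.
#' @export
decision_rule_table <- function(rule) {
  rows <- list()
  walk <- function(node, parent, side) {
    id <- length(rows) + 1L
    rows[[id]] <<- data.frame(
      node = id, parent = parent, side = side,
      type = if (node$leaf) "leaf" else "split",
      feature = if (node$leaf) NA_character_ else node$feature,
      threshold = if (node$leaf) NA_real_ else node$threshold,
      label = if (node$leaf) node$label else NA_character_,
      counts = if (node$leaf)
        paste(sprintf("%s:%d", names(node$counts),
                      as.integer(node$counts)), collapse = ";")
      else NA_character_,
      stringsAsFactors = FALSE)
    if (!node$leaf) {
      walk(node$left, id, "<=")
      walk(node$right, id, ">")
    }
  }
  walk(rule$root, NA_integer_, NA_character_)
  do.call(rbind, rows)
}

# all leaves of a rule (used by tests and reports)
.rule_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(.rule_leaves(node$left), .rule_leaves(node$right))
}

#' Are all terminal nodes of a decision rule pure?
#'
#' @param rule a `decision_rule`.
#' @return `TRUE` when every leaf holds samples of a single class.
#' @export
leaves_pure <- function(rule) {
  all(vapply(.rule_leaves(rule$root),
             function(l) sum(l$counts > 0) == 1, logical(1)))
}
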