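#' Percentage error for one group
#'
#' The percentage ratio of misclassified samples to the total number of
#' samples in one group: 100 * misclassified / group_size.
#'
#' @param misclassified count of misclassified samples in the group.
#' @param group_size total samples in the group (> 0).
#' @return Numeric percentage in \[0, 100\].
#' @export
percent_error <- function(misclassified, group_size) {
  if (group_size <= 0) stop("input error: group_size must be positive")
  if (misclassified < 0 || misclassified > group_size)
    stop("input error: misclassified must be in [0, group_size]")
  100 * misclassified / group_size
}

# Standardize columns to zero mean / unit variance; a constant column (sd 0)
# becomes all zeros so it cannot dominate the distance.
standardize_columns <- function(x) {
  apply(x, 2L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
}

#' Unsupervised classification in the 3-feature space
#'
#' Each ROI is a point in a space of three selected feature coordinates.
#' Features are standardized per column, partitioned into two clusters by
#' k-means (10 restarts under a fixed seed), and clusters are mapped to the
#' C/F classes by the assignment that minimizes the total number of
#' misclassified samples (equivalently, majority label overlap; ties resolved
#' toward the first mapping). Labels are used only for this scoring step,
#' never by the clustering itself. A supervised leave-one-out 1-nearest-
#' neighbour mode is available for sensitivity analysis.
#'
#' If all points are identical the partition degenerates to a single cluster
#' and the minority group scores 100% error.
#'
#' @param table a [feature_table] restricted to exactly 3 feature columns, or
#'   a numeric matrix/data frame of 3 columns plus `labels`.
#' @param labels class labels (taken from the table when omitted).
#' @param seed integer seed controlling the k-means restarts (default 0).
#' @param method `"kmeans"` (unsupervised, default) or `"1nn-loo"`.
#' @return A list of class `classification_result`: `error` (named percent
#'   error per group), `confusion` (2 x 2 table, true class x assigned),
#'   `assigned`, `cluster`, `mapping`, `seed`, `method`.
#' @export
classify_unsupervised <- function(table, labels = NULL, seed = 0L,
                                  method = c("kmeans", "1nn-loo")) {
  method <- match.arg(method)
  if (inherits(table, "feature_table")) {
    if (is.null(labels)) labels <- table$label
    x <- as.matrix(table[, feature_columns(table), drop = FALSE])
  } else {
    x <- as.matrix(table)
  }
  if (ncol(x) != 3L) stop("exactly 3 feature columns required")
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2L) stop("two classes must be present")
  z <- standardize_columns(x)

  if (method == "kmeans") {
    distinct <- nrow(unique(z))
    if (distinct < 2L) {
      cluster <- rep(1L, nrow(z))
    } else {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      cluster <- stats::kmeans(z, centers = 2L, nstart = 10L, iter.max = 100L)$cluster
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
    # two possible cluster -> class mappings
    maps <- list(stats::setNames(groups, 1:2), stats::setNames(rev(groups), 1:2))
    errs <- vapply(maps, function(mp) sum(mp[cluster] != labels), numeric(1))
    mapping <- maps[[which.min(errs)]]
    assigned <- unname(mapping[cluster])
  } else {
    d <- as.matrix(stats::dist(z))
    diag(d) <- Inf
    assigned <- labels[apply(d, 1L, which.min)]
    cluster <- match(assigned, groups)
    mapping <- stats::setNames(groups, 1:2)
  }

  confusion <- table(factor(labels, groups), factor(assigned, groups),
                     dnn = c("true", "assigned"))
  err <- vapply(groups, function(g) {
    percent_error(sum(labels == g & assigned != g), sum(labels == g))
  }, numeric(1))
  structure(list(error = err, confusion = confusion, assigned = assigned,
                 cluster = cluster, mapping = mapping, seed = seed,
                 method = method),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> method=%s seed=%d\n", x$method, x$seed))
  cat(sprintf("  %% error: %s\n",
              paste(names(x$error), sprintf("%.1f", x$error), collapse = "  ")))
  invisible(x)
}
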