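#' Build a feature table
#'
#' One row per ROI sample: `sample_id`, `label` (C or F), then one column per
#' named texture parameter. Tags recording the provenance cell (scheme,
#' resolution, method) are carried as attributes.
#'
#' @param sample_id character vector of sample identifiers.
#' @param label class labels, `"C"` or `"F"`.
#' @param features numeric matrix or data frame, one named column per
#'   parameter; no missing values allowed.
#' @param scheme,resolution,method optional provenance tags.
#' @return A data frame of class `feature_table`.
#' @export
feature_table <- function(sample_id, label, features,
                          scheme = NA_character_, resolution = NA_character_,
                          method = NA_character_) {
  features <- as.data.frame(features, check.names = FALSE)
  if (anyNA(features)) stop("feature table must not contain missing values")
  if (length(sample_id) != nrow(features) || length(label) != nrow(features))
    stop("sample_id, label and features must have matching length")
  if (!all(label %in% c("C", "F"))) stop("labels must be 'C' or 'F'")
  out <- cbind(data.frame(sample_id = sample_id, label = label,
                          stringsAsFactors = FALSE), features)
  structure(out, scheme = scheme, resolution = resolution, method = method,
            class = c("feature_table", "data.frame"))
}

feature_columns <- function(tab) setdiff(names(tab), c("sample_id", "label"))

#' Pool per-channel feature tables into a scheme
#'
#' Parameters calculated from one texture method on the channels of a scheme
#' are pooled together as one set of descriptors: horizontal concatenation
#' with channel-prefixed column names (`R_`/`G_`/`B_` for the RGB scheme,
#' `H_`/`S_`/`I_` for HSI; the grey-level scheme keeps unprefixed names).
#'
#' @param per_channel_tables named list of [feature_table]s, one per channel,
#'   sharing sample order and labels; names are the channel tags.
#' @param scheme scheme tag: `"greylevel"`, `"RGB"` or `"HSI"`.
#' @return A pooled [feature_table].
#' @export
pool_scheme <- function(per_channel_tables, scheme) {
  stopifnot(length(per_channel_tables) >= 1L)
  ref <- per_channel_tables[[1L]]
  for (tab in per_channel_tables[-1L]) {
    if (!identical(tab$sample_id, ref$sample_id) ||
        !identical(tab$label, ref$label))
      stop("alignment error: channel tables have mismatched samples or labels")
  }
  blocks <- lapply(names(per_channel_tables), function(ch) {
    tab <- per_channel_tables[[ch]]
    f <- tab[, feature_columns(tab), drop = FALSE]
    if (!identical(ch, "grey") && scheme != "greylevel")
      names(f) <- paste0(ch, "_", names(f))
    f
  })
  feature_table(ref$sample_id, ref$label, do.call(cbind, blocks),
                scheme = scheme, resolution = attr(ref, "resolution"),
                method = attr(ref, "method"))
}

#' Fisher coefficient of one parameter
#'
#' Two-class separability ratio F = (m_C - m_F)^2 / (v_C + v_F) with class
#' means m and unbiased sample variances v. A higher F means the classes are
#' more separable along this parameter. Zero within-class variance with
#' differing means yields `Inf`; identical values everywhere yield 0.
#'
#' @param values numeric vector, one value per sample.
#' @param labels two-level class labels aligned with `values`; each class
#'   needs at least 2 samples.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
fisher_coefficient <- function(values, labels) {
  labels <- as.character(labels)
  cls <- unique(labels)
  if (length(cls) != 2L) stop("input error: exactly two classes required")
  a <- values[labels == cls[1L]]; b <- values[labels == cls[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("input error: each class needs at least 2 samples")
  num <- (mean(a) - mean(b))^2
  den <- stats::var(a) + stats::var(b)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Rank parameters by Fisher coefficient and keep the top k
#'
#' Ranks every feature column of the table by [fisher_coefficient] and
#' returns the k most discriminating parameters (default 3, the number used
#' for class separation). Ties are broken by column order (first computed
#' wins), making the selection deterministic. As a guard against classifier
#' over-performance, k may not exceed the smaller class size.
#'
#' @param table a [feature_table] with two classes present.
#' @param k number of features to keep (default 3).
#' @return Data frame of class `fisher_ranking` with columns `rank`,
#'   `feature`, `F`, ordered by non-increasing F.
#' @export
select_top <- function(table, k = 3L) {
  feats <- feature_columns(table)
  if (length(feats) < k) stop("input error: fewer than k feature columns")
  if (k > min(table(table$label)))
    stop("input error: k exceeds the smaller class size")
  f <- vapply(feats, function(cn) fisher_coefficient(table[[cn]], table$label),
              numeric(1))
  ord <- order(-f)                      # stable: ties keep column order
  sel <- ord[seq_len(k)]
  structure(data.frame(rank = seq_len(k), feature = feats[sel], F = f[sel],
                       stringsAsFactors = FALSE),
            scheme = attr(table, "scheme"), resolution = attr(table, "resolution"),
            method = attr(table, "method"),
            class = c("fisher_ranking", "data.frame"))
}
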