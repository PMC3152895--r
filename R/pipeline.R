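scheme_channels <- list(greylevel = "grey",
                        RGB = c("R", "G", "B"),
                        HSI = c("H", "S", "I"))

resolution_factors <- c(full = 1L, half = 2L, quarter = 4L)

# Per-method feature vector of one normalized channel ROI.
channel_method_features <- function(nroi, method) {
  switch(method,
    COM = com_features(compute_com(nroi)),
    RLM = rlm_all_directions(nroi),
    WT  = {
      e <- wavelet_energies(nroi)
      stats::setNames(as.numeric(e), names(e))
    },
    stop("unknown method: ", method))
}

#' Per-channel feature tables for a set of ROIs
#'
#' Normalizes each requested channel of each ROI and computes the texture
#' parameters of each method. The workhorse behind [run_experiment], exposed
#' for feature dumps and custom analyses.
#'
#' @param rois list of multi-channel `roi` objects (see [extract_rois]).
#' @param channels channel tags to analyze.
#' @param methods subset of `"COM"`, `"RLM"`, `"WT"`.
#' @param resolution resolution tag recorded on the tables.
#' @return Nested list `tables[[channel]][[method]]` of [feature_table]s.
#' @export
compute_feature_tables <- function(rois,
                                   channels = c("grey", "R", "G", "B", "H", "S", "I"),
                                   methods = c("COM", "RLM", "WT"),
                                   resolution = NA_character_) {
  ids <- vapply(rois, function(r) sprintf("%s_roi%d", r$parent_id, r$position),
                character(1))
  labels <- vapply(rois, function(r) r$label, character(1))
  rows <- lapply(rois, function(r) {
    chs <- analysis_channels(r$pixels, channels)
    lapply(chs, function(ch) {
      nroi <- normalize_roi(ch)
      lapply(stats::setNames(methods, methods), function(mth)
        channel_method_features(nroi, mth))
    })
  })
  out <- lapply(stats::setNames(channels, channels), function(ch) {
    lapply(stats::setNames(methods, methods), function(mth) {
      feats <- do.call(rbind, lapply(rows, function(rr) rr[[ch]][[mth]]))
      feature_table(ids, labels, feats, resolution = resolution, method = mth)
    })
  })
  out
}

#' Run the full color-space / resolution / texture-method experiment grid
#'
#' For each resolution (full, half, quarter): reduces the images, extracts
#' the 4 ROIs per image, builds the channel views needed by the requested
#' schemes, normalizes each channel ROI, computes the texture parameters of
#' each method, pools them per scheme, selects the top-3 Fisher features per
#' (scheme, resolution, method) cell, classifies the ROIs unsupervised in
#' the 3-feature space, and records the per-group percentage errors together
#' with the selected feature names. A failing cell is skipped with a warning;
#' the remaining cells proceed.
#'
#' @param images list of labeled [rgb_image]s (at least 2 per class), e.g.
#'   `generate_dataset(config)$images`.
#' @param schemes subset of `"greylevel"`, `"RGB"`, `"HSI"`.
#' @param resolutions subset of `"full"`, `"half"`, `"quarter"`.
#' @param methods subset of `"COM"`, `"RLM"`, `"WT"`.
#' @param margin ROI border margin fraction (default 0.05).
#' @param k number of Fisher-selected features per cell (default 3).
#' @param seed integer seed for the classifier restarts.
#' @param classifier `"kmeans"` or `"1nn-loo"` (see [classify_unsupervised]).
#' @return A list of class `experiment_result`: `errors` (data frame with one
#'   row per scheme x resolution x method x group: the percentage-error
#'   table), `features` (data frame of selected features per cell with their
#'   Fisher coefficients), and `seed`.
#' @export
run_experiment <- function(images,
                           schemes = c("greylevel", "RGB", "HSI"),
                           resolutions = c("full", "half", "quarter"),
                           methods = c("COM", "RLM", "WT"),
                           margin = 0.05, k = 3L, seed = 0L,
                           classifier = "kmeans") {
  schemes <- match.arg(schemes, several.ok = TRUE)
  resolutions <- match.arg(resolutions, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- vapply(images, function(im) im$label, character(1))
  if (sum(labels == "C") < 2L || sum(labels == "F") < 2L)
    stop("input error: at least 2 images per class required")
  channels <- unique(unlist(scheme_channels[schemes]))
  err_rows <- list(); feat_rows <- list()
  for (res in resolutions) {
    reduced <- lapply(images, reduce_resolution, factor = resolution_factors[[res]])
    rois <- unlist(lapply(reduced, extract_rois, margin = margin),
                   recursive = FALSE)
    tables <- compute_feature_tables(rois, channels, methods, resolution = res)
    for (sch in schemes) {
      for (mth in methods) {
        cell <- sprintf("%s/%s/%s", sch, res, mth)
        result <- tryCatch({
          pooled <- pool_scheme(
            lapply(stats::setNames(scheme_channels[[sch]], scheme_channels[[sch]]),
                   function(ch) tables[[ch]][[mth]]),
            scheme = sch)
          ranking <- select_top(pooled, k = k)
          sel <- pooled[, c("sample_id", "label", ranking$feature)]
          cls <- classify_unsupervised(
            feature_table(sel$sample_id, sel$label,
                          sel[, ranking$feature, drop = FALSE]),
            seed = seed, method = classifier)
          list(ranking = ranking, cls = cls)
        }, error = function(e) {
          warning("cell ", cell, " failed: ", conditionMessage(e), call. = FALSE)
          NULL
        })
        if (is.null(result)) next
        err_rows[[cell]] <- data.frame(
          scheme = sch, resolution = res, method = mth,
          group = names(result$cls$error), error = unname(result$cls$error),
          stringsAsFactors = FALSE)
        feat_rows[[cell]] <- cbind(
          data.frame(scheme = sch, resolution = res, method = mth,
                     stringsAsFactors = FALSE),
          result$ranking)
      }
    }
  }
  errors <- do.call(rbind, c(err_rows, list(make.row.names = FALSE)))
  features <- do.call(rbind, c(feat_rows, list(make.row.names = FALSE)))
  structure(list(errors = errors, features = features, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  wide <- stats::reshape(x$errors, idvar = c("scheme", "resolution", "method"),
                         timevar = "group", direction = "wide")
  names(wide) <- sub("^error\\.", "% error ", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
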