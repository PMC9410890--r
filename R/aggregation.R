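#' Receiver-operator characteristic curve for the CV aggregate score
#'
#' Sweeps every distinct CV value as a candidate threshold under the rule
#' "score >= threshold implies aggregated" (tied scores therefore move in a
#' single step), records the (false-positive rate, true-positive rate) pair
#' at each, and computes the area under the curve by the trapezoid rule.
#' The curve always passes through (0, 0) (threshold above every score) and
#' (1, 1) (threshold equal to the minimum score).
#'
#' @param cv Numeric vector of CV scores (finite, non-negative).
#' @param label Labels aligned with `cv`: factor or character with values
#'   `"aggregated"` (positive class) and `"diffuse"`.
#' @return An object of class `roc_curve`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, ordered by increasing threshold, the final
#'   row at threshold `Inf`) and `auc`.
#' @export
roc_curve <- function(cv, label) {
  label <- as.character(label)
  stopifnot(length(cv) == length(label),
            all(label %in% c("aggregated", "diffuse")))
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("all CV scores must be finite and non-negative")
  }
  pos <- cv[label == "aggregated"]
  neg <- cv[label == "diffuse"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("ROC requires both an aggregated and a diffuse class")
  }
  thr <- c(sort(unique(cv)), Inf)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  pts <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  # trapezoid AUC over the curve traced from (0,0) to (1,1)
  ord <- order(pts$fpr, pts$tpr)
  fx <- pts$fpr[ord]; fy <- pts$tpr[ord]
  auc <- sum(diff(fx) * (fy[-1] + fy[-length(fy)]) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' Youden-optimal threshold from an ROC curve
#'
#' Returns the candidate threshold maximizing Youden's J = TPR - FPR, with
#' ties broken toward the larger (more specific) threshold. Only finite
#' candidate thresholds (observed scores) are considered unless the curve
#' is degenerate.
#'
#' @param roc An object from [roc_curve()].
#' @return The selected CV threshold.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) pts <- roc$points
  j <- pts$tpr - pts$fpr
  max(pts$threshold[j >= max(j) - 1e-12])
}

#' Classify ROIs as aggregated or diffuse by CV
#'
#' An ROI is called aggregated iff its CV is greater than or equal to the
#' threshold (a CV exactly at the threshold counts as aggregated; the
#' boundary convention is fixed so calls are bit-reproducible).
#'
#' @param cv Numeric vector of CV scores; `NA` (undefined CV) is an error.
#' @param threshold CV threshold (default 1.0, the calibrated operating
#'   point).
#' @return Factor with levels `diffuse`, `aggregated`.
#' @export
classify_roi <- function(cv, threshold = 1.0) {
  if (any(is.na(cv))) {
    stop("undefined CV: cannot classify an ROI without a valid CV")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  factor(ifelse(cv >= threshold, "aggregated", "diffuse"),
         levels = c("diffuse", "aggregated"))
}

#' Per-neuron aggregate status from per-ROI calls
#'
#' A neuron is called aggregate-bearing iff the ROI of any live timepoint
#' is called aggregated (CV >= threshold). Live timepoints are those before
#' the called death interval (all observed timepoints for censored
#' neurons). ROIs with undefined CV are skipped; a neuron with no usable
#' live ROI is excluded (`call = NA`) and flagged in `n_usable`.
#'
#' @param tracks Long-format track table from [link_tracks()].
#' @param deaths Per-track table from [call_death()].
#' @param threshold CV threshold (default 1.0).
#' @return Data frame with one row per track: `track_id`, `n_live`,
#'   `n_usable`, `aggregated` (logical, `NA` if no usable ROI).
#' @export
classify_neurons <- function(tracks, deaths, threshold = 1.0) {
  out <- vector("list", nrow(deaths))
  for (k in seq_len(nrow(deaths))) {
    d <- deaths[k, ]
    if (!isTRUE(d$has_t1)) {
      out[[k]] <- data.frame(track_id = d$track_id, n_live = 0L,
                             n_usable = 0L, aggregated = NA)
      next
    }
    tr <- tracks[tracks$track_id == d$track_id, ]
    live <- if (is.na(d$death_interval)) tr else
      tr[tr$timepoint < d$death_interval, ]
    usable <- live$cv[!is.na(live$cv)]
    out[[k]] <- data.frame(
      track_id = d$track_id, n_live = nrow(live),
      n_usable = length(usable),
      aggregated = if (length(usable)) any(usable >= threshold) else NA)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sensitivity and specificity of aggregate calls
#'
#' Sensitivity = TP / (TP + FN) over truly aggregated ROIs; specificity =
#' TN / (TN + FP) over truly diffuse ROIs.
#'
#' @param calls Factor/character of calls (`aggregated` / `diffuse`).
#' @param labels True labels, aligned with `calls`, same coding.
#' @return List with `sensitivity` and `specificity` (fractions in
#'   `[0, 1]`).
#' @export
confusion_metrics <- function(calls, labels) {
  calls <- as.character(calls)
  labels <- as.character(labels)
  stopifnot(length(calls) == length(labels),
            all(calls %in% c("aggregated", "diffuse")),
            all(labels %in% c("aggregated", "diffuse")))
  npos <- sum(labels == "aggregated")
  nneg <- sum(labels == "diffuse")
  if (npos == 0L || nneg == 0L) {
    stop("confusion_metrics requires both classes among the true labels")
  }
  list(sensitivity = sum(calls == "aggregated" &
                           labels == "aggregated") / npos,
       specificity = sum(calls == "diffuse" & labels == "diffuse") / nneg)
}

#' Calibrate the CV classifier on a labelled ROI set
#'
#' Convenience wrapper reproducing the published calibration procedure:
#' build the ROC over a labelled validation set, select the Youden
#' threshold, and report the operating characteristics of the applied
#' threshold (default 1.0).
#'
#' @param labeled A `labeled_roiset` (or any data frame with columns `cv`
#'   and `true_label`).
#' @param threshold Threshold whose sensitivity/specificity are reported
#'   (default 1.0).
#' @return List with `roc`, `auc`, `threshold_selected` (Youden),
#'   `threshold_applied`, `sensitivity`, `specificity`, `n`.
#' @export
calibrate_classifier <- function(labeled, threshold = 1.0) {
  stopifnot(all(c("cv", "true_label") %in% names(labeled)))
  ok <- !is.na(labeled$cv)
  lab <- labeled[ok, ]
  roc <- roc_curve(lab$cv, lab$true_label)
  calls <- classify_roi(lab$cv, threshold)
  cm <- confusion_metrics(calls, lab$true_label)
  list(roc = roc, auc = roc$auc,
       threshold_selected = youden_threshold(roc),
       threshold_applied = threshold,
       sensitivity = cm$sensitivity, specificity = cm$specificity,
       n = nrow(lab))
}
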