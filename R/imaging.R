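#' Subtract a scalar background estimate from a frame
#'
#' The background of a sparsely populated fluorescence frame is estimated
#' as the global median of all pixels (robust as long as somata occupy less
#' than half the frame) and subtracted, clipping at zero.
#'
#' @param frame Numeric matrix of finite, non-negative intensities.
#' @return Matrix of the same shape, background-subtracted and clipped at 0.
#' @export
subtract_background <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop("frame must be a numeric matrix")
  }
  if (any(!is.finite(frame)) || any(frame < 0)) {
    stop("frame must be finite and non-negative")
  }
  pmax(frame - median(frame), 0)
}

#' Coefficient of variation of an ROI's reporter intensities
#'
#' CV is the ratio of the standard deviation to the mean intensity across
#' the ROI's pixels, using the population (divide-by-N) standard deviation.
#' It is dimensionless, invariant under multiplication by a positive gain,
#' zero iff the ROI is uniform, and is the sole score used to call
#' aggregates (threshold 1.0).
#'
#' @param values Numeric vector of background-subtracted reporter
#'   intensities (at least 2 pixels, positive mean).
#' @return The CV (non-negative scalar).
#' @export
compute_cv <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
    stop("CV requires at least 2 finite pixel values")
  }
  m <- mean(values)
  if (m <= 0) {
    stop("undefined CV: ROI mean intensity is not positive")
  }
  sd_pop(values) / m
}

cv_or_na <- function(values) {
  m <- mean(values)
  if (length(values) < 2L || m <= 0) return(NA_real_)
  sd_pop(values) / m
}

#' Segment somata in one frame
#'
#' Background-subtracts the tracking frame, thresholds it with Otsu's
#' method, labels 4-connected components, and keeps components with
#' `min_area <= area <= max_area`. Two somata closer than one pixel merge
#' into a single component (documented behaviour; the generator's placement
#' separation makes this rare). Reporter statistics (mean, population sd,
#' CV) are computed on the background-subtracted reporter frame over the
#' same pixel set; the CV is `NA` when the ROI's reporter mean is not
#' positive.
#'
#' @param tracking_frame Numeric matrix: the tracking (cell fill) channel.
#' @param reporter_frame Optional numeric matrix of the same shape: the
#'   reporter channel. If `NULL`, reporter statistics are `NA`.
#' @param min_area,max_area Area filter in pixels.
#' @param return_pixels If `TRUE`, attach the per-ROI pixel coordinate
#'   lists (2-column matrices of 0-based `x`, `y`) as attribute `"pixels"`.
#' @return Data frame with one row per ROI: `roi_id`, `x`, `y` (0-based
#'   centroid: `x` = column, `y` = row), `area`, `mean`, `sd`, `cv`
#'   (reporter), `tracking_mean`. An empty frame yields zero rows.
#' @export
segment_frame <- function(tracking_frame, reporter_frame = NULL,
                          min_area = 30, max_area = 400,
                          return_pixels = FALSE) {
  bt <- subtract_background(tracking_frame)
  br <- if (is.null(reporter_frame)) NULL else
    subtract_background(reporter_frame)
  if (!is.null(br) && !identical(dim(bt), dim(br))) {
    stop("tracking and reporter frames must have the same shape")
  }
  empty <- data.frame(roi_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), mean = numeric(0), sd = numeric(0),
                      cv = numeric(0), tracking_mean = numeric(0))
  mx <- max(bt)
  if (mx <= 0) return(empty)
  thr <- EBImage::otsu(EBImage::Image(bt / mx), range = c(0, 1)) * mx
  lab <- EBImage::bwlabel(bt > thr)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  labv <- as.integer(lab)
  keep <- labv > 0L
  labv <- labv[keep]
  idx <- which(keep)
  nr <- nrow(bt)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- tabulate(labv, nbins = nlab)
  ok <- which(area >= min_area & area <= max_area)
  if (length(ok) == 0L) return(empty)
  res <- vector("list", length(ok))
  pixels <- if (return_pixels) vector("list", length(ok)) else NULL
  for (j in seq_along(ok)) {
    l <- ok[j]
    sel <- labv == l
    r <- rows[sel]; cc <- cols[sel]
    tvals <- bt[cbind(r, cc)]
    if (is.null(br)) {
      m <- s <- cv <- NA_real_
    } else {
      rv <- br[cbind(r, cc)]
      m <- mean(rv); s <- sd_pop(rv); cv <- cv_or_na(rv)
    }
    res[[j]] <- data.frame(roi_id = j, x = mean(cc) - 1, y = mean(r) - 1,
                           area = area[l], mean = m, sd = s, cv = cv,
                           tracking_mean = mean(tvals))
    if (return_pixels) pixels[[j]] <- cbind(x = cc - 1L, y = r - 1L)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (return_pixels) attr(out, "pixels") <- pixels
  out
}

#' Segment every timepoint of a movie
#'
#' @param movie A `movie` object (see [render_movie()] / [read_movie()]).
#' @param ... Passed to [segment_frame()].
#' @return A list (one element per timepoint) of ROI data frames.
#' @export
segment_movie <- function(movie, ...) {
  stopifnot(inherits(movie, "movie"))
  tp <- dim(movie$pixels)[4]
  lapply(seq_len(tp), function(t) {
    segment_frame(movie$pixels[, , 1, t], movie$pixels[, , 2, t], ...)
  })
}

#' Link per-timepoint ROIs into neuron tracks
#'
#' Links ROIs between consecutive timepoints by greedy mutual
#' nearest-neighbour matching: candidate pairs are linked in order of
#' increasing centroid distance (ties broken by smaller ROI id, then
#' smaller track id), subject to distance `<= max_displacement`, each ROI
#' used at most once. Only ROIs present at timepoint 1 seed tracks;
#' unmatched later ROIs start no new track, and a track that misses a
#' timepoint is retired (no gap closing).
#'
#' @param rois_by_timepoint List of ROI data frames as produced by
#'   [segment_movie()], one per timepoint in order.
#' @param max_displacement Maximum allowed centroid displacement (pixels)
#'   between consecutive timepoints.
#' @return Long-format data frame: `track_id`, `timepoint`, `roi_id`, `x`,
#'   `y`, `area`, `mean`, `sd`, `cv`, `tracking_mean`.
#' @export
link_tracks <- function(rois_by_timepoint, max_displacement = 15) {
  stopifnot(is.list(rois_by_timepoint), length(rois_by_timepoint) >= 1L,
            max_displacement > 0)
  tp1 <- rois_by_timepoint[[1]]
  if (nrow(tp1) == 0L) {
    return(data.frame(track_id = integer(0), timepoint = integer(0),
                      roi_id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0), mean = numeric(0), sd = numeric(0),
                      cv = numeric(0), tracking_mean = numeric(0)))
  }
  rows <- list()
  emit <- function(track_id, timepoint, roi) {
    data.frame(track_id = track_id, timepoint = timepoint,
               roi_id = roi$roi_id, x = roi$x, y = roi$y, area = roi$area,
               mean = roi$mean, sd = roi$sd, cv = roi$cv,
               tracking_mean = roi$tracking_mean)
  }
  for (k in seq_len(nrow(tp1))) rows[[k]] <- emit(k, 1L, tp1[k, ])
  heads <- data.frame(track_id = seq_len(nrow(tp1)),
                      x = tp1$x, y = tp1$y)
  for (t in seq_along(rois_by_timepoint)[-1]) {
    cur <- rois_by_timepoint[[t]]
    if (nrow(heads) == 0L) break
    if (nrow(cur) == 0L) { heads <- heads[0, ]; next }
    d <- outer(heads$x, cur$x, `-`)^2 + outer(heads$y, cur$y, `-`)^2
    cand <- which(d <= max_displacement^2, arr.ind = TRUE)
    new_heads <- list()
    if (nrow(cand) > 0L) {
      ord <- order(d[cand], cur$roi_id[cand[, 2]],
                   heads$track_id[cand[, 1]])
      cand <- cand[ord, , drop = FALSE]
      used_head <- logical(nrow(heads))
      used_roi <- logical(nrow(cur))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_head[i] || used_roi[j]) next
        used_head[i] <- TRUE; used_roi[j] <- TRUE
        tid <- heads$track_id[i]
        rows[[length(rows) + 1L]] <- emit(tid, t, cur[j, ])
        new_heads[[length(new_heads) + 1L]] <-
          data.frame(track_id = tid, x = cur$x[j], y = cur$y[j])
      }
    }
    heads <- if (length(new_heads)) do.call(rbind, new_heads) else heads[0, ]
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$timepoint), ]
  rownames(out) <- NULL
  out
}

#' Call death events on linked tracks
#'
#' A neuron's death interval is the first timepoint at which its ROI is
#' absent, or present with a mean tracking-channel intensity below
#' `death_fraction` times its timepoint-1 value. If neither occurs through
#' the final timepoint the track is censored there. Observations after the
#' called death are discarded. Tracks lacking a timepoint-1 ROI are flagged
#' (`has_t1 = FALSE`) and excluded from downstream analysis rather than
#' silently dropped; by construction [link_tracks()] only seeds tracks at
#' timepoint 1, so the flag guards externally supplied tables.
#'
#' @param tracks Long-format track table from [link_tracks()].
#' @param n_timepoints Total number of imaging timepoints.
#' @param death_fraction Fraction of the timepoint-1 tracking intensity
#'   below which a neuron is called dead (default 0.2).
#' @return Data frame with one row per track: `track_id`, `x1`, `y1`
#'   (timepoint-1 centroid), `death_interval` (`NA` if censored),
#'   `censored`, `last_alive` (last live timepoint), `has_t1`.
#' @export
call_death <- function(tracks, n_timepoints, death_fraction = 0.2) {
  stopifnot(is.data.frame(tracks), n_timepoints >= 1,
            death_fraction > 0, death_fraction < 1)
  ids <- unique(tracks$track_id)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[k], ]
    tr <- tr[order(tr$timepoint), ]
    if (tr$timepoint[1] != 1L) {
      out[[k]] <- data.frame(track_id = ids[k], x1 = NA_real_, y1 = NA_real_,
                             death_interval = NA_integer_, censored = NA,
                             last_alive = NA_integer_, has_t1 = FALSE)
      next
    }
    ref <- tr$tracking_mean[1]
    death <- NA_integer_
    for (t in seq_len(n_timepoints)[-1]) {
      row <- tr[tr$timepoint == t, ]
      if (nrow(row) == 0L || row$tracking_mean < death_fraction * ref) {
        death <- t
        break
      }
    }
    out[[k]] <- data.frame(track_id = ids[k], x1 = tr$x[1], y1 = tr$y[1],
                           death_interval = death, censored = is.na(death),
                           last_alive = if (is.na(death)) n_timepoints else
                             death - 1L,
                           has_t1 = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match tracks to ground-truth neurons
#'
#' Utility for validating the tracker against a synthetic cohort: each
#' track's timepoint-1 centroid is matched to the nearest ground-truth
#' neuron of the same field within `tol` pixels.
#'
#' @param deaths Per-track table from [call_death()].
#' @param truth A `ground_truth` object.
#' @param field Field name the tracks came from.
#' @param tol Match tolerance in pixels (default 4).
#' @return `deaths` with columns `neuron_id`, `true_death_interval` and
#'   `true_aggregate` appended (`NA` where unmatched).
#' @export
match_truth <- function(deaths, truth, field, tol = 4) {
  stopifnot(inherits(truth, "ground_truth"))
  neurons <- truth$neurons[truth$neurons$field == field, , drop = FALSE]
  p1 <- truth$paths[truth$paths$timepoint == 1L &
                      truth$paths$neuron_id %in% neurons$neuron_id, ]
  p1 <- p1[match(neurons$neuron_id, p1$neuron_id), ]
  deaths$neuron_id <- NA_integer_
  deaths$true_death_interval <- NA_integer_
  deaths$true_aggregate <- NA
  for (k in seq_len(nrow(deaths))) {
    if (!isTRUE(deaths$has_t1[k])) next
    d2 <- (p1$x - deaths$x1[k])^2 + (p1$y - deaths$y1[k])^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol^2) {
      deaths$neuron_id[k] <- neurons$neuron_id[j]
      deaths$true_death_interval[k] <- neurons$death_interval[j]
      deaths$true_aggregate[k] <- neurons$aggregate[j]
    }
  }
  deaths
}
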