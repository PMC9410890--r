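#' Write a two-channel movie as multi-page TIFF
#'
#' Pages are ordered channel-within-timepoint: page `(t - 1) * C + c`
#' holds channel `c` of timepoint `t` (so a 10-frame, 2-channel movie has
#' 20 pages). Intensities are stored as 16-bit integers; values are
#' rounded, so the round trip is lossless for integer intensities up to
#' 65535. A JSON sidecar (`<path>.json`) records the channel order and
#' acquisition times.
#'
#' @param movie A `movie` object.
#' @param path Output TIFF path.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, sidecar = TRUE) {
  stopifnot(inherits(movie, "movie"))
  px <- movie$pixels
  if (max(px) > 65535) stop("intensities exceed the 16-bit range")
  tp <- dim(px)[4]; nc <- dim(px)[3]
  pages <- vector("list", tp * nc)
  for (t in seq_len(tp)) {
    for (c in seq_len(nc)) {
      pages[[(t - 1L) * nc + c]] <- round(px[, , c, t]) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    jsonlite::write_json(
      list(channels = movie$channels, times = movie$times,
           n_timepoints = tp, n_channels = nc),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Inverse of [write_movie()]. If the JSON sidecar is present it supplies
#' the channel names and acquisition times; otherwise `n_channels` and
#' `interval_hours` are used.
#'
#' @param path TIFF path.
#' @param n_channels Channels per timepoint when no sidecar exists.
#' @param interval_hours Frame interval when no sidecar exists.
#' @return A `movie` object.
#' @export
read_movie <- function(path, n_channels = 2, interval_hours = 24) {
  if (!file.exists(path)) stop("movie file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("malformed TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    n_channels <- meta$n_channels
  }
  if (length(pages) %% n_channels != 0L) {
    stop("malformed TIFF '", path, "': ", length(pages),
         " pages are not a multiple of ", n_channels, " channels")
  }
  tp <- length(pages) %/% n_channels
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  px <- array(0, dim = c(h, w, n_channels, tp))
  for (t in seq_len(tp)) {
    for (c in seq_len(n_channels)) {
      pg <- pages[[(t - 1L) * n_channels + c]]
      if (!identical(dim(pg)[1:2], c(h, w))) {
        stop("malformed TIFF '", path, "': page ",
             (t - 1L) * n_channels + c, " has a different shape")
      }
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]
      px[, , c, t] <- round(pg * 65535)
    }
  }
  structure(list(pixels = px,
                 times = if (!is.null(meta)) as.numeric(meta$times) else
                   interval_hours * seq_len(tp),
                 channels = if (!is.null(meta)) meta$channels else
                   paste0("channel", seq_len(n_channels))),
            class = "movie")
}

#' Read a CSV table and check its schema
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return The data frame.
#' @export
read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("table file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("table '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' Write the long-format track table as CSV
#'
#' Columns: `track_id`, `timepoint`, `roi_id`, `x`, `y`, `area`, `mean`,
#' `sd`, `cv`, `tracking_mean`.
#'
#' @param tracks Track table from [link_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read_table_checked(path, c("track_id", "timepoint", "x", "y", "area",
                             "mean", "sd", "cv", "tracking_mean"))
}

#' Write survival records as CSV
#'
#' @param records Record data frame from [build_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  tab <- read_table_checked(path, c("track_id", "group", "time", "event"))
  tab$event <- as.logical(tab$event)
  if ("aggregated" %in% names(tab)) tab$aggregated <- as.logical(tab$aggregated)
  tab
}
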