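#' Binary event raster
#'
#' The lingua franca between detection and the network statistics: a
#' cells x frames binary matrix of event (calcium transient) onsets, with
#' the acquisition frame rate, a per-frame validity mask (frames lost to
#' residual drift are invalid), optional cell centroids (pixel
#' coordinates) and per-cell exclusion flags.
#'
#' @param mat cells x frames matrix with entries 0/1.
#' @param frame_rate acquisition rate (Hz).
#' @param valid_frames logical per frame; defaults to all valid.
#' @param centroids optional cells x 2 matrix (row, col) of pixel coords.
#' @param excluded logical per cell; excluded cells are ignored by the
#'   statistics. Defaults to all included.
#' @return object of class `event_raster`.
#' @export
event_raster <- function(mat, frame_rate, valid_frames = NULL,
                         centroids = NULL, excluded = NULL) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  stopifnot(all(mat %in% c(0L, 1L)), frame_rate > 0)
  n_cells <- nrow(mat); n_frames <- ncol(mat)
  if (is.null(valid_frames)) valid_frames <- rep(TRUE, n_frames)
  stopifnot(length(valid_frames) == n_frames)
  if (any(mat[, !valid_frames] == 1L)) stop("events on invalid frames")
  if (is.null(excluded)) excluded <- rep(FALSE, n_cells)
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    stopifnot(nrow(centroids) == n_cells, ncol(centroids) == 2)
  }
  structure(list(mat = mat, frame_rate = frame_rate,
                 valid_frames = as.logical(valid_frames),
                 centroids = centroids, excluded = as.logical(excluded)),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("event_raster: %d cells x %d frames at %.2f Hz (%d events, %d excluded cells, %d invalid frames)\n",
              nrow(x$mat), ncol(x$mat), x$frame_rate, sum(x$mat),
              sum(x$excluded), sum(!x$valid_frames)))
  invisible(x)
}

#' @export
dim.event_raster <- function(x) dim(x$mat)

#' Read / write rasters as CSV
#'
#' Rasters are exchanged as plain CSV: rows = cells, columns = frames,
#' entries 0/1, no header. `write_raster_csv` also stores the frame rate
#' in a comment on the first line.
#'
#' @param raster `event_raster`.
#' @param path file path.
#' @param frame_rate frame rate used when the file has no rate comment.
#' @return `read_raster_csv` returns an `event_raster`.
#' @export
write_raster_csv <- function(raster, path) {
  con <- file(path, "w")
  writeLines(sprintf("# frame_rate=%.10g", raster$frame_rate), con)
  utils::write.table(raster$mat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path, frame_rate = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# frame_rate=", first)) {
    frame_rate <- as.numeric(sub("^# frame_rate=", "", first))
    mat <- utils::read.csv(path, header = FALSE, skip = 1)
  } else {
    mat <- utils::read.csv(path, header = FALSE)
    if (is.null(frame_rate)) stop("frame_rate required")
  }
  m <- as.matrix(mat)
  dimnames(m) <- NULL
  event_raster(m, frame_rate)
}

## onset frames (1-based) per cell, as a list
onset_list <- function(raster) {
  apply(raster$mat, 1, function(v) which(v == 1L), simplify = FALSE)
}

## binary dilation of event frames by +/- dt, clipped to [1, n]
dilate_events <- function(idx, dt, n) {
  if (!length(idx)) return(integer(0))
  unique(pmin(pmax(rep(idx, each = 2 * dt + 1) + (-dt):dt, 1L), n))
}

## per-cell uniform reshuffle of onsets over the valid frames (counts kept)
shuffle_onsets <- function(raster) {
  valid_idx <- which(raster$valid_frames)
  lapply(onset_list(raster), function(idx)
    if (length(idx)) sort(sample(valid_idx, length(idx))) else integer(0))
}
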