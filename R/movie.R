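#' Fluorescence movie container
#'
#' A single-channel image stack with its frame rate and a per-frame
#' validity mask (frames affected by residual drift are invalid and are
#' treated as missing downstream).
#'
#' @param stack numeric array, rows x cols x frames.
#' @param frame_rate acquisition rate (Hz).
#' @param valid_frames logical per frame (default all valid).
#' @return object of class `fluorescence_movie`.
#' @export
fluorescence_movie <- function(stack, frame_rate, valid_frames = NULL) {
  stopifnot(length(dim(stack)) == 3, frame_rate > 0)
  n <- dim(stack)[3]
  if (is.null(valid_frames)) valid_frames <- rep(TRUE, n)
  stopifnot(length(valid_frames) == n)
  structure(list(stack = stack, frame_rate = frame_rate,
                 valid_frames = as.logical(valid_frames)),
            class = "fluorescence_movie")
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("fluorescence_movie: %d x %d pixels, %d frames at %.2f Hz\n",
              d[1], d[2], d[3], x$frame_rate))
  invisible(x)
}

#' Read / write movies and label masks as TIFF
#'
#' Movies are stored as multi-page 32-bit float TIFF (one page per
#' frame); label masks as single-page 16-bit integer TIFF.
#'
#' @param movie `fluorescence_movie`.
#' @param path file path.
#' @param frame_rate frame rate to attach on reading.
#' @param scale intensity divisor applied when writing (float TIFF stores
#'   values as-is; kept for interoperability with viewers expecting
#'   normalized data).
#' @return `read_movie_tiff` returns a `fluorescence_movie`;
#'   `read_label_tiff` an integer matrix.
#' @export
write_movie_tiff <- function(movie, path, scale = 1) {
  frames <- lapply(seq_len(dim(movie$stack)[3]),
                   function(f) movie$stack[, , f] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_rate, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  stack <- array(unlist(frames),
                 dim = c(dim(frames[[1]])[1:2], length(frames))) * scale
  fluorescence_movie(stack, frame_rate)
}

#' @rdname write_movie_tiff
#' @param labels integer label matrix (0 = background).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}
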