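#' Single greyscale frame
#'
#' Container for one greyscale frame of an image stack. Pixels are stored as
#' an integer matrix in row-major image convention: rows are the y axis,
#' columns the x axis, both 0-based in every user-facing index or message.
#'
#' @param pixels Integer matrix of grey values, `height x width`.
#' @param bit_depth Bits per pixel, 8 or 16. Grey values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param frame_index 0-based position of the frame in its stack.
#' @return An object of class `frame_image` with fields `pixels`,
#'   `bit_depth`, `frame_index`.
#' @examples
#' f <- frame_image(matrix(0:3, 2, 2), bit_depth = 8)
#' f$bit_depth
#' @export
frame_image <- function(pixels, bit_depth = 16L, frame_index = 0L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("invalid input: 'pixels' must be a non-empty matrix", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("invalid input: bit_depth must be 8 or 16", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels))
    stop("invalid input: NA pixel values", call. = FALSE)
  maxval <- 2L^as.integer(bit_depth) - 1L
  if (min(pixels) < 0L || max(pixels) > maxval)
    stop(sprintf("invalid input: grey values outside [0, %d]", maxval),
         call. = FALSE)
  structure(
    list(pixels = pixels,
         bit_depth = as.integer(bit_depth),
         frame_index = as.integer(frame_index)),
    class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  cat(sprintf("<frame_image #%d  %dx%d  %d-bit  grey range [%d, %d]>\n",
              x$frame_index, frame_width(x), frame_height(x), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Frame dimensions
#'
#' @param frame A [frame_image()].
#' @return Pixel count along x (`frame_width`) or y (`frame_height`).
#' @export
frame_width <- function(frame) ncol(frame$pixels)

#' @rdname frame_width
#' @export
frame_height <- function(frame) nrow(frame$pixels)

#' Statistics configuration
#'
#' Settings governing the two custom statistics (sum pixel ramp and segment
#' intensity deviation, SID). `pixel_step` is both the sampling stride and the
#' comparison offset: every `pixel_step`-th pixel is sampled in x and y, and
#' each sampled pixel is compared with the pixel `pixel_step` rows above it.
#' With `normalize = TRUE` both statistics are divided by the number of
#' sampled pixels/comparisons, which makes their scale independent of
#' `pixel_step`; the flag is recorded in saved models so that training and
#' scoring always agree.
#'
#' @param pixel_step Positive integer sampling stride/offset (default 3).
#' @param normalize Divide by the sampled-pixel count (default `TRUE`).
#' @param sid_grid Integer vector `c(rows, cols)` of the SID segment grid
#'   (default 4x4). Remainder rows/columns are absorbed into the last
#'   segment.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(pixel_step = 3L, normalize = TRUE,
                         sid_grid = c(4L, 4L)) {
  pixel_step <- as.integer(pixel_step)
  if (is.na(pixel_step) || pixel_step < 1L)
    stop("invalid configuration: pixel_step must be a positive integer",
         call. = FALSE)
  sid_grid <- as.integer(sid_grid)
  if (length(sid_grid) != 2L || anyNA(sid_grid) || any(sid_grid < 1L))
    stop("invalid configuration: sid_grid must be two positive integers",
         call. = FALSE)
  structure(
    list(pixel_step = pixel_step,
         normalize = isTRUE(normalize),
         sid_grid = sid_grid),
    class = "stats_config")
}

#' @export
print.stats_config <- function(x, ...) {
  cat(sprintf("<stats_config  pixel_step=%d  normalize=%s  sid_grid=%dx%d>\n",
              x$pixel_step, x$normalize, x$sid_grid[1], x$sid_grid[2]))
  invisible(x)
}

same_config <- function(a, b) {
  isTRUE(a$pixel_step == b$pixel_step) &&
    isTRUE(a$normalize == b$normalize) &&
    isTRUE(all(a$sid_grid == b$sid_grid))
}
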