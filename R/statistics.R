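#' Canonical statistic variable names
#'
#' The eleven per-frame statistics used as explanatory variables, in the
#' canonical column order of the statistics CSV. This ordering also breaks
#' ties deterministically during stepwise elimination.
#'
#' @return Character vector of length 11.
#' @export
stat_variable_names <- function() {
  c("unique_greys", "mean", "max", "std", "skewness", "kurtosis",
    "entropy", "integrated_density", "sum_of_squares",
    "sum_pixel_ramp", "sid")
}

#' Basic per-frame statistics
#'
#' Computes the nine standard statistics of a frame, treating the individual
#' pixel grey values as a population: unique grey values, mean, maximum,
#' population standard deviation, population skewness (Fisher-Pearson
#' coefficient \eqn{m_3/m_2^{3/2}}), population excess kurtosis
#' (\eqn{m_4/m_2^2 - 3}), Shannon entropy of the exact grey-level histogram
#' in bits, integrated density (sum of grey values), and sum of squares.
#' Constant frames have skewness and kurtosis defined as 0 (zero-variance
#' convention) so they remain scoreable. The two custom statistics are left
#' `NA`; see [compute_sum_pixel_ramp()] and [compute_sid()].
#'
#' @param frame A [frame_image()].
#' @return One-row data frame with columns `frame` (0-based index), the nine
#'   statistics, and `sum_pixel_ramp`/`sid` set to `NA`.
#' @examples
#' f <- frame_image(matrix(as.integer(c(0, 10, 0, 10)), 2, 2), bit_depth = 8)
#' compute_basic_statistics(f)
#' @export
compute_basic_statistics <- function(frame) {
  stopifnot(inherits(frame, "frame_image"))
  x <- as.numeric(frame$pixels)
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  m2 <- sum(d^2) / n
  # exact integer histogram; bit depth <= 16 keeps tabulate cheap
  counts <- tabulate(frame$pixels + 1L, nbins = 2L^frame$bit_depth)
  counts <- counts[counts > 0L]
  pr <- counts / n
  data.frame(
    frame = frame$frame_index,
    unique_greys = length(counts),
    mean = m,
    max = max(x),
    std = sqrt(m2),
    skewness = if (m2 > 0) (sum(d^3) / n) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) (sum(d^4) / n) / m2^2 - 3 else 0,
    entropy = -sum(pr * log2(pr)),
    integrated_density = sum(x),
    sum_of_squares = sum(x^2),
    sum_pixel_ramp = NA_real_,
    sid = NA_real_)
}

# Sampling lattice shared by both custom statistics: stride = comparison
# offset = pixel_step in both axes; first sampled row is y = pixel_step
# (0-based) so the comparison partner y - pixel_step stays inside the frame;
# first sampled column is x = 0.
sample_lattice <- function(height, width, p) {
  if (p >= height)
    stop(sprintf(
      "invalid configuration: pixel_step %d must be smaller than frame height %d",
      p, height), call. = FALSE)
  list(rows = seq.int(p + 1L, height, by = p),   # 1-based row indices
       cols = seq.int(1L, width, by = p))
}

#' Sum pixel ramp
#'
#' Sharpness proxy: the sum of absolute differences between the intensity at
#' each sampled position (x, y) and the intensity at (x, y - p), where p is
#' the pixel step. Sampling strides by p in both axes, starting at y = p so
#' every comparison stays inside the frame. Blur flattens intensity
#' interfaces (e.g. cell edges against a dark background) and lowers the
#' value. With `normalize = TRUE` the sum is divided by the number of
#' comparisons, removing the dependence on how many pixels were surveyed.
#'
#' @param frame A [frame_image()].
#' @param config A [stats_config()].
#' @return Non-negative scalar.
#' @examples
#' f <- frame_image(matrix(as.integer(seq(0, 50, 10)), ncol = 1), bit_depth = 8)
#' compute_sum_pixel_ramp(f, stats_config(pixel_step = 1, normalize = FALSE))
#' @export
compute_sum_pixel_ramp <- function(frame, config = stats_config()) {
  stopifnot(inherits(frame, "frame_image"), inherits(config, "stats_config"))
  p <- config$pixel_step
  lat <- sample_lattice(frame_height(frame), frame_width(frame), p)
  px <- frame$pixels
  # double arithmetic: integer sums overflow on 16-bit frames at small steps
  s <- sum(abs(as.numeric(px[lat$rows, lat$cols, drop = FALSE]) -
               as.numeric(px[lat$rows - p, lat$cols, drop = FALSE])))
  if (config$normalize) s / (length(lat$rows) * length(lat$cols)) else s
}

# Segment id (1..rows*cols) for each sampled pixel; remainder rows/cols are
# absorbed into the last segment row/column.
segment_ids <- function(idx1, extent, nseg) {
  base <- extent %/% nseg
  if (base == 0L)
    stop("invalid configuration: more SID segments than pixels", call. = FALSE)
  pmin.int((idx1 - 1L) %/% base + 1L, nseg)
}

#' Segment intensity deviation (SID)
#'
#' Uniformity measure: the frame is split into a rectangular grid of
#' segments, the sampled pixel intensities of each segment are summed, and
#' the population standard deviation of the segment sums is returned. A value
#' of 0 indicates perfectly uniform intensity across the frame; partial
#' focus or uneven illumination raises it. Sampling uses the same
#' pixel-step lattice as [compute_sum_pixel_ramp()]. With
#' `normalize = TRUE` each segment sum is first divided by that segment's
#' sampled-pixel count, which also neutralises unequal segment sizes.
#'
#' @inheritParams compute_sum_pixel_ramp
#' @return Non-negative scalar.
#' @export
compute_sid <- function(frame, config = stats_config()) {
  stopifnot(inherits(frame, "frame_image"), inherits(config, "stats_config"))
  p <- config$pixel_step
  gr <- config$sid_grid[1]; gc <- config$sid_grid[2]
  lat <- sample_lattice(frame_height(frame), frame_width(frame), p)
  if (gr * gc > length(lat$rows) * length(lat$cols))
    stop("invalid configuration: more SID segments than sampled pixels",
         call. = FALSE)
  rseg <- segment_ids(lat$rows, frame_height(frame), gr)
  cseg <- segment_ids(lat$cols, frame_width(frame), gc)
  seg <- outer(rseg, cseg, function(a, b) (a - 1L) * gc + b)
  sub <- frame$pixels[lat$rows, lat$cols, drop = FALSE]
  sums <- vapply(split(as.numeric(sub), as.vector(seg)), sum, 0)
  cnts <- tabulate(as.vector(seg), nbins = gr * gc)
  present <- cnts > 0L
  if (!all(present))
    stop("invalid configuration: SID segment without sampled pixels",
         call. = FALSE)
  vals <- numeric(gr * gc)
  vals[as.integer(names(sums))] <- sums
  if (config$normalize) vals <- vals / cnts
  sqrt(mean((vals - mean(vals))^2))
}

#' Statistics for a whole stack
#'
#' Computes the full eleven-statistic vector for every frame of a stack.
#' Frames are processed independently; the result order follows the stack
#' order.
#'
#' @param stack List of [frame_image()] objects sharing dimensions and bit
#'   depth.
#' @param config A [stats_config()].
#' @return Data frame with one row per frame and columns
#'   `frame, unique_greys, mean, max, std, skewness, kurtosis, entropy,
#'   integrated_density, sum_of_squares, sum_pixel_ramp, sid`; the
#'   configuration used is attached as attribute `"config"`.
#' @export
compute_frame_statistics <- function(stack, config = stats_config()) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("invalid input: empty stack", call. = FALSE)
  dims <- vapply(stack, function(f) c(frame_height(f), frame_width(f),
                                      f$bit_depth), integer(3))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1] |
               dims[3, ] != dims[3, 1])
  if (length(bad))
    stop(sprintf(
      "invalid input: frame %d differs in dimensions or bit depth from frame %d",
      stack[[bad[1]]]$frame_index, stack[[1]]$frame_index), call. = FALSE)
  rows <- lapply(stack, function(f) {
    st <- compute_basic_statistics(f)
    st$sum_pixel_ramp <- compute_sum_pixel_ramp(f, config)
    st$sid <- compute_sid(f, config)
    st
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  out
}
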