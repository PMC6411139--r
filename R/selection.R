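new_selection_result <- function(retained, mode, parameter, scores,
                                 window_ids = NULL) {
  structure(list(retained_indices = as.integer(retained),
                 mode = mode, parameter = parameter, scores = scores,
                 window_ids = window_ids),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result  mode=%s (%s=%s)  retained %d of %d frames>\n",
              x$mode, if (x$mode == "QA") "cutoff" else "window",
              format(x$parameter), length(x$retained_indices),
              length(x$scores$frame)))
  invisible(x)
}

#' Quality-alone frame rejection (QA mode)
#'
#' Retains exactly the frames whose calculated score is greater than or
#' equal to the cutoff; frames below the cutoff are removed. Quality is the
#' sole deciding factor, so long runs of poor frames can leave large
#' chronological gaps (see [frame_window_select()] for the
#' chronology-preserving alternative).
#'
#' @param scores A [score_set()].
#' @param cutoff Score threshold (inclusive).
#' @return A `selection_result` with strictly increasing 0-based
#'   `retained_indices` (possibly empty).
#' @export
filter_by_cutoff <- function(scores, cutoff) {
  stopifnot(inherits(scores, "score_set"), is.numeric(cutoff),
            length(cutoff) == 1L)
  keep <- scores$frame[scores$score >= cutoff]
  new_selection_result(keep, "QA", cutoff, scores)
}

#' Best-in-window frame selection (FW mode)
#'
#' Partitions the stack into consecutive non-overlapping windows of length
#' `window` (the last window may be shorter) and retains the single
#' highest-scoring frame of each window, preserving macro-chronology: gaps
#' between retained frames never exceed `2 * window - 1`. Ties within a
#' window keep the earliest frame.
#'
#' @param scores A [score_set()].
#' @param window Positive integer window length.
#' @return A `selection_result`; `window_ids` gives the 1-based window of
#'   each retained frame.
#' @export
frame_window_select <- function(scores, window) {
  stopifnot(inherits(scores, "score_set"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    stop("invalid configuration: window must be a positive integer",
         call. = FALSE)
  n <- length(scores$frame)
  wid <- ((seq_len(n) - 1L) %/% window) + 1L
  pick <- vapply(split(seq_len(n), wid),
                 function(ix) ix[which.max(scores$score[ix])], 0L)
  new_selection_result(scores$frame[pick], "FW", window, scores,
                       window_ids = seq_along(pick))
}

#' Minimum window size for a quality target
#'
#' Scans window sizes in increments of 1, up to 25% of the stack length,
#' until it finds a size at which every window of the partition contains at
#' least one frame meeting the quality target. Combined with
#' [frame_window_select()] this guarantees every retained frame meets the
#' target.
#'
#' @param scores A [score_set()].
#' @param target Quality score every window must reach.
#' @return The smallest such window size, or `NA_integer_` if none exists
#'   within the 25% bound (not-found is a value, not an error).
#' @export
minimum_window_size <- function(scores, target) {
  stopifnot(inherits(scores, "score_set"), is.numeric(target),
            length(target) == 1L)
  n <- length(scores$frame)
  ok <- scores$score >= target
  nmax <- max(1L, n %/% 4L)
  for (w in seq_len(nmax)) {
    wid <- ((seq_len(n) - 1L) %/% w) + 1L
    if (all(vapply(split(ok, wid), any, TRUE)))
      return(w)
  }
  NA_integer_
}

#' Export a selection to disk
#'
#' Writes the retained frames, in order, as individually numbered TIFF files
#' (named by original 0-based frame index) plus a `manifest.csv` with the
#' original index, calculated score, and window id where applicable.
#'
#' @param stack List of [frame_image()] objects the selection refers to.
#' @param result A `selection_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
export_selection <- function(stack, result, out_dir) {
  stopifnot(inherits(result, "selection_result"))
  idx <- result$retained_indices
  stack_idx <- vapply(stack, function(f) f$frame_index, 0L)
  pos <- match(idx, stack_idx)
  if (anyNA(pos))
    stop(sprintf("invalid input: selection index(es) %s not in stack",
                 paste(idx[is.na(pos)], collapse = ", ")), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  sc <- result$scores$score[match(idx, result$scores$frame)]
  manifest <- data.frame(
    original_index = idx,
    score = sc,
    window_id = if (result$mode == "FW") result$window_ids
                else rep(NA_integer_, length(idx)),
    file = if (length(idx)) sprintf("frame_%04d.tif", idx) else character(0))
  if (length(idx) == 0L) {
    warning("empty selection: writing manifest only", call. = FALSE)
  } else {
    for (i in seq_along(idx)) {
      f <- stack[[pos[i]]]
      tiff::writeTIFF(f$pixels / (2^f$bit_depth - 1),
                      file.path(out_dir, manifest$file[i]),
                      bits.per.sample = f$bit_depth)
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
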