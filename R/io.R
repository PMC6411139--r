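as_frame_matrix <- function(arr, path, page = NULL) {
  where <- if (is.null(page)) sprintf("'%s'", path)
           else sprintf("'%s' page %d", path, page)
  if (length(dim(arr)) == 3L && dim(arr)[3] > 1L)
    stop(sprintf(paste("unsupported format: %s has %d channels; convert to",
                       "single-channel greyscale first"),
         where, dim(arr)[3]), call. = FALSE)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  arr
}

read_tiff_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    m <- as_frame_matrix(pages[[i]], path, i)
    bits <- attr(pages[[i]], "bits.per.sample")
    if (is.null(bits)) bits <- if (max(m) > 255) 16L else 8L
    if (!is.integer(m) && any(m != round(m)))
      stop(sprintf("unsupported format: '%s' holds floating-point samples",
                   path), call. = FALSE)
    list(pixels = m, bits = as.integer(bits))
  })
}

read_png_frame <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  m <- as_frame_matrix(arr, path)
  bits <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
  if (!bits %in% c(8L, 16L)) bits <- if (bits < 8L) 8L else 16L
  list(pixels = round(m * (2^bits - 1)), bits = bits)
}

#' Read an image stack
#'
#' Reads a greyscale image stack from either a multi-page TIFF file or a
#' directory of single-frame TIFF/PNG files. Directory frames are taken in
#' lexicographic filename order (note: `f10.tif` sorts before `f2.tif`;
#' zero-pad numeric names if numeric order is intended). 8- and 16-bit
#' greyscale images are accepted; RGB or floating-point images are rejected
#' with a conversion hint.
#'
#' @param path A multi-page TIFF file or a directory of frames.
#' @return List of [frame_image()] objects with 0-based `frame_index` in
#'   read order.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L)
      stop(sprintf("empty stack: no TIFF/PNG frames in '%s'", path),
           call. = FALSE)
    raw <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) list(read_png_frame(f))
      else read_tiff_frames(f)
    })
    raw <- do.call(c, raw)
  } else if (file.exists(path)) {
    raw <- read_tiff_frames(path)
  } else {
    stop(sprintf("cannot read stack: '%s' does not exist", path),
         call. = FALSE)
  }
  if (length(raw) == 0L)
    stop(sprintf("empty stack: '%s'", path), call. = FALSE)
  lapply(seq_along(raw), function(i) {
    frame_image(matrix(as.integer(round(raw[[i]]$pixels)),
                       nrow(raw[[i]]$pixels), ncol(raw[[i]]$pixels)),
                bit_depth = raw[[i]]$bits, frame_index = i - 1L)
  })
}

#' Write a stack as a multi-page TIFF
#'
#' @param stack List of [frame_image()] objects.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  bits <- stack[[1]]$bit_depth
  pages <- lapply(stack, function(f) f$pixels / (2^f$bit_depth - 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write / read frame statistics CSV
#'
#' The statistics table round-trips through CSV with the canonical header
#' `frame,unique_greys,mean,max,std,skewness,kurtosis,entropy,`
#' `integrated_density,sum_of_squares,sum_pixel_ramp,sid`. The
#' configuration is stored in a comment line (`# pixel_step=...`) and
#' restored on read.
#'
#' @param stats Statistics data frame from [compute_frame_statistics()].
#' @param path CSV path.
#' @return `write_statistics` returns `path` invisibly; `read_statistics`
#'   the restored data frame.
#' @export
write_statistics <- function(stats, path) {
  cfg <- attr(stats, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg))
    writeLines(sprintf("# pixel_step=%d normalize=%s sid_grid=%dx%d",
                       cfg$pixel_step, tolower(as.character(cfg$normalize)),
                       cfg$sid_grid[1], cfg$sid_grid[2]), con)
  utils::write.csv(format(stats, digits = 12, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_statistics
#' @export
read_statistics <- function(path) {
  first <- readLines(path, n = 1L)
  cfg <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec(
      "pixel_step=(\\d+) normalize=(true|false) sid_grid=(\\d+)x(\\d+)", first))[[1]]
    if (length(m) == 5L)
      cfg <- stats_config(pixel_step = as.integer(m[2]),
                          normalize = m[3] == "true",
                          sid_grid = as.integer(m[4:5]))
  }
  out <- utils::read.csv(path, skip = skip)
  expect <- c("frame", stat_variable_names())
  if (!identical(names(out), expect))
    stop(sprintf("parse error in '%s': expected header %s", path,
                 paste(expect, collapse = ",")), call. = FALSE)
  attr(out, "config") <- cfg
  out
}

#' Write / read calculated scores CSV
#'
#' CSV with header `frame,score`; values round-trip to at least 10
#' significant digits. Negative and out-of-range scores are preserved
#' unchanged.
#'
#' @param scores A [score_set()].
#' @param path CSV path.
#' @return `write_scores` returns `path` invisibly; `read_scores` a
#'   [score_set()].
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_set"))
  df <- data.frame(frame = scores$frame,
                   score = format(scores$score, digits = 12, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("frame", "score")))
    stop(sprintf("parse error in '%s' line 1: expected header 'frame,score'",
                 path), call. = FALSE)
  frame <- suppressWarnings(as.integer(df$frame))
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(frame) | is.na(score))
  if (length(bad))
    stop(sprintf("parse error in '%s' line %d: malformed row", path,
                 bad[1] + 1L), call. = FALSE)
  score_set(frame, score)
}

#' Run the full pipeline
#'
#' End-to-end flow: read the stack, compute statistics, fit a model from
#' manual scores (or load saved coefficients), calculate scores for every
#' frame, optionally range-adjust, select frames by quality cutoff (QA) or
#' frame windowing (FW), and export the retained frames with a manifest.
#' Every stage's parameters are logged via [message()].
#'
#' @param input Stack path (multi-page TIFF or frame directory), or a list
#'   of [frame_image()] objects.
#' @param output_dir Directory for all artifacts (created if missing).
#' @param scores_csv CSV of manual scores (`frame,score`) for training;
#'   mutually exclusive with `model_path`.
#' @param model_path Saved coefficient JSON to load instead of fitting.
#' @param config A [stats_config()].
#' @param auto_stepwise Use backward elimination (default) rather than a
#'   plain fit of `variables`.
#' @param variables Explanatory variables to start from.
#' @param mode `"qa"` (cutoff) or `"fw"` (windowing).
#' @param cutoff QA-mode score cutoff.
#' @param window FW-mode window size; if `NULL` and `target` is given, the
#'   minimum window size for `target` is computed and reported.
#' @param target FW-mode quality target for the minimum-window search.
#' @param apply_range_adjust Range-adjust calculated scores before
#'   selection.
#' @return Invisibly, a list with `stats`, `model`, `scores`, `selection`,
#'   `manifest`, and (FW target mode) `window`.
#' @export
run_pipeline <- function(input, output_dir,
                         scores_csv = NULL, model_path = NULL,
                         config = stats_config(),
                         auto_stepwise = TRUE,
                         variables = stat_variable_names(),
                         mode = c("qa", "fw"),
                         cutoff = NULL, window = NULL, target = NULL,
                         apply_range_adjust = FALSE) {
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf(
    "pipeline: pixel_step=%d normalize=%s sid_grid=%dx%d mode=%s",
    config$pixel_step, config$normalize, config$sid_grid[1],
    config$sid_grid[2], toupper(mode)))

  stack <- stage("read", {
    if (is.character(input)) read_stack(input) else input
  })
  message(sprintf("read: %d frames, %dx%d, %d-bit", length(stack),
                  frame_width(stack[[1]]), frame_height(stack[[1]]),
                  stack[[1]]$bit_depth))

  stats <- stage("statistics", compute_frame_statistics(stack, config))
  write_statistics(stats, file.path(output_dir, "stats.csv"))

  model <- stage("model", {
    if (!is.null(model_path)) {
      m <- load_model(model_path)
      message(sprintf("model: loaded '%s' (md5 %s), %d variable(s)",
                      model_path, tools::md5sum(model_path)[[1]],
                      length(m$coefficients)))
      m
    } else if (!is.null(scores_csv)) {
      manual <- read_scores(scores_csv)
      samples <- scored_samples(stats, manual)
      m <- if (auto_stepwise) stepwise_backward_eliminate(samples, variables)
           else fit_mlr(samples, variables)
      message(sprintf("model: fitted on %d frames, adj.R2=%.4f, kept: %s",
                      m$n_training, m$adjusted_r2,
                      paste(names(m$coefficients), collapse = ", ")))
      save_model(m, file.path(output_dir, "model.json"))
      m
    } else {
      stop("either scores_csv or model_path is required")
    }
  })

  scores <- stage("score", calculate_scores(stats, model))
  if (apply_range_adjust)
    scores <- stage("range-adjust", range_adjust(scores))
  write_scores(scores, file.path(output_dir, "scores.csv"))
  message(sprintf("score: %d frames, range [%.3g, %.3g]%s",
                  length(scores$frame), min(scores$score), max(scores$score),
                  if (apply_range_adjust) " (range-adjusted)" else ""))

  found_window <- NULL
  selection <- stage("select", {
    if (mode == "qa") {
      if (is.null(cutoff)) stop("QA mode requires a cutoff")
      filter_by_cutoff(scores, cutoff)
    } else {
      if (is.null(window)) {
        if (is.null(target)) stop("FW mode requires a window or a target")
        found_window <- minimum_window_size(scores, target)
        if (is.na(found_window))
          stop(sprintf(
            "no window size up to 25%% of the stack meets target %.3g",
            target))
        message(sprintf("select: minimum window size for target %.3g is %d",
                        target, found_window))
        window <- found_window
      }
      frame_window_select(scores, window)
    }
  })
  message(sprintf("select: retained %d of %d frames",
                  length(selection$retained_indices), length(scores$frame)))

  manifest <- stage("export",
    export_selection(stack, selection, file.path(output_dir, "frames")))

  invisible(list(stats = stats, model = model, scores = scores,
                 selection = selection, manifest = manifest,
                 window = found_window))
}
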