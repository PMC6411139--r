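#' Pearson product-moment correlation
#'
#' Agreement measure between calculated and human scores. Requires at least
#' three paired observations and nonzero variance on both sides.
#'
#' @param a,b Numeric vectors of equal length.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("invalid input: need two equal-length vectors of length >= 3",
         call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(a, b)
}

#' Mean absolute score distance
#'
#' Mean over shared frames of \eqn{d_i = |S_{ip} - S_{ic}|}, the modulus
#' distance between the provided (human) and calculated score of each frame.
#'
#' @param provided,calculated Numeric vectors named by frame index (or
#'   [score_set()] objects). Only frames present in both are compared.
#' @return Non-negative scalar.
#' @export
mean_score_distance <- function(provided, calculated) {
  as_named <- function(x) {
    if (inherits(x, "score_set")) stats::setNames(x$score, x$frame)
    else if (!is.null(names(x))) x
    else stop("invalid input: scores must be named by frame or be score_sets",
              call. = FALSE)
  }
  p <- as_named(provided); c_ <- as_named(calculated)
  shared <- intersect(names(p), names(c_))
  if (length(shared) == 0L)
    stop("invalid input: no shared frames to compare", call. = FALSE)
  mean(abs(p[shared] - c_[shared]))
}

#' Verbal correlation strength label
#'
#' Maps the absolute value of a correlation coefficient to the conventional
#' verbal descriptors: .00-.19 "very weak", .20-.39 "weak", .40-.59
#' "moderate", .60-.79 "strong", .80-1.0 "very strong". Values between the
#' two-decimal band edges are rounded half away from zero to two decimals
#' before lookup.
#'
#' @param r Correlation coefficient with `|r| <= 1`.
#' @return Character label.
#' @examples
#' strength_label(0.15)   # "very weak"
#' strength_label(-0.85)  # "very strong"
#' @export
strength_label <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1)
    stop("invalid input: r must be a single value with |r| <= 1",
         call. = FALSE)
  # round half away from zero to 2 decimals (the bands are 2-decimal);
  # the epsilon guards binary representation of values like 0.195
  x <- floor(abs(r) * 100 + 0.5 + 1e-9) / 100
  if (x <= 0.19) "very weak"
  else if (x <= 0.39) "weak"
  else if (x <= 0.59) "moderate"
  else if (x <= 0.79) "strong"
  else "very strong"
}

#' Agreement between calculated and human scores
#'
#' Summarises how well calculated scores reproduce human scores: Pearson
#' correlation over all scored frames, the same correlation excluding the
#' frames used for training (the primary reported figure, since those frames
#' were seen by the regression), the mean absolute distance, and the verbal
#' strength label of the excluding-training correlation.
#'
#' @param provided,calculated Numeric vectors named by frame index, or
#'   [score_set()] objects.
#' @param training_frames Frame indices that were used to fit the model;
#'   excluded from `pearson_r_excluding_training` and `mean_distance`.
#' @return List of class `agreement_report`: `pearson_r`,
#'   `pearson_r_excluding_training`, `mean_distance`, `n_compared`,
#'   `strength_label`.
#' @export
agreement_report <- function(provided, calculated, training_frames = integer(0)) {
  as_named <- function(x) {
    if (inherits(x, "score_set")) stats::setNames(x$score, x$frame) else x
  }
  p <- as_named(provided); cc <- as_named(calculated)
  shared <- intersect(names(p), names(cc))
  if (length(shared) == 0L)
    stop("invalid input: no shared frames to compare", call. = FALSE)
  held_out <- setdiff(shared, as.character(training_frames))
  if (length(held_out) == 0L)
    stop(paste("invalid input: every compared frame was used for training;",
               "nothing left to evaluate"), call. = FALSE)
  r_all <- pearson_correlation(p[shared], cc[shared])
  r_ex <- pearson_correlation(p[held_out], cc[held_out])
  structure(
    list(pearson_r = r_all,
         pearson_r_excluding_training = r_ex,
         mean_distance = mean(abs(p[held_out] - cc[held_out])),
         n_compared = length(held_out),
         strength_label = strength_label(r_ex)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report  r=%.3f  r(excl. training)=%.3f",
                     " (%s)  mean distance=%.3f  n=%d>\n"),
              x$pearson_r, x$pearson_r_excluding_training,
              x$strength_label, x$mean_distance, x$n_compared))
  invisible(x)
}

#' Training-size curve
#'
#' Re-runs the fit/score/evaluate loop for increasing training sizes: for
#' each `n` in `grid`, a stepwise model is fitted on the first `n` scored
#' samples, scores are calculated for every frame in `stats`, and agreement
#' with the manual scores is reported excluding the `n` training frames.
#' This reproduces the frame-count sweep used to judge how many frames a
#' user must score before calculated quality is reliable.
#'
#' @param samples Scored-sample data frame (see [scored_samples()]), ordered
#'   as the user scored them.
#' @param stats Statistics data frame for all frames to score.
#' @param grid Integer vector of training sizes.
#' @param variables Explanatory variables handed to the stepwise fit;
#'   defaults to every canonical statistic present in `samples`.
#' @return Data frame with one row per grid size: `n_training`, `pearson_r`,
#'   `pearson_r_excluding_training`, `mean_distance`, `n_compared`,
#'   `strength_label`, `stepwise_failed`. A stepwise failure at some size is
#'   recorded in the row (values `NA`), not raised.
#' @export
training_curve <- function(samples, stats, grid,
                           variables = intersect(stat_variable_names(),
                                                 names(samples))) {
  grid <- as.integer(grid)
  if (any(grid > nrow(samples)))
    stop(sprintf("invalid input: grid size(s) %s exceed the %d scored samples",
                 paste(grid[grid > nrow(samples)], collapse = ", "),
                 nrow(samples)), call. = FALSE)
  manual <- stats::setNames(samples$score, samples$frame)
  rows <- lapply(grid, function(n) {
    out <- data.frame(n_training = n, pearson_r = NA_real_,
                      pearson_r_excluding_training = NA_real_,
                      mean_distance = NA_real_, n_compared = NA_integer_,
                      strength_label = NA_character_, stepwise_failed = FALSE)
    train <- samples[seq_len(n), , drop = FALSE]
    attr(train, "config") <- attr(samples, "config")
    model <- tryCatch(
      suppressWarnings(stepwise_backward_eliminate(train, variables)),
      error = function(e) e)
    if (inherits(model, "error")) {
      out$stepwise_failed <- TRUE
      return(out)
    }
    calc <- suppressWarnings(calculate_scores(stats, model))
    rep_ <- agreement_report(manual, calc,
                             training_frames = samples$frame[seq_len(n)])
    out$pearson_r <- rep_$pearson_r
    out$pearson_r_excluding_training <- rep_$pearson_r_excluding_training
    out$mean_distance <- rep_$mean_distance
    out$n_compared <- rep_$n_compared
    out$strength_label <- rep_$strength_label
    out
  })
  do.call(rbind, rows)
}
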