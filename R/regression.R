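MODEL_FILE_VERSION <- "1"

#' Join manual scores onto frame statistics
#'
#' Builds the training table for [fit_mlr()] by joining a statistics table
#' (from [compute_frame_statistics()]) with manual quality scores.
#'
#' @param stats Statistics data frame with a `frame` column.
#' @param scores Data frame with columns `frame` and `score` (manual scores
#'   in 0-5; real values such as half-points are accepted), or a
#'   [score_set()].
#' @param set_label Optional label identifying the source image set.
#' @return Data frame of scored samples: the statistic columns plus `score`
#'   and `set`; the statistics configuration is carried in attribute
#'   `"config"`.
#' @export
scored_samples <- function(stats, scores, set_label = "set1") {
  if (inherits(scores, "score_set"))
    scores <- data.frame(frame = scores$frame, score = scores$score)
  if (!all(c("frame", "score") %in% names(scores)))
    stop("invalid input: scores need columns 'frame' and 'score'",
         call. = FALSE)
  if (any(scores$score < 0 | scores$score > 5))
    stop("invalid input: manual scores must lie in [0, 5]", call. = FALSE)
  idx <- match(scores$frame, stats$frame)
  if (anyNA(idx))
    stop(sprintf("invalid input: no statistics for frame(s) %s",
                 paste(scores$frame[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  out <- stats[idx, , drop = FALSE]
  out$score <- scores$score
  out$set <- set_label
  rownames(out) <- NULL
  attr(out, "config") <- attr(stats, "config")
  out
}

# Internal OLS on standardized predictors, reported on the original scale.
# Returns NULL-free quality_model.
ols_fit <- function(samples, variables, config, warn_aliased = TRUE) {
  y <- samples$score
  n <- length(y)
  X <- as.matrix(samples[, variables, drop = FALSE])
  centers <- colMeans(X)
  scales <- apply(X, 2, stats::sd)
  scales[scales == 0] <- 1          # constant columns alias the intercept
  Z <- sweep(sweep(X, 2, centers), 2, scales, "/")
  d <- data.frame(score = y, Z, check.names = FALSE)
  fm <- stats::lm(score ~ ., data = d)
  co <- stats::coef(fm)
  aliased <- names(co)[is.na(co)]
  aliased <- gsub("^`|`$", "", aliased)
  if (length(aliased)) {
    if (warn_aliased)
      warning(sprintf("dropping aliased variable(s): %s",
                      paste(aliased, collapse = ", ")), call. = FALSE)
    keep <- setdiff(variables, aliased)
    if (length(keep) == 0L)
      stop("invalid input: all explanatory variables are aliased",
           call. = FALSE)
    return(ols_fit(samples, keep, config, warn_aliased = warn_aliased))
  }
  sm <- summary(fm)
  tab <- sm$coefficients
  slope_rows <- rownames(tab) != "(Intercept)"
  vn <- gsub("^`|`$", "", rownames(tab)[slope_rows])
  beta_z <- tab[slope_rows, 1]
  se_z <- tab[slope_rows, 2]
  pv <- tab[slope_rows, 4]
  beta <- beta_z / scales[vn]
  se <- se_z / scales[vn]
  intercept <- unname(co["(Intercept)"]) - sum(beta_z * centers[vn] / scales[vn])
  names(beta) <- names(se) <- names(pv) <- vn
  structure(
    list(intercept = intercept,
         coefficients = beta,
         std_errors = se,
         p_values = pv,
         adjusted_r2 = sm$adj.r.squared,
         statistics_config = config,
         n_training = n),
    class = "quality_model")
}

#' Fit the quality model by multiple linear regression
#'
#' Ordinary least squares with the selected image statistics as explanatory
#' variables and the manual quality score as the dependent variable.
#' Predictors are standardized internally for numerical stability; reported
#' coefficients are on the original statistic scale. Per-coefficient
#' two-sided p-values come from the t distribution with n - k - 1 degrees of
#' freedom. Rank-deficient designs drop the aliased variables with a warning
#' naming them (on fixed-size stacks `integrated_density` is exactly
#' collinear with `mean` and is dropped this way).
#'
#' @param samples Scored-sample data frame from [scored_samples()] (or any
#'   data frame with a `score` column and the statistic columns).
#' @param variables Character vector of explanatory variable names; defaults
#'   to all eleven statistics.
#' @return A `quality_model`: list with `intercept`, named `coefficients`,
#'   `std_errors`, `p_values`, `adjusted_r2`, `statistics_config`,
#'   `n_training`.
#' @seealso [stepwise_backward_eliminate()], [calculate_scores()]
#' @export
fit_mlr <- function(samples, variables = stat_variable_names()) {
  if (length(variables) == 0L)
    stop("invalid input: no explanatory variables", call. = FALSE)
  missing_vars <- setdiff(variables, names(samples))
  if (length(missing_vars))
    stop(sprintf("invalid input: variable(s) not in samples: %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  if (!"score" %in% names(samples))
    stop("invalid input: samples need a 'score' column", call. = FALSE)
  n <- nrow(samples)
  if (n <= length(variables) + 1L)
    stop(sprintf(
      "invalid input: %d samples cannot support %d variables (need > k + 1)",
      n, length(variables)), call. = FALSE)
  ols_fit(samples, variables, attr(samples, "config"))
}

#' Backward stepwise elimination
#'
#' Automated variable selection: fit the full model, then repeatedly remove
#' the variable with the highest p-value above 0.05 and refit. If a removal
#' lowers the adjusted R-squared, the variable is returned to the model and
#' the process ends; it also ends when no p-value exceeds 0.05. Ties on the
#' maximal p-value remove the variable later in the canonical
#' [stat_variable_names()] order, for determinism. If removal would leave no
#' variables, the stepwise process fails and user intervention is required.
#'
#' @inheritParams fit_mlr
#' @param initial_variables Starting variable set.
#' @return A `quality_model` (see [fit_mlr()]).
#' @export
stepwise_backward_eliminate <- function(samples,
                                        initial_variables = stat_variable_names()) {
  model <- fit_mlr(samples, initial_variables)
  repeat {
    pv <- model$p_values
    pv[is.na(pv)] <- 1       # indistinguishable from noise
    if (all(pv <= 0.05))
      return(model)
    mx <- max(pv)
    cand <- names(pv)[pv == mx]
    ord <- match(cand, stat_variable_names())
    ord[is.na(ord)] <- length(stat_variable_names()) + seq_along(ord[is.na(ord)])
    victim <- cand[which.max(ord)]
    remaining <- setdiff(names(pv), victim)
    if (length(remaining) == 0L)
      stop(paste("stepwise failed: no variables are left;",
                 "user intervention is required"), call. = FALSE)
    refit <- fit_mlr(samples, remaining)
    if (refit$adjusted_r2 < model$adjusted_r2)
      return(model)          # removal made the model worse: revert and stop
    model <- refit
  }
}

#' @export
print.quality_model <- function(x, ...) {
  cat(sprintf("<quality_model  n=%d  adj.R2=%.4f>\n", x$n_training,
              x$adjusted_r2))
  tab <- data.frame(coefficient = x$coefficients,
                    std_error = x$std_errors,
                    p_value = x$p_values)
  cat(sprintf("  intercept: %.6g\n", x$intercept))
  print(round(tab, 6))
  invisible(x)
}

#' Calculated frame scores
#'
#' Ordered container of per-frame calculated quality scores.
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param score Numeric scores (unclamped; values outside 0-5 are legal
#'   before range adjustment).
#' @param range_adjusted Whether [range_adjust()] has been applied.
#' @param model The `quality_model` that produced the scores, if any.
#' @return An object of class `score_set`.
#' @export
score_set <- function(frame, score, range_adjusted = FALSE, model = NULL) {
  frame <- as.integer(frame)
  score <- as.numeric(score)
  if (length(frame) != length(score) || length(frame) == 0L)
    stop("invalid input: frame and score must be non-empty and equal length",
         call. = FALSE)
  structure(list(frame = frame, score = score,
                 range_adjusted = isTRUE(range_adjusted), model = model),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set  %d frames  range [%.3g, %.3g]%s>\n",
              length(x$frame), min(x$score), max(x$score),
              if (x$range_adjusted) "  range-adjusted" else ""))
  invisible(x)
}

#' @export
as.data.frame.score_set <- function(x, ...) {
  data.frame(frame = x$frame, score = x$score)
}

#' Predict quality scores for all frames
#'
#' Applies a fitted quality model to a statistics table:
#' \eqn{y_i = \beta_0 + \sum_n \beta_n X_{in}}. Scores are not clamped;
#' values below 0 or above 5 are legal and occur in practice (use
#' [range_adjust()] if a 0-5 range is required). A warning is emitted when
#' the statistics were computed under a different configuration than the
#' model was trained with.
#'
#' @param stats Statistics data frame from [compute_frame_statistics()].
#' @param model A `quality_model`.
#' @return A [score_set()].
#' @export
calculate_scores <- function(stats, model) {
  stopifnot(inherits(model, "quality_model"))
  vars <- names(model$coefficients)
  missing_vars <- setdiff(vars, names(stats))
  if (length(missing_vars))
    stop(sprintf("invalid input: statistics lack model variable(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  cfg <- attr(stats, "config")
  if (!is.null(cfg) && !is.null(model$statistics_config) &&
      !same_config(cfg, model$statistics_config))
    warning(paste("statistics configuration differs from the one the model",
                  "was trained with; scores may not be comparable"),
            call. = FALSE)
  X <- as.matrix(stats[, vars, drop = FALSE])
  s <- drop(model$intercept + X %*% model$coefficients)
  score_set(stats$frame, s, model = model)
}

#' Range adjustment of calculated scores
#'
#' Affine rescaling of calculated scores into the 0-5 range:
#' \eqn{C_{adj} = (C_i - C_{min}) / (C_{max} - C_{min}) \times 5}. Useful
#' when coefficients transferred from other image sets produce range-shifted
#' but well-ordered scores. Rank order is preserved and the operation is
#' idempotent. A degenerate range (all scores equal) maps every score to 0
#' with a warning rather than failing, so pipelines continue.
#'
#' @param scores A [score_set()].
#' @return A [score_set()] with `range_adjusted = TRUE`.
#' @export
range_adjust <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  lo <- min(scores$score); hi <- max(scores$score)
  adj <- if (hi == lo) {
    warning("degenerate score range: all scores equal; mapping to 0",
            call. = FALSE)
    rep(0, length(scores$score))
  } else {
    (scores$score - lo) / (hi - lo) * 5
  }
  score_set(scores$frame, adj, range_adjusted = TRUE, model = scores$model)
}

#' Consolidate scored samples across image sets
#'
#' Concatenates the first `frames_per_set` scored samples of each image set
#' into one training table, e.g. three sets of 20 frames give 60 samples.
#' Consolidated coefficients can score sets without fresh manual input. All
#' sets must share one statistics configuration.
#'
#' @param samplesets Named list of scored-sample data frames (see
#'   [scored_samples()]).
#' @param frames_per_set Number of leading samples taken from each set.
#' @return A scored-sample data frame of `length(samplesets) *
#'   frames_per_set` rows; `set` records the origin of each row.
#' @export
consolidate_samples <- function(samplesets, frames_per_set = 20L) {
  if (!is.list(samplesets) || length(samplesets) == 0L)
    stop("invalid input: empty sample set list", call. = FALSE)
  labels <- names(samplesets)
  if (is.null(labels))
    labels <- paste0("set", seq_along(samplesets))
  cfgs <- lapply(samplesets, attr, "config")
  ref <- cfgs[[1]]
  for (i in seq_along(cfgs)) {
    if (is.null(cfgs[[i]]) != is.null(ref) ||
        (!is.null(ref) && !same_config(cfgs[[i]], ref)))
      stop("invalid input: statistics configuration differs across sets",
           call. = FALSE)
  }
  pieces <- vector("list", length(samplesets))
  for (i in seq_along(samplesets)) {
    s <- samplesets[[i]]
    if (nrow(s) < frames_per_set)
      stop(sprintf("invalid input: set '%s' has %d < %d samples",
                   labels[i], nrow(s), frames_per_set), call. = FALSE)
    piece <- s[seq_len(frames_per_set), , drop = FALSE]
    piece$set <- if (!is.null(s$set) && length(unique(s$set)) == 1L)
      s$set[1] else labels[i]
    pieces[[i]] <- piece
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "config") <- ref
  out
}

#' Save / load model coefficients
#'
#' Persists a fitted `quality_model` (the "coefficients") as JSON so it can
#' be applied to other similar image sets without new manual scoring. The
#' statistics configuration and the statistic conventions (excess kurtosis,
#' entropy in bits) are stored alongside the coefficients so training and
#' scoring cannot silently disagree.
#'
#' @param model A `quality_model`.
#' @param path File path of the JSON coefficient file.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `quality_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "quality_model"))
  payload <- list(
    version = MODEL_FILE_VERSION,
    variables = names(model$coefficients),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    std_errors = as.list(model$std_errors),
    p_values = as.list(model$p_values),
    adjusted_r2 = model$adjusted_r2,
    n_training = model$n_training,
    conventions = list(kurtosis = "excess", entropy = "bits",
                       moments = "population"),
    statistics_config = list(
      pixel_step = model$statistics_config$pixel_step,
      normalize = model$statistics_config$normalize,
      sid_grid = model$statistics_config$sid_grid))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read model file '%s'", path), call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("version", "variables", "intercept", "coefficients",
                "p_values", "adjusted_r2", "statistics_config", "n_training")
  miss <- setdiff(required, names(j))
  if (length(miss))
    stop(sprintf("model file schema mismatch: missing field(s) %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!identical(as.character(j$version), MODEL_FILE_VERSION))
    stop(sprintf("model file version '%s' is not supported (expected '%s')",
                 j$version, MODEL_FILE_VERSION), call. = FALSE)
  unknown <- setdiff(j$variables, stat_variable_names())
  if (length(unknown))
    stop(sprintf("model file contains unknown variable(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- stats_config(pixel_step = j$statistics_config$pixel_step,
                      normalize = j$statistics_config$normalize,
                      sid_grid = unlist(j$statistics_config$sid_grid))
  coefs <- unlist(j$coefficients)[j$variables]
  pvals <- unlist(j$p_values)[j$variables]
  ses <- if (!is.null(j$std_errors)) unlist(j$std_errors)[j$variables]
         else rep(NA_real_, length(coefs))
  names(coefs) <- names(pvals) <- names(ses) <- j$variables
  structure(
    list(intercept = j$intercept,
         coefficients = coefs,
         std_errors = ses,
         p_values = pvals,
         adjusted_r2 = j$adjusted_r2,
         statistics_config = cfg,
         n_training = as.integer(j$n_training)),
    class = "quality_model")
}
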