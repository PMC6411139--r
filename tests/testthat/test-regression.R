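test_that("exact linear relations are fitted exactly", {
  set.seed(31)
  d <- data.frame(mean = runif(12, 0, 100))
  d$score <- 2 + 3 * d$mean
  m <- suppressWarnings(fit_mlr(d, "mean"))  # lm flags the perfect fit
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(unname(m$coefficients["mean"]), 3, tolerance = 1e-9)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-9)
  # scoring the training frames reproduces the manual scores
  st <- data.frame(frame = 0:11, mean = d$mean)
  sc <- calculate_scores(st, m)
  expect_equal(sc$score, d$score, tolerance = 1e-10)
})

test_that("constant scores yield zero slopes and the constant intercept", {
  set.seed(32)
  d <- data.frame(mean = runif(10), std = runif(10), score = 3.5)
  m <- suppressWarnings(fit_mlr(d, c("mean", "std")))
  expect_equal(unname(m$coefficients), c(0, 0), tolerance = 1e-12)
  expect_equal(m$intercept, 3.5, tolerance = 1e-12)
})

test_that("coefficients equal the normal-equations solution", {
  set.seed(33)
  for (rep in 1:5) {
    n <- 30
    d <- data.frame(mean = runif(n, 0, 50), std = runif(n, 0, 10),
                    entropy = runif(n, 0, 8), sid = runif(n, 0, 100))
    d$score <- 1 + 0.05 * d$mean - 0.2 * d$std + 0.3 * d$entropy +
      0.01 * d$sid + rnorm(n, 0, 0.5)
    vars <- c("mean", "std", "entropy", "sid")
    m <- fit_mlr(d, vars)
    ref <- ols_brute(d[vars], d$score)
    expect_equal(m$intercept, unname(ref[1]), tolerance = 1e-8)
    expect_equal(unname(m$coefficients[vars]), unname(ref[-1]),
                 tolerance = 1e-8)
  }
})

test_that("aliased variables are dropped with a warning naming them", {
  set.seed(34)
  d <- data.frame(mean = runif(20, 0, 50))
  d$integrated_density <- d$mean * 100   # exactly collinear
  d$score <- 1 + 0.1 * d$mean + rnorm(20, 0, 0.1)
  expect_warning(m <- fit_mlr(d, c("mean", "integrated_density")),
                 "integrated_density")
  expect_named(m$coefficients, "mean")
})

test_that("too few samples or empty variable sets are rejected", {
  d <- data.frame(mean = runif(4), std = runif(4), entropy = runif(4),
                  score = runif(4))
  expect_error(fit_mlr(d, c("mean", "std", "entropy")), "samples")
  expect_error(fit_mlr(d, character(0)), "variables")
  expect_error(fit_mlr(d, "absent_stat"), "absent_stat")
})

test_that("stepwise removes planted noise and keeps the informative variable", {
  set.seed(35)
  n <- 40
  d <- data.frame(mean = runif(n, 0, 50), entropy = runif(n, 0, 8))
  d$score <- 2 + 3 * d$mean + rnorm(n, 0, 0.1)  # entropy is pure noise
  m <- stepwise_backward_eliminate(d, c("mean", "entropy"))
  expect_true("mean" %in% names(m$coefficients))
  expect_false("entropy" %in% names(m$coefficients))
})

test_that("stepwise exits immediately when everything is significant", {
  set.seed(36)
  n <- 60
  d <- data.frame(mean = runif(n, 0, 50), std = runif(n, 0, 10))
  d$score <- 1 + 2 * d$mean - 3 * d$std + rnorm(n, 0, 0.05)
  full <- fit_mlr(d, c("mean", "std"))
  expect_true(all(full$p_values <= 0.05))
  sw <- stepwise_backward_eliminate(d, c("mean", "std"))
  expect_equal(sw$coefficients, full$coefficients)
  expect_equal(sw$adjusted_r2, full$adjusted_r2)
})

test_that("stepwise fails loudly when removal would empty the model", {
  set.seed(37)
  n <- 30
  d <- data.frame(mean = runif(n), score = rnorm(n))
  expect_gt(fit_mlr(d, "mean")$p_values[["mean"]], 0.05)
  expect_error(stepwise_backward_eliminate(d, "mean"),
               "user intervention is required")
})

test_that("stepwise result is valid: all significant, or last removal reverted", {
  set.seed(38)
  for (rep in 1:8) {
    n <- 45
    d <- data.frame(mean = runif(n, 0, 50), std = runif(n, 0, 10),
                    entropy = runif(n, 0, 8), skewness = rnorm(n),
                    sid = runif(n, 0, 100))
    d$score <- 1 + 0.08 * d$mean + 0.3 * d$entropy + rnorm(n, 0, 0.3)
    vars <- c("mean", "std", "entropy", "skewness", "sid")
    m <- tryCatch(stepwise_backward_eliminate(d, vars),
                  error = function(e) NULL)
    if (is.null(m)) next
    if (any(m$p_values > 0.05)) {
      # the offending variable must be protected: removing the worst one
      # has to lower adjusted R-squared
      pv <- m$p_values
      victim <- names(pv)[which.max(pv)]
      refit <- fit_mlr(d, setdiff(names(pv), victim))
      expect_lt(refit$adjusted_r2, m$adjusted_r2)
    } else {
      expect_true(all(m$p_values <= 0.05))
    }
  }
})

test_that("score calculation is the affine model equation, unclamped", {
  st <- data.frame(frame = 0:1, mean = c(3, 10))
  m <- structure(list(intercept = 1, coefficients = c(mean = 2),
                      std_errors = c(mean = 0), p_values = c(mean = 0),
                      adjusted_r2 = 1, statistics_config = NULL,
                      n_training = 5L), class = "quality_model")
  sc <- calculate_scores(st, m)
  expect_equal(sc$score, c(7, 21))
  m$intercept <- -1; m$coefficients <- c(mean = 0)
  expect_equal(calculate_scores(st, m)$score, c(-1, -1))  # below zero legal
  m$coefficients <- c(sid = 1)
  expect_error(calculate_scores(st, m), "sid")
})

test_that("scoring is affine in the statistics", {
  set.seed(39)
  m <- structure(list(intercept = 0.5,
                      coefficients = c(mean = 0.2, std = -0.4, entropy = 1.1),
                      std_errors = NULL, p_values = NULL, adjusted_r2 = NA,
                      statistics_config = NULL, n_training = 10L),
                 class = "quality_model")
  a <- data.frame(frame = 0L, mean = 4, std = 2, entropy = 6)
  b <- data.frame(frame = 0L, mean = 10, std = 1, entropy = 3)
  avg <- data.frame(frame = 0L, mean = 7, std = 1.5, entropy = 4.5)
  expect_equal(calculate_scores(avg, m)$score,
               (calculate_scores(a, m)$score + calculate_scores(b, m)$score) / 2)
})

test_that("range adjustment maps to [0,5], preserves rank, is idempotent", {
  ss <- score_set(0:1, c(18, 34))
  expect_equal(range_adjust(ss)$score, c(0, 5))
  ss3 <- score_set(0:2, c(18, 26, 34))
  expect_equal(range_adjust(ss3)$score, c(0, 2.5, 5))
  set.seed(40)
  for (rep in 1:20) {
    x <- rnorm(30, sd = 10)
    adj <- range_adjust(score_set(seq_along(x) - 1L, x))
    expect_equal(min(adj$score), 0)
    expect_equal(max(adj$score), 5)
    expect_identical(order(adj$score), order(x))
    twice <- range_adjust(adj)
    expect_equal(twice$score, adj$score, tolerance = 1e-12)
  }
  expect_warning(flat <- range_adjust(score_set(0:2, c(4, 4, 4))),
                 "degenerate")
  expect_equal(flat$score, c(0, 0, 0))
})

test_that("consolidation concatenates the first n samples of each set", {
  set.seed(41)
  mk <- function(label, n) {
    d <- data.frame(frame = 0:(n - 1), mean = runif(n), score = runif(n, 0, 5),
                    set = label)
    attr(d, "config") <- stats_config()
    d
  }
  three <- list(s1 = mk("s1", 25), s2 = mk("s2", 30), s3 = mk("s3", 20))
  out <- consolidate_samples(three, 20)
  expect_equal(nrow(out), 60)
  expect_equal(as.vector(table(out$set)), c(20, 20, 20))
  expect_equal(out$mean[1:20], three$s1$mean[1:20])
  one <- consolidate_samples(three["s2"], 20)
  expect_equal(one$mean, three$s2$mean[1:20])
  two <- consolidate_samples(list(a = mk("a", 15), b = mk("b", 15)), 15)
  expect_equal(nrow(two), 30)
  expect_equal(sum(two$set == "a"), 15)
  expect_error(consolidate_samples(three, 24), "s3")
  mixed <- three
  attr(mixed$s2, "config") <- stats_config(pixel_step = 5)
  expect_error(consolidate_samples(mixed, 15), "configuration")
})

test_that("models round-trip through JSON coefficient files", {
  set.seed(42)
  d <- data.frame(mean = runif(20, 0, 50), entropy = runif(20, 0, 8))
  d$score <- 1 + 0.1 * d$mean + 0.2 * d$entropy + rnorm(20, 0, 0.1)
  attr(d, "config") <- stats_config(pixel_step = 2, normalize = FALSE,
                                    sid_grid = c(3, 5))
  m <- fit_mlr(d, c("mean", "entropy"))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$p_values, m$p_values)
  expect_equal(m2$std_errors, m$std_errors)
  expect_equal(m2$adjusted_r2, m$adjusted_r2)
  expect_equal(m2$n_training, m$n_training)
  expect_equal(m2$statistics_config$pixel_step, 2L)
  expect_false(m2$statistics_config$normalize)
  expect_equal(m2$statistics_config$sid_grid, c(3L, 5L))
})

test_that("corrupt or mismatched model files are rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  good <- list(version = "1", variables = "mean", intercept = 0,
               coefficients = list(mean = 1), p_values = list(mean = 0.01),
               std_errors = list(mean = 0.1), adjusted_r2 = 0.9,
               n_training = 10,
               statistics_config = list(pixel_step = 3, normalize = TRUE,
                                        sid_grid = c(4, 4)))
  bad <- good; bad$variables <- "mystery_stat"
  bad$coefficients <- list(mystery_stat = 1)
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_model(path), "mystery_stat")
  bad2 <- good; bad2$version <- "99"
  jsonlite::write_json(bad2, path, auto_unbox = TRUE)
  expect_error(load_model(path), "version")
  bad3 <- good[setdiff(names(good), "p_values")]
  jsonlite::write_json(bad3, path, auto_unbox = TRUE)
  expect_error(load_model(path), "p_values")
})

test_that("config mismatch between model and statistics warns at scoring", {
  set.seed(43)
  d <- data.frame(mean = runif(15, 0, 50))
  d$score <- 2 + 0.05 * d$mean + rnorm(15, 0, 0.1)
  attr(d, "config") <- stats_config(normalize = TRUE)
  m <- fit_mlr(d, "mean")
  st <- data.frame(frame = 0:4, mean = runif(5, 0, 50))
  attr(st, "config") <- stats_config(normalize = FALSE)
  expect_warning(calculate_scores(st, m), "configuration")
})

test_that("coefficients recover a known score-generating model", {
  b <- benchmark_fixture()
  st <- b$stats[1:50, ]
  truth <- c(intercept = 1, mean = 0.002, sum_pixel_ramp = 0.004,
             entropy = -0.3)
  set.seed(44)
  d <- data.frame(mean = st$mean, sum_pixel_ramp = st$sum_pixel_ramp,
                  entropy = st$entropy)
  d$score <- truth["intercept"] + truth["mean"] * d$mean +
    truth["sum_pixel_ramp"] * d$sum_pixel_ramp +
    truth["entropy"] * d$entropy + rnorm(50, 0, 0.1)
  m <- fit_mlr(d, c("mean", "sum_pixel_ramp", "entropy"))
  for (v in c("mean", "sum_pixel_ramp", "entropy"))
    expect_lt(abs(m$coefficients[[v]] - truth[[v]]), 3 * m$std_errors[[v]])
})
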