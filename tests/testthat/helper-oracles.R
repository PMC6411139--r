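# Independent brute-force oracles. These re-derive every quantity with plain
# loops / textbook formulas and must stay independent of the package code
# paths they check.

# frame helper ---------------------------------------------------------------

int_frame <- function(values, nrow, bit_depth = 8L, frame_index = 0L) {
  frame_image(matrix(as.integer(values), nrow = nrow),
              bit_depth = bit_depth, frame_index = frame_index)
}

random_frame <- function(width, height, bit_depth = 8L, frame_index = 0L) {
  int_frame(sample.int(2L^bit_depth, width * height, replace = TRUE) - 1L,
            nrow = height, bit_depth = bit_depth, frame_index = frame_index)
}

# sum pixel ramp, explicit double loop over the 0-based sampling lattice
ramp_brute <- function(px, p, normalize) {
  H <- nrow(px); W <- ncol(px)
  s <- 0; count <- 0L
  for (x0 in seq(0L, W - 1L, by = p)) {
    y0 <- p
    while (y0 <= H - 1L) {
      s <- s + abs(px[y0 + 1L, x0 + 1L] - px[y0 - p + 1L, x0 + 1L])
      count <- count + 1L
      y0 <- y0 + p
    }
  }
  if (normalize) s / count else s
}

# SID, explicit loops; returns NULL when a segment receives no sampled pixel
sid_brute <- function(px, p, normalize, gr, gc) {
  H <- nrow(px); W <- ncol(px)
  rbase <- H %/% gr; cbase <- W %/% gc
  if (rbase == 0L || cbase == 0L) return(NULL)
  sums <- matrix(0, gr, gc); cnts <- matrix(0L, gr, gc)
  for (x0 in seq(0L, W - 1L, by = p)) {
    y0 <- p
    while (y0 <= H - 1L) {
      r <- min(y0 %/% rbase, gr - 1L) + 1L
      cc <- min(x0 %/% cbase, gc - 1L) + 1L
      sums[r, cc] <- sums[r, cc] + px[y0 + 1L, x0 + 1L]
      cnts[r, cc] <- cnts[r, cc] + 1L
      y0 <- y0 + p
    }
  }
  if (any(cnts == 0L)) return(NULL)
  v <- if (normalize) as.vector(sums / cnts) else as.vector(sums)
  sqrt(mean((v - mean(v))^2))
}

# OLS by the normal equations
ols_brute <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# textbook Pearson correlation
pearson_brute <- function(a, b) {
  n <- length(a)
  num <- sum(a * b) / n - mean(a) * mean(b)
  den <- sqrt(sum(a^2) / n - mean(a)^2) * sqrt(sum(b^2) / n - mean(b)^2)
  num / den
}

# per-window argmax by enumeration
window_select_brute <- function(scores, window) {
  n <- length(scores)
  picks <- integer(0)
  start <- 1L
  while (start <= n) {
    end <- min(start + window - 1L, n)
    best <- start
    for (i in start:end) if (scores[i] > scores[best]) best <- i
    picks <- c(picks, best - 1L)   # 0-based
    start <- end + 1L
  }
  picks
}

# smallest window size (up to floor(N/4)) with a passing frame per window
min_window_brute <- function(scores, target) {
  n <- length(scores)
  for (w in seq_len(max(1L, n %/% 4L))) {
    ok <- TRUE
    start <- 1L
    while (start <= n) {
      end <- min(start + w - 1L, n)
      if (!any(scores[start:end] >= target)) { ok <- FALSE; break }
      start <- end + 1L
    }
    if (ok) return(w)
  }
  NA_integer_
}
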