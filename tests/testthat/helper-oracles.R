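# Brute-force morphological oracles built directly from the definitions
# (min/max over translates with background-0 padding), independent of the
# compiled implementation.

shift_cols <- function(m, by) {
  # content moved `by` columns towards lower indices (by >= 0), 0-fill
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  if (by < n) out[, seq_len(n - by)] <- m[, seq_len(n - by) + by]
  out
}

shift_cols_right <- function(m, by) {
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  if (by < n) out[, seq_len(n - by) + by] <- m[, seq_len(n - by)]
  out
}

oracle_line_opening <- function(m, k, horizontal) {
  if (!horizontal) return(t(oracle_line_opening(t(m), k, TRUE)))
  er <- shift_cols(m, 0)
  for (i in seq_len(k - 1)) er <- pmin(er, shift_cols(m, i))
  if (k > 1) { # windows running past the right edge include background 0
    n <- ncol(m)
    drop <- (n - k + 2):n
    er[, drop[drop >= 1]] <- 0
  }
  di <- er
  for (j in seq_len(k - 1)) di <- pmax(di, shift_cols_right(er, j))
  di
}

oracle_square_opening <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  er <- m
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    if (i == 0 && j == 0) next
    er <- pmin(er, shift_cols(t(shift_cols(t(m), i)), j))
  }
  if (k > 1) {
    er[(nr - k + 2):nr, ] <- 0
    er[, (nc - k + 2):nc] <- 0
  }
  di <- er
  for (i in 0:(k - 1)) for (j in 0:(k - 1)) {
    if (i == 0 && j == 0) next
    di <- pmax(di, shift_cols_right(t(shift_cols_right(t(er), i)), j))
  }
  di
}

# closed-form OLS on (x, y): slope, intercept, r2 from the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sxy^2 / (sxx * syy))
}
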