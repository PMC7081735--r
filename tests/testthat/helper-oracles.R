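# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the implementation they check.

brute_argmax_depth <- function(column, axial_spacing) {
  best <- 1L
  for (i in seq_along(column)) if (column[i] > column[best]) best <- i
  (best - 1) * axial_spacing
}

# First strict local minimum scanning upward (decreasing index) from the
# sclera row. Assumes no ties (continuous-valued test columns).
brute_first_valley <- function(column, sclera_depth, axial_spacing) {
  start <- min(floor(sclera_depth / axial_spacing), length(column) - 1L)
  if (start < 2L) return(NA_real_)
  for (i in seq(start, 2L)) {  # first index above the sclera, scanning up
    if (column[i] < column[i - 1L] && column[i] < column[i + 1L]) {
      return((i - 1) * axial_spacing)
    }
  }
  NA_real_
}

brute_best_peak <- function(column, orl_depth, min_irl_offset, axial_spacing) {
  best_val <- -Inf
  best_depth <- NA_real_
  for (i in 2:(length(column) - 1L)) {
    d <- (i - 1) * axial_spacing
    if (orl_depth - d > min_irl_offset &&
        column[i] > column[i - 1L] && column[i] > column[i + 1L]) {
      if (column[i] > best_val ||
          (column[i] == best_val && d > best_depth)) {
        best_val <- column[i]
        best_depth <- d
      }
    }
  }
  best_depth
}

# One-way ANOVA from raw sums of squares.
brute_anova <- function(groups) {
  all_y <- unlist(groups)
  grand <- mean(all_y)
  ss_between <- 0
  ss_within <- 0
  for (g in groups) {
    ss_between <- ss_between + length(g) * (mean(g) - grand)^2
    ss_within <- ss_within + sum((g - mean(g))^2)
  }
  df1 <- length(groups) - 1L
  df2 <- length(all_y) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Random slope-like columns with well-separated extrema: smoothed noise.
random_smooth_column <- function(seed, n = 240) {
  set.seed(seed)
  gaussian_smooth(cumsum(rnorm(n)), sigma_um = 6, spacing_um = 1)
}
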