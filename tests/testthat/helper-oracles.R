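# Shared fixtures and independent oracles used across test files.

# A clean alternating red/blue log: red frames carry r_level, blue
# frames b_level, with 2% crosstalk elsewhere.
make_alternating_log <- function(n = 60, frame_rate = 30,
                                 r_level = 120, b_level = 80,
                                 labeled = FALSE) {
  illum <- rep(c("red", "blue"), length.out = n)
  r <- ifelse(illum == "red", r_level, 0.02 * b_level)
  b <- ifelse(illum == "blue", b_level, 0.02 * r_level)
  g <- 0.02 * ifelse(illum == "red", r_level, b_level)
  frame_log(data.frame(timestamp = (seq_len(n) - 1) / frame_rate,
                       r = r, g = g, b = b,
                       illum = if (labeled) illum else "unknown"),
            frame_rate = frame_rate)
}

# Brute-force one-way ANOVA straight from the sum-of-squares
# definitions, no shared code with the implementation.
brute_force_anova_f <- function(groups) {
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (xi in g) ssw <- ssw + (xi - mean(g))^2
  }
  (ssb / (length(groups) - 1)) / (ssw / (length(all_x) - length(groups)))
}

# Exhaustive-loop nearest-reference classification.
brute_force_class <- function(patch, strip) {
  best <- Inf
  best_k <- NA
  for (k in seq_len(nrow(strip))) {
    d <- sqrt(sum((patch - strip[k, ])^2))
    if (d < best) {
      best <- d
      best_k <- k
    }
  }
  best_k
}
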