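# Brute-force oracle for the power-law fit: dense grid search over
# (log a, b) minimising the sum of squared log residuals, +/-50% around a
# supplied centre. Independent of the lm-based implementation path.
grid_search_power_law <- function(weights, values, centre_a, centre_b,
                                  n = 201) {
  la <- seq(log(centre_a * 0.5), log(centre_a * 1.5), length.out = n)
  bs <- seq(centre_b - abs(centre_b) * 0.5, centre_b + abs(centre_b) * 0.5,
            length.out = n)
  lw <- log(weights)
  lv <- log(values)
  best <- c(a = NA_real_, b = NA_real_, sse = Inf)
  for (b in bs) {
    # for fixed b the optimal log a is the mean residual, but the oracle
    # stays a pure grid: evaluate every (la, b) cell
    resid0 <- lv - b * lw
    sse <- vapply(la, function(l) sum((resid0 - l)^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < best["sse"]) best <- c(a = exp(la[i]), b = b, sse = sse[i])
  }
  best
}

grid_resolution <- function(centre_a, centre_b, n = 201) {
  c(a = (log(centre_a * 1.5) - log(centre_a * 0.5)) / (n - 1) * centre_a,
    b = abs(centre_b) / (n - 1))
}
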